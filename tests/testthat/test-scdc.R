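test_that("the threshold sweep matches an exhaustive brute-force oracle", {
  # worked example: band/below tie resolved by smallest lower threshold
  x <- c(1, 2, 3, 10, 11, 12); y <- c(1, 0, 1, 0, 0, 0)
  r <- sweep_single_feature_thresholds(x, y, grid = 10)
  o <- brute_force_sweep(x, y, grid = 10)
  expect_equal(r$accuracy / 100, o$acc)
  expect_equal(r$mode, o$mode)
  expect_equal(r$lower, o$lower)
  expect_equal(r$upper, o$upper)

  # random small datasets against the oracle
  set.seed(14)
  for (i in 1:20) {
    xx <- round(stats::rlnorm(40), 2)
    yy <- stats::rbinom(40, 1, 0.4)
    if (length(unique(yy)) < 2) next
    rr <- sweep_single_feature_thresholds(xx, yy, grid = 25)
    oo <- brute_force_sweep(xx, yy, grid = 25)
    expect_equal(rr$accuracy / 100, oo$acc, tolerance = 1e-12)
    expect_equal(rr$lower, oo$lower)
    expect_equal(rr$upper, oo$upper)
  }

  # perfectly separated feature reaches 100%
  xs <- c(1, 2, 3, 21, 22, 23); ys <- c(0, 0, 0, 1, 1, 1)
  expect_equal(sweep_single_feature_thresholds(xs, ys)$accuracy, 100)

  # label-independent feature cannot beat the base rate by much
  set.seed(15)
  xi <- stats::rnorm(4000); yi <- rep(c(0, 1), 2000)
  ri <- sweep_single_feature_thresholds(xi, yi, grid = 50)
  expect_lt(ri$accuracy, 56)

  expect_error(sweep_single_feature_thresholds(1:5, rep(1, 5)), "degenerate")
})

test_that("applying a rule reproduces its training accuracy", {
  set.seed(16)
  x <- stats::rlnorm(200); y <- as.integer(x > 1.2)
  y[1:20] <- 1 - y[1:20] # some noise
  r <- sweep_single_feature_thresholds(x, y, grid = 50)
  expect_equal(100 * mean(apply_threshold_rule(r, x) == y), r$accuracy)
})

test_that("boosting beats the best stump on XOR data and reduces to a stump", {
  d <- xor_dataset(n = 400, seed = 2)
  # best single-feature stump accuracy (brute force, either feature)
  stump_acc <- max(brute_force_sweep(d$x[, 1], d$y, grid = 50)$acc,
                   brute_force_sweep(d$x[, 2], d$y, grid = 50)$acc)
  expect_lt(stump_acc, 0.62) # XOR defeats single thresholds

  m <- train_boosted_ensemble(d$x, d$y, cfg = ensemble_config(n_estimators = 50,
                                                              max_depth = 2))
  acc <- mean(predict(m, d$x) == d$y)
  expect_gt(acc, stump_acc + 0.2)

  # a single depth-1 round equals that one tree's prediction
  m1 <- train_boosted_ensemble(d$x, d$y,
                               cfg = ensemble_config(n_estimators = 1,
                                                     max_depth = 1))
  expect_equal(length(m1$trees), 1L)
  one_tree <- as.integer(
    predict(m1$trees[[1]], as.data.frame(d$x), type = "class") == "1")
  expect_equal(predict(m1, d$x), one_tree)
})

test_that("boosting is deterministic, keeps stage errors below chance, and its bound shrinks", {
  st <- generate_fbp_stream(fbp_gen_config(n_samples = 400, seed = 31))
  cfg <- ensemble_config(n_estimators = 25)
  m1 <- train_boosted_ensemble(st, cfg = cfg, seed = 9)
  m2 <- train_boosted_ensemble(st, cfg = cfg, seed = 9)
  expect_identical(predict(m1, st), predict(m2, st))

  expect_true(all(m1$stage_errors < 0.5))
  expect_true(all(diff(m1$bound) <= 1e-12)) # exponential bound non-increasing
  # ensemble training error is dominated by the bound
  expect_true(all(m1$train_error <= m1$bound + 1e-12))
})

test_that("the feed-forward network separates blob data and is seed-reproducible", {
  set.seed(18)
  n <- 2000
  y <- stats::rbinom(n, 1, 0.5)
  x <- matrix(stats::rnorm(n * 10), n, 10)
  x[, 1] <- x[, 1] + 4 * y
  x[, 2] <- x[, 2] - 3 * y
  colnames(x) <- paste0("v", 1:10)
  tr <- sample(n, 1500)
  cfg <- network_config(epochs = 40, seed = 4)
  m <- train_network(x[tr, ], y[tr], cfg)
  expect_gt(mean(predict(m, x[-tr, ]) == y[-tr]), 0.95)

  sc <- predict(m, x[-tr, ], type = "score")
  expect_true(all(sc >= 0 & sc <= 1))

  m2 <- train_network(x[tr, ], y[tr], cfg)
  expect_identical(m$W, m2$W)
  expect_identical(predict(m, x), predict(m2, x))

  expect_error(train_network(x, rep(1, n)), "degenerate")
})

test_that("classification metrics satisfy the printed-arithmetic identities", {
  m <- classification_metrics(26, 3, 1, 0)
  expect_equal(m$precision, 100 * 26 / 29)
  expect_equal(m$recall, 100 * 26 / 27)

  # harmonic-mean and count forms of F1 agree for random count tuples
  set.seed(19)
  for (i in 1:2000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp == 0 || tp + fp == 0 || tp + fn == 0) next
    mm <- classification_metrics(tp, fp, fn, sample(0:50, 1))
    f1_hm <- 2 * (mm$precision / 100) * (mm$recall / 100) /
      (mm$precision / 100 + mm$recall / 100)
    expect_equal(mm$f1, f1_hm, tolerance = 1e-12)
  }

  # degenerate counts yield explicit undefined markers, not zeros
  d <- classification_metrics(0, 0, 0, 10)
  expect_equal(d$accuracy, 100)
  expect_true(is.na(d$precision))
  expect_true(is.na(d$recall))
  expect_false(identical(d$precision, 0))
})

test_that("the confidence bound and summary helpers do plain arithmetic", {
  expect_equal(ci95_upper(5, 0, 12), 5)
  expect_equal(ci95_upper(10, 2, 4), 10 + 1.96)
  expect_error(ci95_upper(1, 1, 0), "n >= 1")
  expect_equal(coefficient_of_variation(50, 5), 0.1)
  expect_equal(percent_change(80, 100), 25)
  cov5 <- stats::sd(c(84, 85, 86, 85, 85)) / mean(c(84, 85, 86, 85, 85))
  expect_equal(coefficient_of_variation(mean(c(84, 85, 86, 85, 85)),
                                        stats::sd(c(84, 85, 86, 85, 85))),
               cov5)
})

test_that("five-fold CV partitions the data and is order-invariant given the seed", {
  st <- generate_fbp_stream(fbp_gen_config(n_samples = 200, seed = 23))
  trainer <- function(x, y)
    train_boosted_ensemble(x, y, cfg = ensemble_config(n_estimators = 5,
                                                       max_depth = 2))
  cv <- five_fold_cv(st, trainer = trainer, seed = 3)
  # every index is tested exactly once
  tested <- sort(unname(unlist(cv$folds)))
  expect_equal(tested, 1:200)
  expect_equal(lengths(cv$folds), rep(40L, 5), ignore_attr = TRUE)
  expect_equal(cv$mean_accuracy, mean(cv$accuracy))
  expect_equal(cv$cov, cv$sd_accuracy / cv$mean_accuracy)

  # n = 10: five folds of two (constant function-model, split shape only)
  st10 <- st[1:10, ]
  st10$label <- rep(c(0, 1), 5)
  cv10 <- five_fold_cv(st10, trainer = function(x, y) {
    function(newdata) rep(1L, nrow(newdata))
  }, seed = 1)
  expect_equal(lengths(cv10$folds), rep(2L, 5), ignore_attr = TRUE)

  expect_error(five_fold_cv(st[1:4, ], trainer = trainer, seed = 1),
               "at least 5")
})

test_that("stream decoding debounces consecutive positives and resets after events", {
  canned <- c(0, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0)
  fake_model <- function(newdata) canned[seq_len(nrow(newdata))]

  stream <- data.frame(timestamp = (0:11) / 8,
                       f = stats::runif(12))
  ev3 <- decode_stream(fake_model, stream, debounce_k = 3)
  # run of three at samples 2-4 fires at sample 4 (index 4, time 3/8);
  # the long run of six fires twice (after reset)
  expect_equal(ev3$index, c(4, 8, 11))
  expect_equal(ev3$time, c(3, 7, 10) / 8)

  ev1 <- decode_stream(fake_model, stream, debounce_k = 1)
  expect_equal(ev1$index, which(canned == 1))

  zero_model <- function(newdata) rep(0L, nrow(newdata))
  expect_equal(nrow(decode_stream(zero_model, stream, debounce_k = 3)), 0)
  expect_gte(attr(ev3, "latency_per_sample"), 0)
})
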