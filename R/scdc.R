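#' Boosted-ensemble hyperparameters
#'
#' Defaults follow the tuned trigger classifier: 300 estimators, unit
#' learning rate, trees of maximum depth 7.
#'
#' @param n_estimators Number of boosting rounds (>= 1).
#' @param learning_rate Stage-weight scale (> 0).
#' @param max_depth Maximum tree depth (>= 1).
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_estimators = 300L, learning_rate = 1,
                            max_depth = 7L) {
  stopifnot(n_estimators >= 1, learning_rate > 0, max_depth >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth)),
            class = "ensemble_config")
}

#' Feed-forward network hyperparameters
#'
#' Two rectified-linear hidden layers (80 and 40 units) and a sigmoid output,
#' trained for 100 epochs with batches of 32.
#'
#' @param hidden Hidden layer sizes.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return Object of class `network_config`.
#' @export
network_config <- function(hidden = c(80L, 40L), epochs = 100L,
                           batch_size = 32L, learning_rate = 1e-3,
                           seed = 1L) {
  stopifnot(all(hidden >= 1), epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "network_config")
}

as_feature_matrix <- function(data) {
  if (is.data.frame(data)) {
    keep <- setdiff(names(data), c("timestamp", "label"))
    x <- as.matrix(data[keep])
  } else {
    x <- as.matrix(data)
  }
  storage.mode(x) <- "double"
  x
}

check_binary_labels <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("degenerate data: both labels must be present", call. = FALSE)
  y
}

#' Exhaustive single-feature threshold sweep
#'
#' Evaluates every threshold rule on one feature over a quantile grid
#' (default resolution 1/200): `above` (predict the trigger when the value is
#' at or above a cut), `below`, and `band` (inside a closed interval). Returns
#' the rule with the highest training accuracy; ties are broken by the
#' smallest lower threshold, then by the narrowest band.
#'
#' @param values Numeric feature values (or a data frame / matrix plus
#'   `feature` selecting a column).
#' @param labels Binary 0/1 labels.
#' @param feature Column index or name when `values` is tabular.
#' @param grid Grid resolution: number of quantile steps (default 200).
#' @return List of class `threshold_rule`: `feature`, `mode`, `lower`,
#'   `upper`, `accuracy` (percent).
#' @export
sweep_single_feature_thresholds <- function(values, labels, feature = NULL,
                                            grid = 200L) {
  if (!is.null(dim(values))) {
    stopifnot(!is.null(feature))
    values <- as_feature_matrix(values)[, feature]
  }
  x <- as.numeric(values)
  y <- check_binary_labels(labels)
  stopifnot(length(x) == length(y), all(is.finite(x)))
  n <- length(x)

  cuts <- unique(stats::quantile(x, probs = seq(0, 1, length.out = grid + 1),
                                 names = FALSE, type = 1))
  G <- length(cuts)
  ypos <- x[y == 1L]; yneg <- x[y == 0L]
  npos <- length(ypos); nneg <- length(yneg)
  spos <- sort(ypos); sneg <- sort(yneg)
  # counts of samples strictly below / at-or-below each cut
  pos_lt <- findInterval(cuts, spos, left.open = TRUE)
  pos_le <- findInterval(cuts, spos)
  neg_lt <- findInterval(cuts, sneg, left.open = TRUE)
  neg_le <- findInterval(cuts, sneg)

  # above rule at cut k: predict 1 iff x >= cuts[k]
  acc_above <- ((npos - pos_lt) + neg_lt) / n
  # below rule at cut k: predict 1 iff x <= cuts[k]
  acc_below <- (pos_le + (nneg - neg_le)) / n
  # band rule [cuts[i], cuts[j]] (closed), i <= j
  band_pos <- outer(pos_le, pos_lt, `-`) # [j, i] = #pos in [cuts[i], cuts[j]]
  band_neg <- outer(neg_le, neg_lt, `-`)
  acc_band <- (band_pos + (nneg - band_neg)) / n
  acc_band[row(acc_band) < col(acc_band)] <- -Inf

  best <- max(max(acc_above), max(acc_below), max(acc_band))
  cand <- list()
  for (k in which(acc_above >= best - 1e-12))
    cand[[length(cand) + 1]] <- list(mode = "above", lower = cuts[k],
                                     upper = Inf, width = Inf)
  for (k in which(acc_below >= best - 1e-12))
    cand[[length(cand) + 1]] <- list(mode = "below", lower = -Inf,
                                     upper = cuts[k], width = Inf)
  hit <- which(acc_band >= best - 1e-12, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 2]; j <- hit[r, 1]
      cand[[length(cand) + 1]] <- list(mode = "band", lower = cuts[i],
                                       upper = cuts[j],
                                       width = cuts[j] - cuts[i])
    }
  }
  lo <- vapply(cand, function(cc) cc$lower, 0)
  wd <- vapply(cand, function(cc) cc$width, 0)
  pick <- order(lo, wd)[1]
  rule <- cand[[pick]]
  structure(list(feature = feature, mode = rule$mode,
                 lower = rule$lower, upper = rule$upper,
                 accuracy = 100 * best),
            class = "threshold_rule")
}

#' Apply a threshold rule
#'
#' @param rule A `threshold_rule`.
#' @param values Numeric feature values.
#' @return Integer 0/1 predictions.
#' @export
apply_threshold_rule <- function(rule, values) {
  x <- as.numeric(values)
  pred <- switch(rule$mode,
    above = x >= rule$lower,
    below = x <= rule$upper,
    band = x >= rule$lower & x <= rule$upper,
    stop("unknown rule mode", call. = FALSE))
  as.integer(pred)
}

#' Train the adaptive-boosting trigger classifier
#'
#' Two-class discrete adaptive boosting (SAMME with stagewise weights) over
#' depth-limited CART trees. Each round fits a tree under the current sample
#' weights, upweights the samples it misclassifies, and contributes
#' `learning_rate * log((1 - err) / err)` to the weighted vote. Training
#' stops early if a round's weighted error reaches 0.5 (no better than
#' chance) or 0 (perfect).
#'
#' @param data Feature matrix / data frame (a `timestamp` or `label` column
#'   is dropped automatically).
#' @param labels Binary 0/1 labels (taken from `data$label` when missing).
#' @param cfg An [ensemble_config()].
#' @param seed Seed; training is deterministic given it.
#' @return Object of class `scdc_boost` with `trees`, `alphas`,
#'   `stage_errors`, `bound` (cumulative exponential training bound) and
#'   `train_error` (ensemble 0/1 error per round).
#' @export
train_boosted_ensemble <- function(data, labels = NULL,
                                   cfg = ensemble_config(), seed = 1L) {
  if (is.null(labels)) {
    stopifnot(is.data.frame(data), "label" %in% names(data))
    labels <- data$label
  }
  x <- as_feature_matrix(data)
  y <- check_binary_labels(labels)
  stopifnot(nrow(x) == length(y))
  set.seed(seed)
  n <- nrow(x)
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  ctrl <- rpart::rpart.control(maxdepth = cfg$max_depth, cp = 0,
                               minsplit = 10, minbucket = 5, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  stage_errors <- numeric(0); bound <- numeric(0); train_error <- numeric(0)
  score <- numeric(n) # running weighted vote in {-1,+1} space
  for (m in seq_len(cfg$n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(predict(fit, df, type = "class") == "1")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) break
    err_c <- max(err, 1e-12)
    alpha <- cfg$learning_rate * log((1 - err_c) / err_c)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    stage_errors <- c(stage_errors, err)
    z <- 2 * sqrt(err_c * (1 - err_c))
    bound <- c(bound, if (length(bound)) bound[length(bound)] * z else z)
    score <- score + alpha * (2 * pred - 1)
    train_error <- c(train_error,
                     mean((score >= 0) != (y == 1L)))
    if (err_c <= 1e-12) break
  }
  if (length(trees) == 0)
    stop("boosting found no weak learner better than chance", call. = FALSE)
  structure(list(trees = trees, alphas = alphas,
                 stage_errors = stage_errors, bound = bound,
                 train_error = train_error,
                 features = colnames(x), cfg = cfg, seed = seed),
            class = "scdc_boost")
}

#' @export
print.scdc_boost <- function(x, ...) {
  cat(sprintf("adaptive-boosting trigger classifier: %d trees (max depth %d, LR %g)\n",
              length(x$trees), x$cfg$max_depth, x$cfg$learning_rate))
  cat(sprintf("final training error %.4f (exponential bound %.4g)\n",
              x$train_error[length(x$train_error)],
              x$bound[length(x$bound)]))
  invisible(x)
}

#' @export
predict.scdc_boost <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  df <- as.data.frame(x)
  score <- numeric(nrow(df))
  for (m in seq_along(object$trees)) {
    pred <- as.integer(predict(object$trees[[m]], df, type = "class") == "1")
    score <- score + object$alphas[m] * (2 * pred - 1)
  }
  if (type == "score") score else as.integer(score >= 0)
}

# a "model" may also be a plain function mapping a feature table to 0/1
predict_classes <- function(model, newdata) {
  if (is.function(model)) as.integer(model(newdata))
  else as.integer(predict(model, newdata, type = "class"))
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the small feed-forward trigger network
#'
#' A fully connected network with two rectified-linear hidden layers and a
#' sigmoid output, trained on standardized features by minibatch Adam under
#' binary cross-entropy. Fully deterministic given the config seed.
#'
#' @inheritParams train_boosted_ensemble
#' @param cfg A [network_config()].
#' @return Object of class `scdc_net`.
#' @export
train_network <- function(data, labels = NULL, cfg = network_config()) {
  if (is.null(labels)) {
    stopifnot(is.data.frame(data), "label" %in% names(data))
    labels <- data$label
  }
  x <- as_feature_matrix(data)
  y <- check_binary_labels(labels)
  stopifnot(nrow(x) == length(y))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")

  set.seed(cfg$seed)
  sizes <- c(ncol(xs), cfg$hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  n <- nrow(xs)
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      take <- idx[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xs[take, , drop = FALSE]
      yb <- y[take]
      # forward
      a <- vector("list", L + 1); a[[1]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1]] <- if (l < L) relu(z) else sigmoid(z)
      }
      # backward (BCE + sigmoid): delta = p - y
      delta <- a[[L + 1]] - matrix(yb, ncol = 1)
      t <- t + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta) / length(take)
        gb <- colMeans(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        lr_t <- cfg$learning_rate * sqrt(1 - beta2^t) / (1 - beta1^t)
        W[[l]] <- W[[l]] - lr_t * mW[[l]] / (sqrt(vW[[l]]) + eps)
        b[[l]] <- b[[l]] - lr_t * mb[[l]] / (sqrt(vb[[l]]) + eps)
      }
    }
  }
  structure(list(W = W, b = b, mu = mu, sd = sdv,
                 features = colnames(x), cfg = cfg),
            class = "scdc_net")
}

#' @export
print.scdc_net <- function(x, ...) {
  cat(sprintf("feed-forward trigger network: %s -> 1 (ReLU hidden, sigmoid out)\n",
              paste(c(length(x$mu), x$cfg$hidden), collapse = " -> ")))
  invisible(x)
}

#' @export
predict.scdc_net <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  a <- sweep(sweep(x, 2, object$mu), 2, object$sd, "/")
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) relu(z) else sigmoid(z)
  }
  score <- as.numeric(a)
  if (type == "score") score else as.integer(score >= 0.5)
}

#' Confusion-count classification metrics
#'
#' Accuracy, precision, recall (sensitivity) and specificity are reported in
#' percent; the F1 score as a fraction, computed both as the harmonic mean of
#' precision and recall and directly from the counts
#' (`tp / (tp + (fp + fn) / 2)`) -- the two agree to machine precision.
#' Ratios with a zero denominator are reported as `NA` (explicitly
#' undefined), never as 0.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return Object of class `classification_metrics`.
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  total <- sum(counts)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- rate(tp, tp + fp)
  recall <- rate(tp, tp + fn)
  f1 <- if (tp + fp + fn > 0) tp / (tp + (fp + fn) / 2) else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = rate(tp + tn, total),
    precision = precision,
    recall = recall,
    specificity = rate(tn, tn + fp),
    f1 = f1
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("counts: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("accuracy %s  precision %s  recall %s  specificity %s  F1 %s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall),
              fmt(x$specificity),
              if (is.na(x$f1)) "undefined" else sprintf("%.4f", x$f1)))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall. Inputs may be percentages or
#' fractions (both on the same scale); the result is on the 0-1 scale when
#' given percentages.
#'
#' @param precision,recall Same-scale precision and recall values.
#' @return F1 as a fraction of the input scale (divided by 100 when inputs
#'   look like percentages).
#' @export
f1_score <- function(precision, recall) {
  f1 <- 2 * precision * recall / (precision + recall)
  if (precision > 1 || recall > 1) f1 / 100 else f1
}

#' Upper 95% confidence bound on a mean
#'
#' `mean + 1.96 * sd / sqrt(n)` (normal-approximation interval).
#'
#' @param mean Sample mean.
#' @param sample_std Sample standard deviation (>= 0).
#' @param n Sample size (>= 1).
#' @return Upper bound, same units as `mean`.
#' @export
ci95_upper <- function(mean, sample_std, n) {
  stopifnot(n >= 1, sample_std >= 0)
  mean + 1.96 * sample_std / sqrt(n)
}

#' Coefficient of variation
#' @param mean,sd Sample mean and standard deviation.
#' @return `sd / mean`.
#' @export
coefficient_of_variation <- function(mean, sd) {
  stopifnot(mean != 0)
  sd / mean
}

#' Percent change from a reference value
#' @param from Reference value.
#' @param to New value.
#' @return `100 * (to - from) / from`.
#' @export
percent_change <- function(from, to) 100 * (to - from) / from

#' Five-fold cross-validation of a trigger classifier
#'
#' Shuffles the samples once (seeded), splits them into five folds that
#' partition the data (each sample is tested exactly once), trains on the
#' other four folds and evaluates on the held-out fold.
#'
#' @param data Feature data (see [train_boosted_ensemble()]).
#' @param labels Binary labels (taken from `data$label` when missing).
#' @param trainer Function `(data, labels) -> model`; the model must support
#'   `predict(model, newdata, type = "class")` (or itself be a function
#'   mapping features to 0/1 labels).
#' @param seed Shuffle seed.
#' @return Object of class `cv_result`: per-fold `metrics`, `accuracy`
#'   vector (percent), `mean_accuracy`, `sd_accuracy`, `cov`.
#' @export
five_fold_cv <- function(data, labels = NULL, trainer, seed = 1L) {
  if (is.null(labels)) {
    stopifnot(is.data.frame(data), "label" %in% names(data))
    labels <- data$label
  }
  x <- as_feature_matrix(data)
  y <- as.integer(labels)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 samples for five folds", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  fold_id <- rep(seq_len(5), length.out = 0)
  sizes <- rep(n %/% 5, 5) + c(rep(1, n %% 5), rep(0, 5 - n %% 5))
  fold_id <- rep(seq_len(5), times = sizes)
  folds <- split(idx, fold_id)
  metrics <- vector("list", 5)
  acc <- numeric(5)
  for (k in seq_len(5)) {
    test <- folds[[k]]
    train <- setdiff(idx, test)
    model <- trainer(x[train, , drop = FALSE], y[train])
    pred <- predict_classes(model, x[test, , drop = FALSE])
    tp <- sum(pred == 1 & y[test] == 1)
    fp <- sum(pred == 1 & y[test] == 0)
    fn <- sum(pred == 0 & y[test] == 1)
    tn <- sum(pred == 0 & y[test] == 0)
    metrics[[k]] <- classification_metrics(tp, fp, fn, tn)
    acc[k] <- metrics[[k]]$accuracy
  }
  structure(list(metrics = metrics, accuracy = acc, folds = folds,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 cov = stats::sd(acc) / mean(acc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("five-fold CV accuracy: %s\n",
              paste(sprintf("%.2f%%", x$accuracy), collapse = ", ")))
  cat(sprintf("mean %.2f%%, sd %.2f, CoV %.4f\n",
              x$mean_accuracy, x$sd_accuracy, x$cov))
  invisible(x)
}

#' Decode a band-power stream into selection events
#'
#' Runs the trained classifier over each sample of the stream and emits a
#' selection event at the `debounce_k`-th consecutive positive prediction
#' (the debounce counter resets after each emission). `debounce_k = 1` emits
#' on every positive prediction; `debounce_k = 3` reproduces the
#' three-consecutive-labels rule.
#'
#' @param model A trained classifier supporting `predict(..., type = "class")`,
#'   or a plain function mapping the stream to 0/1 predictions.
#' @param stream Data frame with `timestamp` plus feature columns.
#' @param debounce_k Consecutive positives required (>= 1).
#' @return Data frame of events (`time`, `index`) with attributes
#'   `predictions` and `latency_per_sample` (s, wall clock of the decode).
#' @export
decode_stream <- function(model, stream, debounce_k = 1L) {
  stopifnot(is.data.frame(stream), "timestamp" %in% names(stream),
            debounce_k >= 1)
  t0 <- proc.time()[["elapsed"]]
  pred <- predict_classes(model, stream)
  elapsed <- proc.time()[["elapsed"]] - t0
  run <- 0L
  hits <- integer(0)
  for (i in seq_along(pred)) {
    if (pred[i] == 1L) {
      run <- run + 1L
      if (run >= debounce_k) {
        hits <- c(hits, i)
        run <- 0L
      }
    } else {
      run <- 0L
    }
  }
  out <- data.frame(time = stream$timestamp[hits], index = hits)
  attr(out, "predictions") <- pred
  attr(out, "latency_per_sample") <- elapsed / max(1L, length(pred))
  out
}
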