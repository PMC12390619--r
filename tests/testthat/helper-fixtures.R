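# Shared fixtures and independent oracles used across test files.

default_geom <- arm_geometry()

# random in-limit joint angle triples
random_angles <- function(n, g = default_geom) {
  cbind(stats::runif(n, g$joint_limits[1, 1], g$joint_limits[1, 2]),
        stats::runif(n, g$joint_limits[2, 1], g$joint_limits[2, 2]),
        stats::runif(n, g$joint_limits[3, 1], g$joint_limits[3, 2]))
}

# central finite differences of the SSE loss (independent gradient oracle)
fd_gradient <- function(q, target, g, h = 1e-6) {
  vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (sse_loss(forward_kinematics(q + e, g), target) -
       sse_loss(forward_kinematics(q - e, g), target)) / (2 * h)
  }, 0)
}

# exhaustive brute-force threshold-rule search (independent sweep oracle):
# tries every cut and cut pair over the same quantile grid, all three modes
brute_force_sweep <- function(x, y, grid = 200L) {
  cuts <- unique(stats::quantile(x, probs = seq(0, 1, length.out = grid + 1),
                                 names = FALSE, type = 1))
  best <- list(acc = -Inf, lower = Inf, width = Inf)
  consider <- function(pred, mode, lower, upper, width) {
    acc <- mean(pred == y)
    if (acc > best$acc + 1e-12 ||
        (acc > best$acc - 1e-12 &&
         (lower < best$lower - 1e-12 ||
          (abs(lower - best$lower) <= 1e-12 && width < best$width - 1e-12)))) {
      best <<- list(acc = acc, mode = mode, lower = lower, upper = upper,
                    width = width)
    }
  }
  for (t in cuts) {
    consider(as.integer(x >= t), "above", t, Inf, Inf)
    consider(as.integer(x <= t), "below", -Inf, t, Inf)
  }
  for (i in seq_along(cuts)) {
    for (j in i:length(cuts)) {
      consider(as.integer(x >= cuts[i] & x <= cuts[j]), "band",
               cuts[i], cuts[j], cuts[j] - cuts[i])
    }
  }
  best
}

# tiny labeled two-feature dataset with an XOR-like interaction
xor_dataset <- function(n = 400, seed = 1) {
  set.seed(seed)
  a <- stats::runif(n) > 0.5
  b <- stats::runif(n) > 0.5
  y <- as.integer(xor(a, b))
  x <- cbind(f1 = as.numeric(a) + stats::rnorm(n, sd = 0.15),
             f2 = as.numeric(b) + stats::rnorm(n, sd = 0.15))
  list(x = x, y = y)
}

# trial-log stub with a fixed outcome
outcome_log <- function(outcome) structure(list(outcome = outcome),
                                           class = "trial_log")
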