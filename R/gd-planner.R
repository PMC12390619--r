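#' Gradient-descent planner configuration
#'
#' @param learning_rate Step scale `eta` applied to the loss gradient each
#'   iteration. Default 0.001, shared by all three joints.
#' @param sse_threshold Convergence threshold on the sum of squared
#'   end-effector error (cm^2). Default 0.1.
#' @param max_iterations Iteration cap; hitting it yields an explicit
#'   not-converged status.
#' @param quantum Smallest commanded angle change the servo registers (rad).
#'   Default 0.063.
#' @param approach_clearance Hover height above the target for the two-phase
#'   safe approach (cm).
#' @return An object of class `gd_config`.
#' @export
gd_config <- function(learning_rate = 0.001, sse_threshold = 0.1,
                      max_iterations = 100000L, quantum = 0.063,
                      approach_clearance = 5) {
  stopifnot(learning_rate > 0, sse_threshold > 0, quantum > 0,
            max_iterations >= 1, approach_clearance >= 0)
  structure(list(learning_rate = learning_rate,
                 sse_threshold = sse_threshold,
                 max_iterations = as.integer(max_iterations),
                 quantum = quantum,
                 approach_clearance = approach_clearance),
            class = "gd_config")
}

#' Sum-of-squared-error loss between two end-effector positions
#'
#' @param current,target Length-3 positions (cm).
#' @return Scalar loss (cm^2).
#' @export
sse_loss <- function(current, target) {
  current <- as.numeric(current); target <- as.numeric(target)
  stopifnot(length(current) == 3, length(target) == 3)
  sum((target - current)^2)
}

fk_jacobian <- function(q, g) {
  c1 <- cos(q[1]); s1 <- sin(q[1])
  c2 <- cos(q[2]); s2 <- sin(q[2])
  c23 <- cos(q[2] + q[3]); s23 <- sin(q[2] + q[3])
  r <- g$a1 + g$a2 * c2 + g$a3 * c23
  dr2 <- g$a2 * s2 + g$a3 * s23 # -d r / d theta2
  matrix(c(-s1 * r, -c1 * dr2, -g$a3 * c1 * s23,
           c1 * r, -s1 * dr2, -g$a3 * s1 * s23,
           0, g$a2 * c2 + g$a3 * c23, g$a3 * c23),
         nrow = 3, byrow = TRUE)
}

#' Gradient of the SSE loss with respect to the joint angles
#'
#' Analytic gradient of [sse_loss()] composed with [forward_kinematics()]:
#' `grad_i = -2 * sum_k (target_k - P_k) * dP_k/dtheta_i`. The descent update
#' `theta - eta * grad` then adds `2 * eta * (target - P) . dP/dtheta` to each
#' angle.
#'
#' @param q Joint angles (rad).
#' @param target Length-3 target position (cm).
#' @param g An [arm_geometry()].
#' @return Length-3 gradient (cm^2/rad).
#' @export
loss_gradient <- function(q, target, g) {
  q <- check_angles(q)
  target <- as.numeric(target)
  stopifnot(length(target) == 3, all(is.finite(target)))
  p <- forward_kinematics(q, g)
  J <- fk_jacobian(q, g)
  as.numeric(-2 * crossprod(J, target - p))
}

#' One gradient-descent update of the joint angles
#'
#' @param q Joint angles (rad).
#' @param target Target position (cm).
#' @param g An [arm_geometry()].
#' @param eta Learning rate (> 0).
#' @return Updated joint angles (not clamped; clamping is the planner's job).
#' @export
gd_update <- function(q, target, g, eta) {
  stopifnot(eta > 0)
  check_angles(q) - eta * loss_gradient(q, target, g)
}

#' Plan a reach by iterative gradient descent
#'
#' From a start pose (default the home pose), repeatedly steps the joint
#' angles down the SSE gradient until the loss falls below
#' `cfg$sse_threshold` or `cfg$max_iterations` is hit. Angles are clamped to
#' the joint limits (with a warning if clamping occurred). The returned trace
#' records, per iteration, the written ("dummy variable") angles, the
#' quantized angles a servo would actually read, and the SSE.
#'
#' @param target Length-3 target position (cm), must be reachable.
#' @param g An [arm_geometry()].
#' @param cfg A [gd_config()].
#' @param start Starting joint angles (rad), default [home_angles()].
#' @return An object of class `reach_plan`: list with `written` and `read`
#'   (n x 3 matrices including the start row), `sse` (length n), `converged`,
#'   `iterations`, `final_angles`, `target`, plus the geometry and config.
#' @export
plan_reach <- function(target, g, cfg = gd_config(), start = home_angles()) {
  stopifnot(inherits(g, "arm_geometry"), inherits(cfg, "gd_config"))
  target <- as.numeric(target)
  stopifnot(length(target) == 3, all(is.finite(target)))
  ok <- is_reachable(target, g)
  if (!ok)
    stop("target unreachable: ", attr(ok, "reason"), call. = FALSE)
  q <- check_angles(start)

  eta <- cfg$learning_rate
  lim_lo <- g$joint_limits[, 1]; lim_hi <- g$joint_limits[, 2]
  a1 <- g$a1; a2 <- g$a2; a3 <- g$a3; a0 <- g$a0
  tx <- target[1]; ty <- target[2]; tz <- target[3]

  cap <- min(cfg$max_iterations + 1L, 4096L)
  written <- matrix(NA_real_, cap, 3)
  sse <- numeric(cap)
  n <- 0L
  clamped <- FALSE
  converged <- FALSE

  repeat {
    c1 <- cos(q[1]); s1 <- sin(q[1])
    c2 <- cos(q[2]); s2 <- sin(q[2])
    c23 <- cos(q[2] + q[3]); s23 <- sin(q[2] + q[3])
    r <- a1 + a2 * c2 + a3 * c23
    px <- c1 * r; py <- s1 * r; pz <- a0 + a2 * s2 + a3 * s23
    rx <- tx - px; ry <- ty - py; rz <- tz - pz
    e <- rx * rx + ry * ry + rz * rz

    n <- n + 1L
    if (n > nrow(written)) {
      grow <- min(cfg$max_iterations + 1L, 2L * nrow(written))
      written <- rbind(written, matrix(NA_real_, grow - nrow(written), 3))
      sse <- c(sse, numeric(grow - length(sse)))
    }
    written[n, ] <- q
    sse[n] <- e

    if (e < cfg$sse_threshold) { converged <- TRUE; break }
    if (n > cfg$max_iterations) break

    dr2 <- a2 * s2 + a3 * s23
    g1 <- -2 * (rx * (-s1 * r) + ry * (c1 * r))
    g2 <- -2 * (rx * (-c1 * dr2) + ry * (-s1 * dr2) + rz * (a2 * c2 + a3 * c23))
    g3 <- -2 * (rx * (-a3 * c1 * s23) + ry * (-a3 * s1 * s23) + rz * (a3 * c23))
    q <- q - eta * c(g1, g2, g3)
    qc <- pmin(pmax(q, lim_lo), lim_hi)
    if (any(qc != q)) clamped <- TRUE
    q <- qc
  }

  written <- written[seq_len(n), , drop = FALSE]
  sse <- sse[seq_len(n)]
  if (clamped)
    warning("joint limits hit during descent; angles were clamped", call. = FALSE)
  read <- simulate_servo_readout(written, cfg$quantum)
  structure(
    list(written = written, read = read, sse = sse,
         converged = converged, iterations = n - 1L,
         final_angles = written[n, ], final_sse = sse[n],
         target = target, geometry = g, config = cfg, clamped = clamped),
    class = "reach_plan"
  )
}

#' @export
print.reach_plan <- function(x, ...) {
  cat(sprintf("reach plan to (%.2f, %.2f, %.2f) cm: %s after %d iterations, final SSE %.4g cm^2\n",
              x$target[1], x$target[2], x$target[3],
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_sse))
  invisible(x)
}

#' @export
summary.reach_plan <- function(object, ...) {
  fk_w <- forward_kinematics(object$final_angles, object$geometry)
  fk_r <- forward_kinematics(object$read[nrow(object$read), ], object$geometry)
  out <- list(
    converged = object$converged,
    iterations = object$iterations,
    final_sse = object$final_sse,
    ee_written = fk_w,
    ee_read = fk_r,
    total_positional_error = total_positional_error(object, object$config,
                                                    object$geometry),
    clamped = object$clamped
  )
  class(out) <- "summary.reach_plan"
  out
}

#' @export
print.summary.reach_plan <- function(x, ...) {
  cat(sprintf("%s in %d iterations; final SSE %.4g cm^2\n",
              if (x$converged) "converged" else "not converged",
              x$iterations, x$final_sse))
  cat(sprintf("EE (written) = (%.3f, %.3f, %.3f) cm; EE (read) = (%.3f, %.3f, %.3f) cm\n",
              x$ee_written[1], x$ee_written[2], x$ee_written[3],
              x$ee_read[1], x$ee_read[2], x$ee_read[3]))
  cat(sprintf("total positional error = %.4g cm^2\n", x$total_positional_error))
  invisible(x)
}

#' @export
plot.reach_plan <- function(x, joint = 1L, ...) {
  it <- seq_len(nrow(x$written)) - 1L
  graphics::matplot(it, cbind(x$written[, joint], x$read[, joint]),
                    type = c("l", "s"), lty = c(1, 1), col = c("grey40", "red3"),
                    xlab = "iteration", ylab = sprintf("joint %d angle (rad)", joint), ...)
  graphics::legend("bottomright", c("written", "read (quantized)"),
                   lty = 1, col = c("grey40", "red3"), bty = "n")
  invisible(x)
}

#' Quantized servo readout of a written angle sequence
#'
#' A servo registers a new command only once the written angle has moved at
#' least one quantum away from the last value it read; the read value then
#' jumps to the written value. Joints are independent.
#'
#' @param written Numeric vector (one joint) or n x 3 matrix of written
#'   angles (rad).
#' @param quantum Servo resolution (rad).
#' @return Read angles, same shape as `written`.
#' @export
simulate_servo_readout <- function(written, quantum = 0.063) {
  stopifnot(quantum > 0)
  one <- function(w) {
    r <- numeric(length(w))
    if (length(w) == 0) return(r)
    cur <- w[1]
    r[1] <- cur
    for (i in seq_along(w)[-1]) {
      if (abs(w[i] - cur) >= quantum) cur <- w[i]
      r[i] <- cur
    }
    r
  }
  if (is.matrix(written)) {
    out <- vapply(seq_len(ncol(written)), function(j) one(written[, j]),
                  numeric(nrow(written)))
    matrix(out, nrow = nrow(written), dimnames = dimnames(written))
  } else {
    one(as.numeric(written))
  }
}

#' Total positional error of a completed plan
#'
#' The convergence threshold accounts for how far the written angles may
#' still be from the target; the quantized readout adds a second term: the
#' squared end-effector distance between the finally written and finally read
#' poses.
#'
#' @param trace A `reach_plan`.
#' @param cfg A [gd_config()] (for the threshold).
#' @param g An [arm_geometry()].
#' @return Error bound in cm^2, at least `cfg$sse_threshold`.
#' @export
total_positional_error <- function(trace, cfg = trace$config, g = trace$geometry) {
  stopifnot(inherits(trace, "reach_plan"))
  if (is.null(trace$written) || nrow(trace$written) == 0)
    stop("empty optimization trace", call. = FALSE)
  n <- nrow(trace$written)
  fk_w <- forward_kinematics(trace$written[n, ], g)
  fk_r <- forward_kinematics(trace$read[n, ], g)
  cfg$sse_threshold + sum((fk_w - fk_r)^2)
}

#' Two-phase safe approach: hover above, then descend
#'
#' Plans first to a hover point `approach_clearance` cm vertically above the
#' target, then descends onto the target. In the emitted descent command
#' order the elbow joint (J3) is commanded before the shoulder pitch (J2), so
#' the end effector comes down from above rather than sweeping across the
#' table.
#'
#' @param target Length-3 target (cm); both it and the hover point must be
#'   reachable.
#' @param g An [arm_geometry()].
#' @param cfg A [gd_config()].
#' @return An object of class `safe_approach`: `phase1` and `phase2`
#'   (reach plans), `hover` point, and `commands` (descent actuation order, a
#'   data frame of joint/angle rows with J3 before J2).
#' @export
plan_safe_approach <- function(target, g, cfg = gd_config()) {
  target <- as.numeric(target)
  hover <- target + c(0, 0, cfg$approach_clearance)
  if (!is_reachable(hover, g))
    stop("approach infeasible: hover point unreachable", call. = FALSE)
  if (!is_reachable(target, g))
    stop("approach infeasible: target unreachable", call. = FALSE)
  phase1 <- plan_reach(hover, g, cfg)
  phase2 <- plan_reach(target, g, cfg, start = phase1$final_angles)
  qf <- phase2$final_angles
  q0 <- phase1$final_angles
  commands <- data.frame(
    joint = c("J1", "J3", "J2"),
    angle = c(qf[1], qf[3], qf[2]),
    delta = c(qf[1] - q0[1], qf[3] - q0[3], qf[2] - q0[2])
  )
  structure(list(target = target, hover = hover,
                 phase1 = phase1, phase2 = phase2, commands = commands),
            class = "safe_approach")
}

#' @export
print.safe_approach <- function(x, ...) {
  cat(sprintf("safe approach to (%.2f, %.2f, %.2f) cm via hover +%.1f cm\n",
              x$target[1], x$target[2], x$target[3],
              x$hover[3] - x$target[3]))
  cat(sprintf("  phase 1: %d iterations; phase 2: %d iterations (J3 before J2); final SSE %.4g cm^2\n",
              x$phase1$iterations, x$phase2$iterations, x$phase2$final_sse))
  invisible(x)
}

#' Servo fault check
#'
#' Flags a fault whenever the absolute mismatch between written and read
#' angles strictly exceeds the tolerance on any joint (default 0.1 rad), the
#' condition on which the controller stops the servos in place.
#'
#' @param written,read Length-3 joint angles (rad).
#' @param tol Fault tolerance (rad), strict inequality.
#' @return List with `status` (`"ok"` or `"fault"`) and, on fault, `joints`
#'   (e.g. `"J2"`) plus a `"servo fault"` message.
#' @export
servo_fault_check <- function(written, read, tol = 0.1) {
  written <- check_angles(written); read <- check_angles(read)
  # strict inequality, robust to representation error at the boundary
  bad <- which(abs(written - read) > tol + 1e-12)
  if (length(bad) == 0) {
    list(status = "ok")
  } else {
    list(status = "fault", joints = paste0("J", bad), message = "servo fault")
  }
}
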