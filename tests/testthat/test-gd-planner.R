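test_that("the SSE loss is a plain sum of squared coordinate errors", {
  expect_equal(sse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sse_loss(c(1, 2, 3), c(1, 2, 4)), 1)
  expect_equal(sse_loss(c(0, 0, 0), c(1, 1, 1)), 3)
})

test_that("the analytic gradient matches central finite differences", {
  g <- default_geom
  # exact zero at the optimum
  q0 <- c(0.8, 0.1, -0.3)
  expect_equal(loss_gradient(q0, forward_kinematics(q0, g), g), rep(0, 3))

  set.seed(5)
  for (i in 1:200) {
    q <- c(random_angles(1))
    target <- c(stats::runif(1, -20, 20), stats::runif(1, 5, 40),
                stats::runif(1, 0, 35))
    a <- loss_gradient(q, target, g)
    b <- fd_gradient(q, target, g)
    expect_lt(max(abs(a - b)) / max(1, max(abs(b))), 1e-6)
  }

  # a target displaced only upward pulls theta2 up (descent raises the arm)
  q <- c(pi / 2, 0, 0)
  target <- forward_kinematics(q, g) + c(0, 0, 5)
  gr <- loss_gradient(q, target, g)
  expect_lt(gr[2], 0) # descent step -eta*grad increases theta2
})

test_that("one GD update reproduces the literal update relations and descends", {
  g <- default_geom
  q <- home_angles()
  target <- c(12, 20, 3)
  eta <- 0.001
  # literal form: theta_new = theta_old + 2*eta*(residual . dP/dtheta)
  p <- forward_kinematics(q, g)
  c1 <- cos(q[1]); s1 <- sin(q[1]); c2 <- cos(q[2]); s2 <- sin(q[2])
  c23 <- cos(q[2] + q[3]); s23 <- sin(q[2] + q[3])
  rx <- target[1] - p[1]; ry <- target[2] - p[2]; rz <- target[3] - p[3]
  lit1 <- q[1] + 2 * eta *
    (rx * (-g$a1 * s1 - g$a2 * s1 * c2 - g$a3 * s1 * c23) +
       ry * (g$a1 * c1 + g$a2 * c1 * c2 + g$a3 * c1 * c23))
  lit2 <- q[2] + 2 * eta *
    (rx * (-g$a2 * s2 * c1 - g$a3 * c1 * s23) +
       ry * (-g$a2 * s2 * s1 - g$a3 * s1 * s23) +
       rz * (g$a2 * c2 + g$a3 * c23))
  lit3 <- q[3] + 2 * eta *
    (rx * (-g$a3 * c1 * s23) + ry * (-g$a3 * s1 * s23) + rz * (g$a3 * c23))
  upd <- gd_update(q, target, g, eta)
  expect_equal(upd, unname(c(lit1, lit2, lit3)), tolerance = 1e-12)

  # strict descent from home toward a nearby target
  expect_lt(sse_loss(forward_kinematics(upd, g), target),
            sse_loss(p, target))

  # zero-gradient point stays put
  expect_equal(gd_update(q, forward_kinematics(q, g), g, eta), q)
})

test_that("plan_reach converges on tabletop targets, records a full trace, and flags divergence", {
  g <- default_geom
  cfg <- gd_config()

  # target at the start pose: immediate convergence, zero iterations
  p0 <- plan_reach(forward_kinematics(home_angles(), g), g, cfg)
  expect_true(p0$converged)
  expect_equal(p0$iterations, 0L)
  expect_equal(p0$final_sse, 0)

  tgts <- sample_reach_targets(25, g, seed = 77)
  for (i in seq_len(nrow(tgts))) {
    # transient clamping against a joint limit is allowed (and warned about)
    p <- suppressWarnings(plan_reach(tgts[i, ], g, cfg))
    expect_true(p$converged)
    expect_lt(p$final_sse, cfg$sse_threshold)
    expect_true(all(diff(p$sse) <= 1e-9)) # monotone descent
    expect_equal(nrow(p$written), p$iterations + 1L)
    expect_true(within_limits <- all(
      p$final_angles >= g$joint_limits[, 1] - 1e-9 &
        p$final_angles <= g$joint_limits[, 2] + 1e-9))
    # GD agrees with the analytic IK: both poses reach the same point
    qa <- analytic_inverse_kinematics(tgts[i, ], g)
    d <- sqrt(sum((forward_kinematics(p$final_angles, g) -
                     forward_kinematics(qa, g))^2))
    expect_lt(d, sqrt(cfg$sse_threshold))
  }

  # absurd learning rate diverges and is reported, never silent
  pbad <- suppressWarnings(
    plan_reach(c(12, 20, 0), g,
               gd_config(learning_rate = 10, max_iterations = 2000)))
  expect_false(pbad$converged)
  expect_equal(pbad$iterations, 2000L)

  expect_error(plan_reach(c(60, 60, 0), g, cfg), "unreachable")
})

test_that("servo readout is quantized per joint with the threshold-jump rule", {
  # single large step is followed immediately
  expect_equal(simulate_servo_readout(c(0, 0.2), 0.063), c(0, 0.2))

  # +0.01 creep: constant for six steps, first change at cumulative 0.07
  w <- cumsum(c(0, rep(0.01, 10)))
  r <- simulate_servo_readout(w, 0.063)
  expect_equal(r[1:7], rep(0, 7))
  expect_equal(r[8], 0.07)

  # joints are independent and the final gap is always below one quantum
  set.seed(3)
  w3 <- apply(matrix(stats::rnorm(300, sd = 0.02), 100, 3), 2, cumsum)
  r3 <- simulate_servo_readout(w3, 0.063)
  expect_equal(dim(r3), dim(w3))
  expect_true(all(abs(w3[100, ] - r3[100, ]) < 0.063))
  # every change jumps exactly onto the written value, with magnitude >= quantum
  for (j in 1:3) {
    ch <- which(diff(r3[, j]) != 0) + 1
    expect_true(all(abs(r3[ch, j] - w3[ch, j]) < 1e-12))
    expect_true(all(abs(r3[ch, j] - r3[ch - 1, j]) >= 0.063))
  }
})

test_that("total positional error adds the readout mismatch to the threshold", {
  g <- default_geom
  cfg <- gd_config()
  plan <- plan_reach(c(12, 20, 0), g, cfg)
  n <- nrow(plan$written)

  # written == read at termination => exactly the threshold
  plan_eq <- plan
  plan_eq$read <- plan_eq$written
  expect_equal(total_positional_error(plan_eq, cfg, g), cfg$sse_threshold)

  # a 0.05 rad mismatch on theta1 only: FK-oracle cross-check
  plan_mis <- plan
  plan_mis$read <- plan$written
  plan_mis$read[n, 1] <- plan_mis$read[n, 1] - 0.05
  expected <- cfg$sse_threshold +
    sum((forward_kinematics(plan$written[n, ], g) -
           forward_kinematics(plan_mis$read[n, ], g))^2)
  expect_equal(total_positional_error(plan_mis, cfg, g), expected)
  expect_gte(total_positional_error(plan_mis, cfg, g), cfg$sse_threshold)

  # monotone in the mismatch along one joint (small perturbations)
  errs <- vapply(seq(0, 0.08, by = 0.02), function(d) {
    pm <- plan
    pm$read <- plan$written
    pm$read[n, 2] <- pm$read[n, 2] + d
    total_positional_error(pm, cfg, g)
  }, 0)
  expect_true(all(diff(errs) >= 0))

  empty <- plan
  empty$written <- plan$written[0, , drop = FALSE]
  expect_error(total_positional_error(empty, cfg, g), "empty")
})

test_that("the safe approach hovers above the target and commands J3 before J2", {
  g <- default_geom
  cfg <- gd_config()
  target <- c(12, 20, 0)
  sa <- plan_safe_approach(target, g, cfg)

  hover_ee <- forward_kinematics(sa$phase1$final_angles, g)
  expect_lt(abs(hover_ee[3] - (target[3] + cfg$approach_clearance)),
            sqrt(cfg$sse_threshold))
  expect_lt(sa$phase2$final_sse, cfg$sse_threshold)
  expect_lt(which(sa$commands$joint == "J3"),
            which(sa$commands$joint == "J2"))

  # hover point beyond reach makes the approach infeasible
  expect_error(
    plan_safe_approach(c(20, 20, 0), g, gd_config(approach_clearance = 50)),
    "infeasible")
})

test_that("servo fault flags strict 0.1 rad violations with the offending joint", {
  q <- c(1, 0.5, -0.2)
  expect_equal(servo_fault_check(q, q)$status, "ok")
  f <- servo_fault_check(q, q + c(0, 0.15, 0))
  expect_equal(f$status, "fault")
  expect_equal(f$joints, "J2")
  expect_equal(f$message, "servo fault")
  # boundary: exactly 0.1 rad is still ok (strict inequality)
  expect_equal(servo_fault_check(q, q + c(0.1, 0, 0))$status, "ok")
})
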