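test_that("dh_transform reproduces the identity, the J1 matrix, and a hand-evaluated case", {
  expect_equal(dh_transform(0, 0, 0, 0), diag(4))

  # J1 link (theta1, pi/2, a1, a0): middle column collapses, z offset a0
  th <- 0.7; a1 <- 15; a0 <- 22
  T01 <- dh_transform(th, pi / 2, a1, a0)
  expect_equal(T01,
               rbind(c(cos(th), 0, sin(th), a1 * cos(th)),
                     c(sin(th), 0, -cos(th), a1 * sin(th)),
                     c(0, 1, 0, a0),
                     c(0, 0, 0, 1)))

  # (pi/2, 0, 1, 0): unit translation along the rotated x, 90 deg z-rotation
  Tz <- dh_transform(pi / 2, 0, 1, 0)
  expect_equal(Tz[1:3, 4], c(0, 1, 0))
  expect_equal(Tz[1:3, 1:3],
               rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)))

  expect_error(dh_transform(NA, 0, 0, 0), "finite")
})

test_that("chained transforms compose the per-joint matrices and agree with closed-form FK", {
  g <- default_geom
  q <- c(pi / 3, 0.2, -0.4)
  ct <- chain_transforms(q, g)
  T01 <- dh_transform(q[1], pi / 2, g$a1, g$a0)
  T12 <- dh_transform(q[2], 0, g$a2, 0)
  T23 <- dh_transform(q[3], 0, g$a3, 0)
  expect_equal(ct$T02, T01 %*% T12)
  expect_equal(ct$T03, T01 %*% T12 %*% T23)
  # closed-form coordinates evaluated independently
  c1 <- cos(q[1]); s1 <- sin(q[1]); c2 <- cos(q[2])
  c23 <- cos(q[2] + q[3])
  px <- g$a1 * c1 + g$a2 * c1 * c2 + g$a3 * c1 * c23
  py <- g$a1 * s1 + g$a2 * s1 * c2 + g$a3 * s1 * c23
  pz <- g$a0 + g$a2 * sin(q[2]) + g$a3 * sin(q[2] + q[3])
  expect_equal(ct$T03[1:3, 4], c(px, py, pz), tolerance = 1e-12)

  # home pose: straight out at shoulder height
  home <- chain_transforms(home_angles(), g)
  expect_equal(home$T03[1:3, 4], c(0, g$a1 + g$a2 + g$a3, g$a0))
})

test_that("forward kinematics matches the transform chain on random angles", {
  set.seed(101)
  q <- random_angles(1000)
  fk <- forward_kinematics(q, default_geom)
  for (i in c(1, 17, 430, 999)) {
    ct <- chain_transforms(q[i, ], default_geom)
    expect_equal(unname(fk[i, ]), ct$T03[1:3, 4], tolerance = 1e-12)
  }
  expect_equal(forward_kinematics(c(pi / 2, 0, 0), default_geom),
               c(x = 0, y = 43, z = 22))
  expect_equal(forward_kinematics(c(pi / 2, pi / 2, 0), default_geom),
               c(x = 0, y = 15, z = 50))
})

test_that("rotation blocks of all chain transforms are orthonormal", {
  set.seed(7)
  q <- random_angles(100)
  worst <- 0
  for (i in seq_len(nrow(q))) {
    ct <- chain_transforms(q[i, ], default_geom)
    for (Tm in ct) {
      R <- Tm[1:3, 1:3]
      worst <- max(worst, max(abs(crossprod(R) - diag(3))))
      expect_equal(Tm[4, ], c(0, 0, 0, 1))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("analytic IK round-trips through FK on both branches", {
  g <- default_geom
  expect_equal(analytic_inverse_kinematics(c(0, 43, 22), g), c(pi / 2, 0, 0),
               tolerance = 1e-9)

  set.seed(42)
  n_checked <- 0
  while (n_checked < 1000) {
    q <- c(random_angles(1))
    target <- forward_kinematics(q, g)
    for (br in c("elbow-up", "elbow-down")) {
      qi <- analytic_inverse_kinematics(target, g, branch = br)
      expect_lt(max(abs(forward_kinematics(qi, g) - target)), 1e-9)
    }
    n_checked <- n_checked + 1
  }

  # elbow-up keeps theta3 <= 0 when that branch is feasible
  tgt <- c(10, 18, 5)
  expect_lte(analytic_inverse_kinematics(tgt, g, "elbow-up")[3], 0)
  expect_gte(analytic_inverse_kinematics(tgt, g, "elbow-down")[3], 0)
})

test_that("IK rejects unreachable and degenerate targets", {
  g <- default_geom
  expect_error(analytic_inverse_kinematics(c(60, 60, 0), g), "unreachable")
  expect_error(analytic_inverse_kinematics(c(0, 0, 30), g), "degenerate")
})

test_that("is_reachable agrees with a brute-force grid over in-limit angles", {
  g <- default_geom
  expect_false(is_reachable(c(60, 60, 0), g))
  expect_equal(attr(is_reachable(c(60, 60, 0), g), "reason"), "outside reach")

  # brute-force oracle: dense grid of in-limit triples
  grid <- expand.grid(
    t1 = seq(g$joint_limits[1, 1], g$joint_limits[1, 2], length.out = 40),
    t2 = seq(g$joint_limits[2, 1], g$joint_limits[2, 2], length.out = 40),
    t3 = seq(g$joint_limits[3, 1], g$joint_limits[3, 2], length.out = 40)
  )
  pts <- forward_kinematics(as.matrix(grid), g)
  set.seed(9)
  for (i in sample(nrow(pts), 60)) {
    expect_true(isTRUE(is_reachable(pts[i, ], g)),
                info = paste("grid point", i, "should be reachable"))
  }

  # a point inside the annulus but attainable only outside joint limits:
  # tighten theta1 limits so a backward target needs an excluded azimuth
  g2 <- arm_geometry(joint_limits = rbind(c(0, pi), c(-1, 1), c(-2, 1)))
  behind <- c(10, -18, 5) # azimuth < 0, annulus fine
  r <- is_reachable(behind, g2)
  expect_false(isTRUE(r))
  expect_equal(attr(r, "reason"), "joint limits")
})

test_that("zone assignment is deterministic, tie-broken low, and covers the area", {
  lay <- zone_layout()
  expect_equal(zone_of(c(-100, 0), lay), "outside")
  expect_equal(zone_of(c(61, 10), lay), "outside")

  # every in-area point gets exactly one zone
  set.seed(21)
  pts <- cbind(runif(500, 0, 60), runif(500, 0, 30))
  zones <- apply(pts, 1, zone_of, layout = lay)
  expect_true(all(zones %in% paste0("Z", 1:4)))

  # boundary between Z1 and Z2 goes to Z1 (sector boundary at -3pi/8)
  base <- c(0, 30)
  ang <- -pi / 2 + pi / 8
  p <- base + 10 * c(cos(ang), sin(ang))
  expect_equal(zone_of(p, lay), "Z1")

  # custom polygon layout: interior point of Z2, shared edge goes low
  polys <- list(Z1 = rbind(c(0, 0), c(30, 0), c(30, 30), c(0, 30)),
                Z2 = rbind(c(30, 0), c(60, 0), c(60, 30), c(30, 30)))
  lay2 <- zone_layout(polygons = polys)
  expect_equal(zone_of(c(45, 15), lay2), "Z2")
  expect_equal(zone_of(c(30, 15), lay2), "Z1") # shared boundary
})

test_that("geometry constructor enforces its invariants", {
  expect_error(arm_geometry(a1 = -1), "must be > 0")
  expect_error(arm_geometry(joint_limits = rbind(c(0, 2 * pi), c(-1, 1), c(-1, 1))),
               "270")
  g <- arm_geometry(a0 = 10, a1 = 5, a2 = 4, a3 = 3)
  expect_equal(forward_kinematics(c(pi / 2, 0, 0), g), c(x = 0, y = 12, z = 10))
})
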