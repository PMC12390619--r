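#' Arm geometry for the 3-DoF reach manipulator
#'
#' Bundles the Denavit-Hartenberg link constants and joint limits of the
#' three-joint serial arm. All lengths are centimetres; `a0` is the vertical
#' offset of the shoulder (J2) axis above the tabletop, `a1`--`a3` the link
#' lengths entering the DH chain. Joint limits default to a 270 degree span
#' per servo, centred on the home pose (`theta1 = pi/2`, `theta2 = theta3 = 0`).
#'
#' @param a0 Base vertical offset (cm).
#' @param a1,a2,a3 Link lengths (cm), all strictly positive.
#' @param joint_limits 3x2 matrix of per-joint `[min, max]` angles (rad).
#'   Each row may span at most 270 degrees (the servo travel).
#' @param base_position World (x, y) of the J1 axis footprint (cm). The world
#'   origin is the centre of base marker 0, x along the marker-0 to marker-1
#'   edge, y into the table, z up.
#' @return An object of class `arm_geometry`.
#' @examples
#' g <- arm_geometry()
#' forward_kinematics(c(pi / 2, 0, 0), g)
#' @export
arm_geometry <- function(a0 = 22, a1 = 15, a2 = 13, a3 = 15,
                         joint_limits = default_joint_limits(),
                         base_position = c(0, 30)) {
  stopifnot(is.numeric(a0), is.numeric(a1), is.numeric(a2), is.numeric(a3))
  if (!all(is.finite(c(a0, a1, a2, a3))) || a0 < 0 || a1 <= 0 || a2 <= 0 || a3 <= 0)
    stop("link lengths a1, a2, a3 must be > 0 and a0 >= 0", call. = FALSE)
  joint_limits <- as.matrix(joint_limits)
  if (!identical(dim(joint_limits), c(3L, 2L)) || !all(is.finite(joint_limits)))
    stop("joint_limits must be a finite 3x2 matrix", call. = FALSE)
  span <- joint_limits[, 2] - joint_limits[, 1]
  if (any(span <= 0) || any(span > 1.5 * pi + 1e-12))
    stop("each joint limit must span (0, 270] degrees", call. = FALSE)
  if (length(base_position) != 2 || !all(is.finite(base_position)))
    stop("base_position must be a finite (x, y) pair", call. = FALSE)
  structure(
    list(a0 = a0, a1 = a1, a2 = a2, a3 = a3,
         joint_limits = joint_limits,
         base_position = as.numeric(base_position)),
    class = "arm_geometry"
  )
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("3-DoF arm geometry (cm)\n")
  cat(sprintf("  a0 = %.3g, a1 = %.3g, a2 = %.3g, a3 = %.3g\n",
              x$a0, x$a1, x$a2, x$a3))
  lim <- round(x$joint_limits, 4)
  cat(sprintf("  joint limits (rad): J1 [%g, %g]  J2 [%g, %g]  J3 [%g, %g]\n",
              lim[1, 1], lim[1, 2], lim[2, 1], lim[2, 2], lim[3, 1], lim[3, 2]))
  cat(sprintf("  base footprint at (%g, %g) cm\n",
              x$base_position[1], x$base_position[2]))
  invisible(x)
}

#' Default joint limits: 270 degree servo travel centred on the home pose
#' @return 3x2 matrix of angles in radians.
#' @export
default_joint_limits <- function() {
  half <- 0.75 * pi # 135 degrees either side
  rbind(c(pi / 2 - half, pi / 2 + half),
        c(-half, half),
        c(-half, half))
}

#' Home pose of the arm
#'
#' The arm rests at `theta1 = pi/2`, `theta2 = 0`, `theta3 = 0`, pointing
#' straight out over the table at shoulder height.
#' @return Numeric length-3 vector of joint angles (rad).
#' @export
home_angles <- function() c(pi / 2, 0, 0)

check_angles <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 3 || !all(is.finite(q)))
    stop("joint angles must be three finite values (rad)", call. = FALSE)
  q
}

#' Single-link Denavit-Hartenberg transform
#'
#' Builds the 4x4 homogeneous transform of one DH link:
#' rotation `theta` about z, offset `d` along z, length `a` along x,
#' twist `alpha` about x.
#'
#' @param theta Joint angle (rad).
#' @param alpha Twist angle (rad).
#' @param a Link length (cm).
#' @param d Link offset (cm).
#' @return 4x4 homogeneous transformation matrix.
#' @examples
#' dh_transform(0, 0, 0, 0) # identity
#' @export
dh_transform <- function(theta, alpha, a, d) {
  if (!all(is.finite(c(theta, alpha, a, d))))
    stop("dh_transform arguments must be finite", call. = FALSE)
  ct <- cos(theta); st <- sin(theta)
  ca <- cos(alpha); sa <- sin(alpha)
  matrix(c(ct, -st * ca, st * sa, a * ct,
           st, ct * ca, -ct * sa, a * st,
           0, sa, ca, d,
           0, 0, 0, 1),
         nrow = 4, byrow = TRUE)
}

#' Chained joint transforms T01, T02, T03
#'
#' Composes the per-joint DH transforms of the arm. The DH table is
#' `(theta1, pi/2, a1, a0)`, `(theta2, 0, a2, 0)`, `(theta3, 0, a3, 0)`;
#' the translation column of `T03` is the end-effector position.
#'
#' @param q Joint angles, numeric length 3 (rad).
#' @param g An [arm_geometry()].
#' @return Named list with matrices `T01`, `T02`, `T03`.
#' @export
chain_transforms <- function(q, g) {
  q <- check_angles(q)
  stopifnot(inherits(g, "arm_geometry"))
  T01 <- dh_transform(q[1], pi / 2, g$a1, g$a0)
  T12 <- dh_transform(q[2], 0, g$a2, 0)
  T23 <- dh_transform(q[3], 0, g$a3, 0)
  T02 <- T01 %*% T12
  T03 <- T02 %*% T23
  list(T01 = T01, T02 = T02, T03 = T03)
}

#' End-effector position from joint angles
#'
#' Closed-form forward kinematics of the arm:
#' `Px = c1 (a1 + a2 c2 + a3 c23)`, `Py = s1 (a1 + a2 c2 + a3 c23)`,
#' `Pz = a0 + a2 s2 + a3 s23`, with `c23 = cos(theta2 + theta3)` etc.
#' Coordinates are in the arm frame (origin under J1, z up).
#'
#' @param q Joint angles: a length-3 vector or an n x 3 matrix (rad).
#' @param g An [arm_geometry()].
#' @return Length-3 position (cm), or an n x 3 matrix if `q` is a matrix.
#' @export
forward_kinematics <- function(q, g) {
  stopifnot(inherits(g, "arm_geometry"))
  if (is.matrix(q)) {
    stopifnot(ncol(q) == 3, all(is.finite(q)))
    c1 <- cos(q[, 1]); s1 <- sin(q[, 1])
    c2 <- cos(q[, 2]); s2 <- sin(q[, 2])
    c23 <- cos(q[, 2] + q[, 3]); s23 <- sin(q[, 2] + q[, 3])
    r <- g$a1 + g$a2 * c2 + g$a3 * c23
    cbind(x = c1 * r, y = s1 * r, z = g$a0 + g$a2 * s2 + g$a3 * s23)
  } else {
    q <- check_angles(q)
    stats::setNames(c(forward_kinematics(matrix(q, nrow = 1), g)),
                    c("x", "y", "z"))
  }
}

radial_annulus <- function(target, g, sign = 1) {
  # planar two-link condition in the (u, v) = (signed radial - a1, z - a0)
  # plane; sign = -1 is the wrapped-azimuth family (theta1 offset by pi)
  u <- sign * sqrt(target[1]^2 + target[2]^2) - g$a1
  v <- target[3] - g$a0
  d2 <- u^2 + v^2
  list(u = u, v = v, d2 = d2,
       inside = d2 >= (g$a2 - g$a3)^2 - 1e-12 & d2 <= (g$a2 + g$a3)^2 + 1e-12)
}

planar_pair <- function(ann, g, branch) {
  D <- (ann$d2 - g$a2^2 - g$a3^2) / (2 * g$a2 * g$a3)
  D <- min(1, max(-1, D))
  th3 <- if (branch == "elbow-up") -acos(D) else acos(D)
  th2 <- atan2(ann$v, ann$u) -
    atan2(g$a3 * sin(th3), g$a2 + g$a3 * cos(th3))
  c(th2, th3)
}

within_limits <- function(q, g, tol = 1e-9) {
  all(q >= g$joint_limits[, 1] - tol & q <= g$joint_limits[, 2] + tol)
}

azimuth_values <- function(base, lim) {
  # all angles congruent to base (mod 2pi) inside the J1 limits
  k <- seq(floor((lim[1] - base) / (2 * pi)), ceiling((lim[2] - base) / (2 * pi)))
  v <- base + 2 * pi * k
  v[v >= lim[1] - 1e-9 & v <= lim[2] + 1e-9]
}

# all in-limit solutions, as a list of (angles, family sign, branch)
ik_candidates <- function(target, g) {
  base <- atan2(target[2], target[1])
  lim1 <- g$joint_limits[1, ]
  out <- list()
  any_annulus <- FALSE
  for (fam in c(1, -1)) {
    ann <- radial_annulus(target, g, sign = fam)
    if (!ann$inside) next
    az <- azimuth_values(if (fam == 1) base else base + pi, lim1)
    if (fam == 1) any_annulus <- TRUE
    for (th1 in az) {
      for (br in c("elbow-up", "elbow-down")) {
        q <- c(th1, planar_pair(ann, g, br))
        if (within_limits(q, g))
          out[[length(out) + 1]] <- list(q = q, family = fam, branch = br)
      }
    }
    if (length(az) > 0) any_annulus <- TRUE
  }
  attr(out, "annulus_ok") <- any_annulus ||
    radial_annulus(target, g, 1)$inside || radial_annulus(target, g, -1)$inside
  out
}

#' Is a target position reachable?
#'
#' A point is reachable when the planar two-link annulus condition holds in
#' the radial plane and at least one elbow branch of the analytic inverse
#' kinematics lies within the joint limits.
#'
#' @param target Length-3 position (cm), arm frame.
#' @param g An [arm_geometry()].
#' @return Logical with attribute `reason` (`"ok"`, `"outside reach"`,
#'   `"joint limits"`, or `"degenerate azimuth"`).
#' @export
is_reachable <- function(target, g) {
  target <- as.numeric(target)
  stopifnot(length(target) == 3, all(is.finite(target)))
  out <- function(ok, reason) structure(ok, reason = reason)
  if (target[1] == 0 && target[2] == 0)
    return(out(FALSE, "degenerate azimuth"))
  cand <- ik_candidates(target, g)
  if (length(cand) > 0) return(out(TRUE, "ok"))
  if (attr(cand, "annulus_ok")) out(FALSE, "joint limits")
  else out(FALSE, "outside reach")
}

#' Analytic inverse kinematics
#'
#' Closed-form joint angles for a reachable target: the base azimuth is
#' `atan2(y, x)` and the elbow pair solves the planar two-link problem in the
#' radial-vertical plane. The elbow-up branch (`theta3 <= 0`) approaches the
#' table from above and is the default.
#'
#' @param target Length-3 position (cm), arm frame.
#' @param g An [arm_geometry()].
#' @param branch `"elbow-up"` (default) or `"elbow-down"`.
#' @return Length-3 joint angles (rad) whose forward kinematics reproduce
#'   `target` to better than 1e-9 cm.
#' @export
analytic_inverse_kinematics <- function(target, g,
                                        branch = c("elbow-up", "elbow-down")) {
  branch <- match.arg(branch)
  target <- as.numeric(target)
  stopifnot(length(target) == 3, all(is.finite(target)))
  if (target[1] == 0 && target[2] == 0)
    stop("degenerate azimuth: target lies on the vertical base axis", call. = FALSE)
  cand <- ik_candidates(target, g)
  if (length(cand) == 0)
    stop("target unreachable: ",
         if (attr(cand, "annulus_ok")) "joint limits" else "outside reach",
         call. = FALSE)
  # prefer the principal azimuth family and the requested elbow branch
  score <- vapply(cand, function(cc)
    (cc$family == 1) * 2 + (cc$branch == branch), 0)
  cand[[which.max(score)]]$q
}

#' Work-zone layout of the tabletop
#'
#' The marker-bounded work area (default 60 x 30 cm) is divided into four
#' zones. The default layout splits the field of the arm into four equal
#' angular sectors about the base footprint; a custom layout may instead
#' supply a named list of polygons (`Z1`..`Z4`, each an n x 2 matrix of cm
#' coordinates) which are scanned in order, so boundary points fall to the
#' lowest-numbered zone.
#'
#' @param work_area Width and depth of the table area (cm).
#' @param base World (x, y) of the arm base footprint (cm).
#' @param polygons Optional named list of zone polygons overriding the
#'   sector default.
#' @return An object of class `zone_layout`.
#' @export
zone_layout <- function(work_area = c(60, 30), base = c(0, 30),
                        polygons = NULL) {
  stopifnot(length(work_area) == 2, all(work_area > 0))
  if (!is.null(polygons)) {
    stopifnot(is.list(polygons), length(polygons) >= 1)
    polygons <- lapply(polygons, function(p) {
      p <- as.matrix(p)
      stopifnot(ncol(p) == 2, nrow(p) >= 3)
      p
    })
  }
  structure(list(work_area = as.numeric(work_area), base = as.numeric(base),
                 polygons = polygons),
            class = "zone_layout")
}

point_in_polygon <- function(pt, poly) {
  # even-odd ray cast; points on an edge count as inside
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    d <- abs((xj - xi) * (pt[2] - yi) - (yj - yi) * (pt[1] - xi))
    if (d < 1e-9 &&
        pt[1] >= min(xi, xj) - 1e-9 && pt[1] <= max(xi, xj) + 1e-9 &&
        pt[2] >= min(yi, yj) - 1e-9 && pt[2] <= max(yi, yj) + 1e-9)
      return(TRUE)
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

#' Zone of a tabletop point
#'
#' Assigns a 2-D table coordinate to one of the four work zones (or
#' `"outside"` if it is not in the work area). Boundary points go to the
#' lowest-numbered adjacent zone.
#'
#' @param point Length-2 table coordinate (cm).
#' @param layout A [zone_layout()].
#' @return `"Z1"`..`"Z4"` or `"outside"`.
#' @export
zone_of <- function(point, layout = zone_layout()) {
  stopifnot(inherits(layout, "zone_layout"))
  point <- as.numeric(point)
  stopifnot(length(point) == 2, all(is.finite(point)))
  wa <- layout$work_area
  if (point[1] < 0 || point[1] > wa[1] || point[2] < 0 || point[2] > wa[2])
    return("outside")
  if (!is.null(layout$polygons)) {
    for (nm in names(layout$polygons)) {
      if (point_in_polygon(point, layout$polygons[[nm]])) return(nm)
    }
    return("outside")
  }
  # angular sectors about the base: the rectangle subtends [-pi/2, 0]
  # when the base sits at the (0, depth) corner
  ang <- atan2(point[2] - layout$base[2], point[1] - layout$base[1])
  lo <- -pi / 2
  width <- (pi / 2) / 4
  t <- (ang - lo) / width
  k <- max(1L, min(4L, as.integer(ceiling(t - 1e-12))))
  paste0("Z", k)
}
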