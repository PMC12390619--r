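#' Fiducial-marker layout of the tabletop work area
#'
#' Four square markers sit at the corners of the rectangular work area
#' (default 600 x 300 mm, i.e. 60 x 30 cm). Marker 0 is the base marker: its
#' centre is the world origin, x runs along the marker-0 to marker-1 edge,
#' y into the table, z up.
#'
#' @param work_area_mm Width and depth of the work area in millimetres.
#' @param marker_size_mm Marker edge length in millimetres (default 50).
#' @return Object of class `marker_layout`: per-marker centre and corner
#'   coordinates in cm (z = 0), plus the work-area size in cm.
#' @export
marker_layout <- function(work_area_mm = c(600, 300), marker_size_mm = 50) {
  stopifnot(length(work_area_mm) == 2, all(work_area_mm > 0), marker_size_mm > 0)
  wa <- as.numeric(work_area_mm) / 10 # mm -> cm at the boundary
  h <- marker_size_mm / 10 / 2
  centres <- rbind(`0` = c(0, 0), `1` = c(wa[1], 0),
                   `2` = c(wa[1], wa[2]), `3` = c(0, wa[2]))
  markers <- lapply(seq_len(4), function(i) {
    ctr <- centres[i, ]
    corners <- rbind(ctr + c(-h, -h), ctr + c(h, -h),
                     ctr + c(h, h), ctr + c(-h, h))
    list(id = i - 1L, center = ctr, corners = corners)
  })
  names(markers) <- rownames(centres)
  structure(list(markers = markers, work_area = wa,
                 marker_size = marker_size_mm / 10),
            class = "marker_layout")
}

normalize_points <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  Tm <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  list(T = Tm, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
}

#' Estimate the pixel-to-world planar map (normalized DLT homography)
#'
#' Least-squares estimate of the 3x3 homography taking pixel coordinates to
#' table-plane coordinates, from at least four non-collinear point
#' correspondences, with Hartley normalization of both point sets. The
#' residual is the RMS reprojection error in pixels.
#'
#' @param pixel_points n x 2 matrix of pixel coordinates (0-based, top-left
#'   origin, x right / y down).
#' @param world_points n x 2 matrix of matched table-plane coordinates (cm).
#' @param marker_ids Optional ids of the markers the points came from.
#' @return Object of class `planar_map`: `H` (3x3, scale-normalized),
#'   `residual` (px), `marker_ids`.
#' @export
estimate_planar_map <- function(pixel_points, world_points, marker_ids = NULL) {
  px <- as.matrix(pixel_points); wd <- as.matrix(world_points)
  stopifnot(ncol(px) == 2, ncol(wd) == 2, nrow(px) == nrow(wd))
  if (nrow(px) < 4)
    stop("at least 4 point correspondences are required", call. = FALSE)
  if (!all(is.finite(px)) || !all(is.finite(wd)))
    stop("correspondences must be finite", call. = FALSE)
  np <- normalize_points(px)
  nw <- normalize_points(wd)
  x <- np$p[, 1]; y <- np$p[, 2]
  u <- nw$p[, 1]; v <- nw$p[, 2]
  zero <- rep(0, nrow(px)); one <- rep(1, nrow(px))
  A <- rbind(
    cbind(-x, -y, -one, zero, zero, zero, u * x, u * y, u),
    cbind(zero, zero, zero, -x, -y, -one, v * x, v * y, v)
  )
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1])
    stop("degenerate point configuration (collinear or coincident points)",
         call. = FALSE)
  h <- sv$v[, 9]
  H <- solve(nw$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% np$T
  H <- if (abs(H[3, 3]) > 1e-12) H / H[3, 3] else H / sqrt(sum(H^2))
  map <- structure(list(H = H, residual = 0,
                        marker_ids = marker_ids),
                   class = "planar_map")
  back <- world_to_pixel(map, wd)
  map$residual <- sqrt(mean(rowSums((back - px)^2)))
  map
}

#' @export
print.planar_map <- function(x, ...) {
  cat("planar pixel-to-world map (3x3 homography)\n")
  print(round(x$H, 6))
  cat(sprintf("RMS reprojection residual: %.4g px\n", x$residual))
  invisible(x)
}

apply_homography <- function(H, p) {
  p <- if (is.matrix(p)) p else matrix(as.numeric(p), nrow = 1)
  stopifnot(ncol(p) == 2, all(is.finite(p)))
  q <- cbind(p, 1) %*% t(H)
  w <- q[, 3]
  if (any(abs(w) < 1e-12))
    stop("singular projection: point maps to infinity", call. = FALSE)
  cbind(q[, 1] / w, q[, 2] / w)
}

#' Map pixel coordinates to the table plane
#'
#' @param map A [estimate_planar_map()] result.
#' @param p Pixel point(s): length-2 vector or n x 2 matrix.
#' @return Table-plane coordinates in cm (same shape as input; z = 0 by
#'   construction).
#' @export
pixel_to_world <- function(map, p) {
  stopifnot(inherits(map, "planar_map"))
  out <- apply_homography(map$H, p)
  if (is.matrix(p)) out else c(out)
}

#' Map table-plane coordinates back to pixels
#'
#' @inheritParams pixel_to_world
#' @param p World point(s) in cm.
#' @export
world_to_pixel <- function(map, p) {
  stopifnot(inherits(map, "planar_map"))
  out <- apply_homography(solve(map$H), p)
  if (is.matrix(p)) out else c(out)
}

#' @export
predict.planar_map <- function(object, newdata, ...) {
  pixel_to_world(object, newdata)
}

#' Marker-validity rule
#'
#' Detection is valid only when at least three markers are visible and the
#' base marker (id 0) is among them.
#'
#' @param detected_ids Integer ids of the detected markers.
#' @return List with `ok`; when invalid, also `reason` and the user-facing
#'   `message` `"ArUco not found; please recalibrate"`.
#' @export
validate_markers <- function(detected_ids) {
  ids <- unique(as.integer(detected_ids))
  ok <- length(ids) >= 3 && 0L %in% ids
  if (ok) {
    list(ok = TRUE)
  } else {
    reason <- if (!0L %in% ids) "base marker (id 0) not detected"
              else "fewer than three markers visible"
    list(ok = FALSE, reason = reason,
         message = "ArUco not found; please recalibrate")
  }
}

#' A detection record
#'
#' @param class_name Object class label.
#' @param box Pixel bounding box `c(x_min, y_min, x_max, y_max)`, 0-based,
#'   top-left origin; must satisfy `x_min < x_max`, `y_min < y_max`.
#' @param confidence Detector confidence in `[0, 1]`.
#' @return Object of class `detection`.
#' @export
detection <- function(class_name, box, confidence = 1) {
  box <- as.numeric(box)
  stopifnot(length(box) == 4, all(is.finite(box)),
            confidence >= 0, confidence <= 1)
  if (box[1] >= box[3] || box[2] >= box[4])
    stop("degenerate bounding box: need x_min < x_max and y_min < y_max",
         call. = FALSE)
  structure(list(class = as.character(class_name), box = box,
                 confidence = confidence),
            class = "detection")
}

#' Centroid of a detection bounding box
#'
#' @param d A [detection()] or a raw `c(x_min, y_min, x_max, y_max)` box.
#' @return Pixel centroid `c(x, y)`.
#' @export
centroid_of_box <- function(d) {
  box <- if (inherits(d, "detection")) d$box else detection("x", d)$box
  c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
}

#' World coordinates of a detected target
#'
#' Maps the detection's bounding-box centroid onto the table plane and sets z
#' to the configured object height (the reach target aims at the top of the
#' object; 0 means tabletop). If the mapped point falls outside the work
#' area a warning is raised but coordinates are still returned, with
#' attribute `in_area = FALSE`.
#'
#' @param d A [detection()].
#' @param map A [estimate_planar_map()] result.
#' @param object_height Height of the target above the table (cm).
#' @param work_area Work-area width and depth (cm).
#' @return Length-3 world position (cm) with attribute `in_area`.
#' @export
target_world_coordinates <- function(d, map, object_height = 0,
                                     work_area = c(60, 30)) {
  stopifnot(inherits(d, "detection"))
  ctr <- centroid_of_box(d)
  xy <- pixel_to_world(map, ctr)
  in_area <- xy[1] >= 0 && xy[1] <= work_area[1] &&
    xy[2] >= 0 && xy[2] <= work_area[2]
  if (!in_area)
    warning("target centroid maps outside the work area", call. = FALSE)
  structure(c(xy[1], xy[2], object_height), in_area = in_area)
}
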