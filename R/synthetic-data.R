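#' Configuration of the synthetic band-power stream generator
#'
#' The generator emulates a 32-channel, 5-band power stream at 8 samples per
#' second with a binary state label (0 relaxed, 1 jaw clench). Features fall
#' into three behavioural patterns: a minority whose extreme upper tail
#' appears almost exclusively during clench samples but only with partial
#' penetrance (so a single-feature rule misses roughly half the clenches), a
#' majority with overlapping state-conditional distributions that shift only
#' weakly with the clench, and a few whose clench values concentrate in a
#' narrow low-density band. Band powers are drawn from log-normal families
#' (non-negative, right-skewed).
#'
#' @param n_samples Number of stream samples.
#' @param pos_fraction Fraction of clench (label 1) samples, in (0, 1).
#' @param pattern_counts Named counts for `pattern1`, `pattern2`, `pattern3`;
#'   must sum to 160.
#' @param penetrance Marginal probability that a clench sample expresses the
#'   pattern-1 tail (default 0.38, placing the best single-feature accuracy
#'   near 70%).
#' @param tail_shift Log-scale offset of the pattern-1 tail component.
#' @param shift2 Log-scale location shift of pattern-2 features under clench.
#' @param band_prob Probability a clench sample expresses the pattern-3 band.
#' @param band_center,band_sd Log-scale centre offset and width of the
#'   pattern-3 band.
#' @param base_sdlog Log-scale spread of the relaxed-state distribution.
#' @param tail_cor Weight of the shared per-sample latent in the pattern-1/-3
#'   event indicators (0 = independent features, 1 = perfectly co-occurring).
#' @param noise_cor Correlation of the common log-noise component shared by
#'   all pattern-2 features.
#' @param sps Samples per second of the stream (default 8).
#' @param seed Generator seed.
#' @return Object of class `fbp_gen_config`.
#' @export
fbp_gen_config <- function(n_samples = 2000L, pos_fraction = 0.5,
                           pattern_counts = c(pattern1 = 16L, pattern2 = 132L,
                                              pattern3 = 12L),
                           penetrance = 0.38, tail_shift = 2.5,
                           shift2 = 0.35, band_prob = 0.25,
                           band_center = 1.2, band_sd = 0.08,
                           base_sdlog = 0.6, tail_cor = 0.65,
                           noise_cor = 0.7, sps = 8, seed = 1L) {
  stopifnot(n_samples >= 2, pos_fraction > 0, pos_fraction < 1,
            penetrance > 0, penetrance < 1, sps > 0)
  pattern_counts <- as.integer(pattern_counts)
  if (length(pattern_counts) != 3 || any(pattern_counts < 0) ||
      sum(pattern_counts) != 160L)
    stop("pattern counts must be three non-negative integers summing to 160",
         call. = FALSE)
  names(pattern_counts) <- c("pattern1", "pattern2", "pattern3")
  structure(list(n_samples = as.integer(n_samples),
                 pos_fraction = pos_fraction,
                 pattern_counts = pattern_counts,
                 penetrance = penetrance, tail_shift = tail_shift,
                 shift2 = shift2, band_prob = band_prob,
                 band_center = band_center, band_sd = band_sd,
                 base_sdlog = base_sdlog, tail_cor = tail_cor,
                 noise_cor = noise_cor, sps = sps, seed = as.integer(seed)),
            class = "fbp_gen_config")
}

feature_patterns <- function(cfg) {
  rep(c("pattern1", "pattern2", "pattern3"), times = cfg$pattern_counts)
}

feature_names <- function() sprintf("f%03d", 0:159)

# CDF of w*t + (1-w)*u for independent t, u ~ U(0,1) (trapezoidal density);
# used to give the shared-latent tail indicator an exactly uniform margin.
trapezoid_cdf <- function(x, w) {
  a <- min(w, 1 - w); b <- max(w, 1 - w)
  ifelse(x < a, x^2 / (2 * a * b),
         ifelse(x < b, (2 * x - a) / (2 * b),
                1 - pmax(0, 1 - x)^2 / (2 * a * b)))
}

# Features for a given 0/1 label vector; assumes the RNG state is set by the
# caller. Concurrent band powers of one sample are strongly correlated, as
# they would be for a single muscle artifact: a per-sample clench intensity
# scales all pattern responses, a shared tail/band propensity makes the
# pattern-1/-3 events co-occur across features, and a common log-normal
# noise component is shared by all pattern-2 features. This redundancy is
# what keeps ensemble accuracy bounded well below perfect.
fbp_features_for_labels <- function(labels, cfg) {
  n <- length(labels)
  pat <- feature_patterns(cfg)
  meanlog <- seq(1.5, 3.5, length.out = 160) # per-feature baseline level
  rho <- cfg$noise_cor
  z <- stats::rnorm(n) # shared log-noise, both states
  x <- matrix(stats::rlnorm(n * 160, meanlog = rep(meanlog, each = n),
                            sdlog = cfg$base_sdlog), nrow = n)
  for (j in which(pat == "pattern2")) {
    x[, j] <- exp(meanlog[j] + cfg$base_sdlog *
                    (rho * z + sqrt(1 - rho^2) * stats::rnorm(n)))
  }
  pos <- which(labels == 1L)
  if (length(pos)) {
    np <- length(pos)
    s <- stats::runif(np, 0.3, 1) # clench intensity
    gain <- (0.4 + 0.6 * s) / (0.4 + 0.6 * 0.65) # unit-mean modulation
    w <- cfg$tail_cor
    t1 <- stats::runif(np) # shared tail propensity
    t3 <- stats::runif(np) # shared band propensity
    for (j in which(pat == "pattern1")) {
      v <- trapezoid_cdf(w * t1 + (1 - w) * stats::runif(np), w)
      tail <- v < cfg$penetrance * gain
      nt <- sum(tail)
      if (nt) x[pos[tail], j] <-
          stats::rlnorm(nt, meanlog[j] + cfg$tail_shift, 0.3)
    }
    for (j in which(pat == "pattern2")) {
      x[pos, j] <- x[pos, j] * exp(cfg$shift2 * s)
    }
    for (j in which(pat == "pattern3")) {
      v <- trapezoid_cdf(w * t3 + (1 - w) * stats::runif(np), w)
      inband <- v < cfg$band_prob * gain
      nb <- sum(inband)
      if (nb) x[pos[inband], j] <-
          stats::rlnorm(nb, meanlog[j] + cfg$band_center, cfg$band_sd)
    }
  }
  colnames(x) <- feature_names()
  x
}

#' Generate a labeled synthetic band-power stream
#'
#' @param cfg An [fbp_gen_config()].
#' @return Data frame with `timestamp` (s, at `cfg$sps` samples per second),
#'   feature columns `f000`..`f159`, and `label` (0/1). Byte-identical for
#'   the same config and seed.
#' @export
generate_fbp_stream <- function(cfg = fbp_gen_config()) {
  stopifnot(inherits(cfg, "fbp_gen_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  labels <- as.integer(stats::runif(n) < cfg$pos_fraction)
  x <- fbp_features_for_labels(labels, cfg)
  out <- data.frame(timestamp = (seq_len(n) - 1) / cfg$sps, x,
                    label = labels)
  attr(out, "config") <- cfg
  out
}

#' Sample reach targets in the utilized work region
#'
#' Draws tabletop targets uniformly in polar coordinates about the arm base:
#' azimuth across the quarter-plane the table subtends and radius inside the
#' utilized portion of the reach annulus. The default radial band [8, 30] cm
#' keeps a margin inside the stretched-arm rim (about 32.3 cm at tabletop
#' height for the default geometry), where the arm is near-singular and no
#' object of practical size would be placed.
#'
#' @param n Number of targets.
#' @param g An [arm_geometry()].
#' @param radius Radial band (cm) about the base.
#' @param azimuth Azimuth range (rad) in the arm frame.
#' @param z Target height(s) above the table (cm); recycled.
#' @param seed Optional seed.
#' @return n x 3 matrix of arm-frame targets (cm), all reachable.
#' @export
sample_reach_targets <- function(n, g = arm_geometry(), radius = c(8, 30),
                                 azimuth = c(0, pi / 2), z = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  az <- stats::runif(n, azimuth[1], azimuth[2])
  rad <- stats::runif(n, radius[1], radius[2])
  out <- cbind(x = rad * cos(az), y = rad * sin(az),
               z = rep_len(z, n))
  ok <- vapply(seq_len(n), function(i) isTRUE(is_reachable(out[i, ], g)),
               NA)
  if (!all(ok))
    stop("sampled target outside the reachable set; narrow the radius band",
         call. = FALSE)
  out
}

#' Configuration of the synthetic tabletop scene generator
#'
#' @param objects Data frame with columns `class`, `x`, `y` (cm, world) and
#'   optionally `footprint` (edge of the square ground footprint, cm,
#'   default 6) and `height` (cm, default 0).
#' @param work_area Work-area width and depth (cm).
#' @param layout A [marker_layout()].
#' @param camera 3x3 world-to-pixel homography. The default is an affine map
#'   (10 px/cm scale, small shear, offset); a projective map may be supplied.
#' @param pixel_noise Standard deviation of i.i.d. pixel noise added to
#'   every projected point.
#' @param occluded_ids Marker ids hidden from the camera.
#' @param seed Scene seed.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(objects = data.frame(class = "cup", x = 15, y = 20),
                         work_area = c(60, 30),
                         layout = marker_layout(),
                         camera = default_camera_map(),
                         pixel_noise = 0, occluded_ids = integer(0),
                         seed = 1L) {
  stopifnot(is.data.frame(objects), all(c("class", "x", "y") %in% names(objects)),
            pixel_noise >= 0)
  if (is.null(objects$footprint)) objects$footprint <- 6
  if (is.null(objects$height)) objects$height <- 0
  if (any(objects$x < 0 | objects$x > work_area[1] |
          objects$y < 0 | objects$y > work_area[2]))
    stop("objects must lie inside the work area", call. = FALSE)
  camera <- as.matrix(camera)
  stopifnot(identical(dim(camera), c(3L, 3L)), abs(det(camera)) > 1e-12)
  structure(list(objects = objects, work_area = as.numeric(work_area),
                 layout = layout, camera = camera, pixel_noise = pixel_noise,
                 occluded_ids = as.integer(occluded_ids),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Default world-to-pixel camera map (affine)
#'
#' 10 px/cm scale with a mild shear and a (100, 80) px offset. Affine by
#' default so that the centroid of a projected square footprint coincides
#' with the projection of its centre.
#' @return 3x3 matrix.
#' @export
default_camera_map <- function() {
  rbind(c(10, 0.8, 100),
        c(-0.5, 9.5, 80),
        c(0, 0, 1))
}

#' Generate a synthetic tabletop scene
#'
#' Projects the marker corners and object footprints through the known
#' camera map, adds pixel noise, and packages the observations the
#' perception module consumes (marker pixel corners per visible id, a
#' detections list with pixel bounding boxes) together with the retained
#' ground truth.
#'
#' @param cfg A [scene_config()].
#' @return Object of class `scene`: `visible_ids`, `marker_pixels` (named
#'   list of 4 x 2 corner matrices), `detections` (list of [detection()]),
#'   `truth` (the object table), `camera`, `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  project <- function(pts) {
    q <- cbind(pts, 1) %*% t(cfg$camera)
    out <- q[, 1:2, drop = FALSE] / q[, 3]
    if (cfg$pixel_noise > 0)
      out <- out + matrix(stats::rnorm(length(out), sd = cfg$pixel_noise),
                          nrow = nrow(out))
    out
  }
  visible <- setdiff(0:3, cfg$occluded_ids)
  marker_pixels <- list()
  for (id in visible) {
    mk <- cfg$layout$markers[[as.character(id)]]
    marker_pixels[[as.character(id)]] <- project(mk$corners)
  }
  detections <- lapply(seq_len(nrow(cfg$objects)), function(i) {
    ob <- cfg$objects[i, ]
    h <- ob$footprint / 2
    corners <- cbind(ob$x + c(-h, h, h, -h), ob$y + c(-h, -h, h, h))
    px <- project(corners)
    detection(ob$class,
              c(min(px[, 1]), min(px[, 2]), max(px[, 1]), max(px[, 2])))
  })
  structure(list(visible_ids = visible, marker_pixels = marker_pixels,
                 detections = detections, truth = cfg$objects,
                 camera = cfg$camera, config = cfg),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("synthetic tabletop scene: %d object(s), markers visible: %s\n",
              length(x$detections),
              paste(x$visible_ids, collapse = ", ")))
  invisible(x)
}

#' Marker correspondences of a scene
#'
#' Stacks the pixel and world corner coordinates of the visible markers,
#' ready for [estimate_planar_map()].
#'
#' @param scene A [generate_scene()] result.
#' @return List with `pixel`, `world` (matched n x 2 matrices) and `ids`.
#' @export
scene_correspondences <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  px <- do.call(rbind, scene$marker_pixels)
  wd <- do.call(rbind, lapply(scene$visible_ids, function(id)
    scene$config$layout$markers[[as.character(id)]]$corners))
  list(pixel = px, world = wd, ids = scene$visible_ids)
}

#' Configuration of the prompting-session generator
#'
#' @param n_objects Number of prompted objects; drawn uniformly from 5..8
#'   when `NULL`.
#' @param object_names Candidate object names.
#' @param target_index Index of the target statement; random when `NULL`.
#' @param wpm Dictation speech rate (words per minute, default 200).
#' @param gap Pause between statements (s, default 1.5).
#' @param rt_mean,rt_sd Reaction-time distribution (s): normal, truncated at
#'   zero. Defaults 0.756 and 0.14.
#' @param seed Session seed.
#' @return Object of class `session_config`.
#' @export
session_config <- function(n_objects = NULL,
                           object_names = c("mouse", "cellphone", "remote",
                                            "book", "pen", "bottle", "cup",
                                            "scissors"),
                           target_index = NULL, wpm = 200, gap = 1.5,
                           rt_mean = 0.756, rt_sd = 0.14, seed = 1L) {
  if (!is.null(n_objects))
    stopifnot(n_objects >= 5, n_objects <= 8)
  stopifnot(wpm > 0, gap > 0, rt_sd >= 0)
  structure(list(n_objects = n_objects, object_names = object_names,
                 target_index = target_index, wpm = wpm, gap = gap,
                 rt_mean = rt_mean, rt_sd = rt_sd, seed = as.integer(seed)),
            class = "session_config")
}

word_count <- function(s) lengths(strsplit(s, "\\s+"))

number_words <- c("One", "Two", "Three", "Four", "Five", "Six", "Seven",
                  "Eight")

#' Generate a prompting-session timeline
#'
#' Builds the dictation timeline of one selection trial: an introductory
#' summary statement followed by one numbered statement per object, read at
#' the configured speech rate with fixed gaps, plus the user's clench event:
#' a reaction time drawn from the (zero-truncated) normal distribution after
#' the onset of the target statement.
#'
#' @param cfg A [session_config()].
#' @param object_names Optional explicit object list (overrides the sampled
#'   one, e.g. the classes detected in a scene).
#' @return Object of class `session`: `statements` (data frame with text,
#'   start, end), `target_index`, `target_onset`, `reaction_time`,
#'   `clench_time`, and `within_window` (whether the selection lands before
#'   the next statement begins, i.e. inside the statement plus its 1500 ms
#'   gap).
#' @export
generate_session <- function(cfg = session_config(), object_names = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(cfg$seed)
  if (is.null(object_names)) {
    k <- if (is.null(cfg$n_objects)) sample(5:8, 1) else cfg$n_objects
    object_names <- sample(cfg$object_names, k)
  }
  k <- length(object_names)
  target <- if (is.null(cfg$target_index)) sample(k, 1) else cfg$target_index
  stopifnot(target >= 1, target <= k)
  texts <- c(
    sprintf("The number of objects detected are %s. They are %s. Please select any.",
            tolower(number_words[k]), paste(object_names, collapse = ", ")),
    sprintf("%s is %s.", number_words[seq_len(k)], object_names)
  )
  dur <- word_count(texts) / (cfg$wpm / 60)
  start <- cumsum(c(0, utils::head(dur + cfg$gap, -1)))
  end <- start + dur
  st <- data.frame(statement = seq_along(texts) - 1L, text = texts,
                   start = start, end = end)
  onset <- start[target + 1L] # statement 0 is the summary
  rt <- stats::rnorm(1, cfg$rt_mean, cfg$rt_sd)
  while (rt <= 0) rt <- stats::rnorm(1, cfg$rt_mean, cfg$rt_sd)
  clench <- onset + rt
  next_onset <- if (target + 2L <= length(start)) start[target + 2L]
                else end[target + 1L] + cfg$gap
  structure(list(statements = st, object_names = object_names,
                 target_index = target, target_onset = onset,
                 reaction_time = rt, clench_time = clench,
                 window_end = next_onset,
                 within_window = clench < next_onset,
                 config = cfg),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("prompt session: %d objects, target #%d ('%s')\n",
              length(x$object_names), x$target_index,
              x$object_names[x$target_index]))
  cat(sprintf("target onset %.2f s, clench at %.2f s (reaction %.3f s, %s window)\n",
              x$target_onset, x$clench_time, x$reaction_time,
              if (x$within_window) "inside" else "outside"))
  invisible(x)
}
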