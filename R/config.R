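#' Read a structured system configuration file
#'
#' One YAML file with optional sections `geometry`, `gd`, `ensemble`,
#' `network`, `fbp`, `session`, `zones`. Lengths are centimetres and angles
#' radians; keys suffixed `_mm` are converted to cm at this boundary.
#'
#' @param path Path to a YAML config file.
#' @return Named list of constructed configuration objects (sections absent
#'   from the file get package defaults).
#' @export
read_system_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mm_fix <- function(section) {
    if (is.null(section)) return(list())
    for (nm in names(section)) {
      if (grepl("_mm$", nm)) {
        section[[sub("_mm$", "", nm)]] <-
          unlist(section[[nm]]) / 10
        section[[nm]] <- NULL
      }
    }
    section
  }
  build <- function(fun, section) do.call(fun, mm_fix(section))
  geo <- mm_fix(raw$geometry)
  if (!is.null(geo$joint_limits))
    geo$joint_limits <- matrix(unlist(geo$joint_limits), ncol = 2, byrow = TRUE)
  list(
    geometry = do.call(arm_geometry, geo),
    gd = build(gd_config, raw$gd),
    ensemble = build(ensemble_config, raw$ensemble),
    network = build(network_config, raw$network),
    fbp = build(fbp_gen_config, raw$fbp),
    session = build(session_config, raw$session),
    zones = if (is.null(raw$zones)) zone_layout() else
      zone_layout(work_area = unlist(raw$zones$work_area),
                  base = unlist(raw$zones$base),
                  polygons = raw$zones$polygons)
  )
}

#' Export a homogeneous transform or planar map as JSON
#'
#' @param x A 4x4 transform, a `planar_map`, or a `reach_plan`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "planar_map")) {
    list(H = unclass(as.data.frame(x$H)), residual = x$residual)
  } else if (inherits(x, "reach_plan")) {
    list(target = x$target, converged = x$converged,
         iterations = x$iterations, final_sse = x$final_sse,
         written = apply(x$written, 1, c, simplify = FALSE),
         read = apply(x$read, 1, c, simplify = FALSE),
         sse = x$sse)
  } else if (is.matrix(x)) {
    apply(x, 1, c, simplify = FALSE)
  } else {
    x
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
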