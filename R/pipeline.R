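#' Run one simulated closed-loop trial
#'
#' Orchestrates a full selection-and-reach trial: validate the scene's
#' markers, estimate the pixel-to-world map, prompt the detected objects,
#' synthesize the band-power stream aligned with the session's clench event,
#' decode it with the trained classifier, map the selected detection to world
#' coordinates and plan the reach by gradient descent. Stage failures are
#' recorded with the device's message semantics ("ArUco not found; please
#' recalibrate", "servo fault").
#'
#' @param scene A [generate_scene()] result.
#' @param model A trained trigger classifier (`scdc_boost`, `scdc_net`, or
#'   anything with a `predict(..., type = "class")` method).
#' @param geometry An [arm_geometry()].
#' @param gd A [gd_config()].
#' @param fbp An [fbp_gen_config()] providing the stream's feature
#'   distributions.
#' @param session A [session_config()].
#' @param debounce_k Consecutive positive decodes required for a selection.
#' @param clench True clench present? `FALSE` simulates a no-selection trial
#'   (an all-relaxed stream).
#' @param clench_duration Length of the labeled clench burst (s).
#' @param use_safe_approach Plan via [plan_safe_approach()] instead of a
#'   direct reach.
#' @param seed Trial seed (drives the stream noise).
#' @return Object of class `trial_log`: status, decoded events, outcome
#'   (`"TP"`, `"FP"`, `"FN"` or `"TN"`), selected object, target world
#'   coordinates, and a plan summary (iterations, final SSE, convergence).
#' @export
run_trial <- function(scene, model, geometry = arm_geometry(),
                      gd = gd_config(), fbp = fbp_gen_config(),
                      session = session_config(), debounce_k = 3L,
                      clench = TRUE, clench_duration = 0.75,
                      use_safe_approach = FALSE, seed = 1L) {
  stopifnot(inherits(scene, "scene"))
  log <- list(seed = seed, outcome = NA_character_, status = "ok",
              events = numeric(0))

  mv <- validate_markers(scene$visible_ids)
  if (!mv$ok) {
    log$status <- "aborted"
    log$message <- mv$message
    class(log) <- "trial_log"
    return(log)
  }
  corr <- scene_correspondences(scene)
  map <- estimate_planar_map(corr$pixel, corr$world, marker_ids = corr$ids)
  log$map_residual <- map$residual

  classes <- vapply(scene$detections, function(d) d$class, "")
  set.seed(seed)
  target_idx <- sample.int(length(classes), 1) # which prompt the user wants
  ses_cfg <- session
  ses_cfg$target_index <- target_idx
  ses_cfg$seed <- seed
  ses <- generate_session(ses_cfg, object_names = classes)
  log$session <- ses

  # stream covering the session at the nominal rate, clench-labeled samples
  # during the user's reaction burst
  horizon <- max(ses$statements$end) + ses$config$gap + 2
  ts <- seq(0, horizon, by = 1 / fbp$sps)
  labels <- if (clench)
    as.integer(ts >= ses$clench_time & ts < ses$clench_time + clench_duration)
  else integer(length(ts))
  set.seed(seed)
  x <- fbp_features_for_labels(labels, fbp)
  stream <- data.frame(timestamp = ts, x, label = labels)

  events <- decode_stream(model, stream, debounce_k = debounce_k)
  log$events <- events$time
  log$decode_latency <- attr(events, "latency_per_sample")

  # trial-level outcome: decoded event inside the target statement's window
  # counts as the selection; any decode elsewhere is a false trigger
  in_window <- events$time >= ses$target_onset & events$time < ses$window_end
  selected <- any(in_window)
  false_trigger <- any(!in_window)
  log$outcome <- if (clench) {
    if (selected) "TP" else "FN"
  } else {
    if (length(events$time) > 0) "FP" else "TN"
  }
  if (!clench && false_trigger) selected <- FALSE

  if (selected) {
    d <- scene$detections[[target_idx]]
    ht <- scene$truth$height[target_idx]
    tw <- target_world_coordinates(d, map, object_height = ht,
                                   work_area = scene$config$work_area)
    log$selected_object <- d$class
    log$target_world <- tw
    log$zone <- zone_of(tw[1:2], zone_layout(work_area = scene$config$work_area,
                                             base = geometry$base_position))
    # reach target in the arm frame (origin under J1)
    arm_target <- c(tw[1] - geometry$base_position[1],
                    tw[2] - geometry$base_position[2], tw[3])
    plan <- if (use_safe_approach) {
      sa <- plan_safe_approach(arm_target, geometry, gd)
      log$commands <- sa$commands
      sa$phase2
    } else {
      plan_reach(arm_target, geometry, gd)
    }
    log$plan <- list(iterations = plan$iterations, final_sse = plan$final_sse,
                     converged = plan$converged)
    n <- nrow(plan$written)
    fault <- servo_fault_check(plan$written[n, ], plan$read[n, ])
    if (fault$status == "fault") {
      log$status <- "servo fault"
      log$message <- fault$message
    }
  }
  class(log) <- "trial_log"
  log
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("trial (seed %d): outcome %s, status %s\n",
              x$seed, x$outcome, x$status))
  if (!is.null(x$selected_object))
    cat(sprintf("  selected '%s' in %s; plan: %d iterations, final SSE %.4g (%s)\n",
                x$selected_object, x$zone, x$plan$iterations,
                x$plan$final_sse,
                if (x$plan$converged) "converged" else "not converged"))
  invisible(x)
}

#' Confusion tally over a set of trial logs
#'
#' @param logs List of [run_trial()] results (or any objects with an
#'   `outcome` field in `TP`/`FP`/`FN`/`TN`).
#' @return A [classification_metrics()] object of the summed counts.
#' @export
tally_confusion <- function(logs) {
  if (length(logs) == 0) stop("no trial logs to tally", call. = FALSE)
  outcomes <- vapply(logs, function(l) l$outcome, "")
  stopifnot(all(outcomes %in% c("TP", "FP", "FN", "TN")))
  classification_metrics(sum(outcomes == "TP"), sum(outcomes == "FP"),
                         sum(outcomes == "FN"), sum(outcomes == "TN"))
}

#' Per-subsystem latency ledger
#'
#' @param components Named non-negative latencies in seconds (e.g.
#'   perception, prompting, decoding, planning, actuation).
#' @return Object of class `latency_ledger` with `components` and `total`
#'   (the exact sum, left-to-right).
#' @export
latency_ledger <- function(components) {
  components <- unlist(components)
  if (length(components) && (!is.numeric(components) ||
                             any(!is.finite(components)) ||
                             any(components < 0)))
    stop("latencies must be finite and non-negative", call. = FALSE)
  structure(list(components = components,
                 total = sum(components)),
            class = "latency_ledger")
}

#' @export
print.latency_ledger <- function(x, ...) {
  if (length(x$components) == 0) {
    cat("latency ledger: no components, total 0 s\n")
    return(invisible(x))
  }
  nm <- names(x$components)
  if (is.null(nm)) nm <- paste("component", seq_along(x$components))
  width <- max(nchar(nm), nchar("Activity"))
  cat(sprintf("%-*s  %s\n", width, "Activity", "Latency (s)"))
  for (i in seq_along(x$components))
    cat(sprintf("%-*s  %.6g\n", width, nm[i], x$components[i]))
  cat(sprintf("%-*s  %.6g\n", width, "Total", x$total))
  invisible(x)
}

#' System Usability Scale score
#'
#' Ten Likert responses (1..5). Odd items contribute `response - 1`, even
#' items `5 - response`; the sum is scaled by 2.5 to a 0-100 score.
#'
#' @param responses Integer vector of ten responses in 1..5.
#' @return Score in `[0, 100]`.
#' @export
sus_score <- function(responses) {
  responses <- as.numeric(responses)
  if (length(responses) != 10)
    stop("SUS needs exactly ten responses", call. = FALSE)
  if (any(!is.finite(responses)) || any(responses < 1 | responses > 5) ||
      any(responses != round(responses)))
    stop("SUS responses must be integers in 1..5", call. = FALSE)
  odd <- responses[seq(1, 9, by = 2)]
  even <- responses[seq(2, 10, by = 2)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' NASA-TLX scaled average
#'
#' Arithmetic mean of the six scaled subscale scores (0-100 each).
#'
#' @param scaled Numeric vector of six values in `[0, 100]`.
#' @return Mean workload score.
#' @export
tlx_scaled_average <- function(scaled) {
  scaled <- as.numeric(scaled)
  if (length(scaled) != 6)
    stop("TLX needs exactly six scaled subscale scores", call. = FALSE)
  if (any(!is.finite(scaled)) || any(scaled < 0 | scaled > 100))
    stop("TLX scaled scores must lie in [0, 100]", call. = FALSE)
  mean(scaled)
}

#' Emergency-override state
#'
#' A latched halt flag shared by the simulated actuation loop: any override
#' signal halts actuation within one step and stays latched until an
#' explicit reset.
#'
#' @return Object of class `override_state`.
#' @export
override_state <- function() {
  e <- new.env(parent = emptyenv())
  e$halted <- FALSE
  class(e) <- "override_state"
  e
}

#' Trigger the emergency override
#' @param state An [override_state()].
#' @export
trigger_override <- function(state) {
  stopifnot(inherits(state, "override_state"))
  state$halted <- TRUE
  invisible(state)
}

#' Reset the emergency override latch
#' @param state An [override_state()].
#' @export
reset_override <- function(state) {
  stopifnot(inherits(state, "override_state"))
  state$halted <- FALSE
  invisible(state)
}

#' Execute a planned reach under override supervision
#'
#' Steps through the plan's written-angle trace, checking the override latch
#' before every step (and honouring a simulated key press at `interrupt_at`).
#' A halted execution truncates the trace and reports status
#' `"halted by override"`; re-running without a reset stays halted.
#'
#' @param plan A [plan_reach()] result.
#' @param state An [override_state()].
#' @param interrupt_at Optional step index at which an override signal
#'   arrives during this execution.
#' @return List with `status` (`"completed"` or `"halted by override"`),
#'   `steps_executed`, and the truncated `written` trace.
#' @export
execute_plan <- function(plan, state = override_state(), interrupt_at = NULL) {
  stopifnot(inherits(plan, "reach_plan"), inherits(state, "override_state"))
  n <- nrow(plan$written)
  executed <- 0L
  for (i in seq_len(n)) {
    if (!is.null(interrupt_at) && i >= interrupt_at) trigger_override(state)
    if (state$halted) break
    executed <- i
  }
  list(status = if (state$halted) "halted by override" else "completed",
       steps_executed = executed,
       written = plan$written[seq_len(max(executed, 1L)), , drop = FALSE])
}
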