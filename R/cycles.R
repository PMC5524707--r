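# Cycle containers: one subject's observed cardiac cycle of landmark clouds
# (shape_cycle) and its interpolation at the 16 homologous times
# (homologous_cycle).

EVENT_NAMES <- c("R_peak", "LV_end_systole", "mitral_valve_opening", "P_peak")

#' Construct a subject's cardiac shape cycle
#'
#' Bundles the time-ordered endocardial landmark configurations of one
#' acquired heartbeat with its frame times, the four annotated
#' electro-mechanical event times (R peak, LV end-systole, mitral valve
#' opening, P peak), and subject metadata.
#'
#' @param frames k x 3 x n_frames array of landmark configurations (all
#'   frames share the same landmarks).
#' @param frame_times_ms strictly increasing frame times, in ms, within
#'   `[0, cycle_length_ms)`.
#' @param events named numeric vector with entries `R_peak`,
#'   `LV_end_systole`, `mitral_valve_opening`, `P_peak` (ms), cyclically
#'   ordered within the cycle.
#' @param cycle_length_ms cycle (RR interval) length in ms.
#' @param subject_id subject identifier.
#' @param group group label, `"Control"` or `"HCM"`.
#' @param chamber factor of length k with levels `LV`, `LA` tagging each
#'   landmark's chamber; `NULL` for single-chamber or abstract data.
#' @param layout optional data.frame with per-landmark `circle_index` and
#'   `point_index` (apex: circle -1, point 0), used by the CSV writers.
#' @return An object of class `"shape_cycle"`.
#' @export
shape_cycle <- function(frames, frame_times_ms, events, cycle_length_ms,
                        subject_id = "s1", group = "Control",
                        chamber = NULL, layout = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(length(dim(frames)) == 3)
  nf <- dim(frames)[3]
  if (length(frame_times_ms) != nf)
    stop("frame_times_ms length must match the number of frames",
         call. = FALSE)
  if (any(diff(frame_times_ms) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (!all(EVENT_NAMES %in% names(events)))
    stop("missing event time(s): ",
         paste(setdiff(EVENT_NAMES, names(events)), collapse = ", "),
         call. = FALSE)
  events <- events[EVENT_NAMES]
  if (any(events < 0 | events >= cycle_length_ms))
    stop("event times must lie within [0, cycle_length_ms)", call. = FALSE)
  # cyclic order check: unwrapped relative to R peak, gaps must be positive
  rel <- (events - events["R_peak"]) %% cycle_length_ms
  if (any(diff(rel) <= 0))
    stop("events must be cyclically ordered R_peak -> LV_end_systole -> ",
         "mitral_valve_opening -> P_peak", call. = FALSE)
  if (!is.null(chamber)) {
    chamber <- factor(chamber, levels = c("LV", "LA"))
    if (length(chamber) != dim(frames)[1])
      stop("chamber labels must tag every landmark", call. = FALSE)
  }
  structure(list(frames = frames, frame_times_ms = as.numeric(frame_times_ms),
                 events = events, cycle_length_ms = cycle_length_ms,
                 subject_id = subject_id, group = group,
                 chamber = chamber, layout = layout),
            class = "shape_cycle")
}

#' @export
print.shape_cycle <- function(x, ...) {
  cat("shape_cycle:", x$subject_id, "(", x$group, ")\n")
  cat("  ", dim(x$frames)[3], "frames of", dim(x$frames)[1],
      "landmarks; cycle", round(x$cycle_length_ms, 1), "ms\n")
  invisible(x)
}

# internal constructor for the interpolated cycle
new_homologous_cycle <- function(shapes, times, subject_id, group,
                                 chamber = NULL, layout = NULL) {
  structure(list(shapes = shapes, homologous_times_ms = times,
                 strict_indices = c(1L, 5L, 9L, 13L),
                 subject_id = subject_id, group = group,
                 chamber = chamber, layout = layout),
            class = "homologous_cycle")
}

#' @export
print.homologous_cycle <- function(x, ...) {
  cat("homologous_cycle:", x$subject_id, "(", x$group, ") —",
      dim(x$shapes)[3], "shapes of", dim(x$shapes)[1], "landmarks\n")
  invisible(x)
}
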