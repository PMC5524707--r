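# Homologous-time construction and cubic-spline interpolation of a cycle.

#' Build the 16 homologous times of one cardiac cycle
#'
#' Four strictly homologous electro-mechanical events anchor every cycle:
#' the R wave peak, LV end-systole, mitral valve opening, and the P wave
#' peak. Between each consecutive pair of events (cyclically, wrapping the
#' last back to the first plus one cycle length) three additional equally
#' spaced times are inserted at the 1/4, 1/2 and 3/4 points of the gap,
#' giving 4 strict + 12 interpolated = 16 homologous times per cycle,
#' starting at the R peak.
#'
#' @param events named numeric vector of the four event times (ms), see
#'   [shape_cycle()].
#' @param cycle_length_ms cycle length in ms.
#' @return Numeric vector of 16 times (ms). Times after the wrap point
#'   exceed the nominal event value by one cycle length, so the sequence is
#'   strictly increasing; callers evaluate them modulo the cycle.
#' @examples
#' homologous_times(c(R_peak = 0, LV_end_systole = 300,
#'                    mitral_valve_opening = 450, P_peak = 700), 800)
#' @export
homologous_times <- function(events, cycle_length_ms) {
  if (!all(EVENT_NAMES %in% names(events)))
    stop("events must contain: ", paste(EVENT_NAMES, collapse = ", "),
         call. = FALSE)
  ev <- events[EVENT_NAMES]
  # unwrap into one strictly increasing cycle starting at the R peak
  anchors <- ev["R_peak"] + (ev - ev["R_peak"]) %% cycle_length_ms
  anchors <- c(anchors, anchors[1] + cycle_length_ms)
  gaps <- diff(anchors)
  if (any(gaps <= 0))
    stop("coincident event times: every inter-event gap must be positive",
         call. = FALSE)
  out <- unlist(lapply(seq_len(4), function(i)
    anchors[i] + gaps[i] * c(0, 0.25, 0.5, 0.75)))
  unname(out)
}

#' Interpolate a cardiac cycle at its homologous times
#'
#' First superimposes the subject's observed frames by generalized
#' Procrustes analysis in size-and-shape space (translation and rotation
#' removed, size retained, since size is still meaningful at this stage),
#' then fits one periodic cubic spline per landmark coordinate over the
#' frame times and evaluates it at the 16 homologous times.
#'
#' @param cycle a [shape_cycle()].
#' @param times homologous times (ms); defaults to
#'   `homologous_times(cycle$events, cycle$cycle_length_ms)`.
#' @return A `homologous_cycle`: 16 size-and-shape-aligned configurations,
#'   their times, and the positions of the 4 strict events among the 16.
#' @export
interpolate_cycle <- function(cycle, times = NULL) {
  stopifnot(inherits(cycle, "shape_cycle"))
  if (is.null(times))
    times <- homologous_times(cycle$events, cycle$cycle_length_ms)
  nf <- dim(cycle$frames)[3]
  if (nf < 4)
    stop("at least 4 frames are needed for cubic-spline interpolation",
         call. = FALSE)
  Tms <- cycle$cycle_length_ms
  ft <- cycle$frame_times_ms
  if (any(ft < 0) || any(ft >= Tms))
    stop("frame times must lie within [0, cycle_length_ms)", call. = FALSE)

  fit <- gpa(cycle$frames, space = "size_and_shape")
  k <- dim(fit$aligned)[1]
  # flatten to frames x (3k); close the period by repeating the first frame
  Y <- t(apply(fit$aligned, 3, as.vector))
  x <- c(ft, ft[1] + Tms)
  Y <- rbind(Y, Y[1, ])
  # evaluate homologous times inside [ft[1], ft[1] + T)
  tq <- ft[1] + (times - ft[1]) %% Tms
  Z <- vapply(seq_len(ncol(Y)), function(j)
    stats::spline(x, Y[, j], method = "periodic", xout = tq)$y,
    numeric(length(tq)))
  shapes <- array(t(Z), dim = c(k, 3, length(tq)))
  new_homologous_cycle(shapes, times, cycle$subject_id, cycle$group,
                       cycle$chamber, cycle$layout)
}
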