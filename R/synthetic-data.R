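# Synthetic 4D left-heart generator: two stacked quasi-ellipsoidal chamber
# surfaces (36 circles x 36 landmarks + apex each) deforming periodically
# over a heartbeat, with a planted LA:LV shape-change rate (covariation
# slope), between-subject baseline shape variation, frame-rate jitter, and
# landmark noise. Closed-form phase-dependent deformation fields make every
# downstream stage testable against construction.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generator parameters for the synthetic left heart
#'
#' Defaults follow the acquisition this generator emulates: a mean frame
#' interval of 41.6 ms, beat rates of 77 +/- 13.16 per minute, chambers of
#' 36 circles x 36 landmarks plus an apex (1297 landmarks each), and, for
#' the default Control-like parameter set, a fractional LV deformation
#' amplitude of 0.10 with a planted LA:LV shape-change rate of 1.25.
#'
#' @param n_circles,n_per_circle chamber surface sampling (36 x 36 by
#'   default; smaller values give cheaper, structurally identical cohorts).
#' @param lv_amplitude LV deformation amplitude as a fraction of the
#'   configuration's centroid size.
#' @param la_amplitude LA amplitude; default `covariation_slope *
#'   lv_amplitude`, which plants the covariation slope exactly.
#' @param covariation_slope planted LA:LV shape-change rate.
#' @param mode_mix weights of the affine (uniform chamber contraction) and
#'   non-affine (tapered radial/longitudinal) deformation components.
#' @param subject_shape_sd sd of the random linear warp generating
#'   between-subject baseline shape variation.
#' @param landmark_noise_sd per-coordinate landmark noise sd, in device
#'   length units (chamber radii are ~25 units).
#' @param beat_rate_mean,beat_rate_sd beats per minute.
#' @param frame_interval_ms nominal frame interval.
#' @param frame_jitter fractional jitter applied to frame intervals.
#' @param event_phase_fractions cycle-phase fractions of the four events.
#' @param activation_sharpness concentration of the periodic activation
#'   bumps at end-systole and at the P peak.
#' @return A list of class `"lh_params"`.
#' @export
lh_params <- function(n_circles = 36L, n_per_circle = 36L,
                      lv_amplitude = 0.10, la_amplitude = NULL,
                      covariation_slope = 1.25,
                      mode_mix = c(affine = 0.25, nonaffine = 0.75),
                      subject_shape_sd = 0.03,
                      landmark_noise_sd = 0.15,
                      beat_rate_mean = 77, beat_rate_sd = 13.16,
                      frame_interval_ms = 41.6, frame_jitter = 0.05,
                      event_phase_fractions = c(R_peak = 0,
                                                LV_end_systole = 0.35,
                                                mitral_valve_opening = 0.45,
                                                P_peak = 0.85),
                      activation_sharpness = 8) {
  stopifnot(lv_amplitude >= 0, covariation_slope > 0, frame_interval_ms > 0,
            n_circles >= 3, n_per_circle >= 3, landmark_noise_sd >= 0)
  ph <- event_phase_fractions[EVENT_NAMES]
  if (any(is.na(ph)) || any(diff(ph) <= 0) || any(ph < 0) || any(ph >= 1))
    stop("event phase fractions must be cyclically ordered within [0, 1)",
         call. = FALSE)
  structure(list(n_circles = as.integer(n_circles),
                 n_per_circle = as.integer(n_per_circle),
                 lv_amplitude = lv_amplitude, la_amplitude = la_amplitude,
                 covariation_slope = covariation_slope,
                 mode_mix = mode_mix / sum(mode_mix),
                 subject_shape_sd = subject_shape_sd,
                 landmark_noise_sd = landmark_noise_sd,
                 beat_rate_mean = beat_rate_mean, beat_rate_sd = beat_rate_sd,
                 frame_interval_ms = frame_interval_ms,
                 frame_jitter = frame_jitter,
                 event_phase_fractions = ph,
                 activation_sharpness = activation_sharpness),
            class = "lh_params")
}

# one chamber surface: n_circles parallel circles of n_per_circle landmarks
# plus the apex. LV: prolate ellipsoid hanging below the annulus plane
# (z = 0); LA: oblate ellipsoid stacked above it, base-to-base, matching
# the annulus radius.
generate_chamber_surface <- function(params, chamber = c("LV", "LA")) {
  chamber <- match.arg(chamber)
  nc <- params$n_circles; np <- params$n_per_circle
  a <- 25                                    # annulus/equatorial radius
  cax <- if (chamber == "LV") 45 else 18     # polar semi-axis
  zsign <- if (chamber == "LV") -1 else 1    # LV apex down, LA roof up
  theta <- (nc + 1 - seq_len(nc)) / (nc + 1) * (pi / 2)
  psi <- 2 * pi * (seq_len(np) - 1) / np
  coords <- do.call(rbind, lapply(seq_len(nc), function(j) {
    r <- a * sin(theta[j])
    cbind(r * cos(psi), r * sin(psi), zsign * cax * cos(theta[j]))
  }))
  coords <- rbind(coords, c(0, 0, zsign * cax))  # apex / atrial roof
  layout <- data.frame(
    circle_index = c(rep(seq_len(nc), each = np), -1L),
    point_index = c(rep(seq_len(np), nc), 0L))
  list(coords = coords, layout = layout)
}

#' Generate the whole left-heart reference surface
#'
#' LV (prolate) and LA (oblate) chamber surfaces stacked base-to-base
#' across a shared annulus plane: one connected landmark cloud of
#' `2 * (n_circles * n_per_circle + 1)` points (2594 at the default 36 x 36
#' sampling), LV block first.
#'
#' @param params an [lh_params()] list.
#' @return List with `coords` (k x 3), `chamber` (factor), `layout`
#'   (data.frame of `chamber`, `circle_index`, `point_index`).
#' @export
generate_lh_surface <- function(params = lh_params()) {
  lv <- generate_chamber_surface(params, "LV")
  la <- generate_chamber_surface(params, "LA")
  kc <- nrow(lv$coords)
  chamber <- factor(rep(c("LV", "LA"), each = kc), levels = c("LV", "LA"))
  layout <- rbind(cbind(chamber = "LV", lv$layout),
                  cbind(chamber = "LA", la$layout))
  list(coords = rbind(lv$coords, la$coords), chamber = chamber,
       layout = layout)
}

# unit-Frobenius chamber deformation field, zero outside the chamber and
# with zero mean inside it (so whole-configuration centring is untouched).
# mode_mix blends a deviatoric (traceless, non-homothetic) affine stretch
# with a tapered radial + longitudinal squeeze (non-affine); both are kept
# orthogonal to the chamber's scaling direction, and a small controlled
# volume (uniform contraction) component is added separately. Keeping the
# scaling content small matters: unit-size normalization spreads any global
# scaling content of one chamber's field across both chamber blocks, which
# would contaminate the planted LA:LV rate.
.chamber_field <- function(coords, idx, mode_mix, volume_frac = 0.15) {
  k <- nrow(coords)
  P <- coords[idx, , drop = FALSE]
  Pc <- sweep(P, 2, colMeans(P))
  zr <- range(Pc[, 3])
  zn <- (Pc[, 3] - zr[1]) / diff(zr)
  w <- sin(pi * zn)^2
  # tapered squeeze, chamber-mean-free and orthogonal to chamber scaling
  N <- cbind(-Pc[, 1] * w, -Pc[, 2] * w, -Pc[, 3] * w / 2)
  N <- sweep(N, 2, colMeans(N))
  N <- N - sum(N * Pc) / sum(Pc * Pc) * Pc
  N <- N / sqrt(sum(N^2))
  # deviatoric affine: elliptical cross-section stretch, traceless in the
  # shape metric (x and y moments are equal by axisymmetry)
  A <- Pc %*% diag(c(1, -1, 0))
  A <- A / sqrt(sum(A^2))
  # uniform contraction toward the chamber centroid: the volume component
  S <- -Pc / sqrt(sum(Pc^2))
  U <- matrix(0, k, 3)
  U[idx, ] <- mode_mix[["affine"]] * A + mode_mix[["nonaffine"]] * N +
    volume_frac * S
  U / sqrt(sum(U^2))
}

# periodic activation: a sharp bump at end-systole minus a bump at the P
# peak, so the LV contracts in systole and the (anti-phase) LA contracts
# at atrial systole
.activation <- function(phase, params) {
  bump <- function(mu) exp(params$activation_sharpness *
                             (cos(2 * pi * (phase - mu)) - 1))
  ph <- params$event_phase_fractions
  bump(ph[["LV_end_systole"]]) - bump(ph[["P_peak"]])
}

#' Generate one subject's synthetic cardiac cycle
#'
#' Builds the subject's baseline left heart (the reference surface under a
#' random linear warp), then deforms it periodically: the LV contracts
#' between the R peak and end-systole and re-expands through mitral valve
#' opening, the LA moves in anti-phase (atrial systole at the P peak) with
#' deformation magnitude `covariation_slope` times the LV magnitude along
#' the planted chamber fields. Frames are sampled at the nominal frame
#' interval with jitter; landmark noise is added last. Two calls with the
#' same `subject_seed` are identical.
#'
#' @param params an [lh_params()] list.
#' @param subject_seed integer seed for this subject.
#' @param subject_id,group metadata passed into the cycle.
#' @return A [shape_cycle()].
#' @export
generate_cycle <- function(params = lh_params(), subject_seed = 1L,
                           subject_id = "s1", group = "Control") {
  set.seed(subject_seed)
  base <- generate_lh_surface(params)
  warp <- diag(3) + matrix(stats::rnorm(9, 0, params$subject_shape_sd), 3, 3)
  X0 <- base$coords %*% warp
  cs0 <- centroid_size(X0)
  U_lv <- .chamber_field(X0, which(base$chamber == "LV"), params$mode_mix)
  U_la <- .chamber_field(X0, which(base$chamber == "LA"), params$mode_mix)

  bpm <- max(40, stats::rnorm(1, params$beat_rate_mean, params$beat_rate_sd))
  Tms <- 60000 / bpm
  nf <- max(4L, floor(Tms / params$frame_interval_ms))
  ft <- (seq_len(nf) - 1) * params$frame_interval_ms
  if (params$frame_jitter > 0 && nf > 1)
    ft[-1] <- ft[-1] + stats::runif(nf - 1, -0.5, 0.5) *
      params$frame_jitter * params$frame_interval_ms
  ft <- ft[ft < Tms]

  la_amp <- params$la_amplitude %||%
    (params$covariation_slope * params$lv_amplitude)
  alpha <- .activation(ft / Tms, params)
  k <- nrow(X0)
  frames <- array(0, dim = c(k, 3, length(ft)))
  for (t in seq_along(ft)) {
    frames[, , t] <- X0 +
      params$lv_amplitude * alpha[t] * cs0 * U_lv -
      la_amp * alpha[t] * cs0 * U_la
  }
  if (params$landmark_noise_sd > 0)
    frames <- frames + array(stats::rnorm(length(frames), 0,
                                          params$landmark_noise_sd),
                             dim = dim(frames))
  shape_cycle(frames, ft,
              events = params$event_phase_fractions * Tms,
              cycle_length_ms = Tms,
              subject_id = subject_id, group = group,
              chamber = base$chamber, layout = base$layout)
}

#' Generate a two-group synthetic cohort
#'
#' Default group contrasts mirror the structure the analysis targets:
#' Control deforms more than HCM (amplitudes 0.10 vs 0.06) and the planted
#' LA:LV covariation slopes are 1.25 (Control) vs 0.89 (HCM), with the same
#' integration law in both groups. Default group sizes are 46 and 20.
#' Per-subject seeds are derived from the cohort seed.
#'
#' @param n_control,n_hcm group sizes.
#' @param control_params,hcm_params [lh_params()] lists for each group.
#' @param seed cohort seed.
#' @return A list of class `"lh_cohort"`: `cycles` (list of
#'   [shape_cycle()]), `manifest` (parameters and per-subject seeds).
#' @export
generate_cohort <- function(n_control = 46, n_hcm = 20,
                            control_params = lh_params(),
                            hcm_params = lh_params(lv_amplitude = 0.06,
                                                   covariation_slope = 0.89),
                            seed = 1L) {
  set.seed(seed)
  n <- n_control + n_hcm
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- rep(c("Control", "HCM"), c(n_control, n_hcm))
  ids <- sprintf("%s%02d", ifelse(groups == "Control", "C", "H"),
                 c(seq_len(n_control), seq_len(n_hcm)))
  cycles <- lapply(seq_len(n), function(i)
    generate_cycle(if (groups[i] == "Control") control_params else hcm_params,
                   subject_seed = seeds[i], subject_id = ids[i],
                   group = groups[i]))
  structure(list(cycles = cycles,
                 manifest = list(seed = seed, subject_seeds = seeds,
                                 n_control = n_control, n_hcm = n_hcm,
                                 control_params = unclass(control_params),
                                 hcm_params = unclass(hcm_params))),
            class = "lh_cohort")
}

#' @export
print.lh_cohort <- function(x, ...) {
  cat("lh_cohort:", length(x$cycles), "subjects (",
    x$manifest$n_control, "Control /", x$manifest$n_hcm, "HCM )\n")
  invisible(x)
}

#' Generate a self-similar (power-law) shape series
#'
#' Draws `n_shapes` independent configurations around a reference by
#' sampling each partial warp of the reference's bending-energy basis with
#' variance `scale * eigenvalue^law_exponent` (split evenly over the three
#' coordinate axes). With `law_exponent = -1` the series is self-similar
#' and its disintegration slope equals -1 in expectation; 0 gives a flat
#' (disintegrated) law.
#'
#' @param reference k x 3 landmark matrix.
#' @param n_shapes number of shapes to draw.
#' @param law_exponent power-law exponent on the bending-energy eigenvalue.
#' @param scale overall variance scale.
#' @param seed RNG seed.
#' @return List with `shapes` (k x 3 x n array) and `basis` (the
#'   `partial_warp_basis` used).
#' @export
generate_self_similar_series <- function(reference, n_shapes,
                                         law_exponent = -1, scale = 1e-3,
                                         seed = NULL) {
  basis <- bending_energy_basis(reference)
  if (!is.null(seed)) set.seed(seed)
  nw <- length(basis$eigenvalues)
  sdw <- sqrt(scale * basis$eigenvalues^law_exponent / 3)
  k <- nrow(reference)
  shapes <- array(0, dim = c(k, 3, n_shapes))
  for (i in seq_len(n_shapes)) {
    S <- matrix(stats::rnorm(nw * 3, 0, sdw), nw, 3)
    shapes[, , i] <- reference + basis$eigenvectors %*% S
  }
  list(shapes = shapes, basis = basis)
}
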