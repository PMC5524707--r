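# Dataset readers/writers (long-form landmark CSV + events JSON) and the
# end-to-end pipeline driver.

.CSV_COLS <- c("subject_id", "frame_index", "time_ms", "chamber",
               "circle_index", "point_index", "x", "y", "z")

# canonical landmark order: LV block then LA block; within a chamber,
# circles ascending, points ascending, apex (circle -1) last
.canonical_order <- function(chamber, circle_index, point_index) {
  order(match(chamber, c("LV", "LA")),
        ifelse(circle_index < 0, .Machine$integer.max, circle_index),
        point_index)
}

.default_layout <- function(k) {
  data.frame(chamber = rep("LV", k), circle_index = seq_len(k),
             point_index = rep(1L, k))
}

#' Write a cohort of cycles as landmark CSV + events JSON
#'
#' Long-form landmark CSV with columns `subject_id, frame_index, time_ms,
#' chamber, circle_index, point_index, x, y, z` (apex rows: circle -1,
#' point 0; coordinates at fixed `%.6f` formatting so output is
#' byte-stable), plus an events JSON array of
#' `{subject_id, group, cycle_length_ms, events:{...}}` records.
#'
#' @param cycles list of [shape_cycle()] (or an `lh_cohort`).
#' @param dir output directory (created if missing).
#' @param basename file stem; writes `<basename>_landmarks.csv` and
#'   `<basename>_events.json`.
#' @return Invisibly, the two file paths.
#' @export
write_lh_dataset <- function(cycles, dir, basename = "cohort") {
  if (inherits(cycles, "lh_cohort")) cycles <- cycles$cycles
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(basename, "_landmarks.csv"))
  js <- file.path(dir, paste0(basename, "_events.json"))
  tabs <- lapply(cycles, function(cy) {
    k <- dim(cy$frames)[1]; nf <- dim(cy$frames)[3]
    lay <- cy$layout
    if (is.null(lay)) {
      lay <- .default_layout(k)
      if (!is.null(cy$chamber)) lay$chamber <- as.character(cy$chamber)
    }
    data.table::data.table(
      subject_id = cy$subject_id,
      frame_index = rep(seq_len(nf), each = k),
      time_ms = sprintf("%.6f", rep(cy$frame_times_ms, each = k)),
      chamber = rep(as.character(lay$chamber), nf),
      circle_index = rep(lay$circle_index, nf),
      point_index = rep(lay$point_index, nf),
      x = sprintf("%.6f", as.vector(cy$frames[, 1, ])),
      y = sprintf("%.6f", as.vector(cy$frames[, 2, ])),
      z = sprintf("%.6f", as.vector(cy$frames[, 3, ])))
  })
  data.table::fwrite(data.table::rbindlist(tabs), csv)
  meta <- lapply(cycles, function(cy)
    list(subject_id = cy$subject_id, group = cy$group,
         cycle_length_ms = cy$cycle_length_ms,
         events = as.list(cy$events)))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(landmarks = csv, events = js))
}

#' Read a landmark CSV + events JSON dataset
#'
#' Validates the schema strictly (column names, event completeness,
#' consistent landmark counts across frames) and normalizes landmark rows
#' to the canonical chamber-block order (LV block, then LA, apex last per
#' chamber).
#'
#' @param landmarks_csv,events_json file paths as written by
#'   [write_lh_dataset()].
#' @return List of [shape_cycle()], in the order of the events JSON.
#' @export
read_lh_dataset <- function(landmarks_csv, events_json) {
  dt <- data.table::fread(landmarks_csv)
  missing_cols <- setdiff(.CSV_COLS, names(dt))
  if (length(missing_cols))
    stop("landmark CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(events_json, simplifyVector = FALSE)
  lapply(meta, function(m) {
    if (is.null(m$subject_id) || is.null(m$cycle_length_ms))
      stop("events JSON record lacks subject_id or cycle_length_ms",
           call. = FALSE)
    miss <- setdiff(EVENT_NAMES, names(m$events))
    if (length(miss))
      stop("subject ", m$subject_id, ": missing event(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    rows <- dt[dt$subject_id == m$subject_id, ]
    if (nrow(rows) == 0)
      stop("subject ", m$subject_id, " absent from the landmark CSV",
           call. = FALSE)
    frames_idx <- sort(unique(rows$frame_index))
    k <- nrow(rows) / length(frames_idx)
    if (k != round(k))
      stop("subject ", m$subject_id,
           ": landmark count differs across frames", call. = FALSE)
    f1 <- rows[rows$frame_index == frames_idx[1], ]
    ord <- .canonical_order(f1$chamber, f1$circle_index, f1$point_index)
    frames <- array(0, dim = c(k, 3, length(frames_idx)))
    times <- numeric(length(frames_idx))
    for (i in seq_along(frames_idx)) {
      fr <- rows[rows$frame_index == frames_idx[i], ]
      if (nrow(fr) != k)
        stop("subject ", m$subject_id, ", frame ", frames_idx[i],
             ": expected ", k, " landmarks, found ", nrow(fr),
             call. = FALSE)
      fr <- fr[.canonical_order(fr$chamber, fr$circle_index,
                                fr$point_index), ]
      frames[, , i] <- as.matrix(fr[, c("x", "y", "z")])
      times[i] <- fr$time_ms[1]
    }
    f1 <- f1[ord, ]
    chamber <- if (all(c("LV", "LA") %in% f1$chamber))
      factor(f1$chamber, levels = c("LV", "LA")) else NULL
    shape_cycle(frames, times,
                events = unlist(m$events)[EVENT_NAMES],
                cycle_length_ms = m$cycle_length_ms,
                subject_id = m$subject_id,
                group = m$group %||% "Control",
                chamber = chamber,
                layout = f1[, c("chamber", "circle_index", "point_index")])
  })
}

#' Write an interpolated cycle as homologous-time CSV
#'
#' Same dialect as the landmark CSV, with `frame_index` replaced by
#' `homologous_index` (0-15) and a `strict` flag column marking the four
#' anchored event slots.
#'
#' @param hcycle a `homologous_cycle`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_homologous_csv <- function(hcycle, path) {
  k <- dim(hcycle$shapes)[1]; nt <- dim(hcycle$shapes)[3]
  lay <- hcycle$layout
  if (is.null(lay)) {
    lay <- .default_layout(k)
    if (!is.null(hcycle$chamber)) lay$chamber <- as.character(hcycle$chamber)
  }
  dt <- data.table::data.table(
    subject_id = hcycle$subject_id,
    homologous_index = rep(seq_len(nt) - 1L, each = k),
    time_ms = sprintf("%.6f", rep(hcycle$homologous_times_ms, each = k)),
    strict = rep(seq_len(nt) %in% hcycle$strict_indices, each = k),
    chamber = rep(as.character(lay$chamber), nt),
    circle_index = rep(lay$circle_index, nt),
    point_index = rep(lay$point_index, nt),
    x = sprintf("%.6f", as.vector(hcycle$shapes[, 1, ])),
    y = sprintf("%.6f", as.vector(hcycle$shapes[, 2, ])),
    z = sprintf("%.6f", as.vector(hcycle$shapes[, 3, ])))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Run the full left-heart analysis pipeline
#'
#' Executes the whole chain on a cohort of cycles: interpolation at the 16
#' homologous times, linear-shift transport to the common template,
#' trajectory attributes with permutation ANOVA/MANOVA group tests,
#' within-individual LV-LA covariation (PLS z-scores and major-axis
#' slopes), per-subject disintegration slopes, and a randomized SVM
#' evaluation of the trajectory attribute table. Every stochastic stage is
#' seeded from `seed`.
#'
#' @param cycles list of [shape_cycle()] or an `lh_cohort` (if `NULL`, a
#'   default cohort is simulated with [generate_cohort()]).
#' @param seed master seed.
#' @param n_perm permutations for the group tests.
#' @param n_perm_z row permutations for per-subject PLS z-scores (0 skips).
#' @param svm logical: run the randomized SVM evaluation? Needs enough
#'   subjects per class for the requested split.
#' @param svm_train per-class training counts for the SVM stage; default
#'   scales the 35/17 split proportionally to the cohort at hand.
#' @param n_reps SVM repetitions.
#' @return List of class `"lh_report"` with the stage outputs.
#' @export
run_pipeline <- function(cycles = NULL, seed = 1L, n_perm = 999,
                         n_perm_z = 0, svm = FALSE, svm_train = NULL,
                         n_reps = 200) {
  set.seed(seed)
  if (is.null(cycles)) cycles <- generate_cohort(seed = seed)
  if (inherits(cycles, "lh_cohort")) cycles <- cycles$cycles

  hcycles <- lapply(cycles, interpolate_cycle)
  ts <- linear_shift(hcycles)
  groups <- factor(ts$groups)

  ta <- trajectory_attributes(ts)
  anova_cs <- perm_anova(ta$table$traj_cs, groups, n_perm = n_perm,
                         seed = seed + 1L)
  anova_a12 <- perm_anova(ta$table$angle_12, groups, n_perm = n_perm,
                          seed = seed + 2L)
  anova_a13 <- perm_anova(ta$table$angle_13, groups, n_perm = n_perm,
                          seed = seed + 3L)
  manova_shape <- perm_anova(
    t(apply(ta$shape_analysis$aligned, 3, as.vector)), groups,
    n_perm = n_perm, seed = seed + 4L)

  cov_tab <- cohort_covariation(ts, n_perm = n_perm_z, seed = seed + 5L)
  anova_slope <- perm_anova(cov_tab$ma_slope, groups, n_perm = n_perm,
                            seed = seed + 6L)
  anova_z <- if (n_perm_z > 0)
    perm_anova(cov_tab$z_score, groups, n_perm = n_perm, seed = seed + 7L)
  else NULL

  dis_tab <- cohort_disintegration(ts)
  anova_dis <- perm_anova(dis_tab$slope, groups, n_perm = n_perm,
                          seed = seed + 8L)

  svm_res <- NULL
  if (svm) {
    feats <- ta$table[, setdiff(names(ta$table), c("subject_id", "group"))]
    if (is.null(svm_train)) {
      tb <- table(groups)
      # the 35/46 + 17/20 split, scaled proportionally to the cohort at hand
      frac <- c(Control = 35 / 46, HCM = 17 / 20)[names(tb)]
      frac[is.na(frac)] <- 0.8
      svm_train <- stats::setNames(
        pmin(pmax(2, round(as.numeric(tb) * frac)), as.numeric(tb) - 1),
        names(tb))
    }
    svm_res <- randomized_svm_eval(feats, groups, n_train = svm_train,
                                   n_reps = n_reps, seed = seed + 9L)
  }
  structure(list(
    transported = ts,
    trajectory = ta,
    anova = list(traj_cs = anova_cs, angle_12 = anova_a12,
                 angle_13 = anova_a13, shape = manova_shape,
                 ma_slope = anova_slope, z_score = anova_z,
                 disintegration = anova_dis),
    covariation = cov_tab,
    disintegration = dis_tab,
    svm = svm_res,
    group_means = list(
      traj_cs = tapply(ta$table$traj_cs, groups, mean),
      ma_slope = tapply(cov_tab$ma_slope, groups, mean),
      dis_slope = tapply(dis_tab$slope, groups, mean)),
    seed = seed), class = "lh_report")
}

#' @export
print.lh_report <- function(x, ...) {
  gm <- x$group_means
  cat("left-heart pipeline report (seed", x$seed, ")\n")
  cat("  trajectory CS by group: ",
      paste(names(gm$traj_cs), round(gm$traj_cs, 4), collapse = " | "),
      "  (perm-ANOVA R2 =", round(x$anova$traj_cs$R_sq, 3),
      ", p =", signif(x$anova$traj_cs$p, 3), ")\n")
  cat("  MA slope by group:      ",
      paste(names(gm$ma_slope), round(gm$ma_slope, 3), collapse = " | "),
      "  (perm-ANOVA R2 =", round(x$anova$ma_slope$R_sq, 3),
      ", p =", signif(x$anova$ma_slope$p, 3), ")\n")
  cat("  disintegration slope:   ",
      paste(names(gm$dis_slope), round(gm$dis_slope, 3), collapse = " | "),
      "  (p =", signif(x$anova$disintegration$p, 3), ")\n")
  if (!is.null(x$svm))
    cat("  SVM: AUC", round(x$svm$auc, 3), "accuracy",
        round(x$svm$accuracy, 3), "\n")
  invisible(x)
}
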