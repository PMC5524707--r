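# Motion-trajectory analysis: PCA of transported deformations, per-subject
# trajectories in the space of the first three PCs, trajectory shape / size /
# angle attributes, and permutation ANOVA / MANOVA of the attributes.

# deterministic sign convention: make each loading's largest-|entry| positive
.fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' PCA of transported shapes
#'
#' Centred principal component analysis over all subjects' transported
#' tangent-space deformations (16 observations per subject). Loadings carry
#' a deterministic sign convention (largest-magnitude entry positive) so
#' that scores, and hence trajectory angles, are reproducible.
#'
#' @param ts a `transported_set` from [linear_shift()], or any numeric
#'   observations x variables matrix.
#' @param rank number of components to retain (default: all non-null).
#' @return List with `scores`, `loadings`, `sdev`, `var_explained`
#'   (fractions summing to 1 over all components), `center`.
#' @export
pca_shapes <- function(ts, rank = NULL) {
  X <- if (inherits(ts, "transported_set")) ts$residuals else as.matrix(ts)
  if (nrow(X) < 2) stop("PCA needs at least 2 observations", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-12
  var_all <- sv$d^2 / sum(sv$d^2)
  r <- if (is.null(rank)) sum(keep) else min(rank, sum(keep))
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  fx <- .fix_signs(loadings, scores)
  list(scores = fx$scores, loadings = fx$loadings,
       sdev = sv$d[seq_len(r)] / sqrt(nrow(X) - 1),
       var_explained = var_all[seq_len(r)], center = ctr)
}

#' Assemble a subject's motion trajectory
#'
#' The 16 triplets of PC1-PC3 scores are the "landmarks" of the subject's
#' motion trajectory: a 16 x 3 configuration whose centroid size measures
#' how much the heart deforms over the cycle and whose end-diastole to
#' end-systole chord orientation gives the trajectory angles.
#'
#' @param scores 16 x 3 matrix of the subject's first three PC scores, in
#'   homologous-time order.
#' @param ed_index,es_index homologous-time indices of end-diastole (the R
#'   peak slot, 1) and end-systole (the LV end-systole slot, 5).
#' @return A list of class `"trajectory_shape"`: `points` (16 x 3), `cs`,
#'   `angle_12`, `angle_13` (degrees), `ed_index`, `es_index`,
#'   `degenerate` flag.
#' @export
build_trajectory <- function(scores, ed_index = 1L, es_index = 5L) {
  scores <- as.matrix(scores)
  if (nrow(scores) != 16 || ncol(scores) != 3)
    stop("a trajectory needs exactly 16 triplets of PC scores", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("trajectory scores contain non-finite values", call. = FALSE)
  degenerate <- sqrt(sum(sweep(scores, 2, colMeans(scores))^2)) <
    .DEGENERATE_TOL * max(1, max(abs(scores)))
  cs <- if (degenerate) 0 else centroid_size(scores)
  obj <- structure(list(points = scores, cs = cs,
                        angle_12 = NA_real_, angle_13 = NA_real_,
                        ed_index = ed_index, es_index = es_index,
                        degenerate = degenerate),
                   class = "trajectory_shape")
  chord <- scores[es_index, ] - scores[ed_index, ]
  if (!degenerate && sqrt(sum(chord^2)) >
        .DEGENERATE_TOL * max(1, max(abs(scores)))) {
    ang <- trajectory_angles(obj)
    obj$angle_12 <- ang[["angle_12"]]
    obj$angle_13 <- ang[["angle_13"]]
  }
  obj
}

#' Trajectory orientation angles
#'
#' Planar angles of the end-diastole to end-systole chord of the trajectory,
#' in the PC1/PC2 and PC1/PC3 planes, via the two-argument arctangent:
#' 0 degrees points along +PC1.
#'
#' @param traj a `trajectory_shape`.
#' @return Named vector `c(angle_12, angle_13)` in degrees, in (-180, 180].
#' @export
trajectory_angles <- function(traj) {
  stopifnot(inherits(traj, "trajectory_shape"))
  chord <- traj$points[traj$es_index, ] - traj$points[traj$ed_index, ]
  if (sqrt(sum(chord^2)) < .DEGENERATE_TOL * max(1, max(abs(traj$points))))
    stop("degenerate trajectory: end-diastole and end-systole coincide",
         call. = FALSE)
  c(angle_12 = atan2(chord[2], chord[1]) * 180 / pi,
    angle_13 = atan2(chord[3], chord[1]) * 180 / pi)
}

#' Shape analysis of motion trajectories
#'
#' Shape-space GPA of the 16 x 3 trajectory configurations followed by PCA
#' of the aligned trajectory coordinates: trajectory-shape scores separate
#' groups whose motion loops differ in form (e.g. flat vs rounded)
#' irrespective of trajectory size and orientation.
#'
#' @param trajs list of `trajectory_shape` objects.
#' @return List with `consensus` (16 x 3), `scores` (subjects x components),
#'   `loadings`, `var_explained`, `aligned` (16 x 3 x n).
#' @export
trajectory_shape_analysis <- function(trajs) {
  if (length(trajs) < 3)
    stop("trajectory shape analysis needs at least 3 trajectories",
         call. = FALSE)
  if (any(vapply(trajs, `[[`, TRUE, "degenerate")))
    stop("degenerate (motionless) trajectories cannot be analysed",
         call. = FALSE)
  A <- simplify2array(lapply(trajs, `[[`, "points"))
  fit <- gpa(A, space = "shape")
  X <- t(apply(fit$aligned, 3, as.vector))
  p <- pca_shapes(X)
  list(consensus = fit$consensus, scores = p$scores, loadings = p$loadings,
       var_explained = p$var_explained, aligned = fit$aligned)
}

#' Permutation ANOVA / MANOVA on a two-level factor
#'
#' Decomposes the total Euclidean sum of squares of `values` (a vector for
#' ANOVA, a matrix for the permutational MANOVA used on aligned trajectory
#' coordinates, where classical parametric MANOVA is unusable at p >> n)
#' into between- and within-group parts. The effect size is
#' R^2 = SS_between / SS_total; its significance is the permutation tail
#' probability over `n_perm` label shuffles, with the observed statistic
#' included in the null set.
#'
#' @param values numeric vector, or observations x variables matrix.
#' @param groups two-level factor (or coercible).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for reproducibility.
#' @return List with `R_sq`, `p`, `n_perm`.
#' @export
perm_anova <- function(values, groups, n_perm = 9999, seed = NULL) {
  X <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("perm_anova needs at least two groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("perm_anova needs at least 2 observations per group", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r2 <- function(g) {
    gm <- colMeans(X)
    ssb <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ssb <- ssb + length(idx) * sum((colMeans(X[idx, , drop = FALSE]) - gm)^2)
    }
    sst <- sum(sweep(X, 2, gm)^2)
    if (sst == 0) return(0)
    ssb / sst
  }
  obs <- r2(groups)
  exceed <- 1L  # observed statistic counts as one member of the null set
  for (b in seq_len(n_perm)) {
    if (r2(sample(groups)) >= obs) exceed <- exceed + 1L
  }
  list(R_sq = obs, p = exceed / (n_perm + 1), n_perm = n_perm)
}

#' Per-subject trajectory attribute table
#'
#' Runs PCA on a transported set, builds each subject's trajectory from the
#' first three PC scores, and returns the attribute table used downstream
#' (classification, group ANOVA): trajectory centroid size, the two
#' orientation angles, and the first `n_shape_pcs` trajectory-shape PCs.
#'
#' @param ts a `transported_set`.
#' @param n_shape_pcs number of trajectory-shape PCs to append (default 10).
#' @return List with `table` (data.frame), `trajectories` (list of
#'   `trajectory_shape`), `pca` (the deformation-space PCA), `shape_analysis`.
#' @export
trajectory_attributes <- function(ts, n_shape_pcs = 10) {
  stopifnot(inherits(ts, "transported_set"))
  p <- pca_shapes(ts, rank = 3)
  n <- length(ts$subject_ids)
  trajs <- lapply(seq_len(n), function(i) {
    rows <- (i - 1) * ts$n_times + seq_len(ts$n_times)
    build_trajectory(p$scores[rows, 1:3, drop = FALSE])
  })
  sa <- trajectory_shape_analysis(trajs)
  npc <- min(n_shape_pcs, ncol(sa$scores))
  tab <- data.frame(subject_id = ts$subject_ids, group = ts$groups,
                    traj_cs = vapply(trajs, `[[`, 0, "cs"),
                    angle_12 = vapply(trajs, `[[`, 0, "angle_12"),
                    angle_13 = vapply(trajs, `[[`, 0, "angle_13"),
                    stringsAsFactors = FALSE)
  shp <- as.data.frame(sa$scores[, seq_len(npc), drop = FALSE])
  names(shp) <- paste0("traj_shape_PC", seq_len(npc))
  list(table = cbind(tab, shp), trajectories = trajs, pca = p,
       shape_analysis = sa)
}
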