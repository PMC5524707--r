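# Two-block PLS (singular warps), permutation z-score effect sizes and
# major-axis slopes: strength and direction of LV-LA covariation, within
# individuals (16 LV vs 16 LA shapes) and across individuals (trajectory
# shapes).

# Economical cross-covariance SVD: with A (n x p), B (n x q) column-centred
# and p, q >> n, the SVD of C = t(A) %*% B / (n - 1) is obtained from the
# thin SVDs of A and B without materializing the p x q matrix.
.pls_svd <- function(Ac, Bc) {
  sa <- svd(Ac); sb <- svd(Bc)
  ka <- sa$d > max(sa$d, 0) * 1e-12
  kb <- sb$d > max(sb$d, 0) * 1e-12
  if (!any(ka) || !any(kb))
    stop("zero-variance block: PLS is undefined", call. = FALSE)
  Ua <- sa$u[, ka, drop = FALSE]; da <- sa$d[ka]; Va <- sa$v[, ka, drop = FALSE]
  Ub <- sb$u[, kb, drop = FALSE]; db <- sb$d[kb]; Vb <- sb$v[, kb, drop = FALSE]
  M <- (da * t(Ua)) %*% Ub %*% diag(db, length(db)) / (nrow(Ac) - 1)
  sm <- svd(M)
  list(Va = Va, Vb = Vb, sm = sm, Ua = Ua, da = da, Ub = Ub, db = db)
}

#' Two-block partial least squares (singular warps)
#'
#' Singular value decomposition of the cross-covariance matrix of two
#' column-centred blocks of variables measured on the same observations.
#' The paired singular vectors (singular warps, SW) are the directions in
#' each block that maximize the between-block covariance; the blocks are
#' treated symmetrically, with no dependence/independence attribution.
#' Works at p, q >> n (shape blocks of thousands of coordinates on 16
#' observations) without forming the p x q matrix.
#'
#' @param block_A,block_B numeric matrices with matched rows (observations).
#' @return An object of class `"pls_result"`: `singular_vectors_A` (p x r),
#'   `singular_vectors_B` (q x r), `singular_values` (non-increasing; the
#'   covariances of the paired scores), `scores_A`, `scores_B`, `r_pls`
#'   (correlation of the first paired scores), `pct_covariance` (squared
#'   first singular value over the sum of squares).
#' @export
two_block_pls <- function(block_A, block_B) {
  A <- as.matrix(block_A); B <- as.matrix(block_B)
  if (nrow(A) != nrow(B))
    stop("blocks must have the same number of rows", call. = FALSE)
  if (nrow(A) < 3)
    stop("two-block PLS needs at least 3 observations", call. = FALSE)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- .pls_svd(Ac, Bc)
  U <- s$Va %*% s$sm$u
  V <- s$Vb %*% s$sm$v
  d <- s$sm$d
  # sign convention: per pair, the A vector's largest-|loading| entry is
  # positive; the B vector flips with it so the singular value stays >= 0
  for (j in seq_along(d)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  scores_A <- Ac %*% U
  scores_B <- Bc %*% V
  structure(list(singular_vectors_A = U, singular_vectors_B = V,
                 singular_values = d,
                 scores_A = scores_A, scores_B = scores_B,
                 r_pls = stats::cor(scores_A[, 1], scores_B[, 1]),
                 pct_covariance = d[1]^2 / sum(d^2)),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("two-block PLS: r_PLS =", round(x$r_pls, 4),
      "| first pair carries", round(100 * x$pct_covariance, 1),
      "% of squared cross-covariance\n")
  invisible(x)
}

#' Permutation z-score for the strength of covariation
#'
#' Standardized effect size of morphological integration: the rows of one
#' block are permuted `n_perm` times, the first-pair PLS correlation is
#' recomputed for each permutation, and
#' `z = (r_obs - mean(r_perm)) / sd(r_perm)`.
#'
#' @inheritParams two_block_pls
#' @param n_perm number of row permutations.
#' @param seed optional RNG seed.
#' @return The z-score (scalar).
#' @export
pls_effect_size <- function(block_A, block_B, n_perm = 999, seed = NULL) {
  A <- as.matrix(block_A); B <- as.matrix(block_B)
  if (nrow(A) != nrow(B))
    stop("blocks must have the same number of rows", call. = FALSE)
  if (nrow(A) < 3)
    stop("effect size needs at least 3 observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- .pls_svd(Ac, Bc)
  # first-pair score correlation for a given row order of block B: only the
  # left singular rows of B move under permutation, so everything is small
  r_first <- function(perm) {
    M <- (s$da * t(s$Ua)) %*% s$Ub[perm, , drop = FALSE] %*%
      diag(s$db, length(s$db))
    sm <- svd(M)
    a <- s$Ua %*% (s$da * sm$u[, 1])
    b <- s$Ub[perm, , drop = FALSE] %*% (s$db * sm$v[, 1])
    stats::cor(a, b)[1]
  }
  n <- nrow(A)
  r_obs <- r_first(seq_len(n))
  r_perm <- vapply(seq_len(n_perm), function(i) r_first(sample(n)),
                   numeric(1))
  sd_p <- stats::sd(r_perm)
  if (!is.finite(sd_p) || sd_p == 0)
    stop("degenerate permutation distribution (sd = 0): ",
         "z-score is undefined", call. = FALSE)
  (r_obs - mean(r_perm)) / sd_p
}

#' Major-axis regression slope
#'
#' Slope of the first eigenvector of the 2 x 2 covariance matrix of (x, y):
#' the symmetric line of best fit, with residuals measured orthogonally to
#' the line, appropriate when neither variable is the dependent one (as for
#' paired PLS scores). The returned slope carries the sign of the
#' covariance.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return The slope of y on x.
#' @export
major_axis_slope <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("major axis regression needs >= 3 paired points", call. = FALSE)
  a <- stats::var(x); b <- stats::var(y); cc <- stats::cov(x, y)
  if (a + b == 0)
    stop("zero total variance: slope undefined", call. = FALSE)
  if (cc == 0) {
    if (a == b)
      stop("isotropic point cloud: major-axis slope is indeterminate",
           call. = FALSE)
    return(if (a > b) 0 else Inf)
  }
  (b - a + sqrt((a - b)^2 + 4 * cc^2)) / (2 * cc)
}

# column indices of one chamber's coordinates in the flattened (3k) layout
.chamber_cols <- function(chamber, k, which) {
  idx <- which(chamber == which)
  c(idx, idx + k, idx + 2L * k)
}

#' Within-individual LV-LA covariation
#'
#' Strength and direction of the covariation between a subject's 16
#' transported LV shapes and its 16 transported LA shapes: a two-block PLS
#' of the chamber blocks, the permutation z-score of its first-pair
#' correlation, and the major-axis slope of the first singular-warp scores
#' (SW1_LA on SW1_LV, so a slope above 1 means the LA changes shape faster
#' per unit of LV shape change).
#'
#' @param ts a `transported_set` with LV/LA chamber labels.
#' @param subject subject id or index.
#' @param n_perm permutations for the z-score; 0 skips it (`z = NA`).
#' @param seed optional RNG seed.
#' @return List with `z`, `ma_slope`, `r_pls`, `pct_covariance`, `pls`.
#' @export
individual_covariation <- function(ts, subject, n_perm = 999, seed = NULL) {
  stopifnot(inherits(ts, "transported_set"))
  if (is.null(ts$chamber))
    stop("transported set carries no LV/LA chamber labels", call. = FALSE)
  i <- if (is.character(subject)) match(subject, ts$subject_ids)
       else as.integer(subject)
  if (is.na(i)) stop("unknown subject: ", subject, call. = FALSE)
  rows <- (i - 1) * ts$n_times + seq_len(ts$n_times)
  lv <- ts$residuals[rows, .chamber_cols(ts$chamber, ts$k, "LV"),
                     drop = FALSE]
  la <- ts$residuals[rows, .chamber_cols(ts$chamber, ts$k, "LA"),
                     drop = FALSE]
  pls <- two_block_pls(lv, la)
  z <- if (n_perm > 0) pls_effect_size(lv, la, n_perm = n_perm, seed = seed)
       else NA_real_
  list(z = z,
       ma_slope = major_axis_slope(pls$scores_A[, 1], pls$scores_B[, 1]),
       r_pls = pls$r_pls, pct_covariance = pls$pct_covariance, pls = pls)
}

#' Per-subject covariation table for a cohort
#'
#' Applies [individual_covariation()] to every subject of a transported set.
#'
#' @inheritParams individual_covariation
#' @return data.frame with `subject_id`, `group`, `z_score`, `ma_slope`,
#'   `r_pls`.
#' @export
cohort_covariation <- function(ts, n_perm = 999, seed = NULL) {
  n <- length(ts$subject_ids)
  if (!is.null(seed)) set.seed(seed)
  subject_seeds <- if (is.null(seed)) rep(list(NULL), n)
                   else as.list(sample.int(.Machine$integer.max, n))
  res <- lapply(seq_len(n), function(i)
    individual_covariation(ts, i, n_perm = n_perm,
                           seed = subject_seeds[[i]]))
  data.frame(subject_id = ts$subject_ids, group = ts$groups,
             z_score = vapply(res, `[[`, 0, "z"),
             ma_slope = vapply(res, `[[`, 0, "ma_slope"),
             r_pls = vapply(res, `[[`, 0, "r_pls"),
             stringsAsFactors = FALSE)
}

#' Covariation between LV and LA trajectory shapes
#'
#' Second-order covariation: each subject is one observation, represented by
#' its per-chamber trajectory shapes (each chamber run through the full
#' transport + PCA pipeline separately). Trajectories of each chamber are
#' GPA-aligned across all subjects; within each group a two-block PLS of the
#' aligned LV vs LA trajectory coordinates gives a z-score (strength) and a
#' major-axis slope on the first singular-warp pair (direction). Group
#' differences in z and in slope are assessed by permutation of the group
#' labels.
#'
#' @param lv_trajs,la_trajs lists of `trajectory_shape`, one per subject,
#'   in matching order.
#' @param groups two-level factor over subjects.
#' @param n_perm label permutations for the group-difference tests.
#' @param n_perm_z row permutations inside each z-score computation.
#' @param seed optional RNG seed.
#' @return List with per-group `z`, `ma_slope`, `pct_covariance`, and
#'   permutation p-values `p_z_diff`, `p_slope_diff`.
#' @export
trajectory_covariation <- function(lv_trajs, la_trajs, groups,
                                   n_perm = 499, n_perm_z = 99,
                                   seed = NULL) {
  groups <- factor(groups)
  if (any(table(groups) < 3))
    stop("each group needs at least 3 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  flat <- function(trajs) {
    A <- simplify2array(lapply(trajs, `[[`, "points"))
    t(apply(gpa(A, space = "shape")$aligned, 3, as.vector))
  }
  LV <- flat(lv_trajs)
  LA <- flat(la_trajs)
  stats_for <- function(g) {
    out <- lapply(levels(groups), function(lev) {
      idx <- which(g == lev)
      pls <- two_block_pls(LV[idx, , drop = FALSE], LA[idx, , drop = FALSE])
      z <- pls_effect_size(LV[idx, , drop = FALSE], LA[idx, , drop = FALSE],
                           n_perm = n_perm_z)
      list(z = z,
           slope = major_axis_slope(pls$scores_A[, 1], pls$scores_B[, 1]),
           pct = pls$pct_covariance)
    })
    names(out) <- levels(groups)
    out
  }
  obs <- stats_for(groups)
  z_obs <- abs(obs[[1]]$z - obs[[2]]$z)
  s_obs <- abs(obs[[1]]$slope - obs[[2]]$slope)
  z_ge <- 1L; s_ge <- 1L
  for (b in seq_len(n_perm)) {
    perm <- stats_for(sample(groups))
    if (abs(perm[[1]]$z - perm[[2]]$z) >= z_obs) z_ge <- z_ge + 1L
    if (abs(perm[[1]]$slope - perm[[2]]$slope) >= s_obs) s_ge <- s_ge + 1L
  }
  list(z = vapply(obs, `[[`, 0, "z"),
       ma_slope = vapply(obs, `[[`, 0, "slope"),
       pct_covariance = vapply(obs, `[[`, 0, "pct"),
       p_z_diff = z_ge / (n_perm + 1),
       p_slope_diff = s_ge / (n_perm + 1),
       n_perm = n_perm)
}
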