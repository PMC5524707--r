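# Thin-plate-spline bending energy, partial warps, and the disintegration
# slope: the regression coefficient of log partial-warp variance on log
# bending energy. A slope of -1 marks a self-similar shape series; more
# negative slopes mark stronger integration, slopes near 0 a disintegrated
# (biologically implausible) series.

#' Bending-energy (partial-warp) basis of a reference configuration
#'
#' Builds the thin-plate-spline bending-energy matrix of a 3D reference
#' configuration, using the 3D biharmonic kernel U(r) = -r (the 2D
#' r^2 log r kernel does not apply in three dimensions), and
#' eigen-decomposes it. The eigenvectors with positive eigenvalue are the
#' partial warps; the null space (4 dimensions in 3D: affine terms absorb
#' the rest) is discarded. Eigenvalues are returned in ascending order, so
#' large-scale (low bending energy) warps come first.
#'
#' @param reference k x 3 landmark matrix, no duplicate landmarks.
#' @return An object of class `"partial_warp_basis"`: `reference`,
#'   `eigenvalues` (positive, ascending), `eigenvectors` (k x (k-4),
#'   orthonormal, orthogonal to the affine subspace of the reference).
#' @export
bending_energy_basis <- function(reference) {
  check_config(reference, min_k = 5)
  k <- nrow(reference)
  D <- as.matrix(stats::dist(reference))
  if (any(D[upper.tri(D)] < .DEGENERATE_TOL * max(D)))
    stop("duplicate landmarks: thin-plate-spline kernel is singular",
         call. = FALSE)
  K <- -D
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  Linv <- solve(L)
  Be <- Linv[seq_len(k), seq_len(k)]
  Be <- (Be + t(Be)) / 2
  eig <- eigen(Be, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  ord <- rev(which(pos)) # ascending bending energy
  structure(list(reference = reference,
                 eigenvalues = eig$values[ord],
                 eigenvectors = eig$vectors[, ord, drop = FALSE]),
            class = "partial_warp_basis")
}

#' @export
print.partial_warp_basis <- function(x, ...) {
  cat("partial_warp_basis:", nrow(x$reference), "landmarks,",
      length(x$eigenvalues), "partial warps; bending energies in [",
      signif(min(x$eigenvalues), 3), ",", signif(max(x$eigenvalues), 3),
      "]\n")
  invisible(x)
}

# partial-warp scores of one configuration: (k-4) x 3 matrix. Affine
# deformations of the reference score exactly zero on every warp.
partial_warp_scores <- function(shape, basis) {
  crossprod(basis$eigenvectors, shape - basis$reference)
}

#' Per-warp variances of a shape series
#'
#' For each partial warp, the variance of its score across the series,
#' summed over the three coordinate dimensions. Shapes must be superimposed
#' on the basis reference (as after a GPA against it); a shared affine
#' component contributes nothing, by orthogonality of the warps to the
#' affine subspace.
#'
#' @param shapes k x 3 x n array of configurations aligned to the reference.
#' @param basis a `partial_warp_basis`.
#' @return Numeric vector of length k - 4 (ascending bending energy order).
#' @export
partial_warp_variances <- function(shapes, basis) {
  if (is.list(shapes)) shapes <- simplify2array(shapes)
  stopifnot(length(dim(shapes)) == 3)
  n <- dim(shapes)[3]
  sc <- vapply(seq_len(n),
               function(i) as.vector(partial_warp_scores(shapes[, , i],
                                                         basis)),
               numeric(3 * length(basis$eigenvalues)))
  v <- apply(sc, 1, stats::var)
  m <- matrix(v, nrow = length(basis$eigenvalues))
  rowSums(m)
}

#' Disintegration slope of a shape series
#'
#' Ordinary least-squares slope of log partial-warp variance on log bending
#' energy. Self-similar series give -1; integrated series give more
#' negative values; values near 0 indicate disintegration. Warps whose
#' variance falls below `floor_frac` times the largest variance are dropped
#' (their logarithm is numerically meaningless).
#'
#' @param shapes k x 3 x n array of shapes (a `homologous_cycle`'s shapes,
#'   typically), or a `homologous_cycle`.
#' @param basis a `partial_warp_basis`; its reference is the template the
#'   shapes are aligned against. If the shapes are not yet superimposed on
#'   it set `align = TRUE`.
#' @param align superimpose each shape on the reference (rotation after
#'   centring and unit-scaling both) before scoring?
#' @param floor_frac relative variance floor below which warps are excluded.
#' @return List with `slope`, `intercept`, `log_energy`, `log_variance`,
#'   `n_warps` used.
#' @export
disintegration_slope <- function(shapes, basis, align = FALSE,
                                 floor_frac = 1e-15) {
  if (inherits(shapes, "homologous_cycle")) shapes <- shapes$shapes
  if (is.list(shapes)) shapes <- simplify2array(shapes)
  if (align) {
    ref <- preshape(basis$reference)
    basis2 <- basis
    basis2$reference <- ref
    for (i in seq_len(dim(shapes)[3]))
      shapes[, , i] <- opa_align(preshape(shapes[, , i]), ref)$aligned
    basis <- basis2
  }
  v <- partial_warp_variances(shapes, basis)
  keep <- v > floor_frac * max(v)
  if (sum(keep) < 2)
    stop("fewer than 2 partial warps with positive variance: ",
         "disintegration slope is undefined", call. = FALSE)
  lx <- log(basis$eigenvalues[keep])
  ly <- log(v[keep])
  slope <- stats::cov(lx, ly) / stats::var(lx)
  list(slope = slope, intercept = mean(ly) - slope * mean(lx),
       log_energy = lx, log_variance = ly, n_warps = sum(keep))
}

#' Per-subject disintegration slopes for a transported cohort
#'
#' Computes each subject's disintegration slope from its 16 transported
#' shapes, scored against a single partial-warp basis built on the common
#' template, so slopes are comparable across subjects.
#'
#' @param ts a `transported_set`.
#' @param basis optional pre-built basis on `ts$ct` (built here if omitted).
#' @return data.frame with `subject_id`, `group`, `slope`.
#' @export
cohort_disintegration <- function(ts, basis = NULL) {
  stopifnot(inherits(ts, "transported_set"))
  if (is.null(basis)) basis <- bending_energy_basis(ts$ct)
  slopes <- vapply(seq_along(ts$subject_ids), function(i)
    disintegration_slope(transported_shapes(ts, i), basis)$slope,
    numeric(1))
  data.frame(subject_id = ts$subject_ids, group = ts$groups,
             slope = slopes, stringsAsFactors = FALSE)
}
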