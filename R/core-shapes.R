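# Core landmark-configuration machinery: centroid size, ordinary and
# generalized Procrustes superimposition, Procrustes distance, tangent space.
#
# A landmark configuration is a plain numeric k x m matrix (m = 2 or 3; all
# cardiac data are 3D, 2D is supported for planar shape arithmetic). Sets of
# configurations travel as k x m x n arrays, as in the geometric-morphometrics
# packages this design follows.

.DEGENERATE_TOL <- 1e-12

#' Validate a landmark configuration matrix
#'
#' @param x numeric matrix, k landmarks by m (2 or 3) coordinates.
#' @param min_k minimum number of landmarks required.
#' @return `x`, invisibly, after validation.
#' @keywords internal
check_config <- function(x, min_k = 2) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("landmark configuration must be a numeric matrix", call. = FALSE)
  if (!ncol(x) %in% c(2L, 3L))
    stop("landmark configuration must have 2 or 3 coordinate columns",
         call. = FALSE)
  if (nrow(x) < min_k)
    stop("configuration needs at least ", min_k, " landmarks", call. = FALSE)
  if (!all(is.finite(x)))
    stop("configuration contains non-finite coordinates", call. = FALSE)
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid: the standard size measure of geometric morphometrics.
#' It scales linearly under uniform scaling of the configuration.
#'
#' @param x numeric k x m landmark matrix.
#' @return A positive scalar.
#' @examples
#' sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
#' centroid_size(sq) # sqrt(8)
#' @export
centroid_size <- function(x) {
  check_config(x)
  cx <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(cx^2))
  if (cs < .DEGENERATE_TOL * max(1, max(abs(x))))
    stop("degenerate configuration: all landmarks coincide (centroid size 0)",
         call. = FALSE)
  cs
}

# centre a configuration on its centroid
center_config <- function(x) sweep(x, 2, colMeans(x))

# centred, unit-centroid-size pre-shape
preshape <- function(x) {
  cx <- center_config(x)
  cx / centroid_size(x)
}

# optimal rotation (SO(m), no reflection unless allowed) taking A onto B,
# both already centred: Kabsch via SVD of t(A) %*% B
.opt_rotation <- function(A, B, allow_reflection = FALSE) {
  H <- crossprod(A, B)
  s <- svd(H)
  d <- rep(1, ncol(A))
  if (!allow_reflection && det(s$u %*% t(s$v)) < 0)
    d[length(d)] <- -1
  rot <- s$u %*% (d * t(s$v))
  list(rotation = rot, trace = sum(s$d * d))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Least-squares superimposition of `source` onto `target`: translation,
#' rotation, and optionally uniform scale. Reflections are excluded by
#' default (the rotation has determinant +1), since anatomical landmark sets
#' have a fixed chirality.
#'
#' @param source,target k x m landmark matrices with equal dimensions.
#' @param scale fit a uniform scale factor as well?
#' @param allow_reflection permit improper rotations?
#' @return A list with `aligned` (the transformed source, in the target's
#'   frame), `rotation` (m x m), `scale`, `translation`, and `residual`
#'   (root summed squared distance between `aligned` and `target`).
#' @export
opa_align <- function(source, target, scale = FALSE, allow_reflection = FALSE) {
  check_config(source); check_config(target)
  if (!all(dim(source) == dim(target)))
    stop("source and target must have the same landmark dimensions",
         call. = FALSE)
  A <- center_config(source)
  B <- center_config(target)
  centroid_size(source); centroid_size(target) # degenerate guard
  fit <- .opt_rotation(A, B, allow_reflection)
  beta <- if (scale) fit$trace / sum(A^2) else 1
  aligned <- beta * A %*% fit$rotation
  aligned <- sweep(aligned, 2, colMeans(target), "+")
  list(aligned    = aligned,
       rotation   = fit$rotation,
       scale      = beta,
       translation = colMeans(target) - beta * colMeans(source) %*% fit$rotation,
       residual   = sqrt(sum((aligned - target)^2)))
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of a set of configurations onto their evolving
#' mean, either in shape space (translation, rotation and scaling to unit
#' centroid size removed) or in size-and-shape space (translation and
#' rotation only, size retained). The consensus is the arithmetic mean of
#' the aligned coordinates, re-normalized to unit centroid size at each
#' iteration when working in shape space. Iteration stops when the
#' root-mean-square displacement of the consensus falls below `tol`.
#'
#' @param configs k x m x n array (or list) of landmark configurations.
#' @param space `"shape"` or `"size_and_shape"`.
#' @param tol convergence tolerance on the consensus RMS displacement.
#' @param max_iter maximum number of iterations.
#' @return A list of class `"gpa"` with `consensus` (k x m), `aligned`
#'   (k x m x n), `cs` (original centroid sizes), `space`, and `iterations`.
#' @export
gpa <- function(configs, space = c("shape", "size_and_shape"),
                tol = 1e-8, max_iter = 200) {
  space <- match.arg(space)
  if (is.list(configs))
    configs <- simplify2array(configs)
  if (length(dim(configs)) != 3 || dim(configs)[3] < 2)
    stop("gpa() needs at least 2 configurations (k x m x n array)",
         call. = FALSE)
  k <- dim(configs)[1]; m <- dim(configs)[2]; n <- dim(configs)[3]
  cs <- numeric(n)
  aligned <- configs
  for (i in seq_len(n)) {
    check_config(configs[, , i])
    cs[i] <- centroid_size(configs[, , i])
    aligned[, , i] <- center_config(configs[, , i])
    if (space == "shape")
      aligned[, , i] <- aligned[, , i] / cs[i]
  }
  consensus <- aligned[, , 1]
  if (space == "shape") consensus <- consensus / sqrt(sum(consensus^2))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      rot <- .opt_rotation(aligned[, , i], consensus)$rotation
      aligned[, , i] <- aligned[, , i] %*% rot
    }
    new_consensus <- apply(aligned, c(1, 2), mean)
    if (space == "shape")
      new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    trace <- c(trace, delta)
    if (delta < tol) {
      out <- list(consensus = consensus, aligned = aligned, cs = cs,
                  space = space, iterations = iter)
      class(out) <- "gpa"
      return(out)
    }
  }
  stop("GPA did not converge in ", max_iter,
       " iterations; consensus displacement trace: ",
       paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
       call. = FALSE)
}

#' Procrustes (geodesic) distance between two shapes
#'
#' Arc distance in Kendall shape space between the centred, unit-size,
#' optimally rotated pre-shapes of `a` and `b`. Reflections are excluded
#' from the rotation search; because the two largest singular values of the
#' cross-product always dominate the smallest, the distance is bounded by
#' pi/2, attained e.g. by a labelled planar triangle and its mirror image.
#'
#' @param a,b landmark matrices of equal dimensions.
#' @return The geodesic distance, in `[0, pi/2]`.
#' @export
procrustes_distance <- function(a, b) {
  check_config(a); check_config(b)
  if (!all(dim(a) == dim(b)))
    stop("configurations must have the same landmark dimensions",
         call. = FALSE)
  pa <- preshape(a); pb <- preshape(b)
  tr <- .opt_rotation(pa, pb)$trace
  acos(min(1, max(-1, tr)))
}

#' Project a shape onto the tangent space at a pole
#'
#' Orthogonal projection of a centred, unit-centroid-size configuration onto
#' the Euclidean tangent plane at the `pole` pre-shape. The configuration is
#' assumed already rotated onto the pole (as after a GPA); centring and unit
#' scaling are applied here. The linear orthogonal projection is the one
#' compatible with subtraction/addition arithmetic in the tangent plane.
#'
#' @param x configuration, pre-rotated onto the pole.
#' @param pole the tangent-space pole (centred, unit centroid size).
#' @return A k x m matrix: the tangent-space vector, orthogonal to the pole.
#' @export
tangent_project <- function(x, pole) {
  px <- preshape(x); pp <- preshape(pole)
  px - sum(px * pp) * pp
}

#' Map a tangent vector back to a configuration
#'
#' Inverse of [tangent_project()]: reconstructs the unit-size pre-shape whose
#' orthogonal projection at `pole` is `v`. Exact for shapes within pi/2 of
#' the pole.
#'
#' @param v tangent vector (k x m, orthogonal to the pole).
#' @param pole the tangent-space pole.
#' @return A centred, unit-centroid-size configuration.
#' @export
tangent_unproject <- function(v, pole) {
  pp <- preshape(pole)
  sq <- sqrt(max(0, 1 - sum(v^2)))
  sq * pp + v
}
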