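# Linear-shift parallel transport: move each subject's within-cycle
# deformations from its local template (local mean shape) to the common
# template (grand mean), by subtraction and addition in the common tangent
# plane. Inter-individual baseline shape differences are thereby filtered
# out and only deformations remain.

#' Local template of a subject's cycle
#'
#' The shape-space GPA consensus of the subject's 16 homologous shapes: the
#' subject's local mean shape.
#'
#' @param hcycle a `homologous_cycle`.
#' @return A k x 3 centred, unit-centroid-size configuration.
#' @export
local_template <- function(hcycle) {
  stopifnot(inherits(hcycle, "homologous_cycle"))
  gpa(hcycle$shapes, space = "shape")$consensus
}

#' Linear-shift parallel transport of a cohort of cycles
#'
#' For each subject the 16 homologous shapes are superimposed by shape-space
#' GPA, yielding the local template (LT, the local mean). The common
#' template (CT) is the shape-space grand mean of all shapes of all
#' subjects. Each subject's LT is rotated onto the CT and the same rotation
#' is applied rigidly to its 16 aligned shapes, keeping the within-subject
#' deformations coherent. All shapes are then projected orthogonally onto
#' the tangent plane at the CT, and each subject's tangent mean is
#' subtracted, so that every transported cycle is exactly centred on the CT:
#' the residuals are the pure deformations, comparable across subjects.
#'
#' @param hcycles list of `homologous_cycle` objects (one per subject),
#'   all with 16 shapes over the same landmarks.
#' @param tol GPA convergence tolerance.
#' @return An object of class `"transported_set"` with elements
#'   `ct` (k x 3 common template), `lt` (k x 3 x n local templates, rotated
#'   onto the CT), `residuals` ((n*16) x 3k matrix of tangent-space
#'   deformations, subject-major row order), `subject_ids`, `groups`,
#'   `chamber`, `k`, `n_times`.
#' @export
linear_shift <- function(hcycles, tol = 1e-8) {
  if (length(hcycles) < 2)
    stop("linear shift needs at least 2 subjects", call. = FALSE)
  n_times <- dim(hcycles[[1]]$shapes)[3]
  k <- dim(hcycles[[1]]$shapes)[1]
  for (h in hcycles) {
    stopifnot(inherits(h, "homologous_cycle"))
    if (dim(h$shapes)[3] != n_times || dim(h$shapes)[1] != k)
      stop("subject ", h$subject_id,
           " has an incompatible number of shapes or landmarks",
           call. = FALSE)
  }
  n <- length(hcycles)

  # per-subject shape-space GPA: aligned unit-CS shapes + local template
  local <- lapply(hcycles, function(h) gpa(h$shapes, space = "shape",
                                           tol = tol))

  # common template: grand mean of all shapes of all subjects
  allshapes <- array(unlist(lapply(local, function(g) g$aligned)),
                     dim = c(k, 3, n * n_times))
  ct <- gpa(allshapes, space = "shape", tol = tol)$consensus

  residuals <- matrix(0, n * n_times, 3 * k)
  lt <- array(0, dim = c(k, 3, n))
  for (i in seq_len(n)) {
    rot <- .opt_rotation(local[[i]]$consensus, ct)$rotation
    lt[, , i] <- local[[i]]$consensus %*% rot
    proj <- vapply(seq_len(n_times), function(t)
      as.vector(tangent_project(local[[i]]$aligned[, , t] %*% rot, ct)),
      numeric(3 * k))                        # 3k x n_times
    proj <- t(proj)
    residuals[(i - 1) * n_times + seq_len(n_times), ] <-
      sweep(proj, 2, colMeans(proj))
  }
  structure(list(ct = ct, lt = lt, residuals = residuals,
                 subject_ids = vapply(hcycles, `[[`, "", "subject_id"),
                 groups = vapply(hcycles, `[[`, "", "group"),
                 chamber = hcycles[[1]]$chamber,
                 k = k, n_times = n_times),
            class = "transported_set")
}

#' @export
print.transported_set <- function(x, ...) {
  cat("transported_set:", length(x$subject_ids), "subjects x", x$n_times,
      "shapes of", x$k, "landmarks (tangent space at the common template)\n")
  invisible(x)
}

#' Transported shapes of a subject
#'
#' Reconstructs the subject's transported configurations, `CT + residual`,
#' as a k x 3 x n_times array.
#'
#' @param ts a `transported_set`.
#' @param subject subject id or index.
#' @return k x 3 x n_times array.
#' @export
transported_shapes <- function(ts, subject) {
  i <- if (is.character(subject)) match(subject, ts$subject_ids)
       else as.integer(subject)
  if (is.na(i) || i < 1 || i > length(ts$subject_ids))
    stop("unknown subject: ", subject, call. = FALSE)
  rows <- (i - 1) * ts$n_times + seq_len(ts$n_times)
  out <- array(0, dim = c(ts$k, 3, ts$n_times))
  for (t in seq_len(ts$n_times))
    out[, , t] <- ts$ct + matrix(ts$residuals[rows[t], ], ts$k, 3)
  out
}
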