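# Randomized-split SVM evaluation of feature tables, plus the
# reproducibility utilities (coefficient of variation of replica
# differences and the normalized cycle-shape distance).

# AUC by the rank (Mann-Whitney) statistic; `positive` scores should be
# larger for the positive class
.auc <- function(score, truth_positive) {
  pos <- score[truth_positive]
  neg <- score[!truth_positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Randomized-split SVM evaluation
#'
#' Repeated random sub-sampling evaluation of a radial-basis (Gaussian)
#' kernel support vector machine with cost C = 1. Per repetition, the
#' stated number of training cases is drawn from each class without
#' replacement, features are standardized using training-split statistics
#' only (no test-set leakage), the SVM is fitted (kernel bandwidth
#' gamma = 1/d on the standardized features), and the held-out remainder is
#' classified. Means over repetitions of total accuracy, specificity
#' (majority class, Control), sensitivity (HCM), and the AUC of the ROC of
#' the decision scores are reported.
#'
#' @param features n x d numeric matrix or data.frame of predictors.
#' @param labels two-level factor (or coercible); level `"HCM"` (or the
#'   second level) is the positive class.
#' @param n_train named or ordered vector of per-class training counts,
#'   default `c(Control = 35, HCM = 17)` leaving 10 + 3 test cases at the
#'   study's group sizes.
#' @param n_reps number of random splits (default 1000).
#' @param seed RNG seed.
#' @param positive label of the positive (disease) class; default `"HCM"`
#'   if present, else the rarer level.
#' @return List with `auc`, `accuracy`, `specificity`, `sensitivity`
#'   (means over repetitions), `per_rep` data.frame, `n_reps`, `dropped`
#'   (names of constant feature columns removed).
#' @export
randomized_svm_eval <- function(features, labels,
                                n_train = c(Control = 35, HCM = 17),
                                n_reps = 1000, seed = NULL,
                                positive = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must have exactly two levels", call. = FALSE)
  if (is.null(positive))
    positive <- if ("HCM" %in% levels(labels)) "HCM"
                else levels(labels)[which.min(table(labels))]
  negative <- setdiff(levels(labels), positive)
  # constant columns carry no information and break standardization
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    message("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("no informative features left", call. = FALSE)
  if (is.null(names(n_train))) names(n_train) <- levels(labels)
  for (lev in levels(labels)) {
    n_lev <- sum(labels == lev)
    if (!lev %in% names(n_train))
      stop("n_train has no entry for class ", lev, call. = FALSE)
    if (n_train[lev] < 1 || n_train[lev] >= n_lev)
      stop("n_train for class ", lev, " must leave at least 1 test case",
           call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  per_rep <- matrix(NA_real_, n_reps, 4,
                    dimnames = list(NULL, c("auc", "accuracy",
                                            "specificity", "sensitivity")))
  idx_by_class <- split(seq_along(labels), labels)
  for (r in seq_len(n_reps)) {
    train <- unlist(lapply(levels(labels), function(lev)
      sample(idx_by_class[[lev]], n_train[lev])))
    test <- setdiff(seq_along(labels), train)
    mu <- colMeans(X[train, , drop = FALSE])
    sg <- apply(X[train, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(X[train, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- e1071::svm(Ztr, labels[train], kernel = "radial", cost = 1,
                      gamma = 1 / ncol(Ztr), scale = FALSE)
    pred <- stats::predict(fit, Zte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # e1071 labels the decision column "first/second": positive values
    # favour the first class
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    score_pos <- if (first == positive) dv[, 1] else -dv[, 1]
    truth <- labels[test]
    per_rep[r, "auc"] <- .auc(score_pos, truth == positive)
    per_rep[r, "accuracy"] <- mean(pred == truth)
    per_rep[r, "specificity"] <- mean(pred[truth == negative] == negative)
    per_rep[r, "sensitivity"] <- mean(pred[truth == positive] == positive)
  }
  list(auc = mean(per_rep[, "auc"]),
       accuracy = mean(per_rep[, "accuracy"]),
       specificity = mean(per_rep[, "specificity"]),
       sensitivity = mean(per_rep[, "sensitivity"]),
       per_rep = as.data.frame(per_rep), n_reps = n_reps,
       dropped = dropped)
}

#' Coefficient of variation of replica differences
#'
#' Reproducibility summary for paired replica measurements: the per-subject
#' absolute differences between the two replicas are taken, and their
#' standard deviation divided by their mean, times 100, is returned.
#'
#' @param a,b paired replica measurements (equal-length numeric vectors),
#'   or a two-column matrix in `a` alone.
#' @return Percent CV (scalar). Identical replicas (all differences zero)
#'   yield 0 with attribute `degenerate = TRUE`, since sd/mean is 0/0.
#' @export
coefficient_of_variation <- function(a, b = NULL) {
  if (is.null(b)) {
    a <- as.matrix(a)
    stopifnot(ncol(a) == 2)
    b <- a[, 2]; a <- a[, 1]
  }
  if (length(a) != length(b) || length(a) < 2)
    stop("need at least 2 paired replicas", call. = FALSE)
  d <- abs(a - b)
  if (mean(d) == 0)
    return(structure(0, degenerate = TRUE))
  100 * stats::sd(d) / mean(d)
}

#' Normalized cycle-shape distance between two replicas
#'
#' Runs the two replica cycles jointly through transport and PCA, builds
#' each replica's trajectory from the first three PC scores, and returns
#' the Procrustes distance between the two trajectory shapes normalized by
#' its tangent-space maximum pi/2: 0 means identical cycle shapes, 1 the
#' maximal possible discrepancy.
#'
#' @param hcycle_a,hcycle_b `homologous_cycle` replicas of one subject.
#' @return Normalized distance in `[0, 1]`.
#' @export
replica_cycle_distance <- function(hcycle_a, hcycle_b) {
  ts <- linear_shift(list(hcycle_a, hcycle_b))
  p <- pca_shapes(ts, rank = 3)
  nt <- ts$n_times
  sc <- p$scores
  if (ncol(sc) < 3) sc <- cbind(sc, matrix(0, nrow(sc), 3 - ncol(sc)))
  ta <- sc[seq_len(nt), 1:3, drop = FALSE]
  tb <- sc[nt + seq_len(nt), 1:3, drop = FALSE]
  procrustes_distance(ta, tb) / (pi / 2)
}
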