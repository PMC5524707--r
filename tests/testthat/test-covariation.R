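test_that("two-block PLS basics: identity, symmetry, Frobenius conservation", {
  set.seed(80)
  A <- matrix(rnorm(16 * 30), 16, 30)
  p_same <- two_block_pls(A, A)
  expect_equal(p_same$r_pls, 1, tolerance = 1e-10)
  expect_equal(p_same$singular_vectors_A[, 1], p_same$singular_vectors_B[, 1],
               tolerance = 1e-8)
  B <- matrix(rnorm(16 * 20), 16, 20)
  p1 <- two_block_pls(A, B)
  p2 <- two_block_pls(B, A)
  expect_equal(p1$singular_values, p2$singular_values, tolerance = 1e-10)
  # squared singular values sum to the squared cross-covariance norm
  Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
  C <- crossprod(Ac, Bc) / (nrow(A) - 1)
  expect_equal(sum(p1$singular_values^2), sum(C^2), tolerance = 1e-10)
  # paired-score covariances reproduce the singular values
  for (j in 1:3)
    expect_equal(cov(p1$scores_A[, j], p1$scores_B[, j]),
                 p1$singular_values[j], tolerance = 1e-10)
  expect_error(two_block_pls(A[1:2, ], B[1:2, ]), "at least 3")
  expect_error(two_block_pls(A, matrix(1, 16, 4)), "zero-variance")
})

test_that("PLS recovers a planted rank-1 response", {
  set.seed(81)
  A <- matrix(rnorm(40 * 25), 40, 25)
  t1 <- prcomp(A)$x[, 1]
  w <- rnorm(12); w <- w / sqrt(sum(w^2))
  B <- outer(t1, w)
  p <- two_block_pls(A, B)
  expect_equal(abs(sum(p$singular_vectors_B[, 1] * w)), 1, tolerance = 1e-8)
  expect_equal(abs(cor(p$scores_A[, 1], t1)), 1, tolerance = 1e-8)
  expect_gte(p$pct_covariance, 0.9)
})

test_that("PLS effect size: signal, whole-block scale invariance", {
  set.seed(82)
  A <- matrix(rnorm(16 * 40), 16, 40)
  B <- A + matrix(rnorm(16 * 40, sd = 0.1), 16, 40)
  z <- pls_effect_size(A, B, n_perm = 199, seed = 5)
  expect_gt(z, 3)
  z2 <- pls_effect_size(10 * A, 0.1 * B, n_perm = 199, seed = 5)
  expect_equal(z, z2, tolerance = 1e-10)
  # reproducibility under a fixed seed
  expect_identical(z, pls_effect_size(A, B, n_perm = 199, seed = 5))
})

test_that("major axis slope: line fits, eigen oracle, reciprocity", {
  expect_equal(major_axis_slope(0:2, 0:2), 1)
  # sample with exact covariance [[2,1],[1,1]]
  set.seed(83)
  Z <- matrix(rnorm(40), 20, 2)
  Z <- scale(Z, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))
  X <- Z %*% chol(rbind(c(2, 1), c(1, 1)))
  expect_equal(cov(X), rbind(c(2, 1), c(1, 1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(major_axis_slope(X[, 1], X[, 2]), (sqrt(5) - 1) / 2,
               tolerance = 1e-10)
  # eigen-decomposition oracle
  ev <- eigen(cov(X))$vectors[, 1]
  expect_equal(major_axis_slope(X[, 1], X[, 2]), ev[2] / ev[1],
               tolerance = 1e-10)
  # slope(x, y) * slope(y, x) = 1
  x <- rnorm(25); y <- 0.7 * x + rnorm(25, sd = 0.3)
  expect_equal(major_axis_slope(x, y) * major_axis_slope(y, x), 1,
               tolerance = 1e-10)
  # isotropic cloud: equal variances, zero covariance
  expect_error(major_axis_slope(c(1, -1, 1, -1), c(1, 1, -1, -1)),
               "indeterminate")
  expect_error(major_axis_slope(rep(0, 5), rep(0, 5)), "zero total variance")
})

# build a transported_set with planted per-chamber score sequences
fake_transported <- function(lv_scores, la_scores, kc = 10, seed = 1,
                             noise = 0) {
  set.seed(seed)
  k <- 2 * kc
  u <- rnorm(3 * kc); u <- u / sqrt(sum(u^2))
  v <- rnorm(3 * kc); v <- v / sqrt(sum(v^2))
  chamber <- factor(rep(c("LV", "LA"), each = kc), levels = c("LV", "LA"))
  lv_cols <- lhmorph:::.chamber_cols(chamber, k, "LV")
  la_cols <- lhmorph:::.chamber_cols(chamber, k, "LA")
  R <- matrix(rnorm(16 * 3 * k, sd = noise), 16, 3 * k)
  R[, lv_cols] <- R[, lv_cols] + outer(lv_scores, u)
  R[, la_cols] <- R[, la_cols] + outer(la_scores, v)
  R <- sweep(R, 2, colMeans(R))
  structure(list(ct = matrix(rnorm(3 * k), k, 3), lt = NULL,
                 residuals = R, subject_ids = "s1", groups = "Control",
                 chamber = chamber, k = k, n_times = 16),
            class = "transported_set")
}

test_that("individual covariation: isometry line and order invariance", {
  a <- sin(2 * pi * (0:15) / 16)
  ts <- fake_transported(a, a, seed = 7)
  ic <- individual_covariation(ts, 1, n_perm = 0)
  expect_equal(ic$ma_slope, 1, tolerance = 1e-8)
  expect_equal(ic$r_pls, 1, tolerance = 1e-8)
  # joint time permutation leaves slope and r untouched
  perm <- sample(16)
  ts2 <- ts
  ts2$residuals <- ts$residuals[perm, ]
  ic2 <- individual_covariation(ts2, 1, n_perm = 0)
  expect_equal(ic2$ma_slope, ic$ma_slope, tolerance = 1e-10)
  expect_equal(ic2$r_pls, ic$r_pls, tolerance = 1e-10)
})

test_that("cohort covariation recovers planted LA:LV rates", {
  ts <- small_transported()
  tab <- cohort_covariation(ts, n_perm = 0)
  m <- tapply(tab$ma_slope, tab$group, mean)
  expect_equal(m[["Control"]], 1.25, tolerance = 0.08)
  expect_equal(m[["HCM"]], 0.89, tolerance = 0.08)
})

test_that("trajectory covariation: identical chambers give slope 1,
           null cohorts stay non-significant", {
  set.seed(85)
  th <- 2 * pi * (0:15) / 16
  mk_traj <- function(e, noise = 0.05)
    build_trajectory(cbind(cos(th), e * sin(th), 0.3 * sin(2 * th)) +
                       matrix(rnorm(48, sd = noise), 16, 3))
  n <- 20
  groups <- rep(c("Control", "HCM"), each = n / 2)
  lv <- lapply(1:n, function(i) mk_traj(runif(1, 0.4, 0.9)))
  tc <- trajectory_covariation(lv, lv, groups, n_perm = 49, n_perm_z = 199,
                               seed = 6)
  expect_equal(unname(tc$ma_slope), c(1, 1), tolerance = 1e-6)
  expect_gt(min(tc$z), 3)

  # both groups from one covariation model: slope difference rarely
  # significant
  sig <- 0L
  for (r in 1:8) {
    set.seed(500 + r)
    lv2 <- lapply(1:n, function(i) mk_traj(runif(1, 0.4, 0.9)))
    la2 <- lapply(1:n, function(i) mk_traj(runif(1, 0.4, 0.9)))
    tcr <- trajectory_covariation(lv2, la2, groups, n_perm = 49,
                                  n_perm_z = 19, seed = r)
    if (tcr$p_slope_diff <= 0.05) sig <- sig + 1L
  }
  expect_lte(sig, 1)
})
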