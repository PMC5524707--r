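test_that("centroid size: direct value, homogeneity, normalization", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroid_size(sq), sqrt(8))
  x <- rand_config(17, seed = 3)
  expect_equal(centroid_size(3 * x), 3 * centroid_size(x))
  ch <- generate_lh_surface(small_params())
  lv <- ch$coords[ch$chamber == "LV", ]
  expect_equal(centroid_size(lv / centroid_size(lv)), 1)
  expect_error(centroid_size(matrix(1, 5, 3)), "degenerate")
})

test_that("OPA recovers known rigid and similarity transforms", {
  x <- rand_config(12, seed = 7)
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)) # 90 deg about z
  fit <- opa_align(x %*% R, x)
  expect_lt(fit$residual, 1e-10)
  expect_equal(fit$rotation, t(R), tolerance = 1e-10)
  fit2 <- opa_align(2 * x, x, scale = TRUE)
  expect_equal(fit2$scale, 0.5)
  expect_lt(fit2$residual, 1e-10)
  expect_error(opa_align(x, rand_config(5)), "same landmark dimensions")
})

test_that("OPA rotation is optimal against a dense rotation grid", {
  set.seed(11)
  a <- rand_config(10)
  b <- rand_config(10)
  fit <- opa_align(a, b)
  # brute force: Euler-angle grid over SO(3)
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  ang2 <- seq(0, pi, length.out = 13)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  best <- Inf
  for (p1 in ang) for (p2 in ang2) for (p3 in ang) {
    cz <- cos(p1); sz <- sin(p1); cy <- cos(p2); sy <- sin(p2)
    cx <- cos(p3); sx <- sin(p3)
    R <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    best <- min(best, sum((ac %*% R - bc)^2))
  }
  expect_lte(fit$residual^2, best + 1e-12)
  # grid should come close to the analytic optimum
  expect_lt(best - fit$residual^2, 0.05 * fit$residual^2 + 1e-8)
})

test_that("GPA aligns rotated/translated copies exactly", {
  x <- rand_config(9, seed = 5)
  copies <- array(0, dim = c(9, 3, 4))
  for (i in 1:4) {
    copies[, , i] <- x %*% rand_rotation(seed = i) +
      matrix(rnorm(3), 9, 3, byrow = TRUE)
  }
  fit <- gpa(copies, space = "shape")
  for (i in 2:4)
    expect_equal(fit$aligned[, , i], fit$aligned[, , 1], tolerance = 1e-7)
  expect_lt(procrustes_distance(fit$consensus, x), 1e-7)
})

test_that("GPA consensus is a Procrustes mean", {
  # two shapes: consensus equidistant from both
  a <- rand_config(8, seed = 21)
  b <- rand_config(8, seed = 22)
  fit <- gpa(simplify2array(list(a, b)), space = "shape")
  expect_equal(procrustes_distance(fit$consensus, a),
               procrustes_distance(fit$consensus, b), tolerance = 1e-6)
  # five shapes: summed squared residuals to the consensus beat alignment
  # onto any single configuration (pairwise OPA oracle)
  set.seed(30)
  A <- array(rnorm(8 * 3 * 5), dim = c(8, 3, 5))
  fit5 <- gpa(A, space = "shape")
  ss_cons <- sum((fit5$aligned -
                  array(fit5$consensus, dim = dim(fit5$aligned)))^2)
  for (j in 1:5) {
    tgt <- fit5$aligned[, , j]
    ss_j <- sum(vapply(1:5, function(i)
      opa_align(fit5$aligned[, , i], tgt)$residual^2, 0))
    expect_lte(ss_cons, ss_j + 1e-10)
  }
})

test_that("GPA respects its space: unit CS in shape space, sizes kept in SSS", {
  set.seed(40)
  A <- array(rnorm(10 * 3 * 4), dim = c(10, 3, 4))
  fs <- gpa(A, space = "shape")
  for (i in 1:4)
    expect_equal(centroid_size(fs$aligned[, , i]), 1, tolerance = 1e-10)
  fss <- gpa(A, space = "size_and_shape")
  for (i in 1:4)
    expect_equal(centroid_size(fss$aligned[, , i]),
                 centroid_size(A[, , i]), tolerance = 1e-10)
})

test_that("GPA consensus shape does not depend on input order", {
  set.seed(41)
  A <- array(rnorm(7 * 3 * 5), dim = c(7, 3, 5))
  c1 <- gpa(A, space = "shape")$consensus
  c2 <- gpa(A[, , 5:1], space = "shape")$consensus
  expect_lt(procrustes_distance(c1, c2), 1e-8)
})

test_that("Procrustes distance: similarity invariance and the pi/2 maximum", {
  x <- rand_config(14, seed = 8)
  y <- 2.5 * x %*% rand_rotation(seed = 9) + matrix(c(1, 2, 3), 14, 3,
                                                    byrow = TRUE)
  expect_lt(procrustes_distance(x, y), 1e-8)
  mir <- equilateral %*% diag(c(-1, 1))
  expect_equal(procrustes_distance(equilateral, mir), pi / 2,
               tolerance = 1e-9)
})

test_that("Procrustes distance matches tangent norm to first order", {
  set.seed(12)
  tri <- preshape(cbind(rand_config(3, m = 2), 0))
  v <- motion_field(tri, seed = 2)
  v <- (v - sum(v * tri) * tri)
  v <- v / sqrt(sum(v^2))
  eps <- 1e-4
  d <- procrustes_distance(tri, tri + eps * v)
  expect_equal(d, eps, tolerance = 1e-3)
})

test_that("Procrustes distance is a metric bounded by pi/2", {
  set.seed(13)
  for (rep in 1:10) {
    a <- rand_config(6); b <- rand_config(6); c <- rand_config(6)
    dab <- procrustes_distance(a, b)
    dba <- procrustes_distance(b, a)
    expect_equal(dab, dba, tolerance = 1e-8)
    expect_lte(dab, pi / 2 + 1e-12)
    expect_lte(dab, procrustes_distance(a, c) + procrustes_distance(c, b)
               + 1e-10)
  }
})

test_that("tangent projection and unprojection are inverse at the pole", {
  pole <- rand_config(11, seed = 14)
  expect_equal(max(abs(tangent_project(pole, pole))), 0, tolerance = 1e-12)
  # round trip on a perturbed pole
  x <- preshape(pole) + 0.05 * motion_field(preshape(pole), seed = 15)
  fit <- opa_align(preshape(x), preshape(pole))
  v <- tangent_project(fit$aligned, pole)
  back <- tangent_unproject(v, pole)
  expect_equal(back, preshape(fit$aligned), tolerance = 1e-8)
  # norm of the projection approximates the Procrustes distance
  expect_equal(sqrt(sum(v^2)), procrustes_distance(x, pole),
               tolerance = 1e-3)
})
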