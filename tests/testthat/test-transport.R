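# helper: wrap a k x 3 x 16 array as a homologous_cycle
as_hcycle <- function(shapes, id = "s1", group = "Control", chamber = NULL) {
  lhmorph:::new_homologous_cycle(shapes, seq(0, 750, by = 50), id, group,
                                 chamber)
}

# a smooth 16-step deformation sequence around X along field V
def_cycle <- function(X, V, amp, id = "s", phase = 0) {
  a <- amp * sin(2 * pi * (seq_len(16) - 1) / 16 + phase)
  as_hcycle(simplify2array(lapply(a, function(ai) X + ai * V)), id = id)
}

test_that("local template is the mean shape of the cycle", {
  X <- rand_config(12, seed = 60)
  still <- as_hcycle(array(X, dim = c(12, 3, 16)))
  lt <- local_template(still)
  expect_lt(procrustes_distance(lt, X), 1e-8)
  # two-state alternation: template equidistant from the two states
  V <- motion_field(X, seed = 61)
  Y1 <- X + 0.05 * centroid_size(X) * V
  Y2 <- X - 0.05 * centroid_size(X) * V
  alt <- as_hcycle(simplify2array(rep(list(Y1, Y2), 8)))
  lt2 <- local_template(alt)
  expect_equal(procrustes_distance(lt2, Y1), procrustes_distance(lt2, Y2),
               tolerance = 1e-6)
  # direct-averaging oracle: consensus equals the renormalized mean of the
  # GPA-aligned shapes
  hc <- def_cycle(X, V, 0.04 * centroid_size(X))
  g <- gpa(hc$shapes, space = "shape")
  avg <- apply(g$aligned, c(1, 2), mean)
  avg <- avg / centroid_size(avg)
  expect_equal(local_template(hc), avg, tolerance = 1e-7)
})

test_that("transported cycles are centred on the common template", {
  ts <- small_transported()
  n <- length(ts$subject_ids)
  for (i in seq_len(n)) {
    rows <- (i - 1) * 16 + 1:16
    expect_lt(max(abs(colMeans(ts$residuals[rows, ]))), 1e-8)
  }
  # grand mean of all transported shapes is the CT
  grand <- ts$ct + matrix(colMeans(ts$residuals), ts$k, 3)
  expect_equal(grand, ts$ct, tolerance = 1e-6)
})

test_that("transport filters out baseline shape differences", {
  X <- rand_config(15, seed = 62)
  cs <- centroid_size(X)
  V <- motion_field(X, seed = 63)
  W <- motion_field(X, seed = 64)  # baseline offset, rigid-motion-free
  W <- W - sum(W * V) * V
  # the baseline leak into the residuals is bilinear in offset x amplitude
  amp <- 1e-3 * cs
  h1 <- def_cycle(X, V, amp, "a")
  h2 <- def_cycle(X + 5e-4 * cs * W, V, amp, "b")
  ts <- linear_shift(list(h1, h2), tol = 1e-11)
  r1 <- ts$residuals[1:16, ]
  r2 <- ts$residuals[17:32, ]
  expect_lt(sqrt(sum((r1 - r2)^2)), 1e-6)
})

test_that("a subject whose local template equals the CT is untouched", {
  X <- rand_config(13, seed = 65)
  V <- motion_field(X, seed = 66)
  amp <- 0.02 * centroid_size(X)
  # two subjects with identical shape sequences: LT = CT for both
  h1 <- def_cycle(X, V, amp, "a")
  h2 <- def_cycle(X, V, amp, "b")
  ts <- linear_shift(list(h1, h2))
  expect_equal(ts$residuals[1:16, ], ts$residuals[17:32, ],
               tolerance = 1e-9)
  # the transported shapes reproduce the subject's own aligned shapes
  tr <- transported_shapes(ts, "a")
  g <- gpa(h1$shapes, space = "shape")
  for (t in seq_len(16))
    expect_lt(procrustes_distance(tr[, , t], g$aligned[, , t]), 5e-3)
})

test_that("linear shift matches the direct re-centring oracle on small
           deformations", {
  # the tangent-plane arithmetic agrees with plain re-centring to first
  # order, so the match tightens linearly as deformations shrink
  set.seed(67)
  X <- rand_config(15)
  cs <- centroid_size(X)
  hcycles <- lapply(1:10, function(i) {
    Xi <- X + 5e-5 * cs * motion_field(X, seed = 200 + i)
    def_cycle(Xi, motion_field(Xi, seed = 300 + i), 1e-4 * cs,
              id = paste0("s", i), phase = i / 3)
  })
  ts <- linear_shift(hcycles, tol = 1e-11)
  for (i in 1:10) {
    g <- gpa(hcycles[[i]]$shapes, space = "shape", tol = 1e-11)
    rot <- lhmorph:::.opt_rotation(g$consensus, ts$ct)$rotation
    mean_shape <- apply(g$aligned, c(1, 2), mean)
    oracle <- t(vapply(1:16, function(t)
      as.vector((g$aligned[, , t] - mean_shape) %*% rot),
      numeric(3 * 15)))
    got <- ts$residuals[(i - 1) * 16 + 1:16, ]
    expect_lt(sqrt(sum((got - oracle)^2)) / sqrt(sum(oracle^2)), 1e-4)
  }
})

test_that("transport is idempotent when cycles already sit at the CT", {
  # idempotence holds to linearization order, so use small deformations
  X <- rand_config(14, seed = 68)
  cs <- centroid_size(X)
  hc1 <- lapply(1:4, function(i) {
    Xi <- X + 5e-4 * cs * motion_field(X, seed = 700 + i)
    def_cycle(Xi, motion_field(Xi, seed = 800 + i), 1e-3 * cs,
              id = paste0("s", i), phase = i)
  })
  ts <- linear_shift(hc1, tol = 1e-11)
  hc2 <- lapply(seq_along(ts$subject_ids), function(i)
    as_hcycle(transported_shapes(ts, i), id = ts$subject_ids[i]))
  ts2 <- linear_shift(hc2, tol = 1e-11)
  expect_lt(procrustes_distance(ts2$ct, ts$ct), 1e-5)
  rot <- lhmorph:::.opt_rotation(ts$ct, ts2$ct)$rotation
  for (i in c(1, 4)) {
    rows <- (i - 1) * 16 + 1:16
    # rotate the old residuals into the new CT frame before comparing
    a_rot <- t(vapply(seq_len(16), function(t)
      as.vector(matrix(ts$residuals[rows[t], ], ts$k, 3) %*% rot),
      numeric(3 * ts$k)))
    b <- ts2$residuals[rows, ]
    expect_lt(sqrt(sum((a_rot - b)^2)) / sqrt(sum(a_rot^2)), 1e-3)
  }
})

test_that("deformation norms survive the shift (tangent-plane isometry)", {
  ts <- small_transported()
  for (i in seq_along(ts$subject_ids)) {
    rows <- (i - 1) * 16 + 1:16
    norms <- sqrt(rowSums(ts$residuals[rows, ]^2))
    # norms of the centred tangent projections, recomputed independently
    tr <- transported_shapes(ts, i)
    back <- t(vapply(1:16, function(t) as.vector(tr[, , t] - ts$ct),
                     numeric(3 * ts$k)))
    expect_equal(sqrt(rowSums(back^2)), norms, tolerance = 1e-10)
  }
  expect_error(linear_shift(list()), "at least 2")
})
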