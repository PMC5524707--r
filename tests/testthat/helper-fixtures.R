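# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# cheap generator settings: same structure as the full 36 x 36 chambers
small_params <- function(...) {
  lh_params(n_circles = 8L, n_per_circle = 8L, ...)
}

# a random non-degenerate 3D configuration
rand_config <- function(k, m = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(k * m), k, m)
}

# random rotation matrix in SO(m)
rand_rotation <- function(m = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(m * m), m, m))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# displacement field orthogonal to translations and infinitesimal rotations
# of X (so Procrustes superimposition leaves it intact to first order)
motion_field <- function(X, seed = 1) {
  set.seed(seed)
  V <- matrix(stats::rnorm(length(X)), nrow(X), ncol(X))
  V <- sweep(V, 2, colMeans(V))
  Xc <- sweep(X, 2, colMeans(X))
  # rotation generators: e_a x x
  gens <- lapply(1:3, function(a) {
    e <- diag(3)[a, ]
    t(apply(Xc, 1, function(p) c(e[2] * p[3] - e[3] * p[2],
                                 e[3] * p[1] - e[1] * p[3],
                                 e[1] * p[2] - e[2] * p[1])))
  })
  for (g in gens) V <- V - sum(V * g) / sum(g * g) * g
  V / sqrt(sum(V^2))
}

# shared 6-subject transported cohort (slope 1.25 planted), reduced scale
small_transported <- function() {
  cached("small_transported", function() {
    co <- generate_cohort(n_control = 3, n_hcm = 3,
                          control_params = small_params(),
                          hcm_params = small_params(lv_amplitude = 0.06,
                                                    covariation_slope = 0.89),
                          seed = 101)
    linear_shift(lapply(co$cycles, interpolate_cycle))
  })
}

# equilateral triangle in the plane (labelled)
equilateral <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
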