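diatomic_setup <- function(seed = 71) {
  set.seed(seed)
  pes <- make_surrogate(c("H", "H"), "pairwise", seed = seed)
  D <- pes$params$D; alpha <- pes$params$alpha; r0 <- pes$params$r0
  ref <- geometry(rbind(c(0, 0, 0), c(0, 0, r0 * 1.05)), c("H", "H"))
  ds <- sample_dataset(pes, ref, n = 60, sigma = 0.05, cutoff = 8000,
                       seed = seed)
  fit <- pip_fit(ds, generate_basis(fragment_spec(1:2, 2), 8))
  list(pes = pes, D = D, alpha = alpha, r0 = r0, ref = ref, fit = fit)
}

test_that("diatomic pair-Morse closed forms: minimum, force constant, wavenumber", {
  s <- diatomic_setup(71)
  gmin <- minimize_geometry(s$fit, s$ref, tol = 1e-8)
  expect_equal(pair_distances(gmin), s$r0, tolerance = 1e-6)
  # idempotence: restarting at the minimum returns the same point
  gmin2 <- minimize_geometry(s$fit, gmin, tol = 1e-8)
  expect_equal(gmin2$coords, gmin$coords, tolerance = 1e-8)
  # bond-stretch force constant 2 D alpha^2
  H <- pes_hessian(s$fit, gmin)
  u <- (gmin$coords[2, ] - gmin$coords[1, ]) / pair_distances(gmin)
  d6 <- c(-u, u)
  k_fit <- as.numeric(t(d6) %*% H %*% d6) / 4   # dr/dt = 2 along d6
  expect_equal(k_fit, 2 * s$D * s$alpha^2, tolerance = 1e-3)
  # harmonic wavenumber: (alpha / 2 pi c) sqrt(2 D / mu), via SI conversion
  mass <- 1.008
  freqs <- harmonic_frequencies(H, c(mass, mass))
  nu_fit <- max(freqs)
  h_si <- 6.62607015e-34; c_cm <- 2.99792458e10
  a0 <- 5.29177210903e-11; amu <- 1.66053906660e-27
  k_si <- 2 * s$D * s$alpha^2 * (h_si * c_cm) / a0^2   # J/m^2
  nu_closed <- sqrt(k_si / (mass / 2 * amu)) / (2 * pi * c_cm)
  expect_equal(nu_fit, nu_closed, tolerance = 0.1 / nu_closed)
})

test_that("Hessian is symmetric with near-zero invariance modes", {
  set.seed(72)
  sys <- toy_system("a3bc")
  pes <- make_surrogate(sys$species, "pairwise", seed = 72,
                        reference = sys$geometry)
  ds <- sample_dataset(pes, sys$geometry, n = 150, sigma = 0.06,
                       cutoff = 10000, seed = 72)
  fit <- pip_fit(ds, generate_basis(sys$blocks, 3))
  gmin <- minimize_geometry(fit, sys$geometry, tol = 1e-7)
  H <- pes_hessian(fit, gmin)
  expect_lt(attr(H, "asymmetry"), 1e-4 * max(abs(H)))
  expect_equal(H, t(H))
  freqs <- harmonic_frequencies(H, sys$masses)
  # 6 near-zero modes at a nonlinear minimum
  expect_lt(max(abs(sort(abs(freqs))[1:6])), 5)
  # mass scaling: quadrupling all masses halves every frequency
  freqs4 <- harmonic_frequencies(H, 4 * sys$masses)
  expect_equal(freqs4, freqs / 2, tolerance = 1e-10)
})

test_that("minimization is consistent across perturbed starts and rotations", {
  set.seed(73)
  sys <- toy_system("a3bc")
  pes <- make_surrogate(sys$species, "pairwise", seed = 73,
                        reference = sys$geometry)
  ds <- sample_dataset(pes, sys$geometry, n = 150, sigma = 0.06,
                       cutoff = 10000, seed = 73)
  fit <- pip_fit(ds, generate_basis(sys$blocks, 3))
  e_ref <- attr(minimize_geometry(fit, sys$geometry, tol = 1e-7), "energy")
  for (rep in 1:10) {
    start <- geometry(sys$geometry$coords +
                        matrix(rnorm(15, sd = 0.04), ncol = 3),
                      sys$species)
    e <- attr(minimize_geometry(fit, start, tol = 1e-7), "energy")
    expect_equal(e, e_ref, tolerance = 1e-6 / max(1, abs(e_ref)))
  }
  # frequency invariance under rigid rotation + translation of the start
  h0 <- harmonic_analysis(fit, sys$geometry, sys$masses, tol = 1e-7)
  th <- 0.73
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- geometry(sys$geometry$coords %*% R +
                      matrix(rep(c(1.5, -0.7, 2.1), each = 5), ncol = 3),
                    sys$species)
  h1 <- harmonic_analysis(fit, moved, sys$masses, tol = 1e-7)
  expect_lt(max(abs(h1$frequencies - h0$frequencies)), 0.1)
})

test_that("frequency MAE is the plain mean absolute difference", {
  expect_equal(mae_frequencies(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae_frequencies(c(0, 2), c(1, 1)), 1)
  expect_error(mae_frequencies(1:3, 1:4), "equal length")
})

test_that("non-convergence raises a condition carrying the last iterate", {
  s <- diatomic_setup(74)
  err <- tryCatch(
    minimize_geometry(s$fit, s$ref, tol = 1e-30, max_restarts = 1L, maxit = 5L),
    pipfrag_no_convergence = function(e) e)
  expect_s3_class(err, "pipfrag_no_convergence")
  expect_s3_class(err$geometry, "pip_geometry")
})
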