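toy_fit_setup <- function(seed = 61, n = 120, order = 3) {
  set.seed(seed)
  sys <- toy_system("a3bc")
  pes <- make_surrogate(sys$species, "pairwise", seed = seed,
                        reference = sys$geometry)
  ds <- sample_dataset(pes, sys$geometry, n = n, sigma = 0.06,
                       cutoff = 10000, seed = seed)
  basis <- generate_basis(sys$blocks, order)
  list(sys = sys, pes = pes, ds = ds, basis = basis)
}

test_that("design matrix has the contracted shape and FD-consistent gradient rows", {
  set.seed(62)
  s <- toy_fit_setup(62, n = 10)
  dm <- design_matrix(s$ds, s$basis, gradient_weight = 1)
  expect_equal(nrow(dm$A), 10 + 10 * 15)      # N = 5: 3N = 15 rows per record
  expect_equal(ncol(dm$A), s$basis$n_pip)
  expect_equal(sum(dm$row_type == "energy"), 10)
  # zero gradient weight drops the gradient rows entirely
  dm0 <- design_matrix(s$ds, s$basis, gradient_weight = 0)
  expect_equal(nrow(dm0$A), 10)
  expect_true(all(dm0$row_type == "energy"))
  # gradient rows = FD of the energy-row entries w.r.t. coordinates
  g <- s$ds$records[[1]]$geometry
  h <- 1e-5
  par <- as.vector(t(g$coords))
  grad_rows <- dm$A[2:16, , drop = FALSE]
  for (c in c(1, 8, 15)) {
    pp <- par; pp[c] <- pp[c] + h
    pm <- par; pm[c] <- pm[c] - h
    fd <- (evaluate_basis(s$basis, morse_variables(geometry(pp, g$species))) -
           evaluate_basis(s$basis, morse_variables(geometry(pm, g$species)))) /
      (2 * h)
    expect_lt(max(abs(grad_rows[c, ] - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("fitting recovers an exact linear combination of the basis", {
  set.seed(63)
  s <- toy_fit_setup(63, n = 60, order = 2)
  truth <- make_surrogate(s$sys$species, "pip-combo", seed = 63,
                          basis = s$basis)
  ds <- sample_dataset(truth, s$sys$geometry, n = 60, sigma = 0.08,
                       cutoff = 1e7, seed = 63)
  fit <- pip_fit(ds, s$basis)
  expect_lt(fit$rmse, 1e-6)
  # predictions match the generator everywhere, not just at data
  for (rep in 1:5) {
    g <- random_geometry(s$sys$species)
    expect_equal(evaluate_potential(fit, g),
                 surrogate_energy(truth, g) - attr(ds, "min_energy"),
                 tolerance = 1e-6)
  }
})

test_that("duplicate-containing and deduplicated bases give identical predictions", {
  set.seed(64)
  # two overlapping fragments of the 6-atom toy (A atoms 1,2; B atoms 3,4)
  f1 <- fragment_spec(c(1, 2, 5, 6), c(2, 1, 1))
  f2 <- fragment_spec(c(3, 4, 5, 6), c(2, 1, 1))
  b1 <- generate_basis(f1, 2, 6); b2 <- generate_basis(f2, 2, 6)
  dedup <- merge_bases(list(b1, b2))
  concat <- dedup
  # concatenated basis: stack the two bases without removing duplicates
  concat$n_pip <- b1$n_pip + b2$n_pip
  concat$pip_degree <- c(b1$pip_degree, b2$pip_degree)
  concat$mono_vars <- rbind(b1$mono_vars, b2$mono_vars)
  concat$mono_pip <- c(b1$mono_pip, b2$mono_pip + b1$n_pip)
  concat$keys <- c(b1$keys, b2$keys)
  concat$rep_code <- c(b1$rep_code, b2$rep_code)
  concat$provenance <- c(b1$provenance, b2$provenance)
  expect_gt(concat$n_pip, dedup$n_pip)
  sys <- toy_system("a2b2cd")
  pes <- make_surrogate(sys$species, "pairwise", seed = 64,
                        reference = sys$geometry)
  ds <- sample_dataset(pes, sys$geometry, n = 80, sigma = 0.05,
                       cutoff = 1e6, seed = 64)
  fit_c <- pip_fit(ds, concat)
  fit_d <- pip_fit(ds, dedup)
  expect_equal(fit_c$rmse, fit_d$rmse, tolerance = 1e-8)
  for (r in seq(1, 80, by = 16)) {
    g <- ds$records[[r]]$geometry
    expect_lt(abs(evaluate_potential(fit_c, g) - evaluate_potential(fit_d, g)),
              1e-8)
  }
})

test_that("degenerate inputs behave per contract", {
  set.seed(65)
  s <- toy_fit_setup(65, n = 20, order = 2)
  # all-zero targets give all-zero coefficients and zero metrics
  ds0 <- s$ds
  ds0$records <- lapply(ds0$records, function(r) {
    r$energy <- 0; r$gradient <- numeric(15); r })
  fit0 <- pip_fit(ds0, s$basis)
  expect_equal(max(abs(coef(fit0))), 0)
  expect_equal(fit0$rmse, 0)
  expect_equal(fit0$rmsg, 0)
  # only the constant coefficient set: V = K everywhere
  fitK <- fit0
  fitK$coefficients[s$basis$pip_degree == 0] <- 42
  expect_equal(evaluate_potential(fitK, random_geometry(s$sys$species)), 42)
  expect_error(pip_fit(structure(list(records = list()), class = "pip_dataset"),
                       s$basis), "empty")
})

test_that("fitted surfaces are invariant under allowed permutations", {
  set.seed(66)
  s <- toy_fit_setup(66, n = 100)
  fit <- pip_fit(s$ds, s$basis)
  G <- build_group(s$sys$blocks, 5)
  for (rep in 1:4) {
    g <- random_geometry(s$sys$species)
    v <- evaluate_potential(fit, g)
    for (r in seq_len(nrow(G)))
      expect_lt(abs(evaluate_potential(fit, permute_geometry(g, G[r, ])) - v),
                1e-9 * max(1, abs(v)))
  }
})

test_that("analytic gradients: FD agreement, branching, translation invariance", {
  set.seed(67)
  s <- toy_fit_setup(67, n = 100)
  fit <- pip_fit(s$ds, s$basis)
  h <- 1e-5
  for (rep in 1:3) {
    g <- s$ds$records[[rep]]$geometry
    ga <- evaluate_gradient(fit, g)
    # FD oracle
    par <- as.vector(t(g$coords))
    fd <- vapply(seq_along(par), function(c) {
      pp <- par; pp[c] <- pp[c] + h
      pm <- par; pm[c] <- pm[c] - h
      (evaluate_potential(fit, geometry(pp, g$species)) -
         evaluate_potential(fit, geometry(pm, g$species))) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ga - fd)) / max(abs(fd)), 1e-6)
    # branched vs dense
    expect_lt(max(abs(ga - evaluate_gradient(fit, g, branch = FALSE))), 1e-12 * max(abs(ga)))
    # translation invariance: per-component sums vanish
    sums <- colSums(matrix(ga, ncol = 3, byrow = TRUE))
    expect_lt(max(abs(sums)), 1e-8 * max(1, max(abs(ga))))
  }
})

test_that("RMS metrics follow their definitions and nesting is monotone", {
  set.seed(68)
  s <- toy_fit_setup(68, n = 80, order = 3)
  fit <- pip_fit(s$ds, s$basis)
  m <- rms_metrics(fit, s$ds)
  expect_equal(unname(m["rmse"]), fit$rmse)
  expect_equal(unname(m["rmsg"]), fit$rmsg)
  # residuals {+1,-1} -> RMSE 1
  ds2 <- s$ds
  ds2$records <- ds2$records[1:2]
  ds2$records[[1]]$energy <- evaluate_potential(fit, ds2$records[[1]]$geometry) + 1
  ds2$records[[2]]$energy <- evaluate_potential(fit, ds2$records[[2]]$geometry) - 1
  expect_equal(unname(rms_metrics(fit, ds2)["rmse"]), 1)
  # no gradients: RMSG absent
  dsg <- s$ds
  dsg$records <- lapply(dsg$records, function(r) { r$gradient <- NULL; r })
  expect_true(is.na(rms_metrics(fit, dsg)["rmsg"]))
  # enlarging the basis never worsens training RMSE
  fits <- lapply(1:3, function(d)
    pip_fit(s$ds, generate_basis(s$sys$blocks, d)))
  rmses <- vapply(fits, function(f) f$rmse, numeric(1))
  expect_true(all(diff(rmses) <= 1e-8))
})
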