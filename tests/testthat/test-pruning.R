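pruning_setup <- function(seed = 81) {
  set.seed(seed)
  sys <- toy_system("a2b2cd")
  pes <- make_surrogate(sys$species, "pairwise", seed = seed,
                        reference = sys$geometry)
  ds <- sample_dataset(pes, sys$geometry, n = 120, sigma = 0.05,
                       cutoff = 12000, seed = seed)
  basis <- generate_basis(sys$blocks, 2)
  list(sys = sys, ds = ds, basis = basis)
}

test_that("Morse maxima are elementwise maxima over records", {
  s <- pruning_setup(81)
  mx <- max_morse_values(s$ds, s$basis)
  expect_equal(as.integer(names(mx)), s$basis$vars_used)
  expect_true(all(mx > 0 & mx <= 1))
  # brute-force oracle
  brute <- do.call(pmax, lapply(s$ds$records, function(r)
    morse_variables(r$geometry)))
  expect_equal(unname(mx), brute[s$basis$vars_used])
  # monotone as records are appended
  half <- s$ds; half$records <- half$records[1:60]
  expect_true(all(max_morse_values(half, s$basis) <= mx))
  # single-geometry dataset: exactly that geometry's Morse values
  one <- s$ds; one$records <- one$records[1]
  expect_equal(unname(max_morse_values(one, s$basis)),
               morse_variables(one$records[[1]]$geometry)[s$basis$vars_used])
})

test_that("pruning removes the lowest-scoring polynomials, never the constant", {
  # single variable, basis {1, x, x^2, x^3} at maximum 0.5:
  # scores (0.5, 0.25, 0.125); removing one drops x^3
  b <- generate_basis(fragment_spec(1:2), 3)
  mx <- c("1" = 0.5)
  pruned <- prune_basis(b, mx, 1)
  expect_equal(pruned$n_pip, 3)
  expect_equal(pruned$pip_degree, 0:2)
  # strict subset, size decreases by exactly k
  s <- pruning_setup(82)
  mx2 <- max_morse_values(s$ds, s$basis)
  p5 <- prune_basis(s$basis, mx2, 5)
  expect_equal(p5$n_pip, s$basis$n_pip - 5)
  expect_true(all(p5$keys %in% s$basis$keys))
  expect_equal(sum(p5$pip_degree == 0), 1)
  expect_error(prune_basis(s$basis, mx2, s$basis$n_pip), "k_remove")
  # refit after pruning: training RMSE cannot improve (nested LSQ)
  fit_full <- pip_fit(s$ds, s$basis)
  fit_pruned <- pip_fit(s$ds, p5)
  expect_gte(fit_pruned$rmse + 1e-9, fit_full$rmse)
})

test_that("extension adds the highest-scoring novel products", {
  # degree <= 1 basis on one variable extended to degree 2 adds x^2
  b <- generate_basis(fragment_spec(1:2), 1)
  ext <- extend_basis(b, c("1" = 0.5), 2, 1)
  expect_equal(ext$n_pip, 3)
  expect_equal(ext$pip_degree, 0:2)
  # never introduces an orbit key already present
  s <- pruning_setup(83)
  mx <- max_morse_values(s$ds, s$basis)
  ext2 <- extend_basis(s$basis, mx, 3, 10)
  expect_equal(ext2$n_pip, s$basis$n_pip + 10)
  expect_equal(anyDuplicated(ext2$keys), 0)
  expect_true(all(s$basis$keys %in% ext2$keys))
  # extend then fit: RMSE cannot worsen
  fit0 <- pip_fit(s$ds, s$basis)
  fit1 <- pip_fit(s$ds, ext2)
  expect_lte(fit1$rmse, fit0$rmse + 1e-9)
})

test_that("prune and extend preserve permutational invariance", {
  s <- pruning_setup(84)
  mx <- max_morse_values(s$ds, s$basis)
  G <- build_group(s$sys$blocks, 6)
  for (b in list(prune_basis(s$basis, mx, 6),
                 extend_basis(s$basis, mx, 3, 8))) {
    for (rep in 1:3) {
      g <- random_geometry(s$sys$species)
      v <- evaluate_basis(b, morse_variables(g))
      for (r in seq_len(nrow(G))) {
        vp <- evaluate_basis(b, morse_variables(permute_geometry(g, G[r, ])))
        expect_lt(max(abs(vp - v)), 1e-10 * max(1, max(abs(v))))
      }
    }
  }
})

test_that("prune/extend are deterministic with the stated tie-breaks", {
  s <- pruning_setup(85)
  mx <- max_morse_values(s$ds, s$basis)
  expect_identical(prune_basis(s$basis, mx, 4)$keys,
                   prune_basis(s$basis, mx, 4)$keys)
  expect_identical(extend_basis(s$basis, mx, 3, 6)$keys,
                   extend_basis(s$basis, mx, 3, 6)$keys)
})
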