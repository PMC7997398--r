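test_that("group order is the product of block factorials", {
  expect_equal(nrow(build_group(fragment_spec(1:9, c(3, 1, 1, 1, 1, 1, 1)))), 6)
  expect_equal(nrow(build_group(nma_full_spec())), 36)
  expect_equal(nrow(build_group(glycine_full_spec())), 8)
  # closure and identity
  G <- build_group(fragment_spec(1:4, c(2, 2)))
  expect_equal(nrow(G), 4)
  expect_true(any(apply(G, 1, function(p) all(p == 1:4))))
  comps <- apply(G, 1, function(g) apply(G, 1, function(h) paste(g[h], collapse = ",")))
  expect_true(all(comps %in% apply(G, 1, paste, collapse = ",")))
})

test_that("induced pair action follows (i,j) -> (p(i), p(j))", {
  expect_equal(induced_pair_action(1:5), 1:10)   # identity
  # N = 4, swap atoms 1,2: derive expected action by exhaustive enumeration
  perm <- c(2, 1, 3, 4)
  p <- pair_order(4)
  expected <- vapply(seq_len(6), function(l)
    pair_index(perm[p[l, 1]], perm[p[l, 2]], 4), integer(1))
  act <- induced_pair_action(perm)
  expect_equal(act, expected)
  expect_equal(act[pair_index(1, 2, 4)], pair_index(1, 2, 4))  # fixed
  expect_equal(act[pair_index(3, 4, 4)], pair_index(3, 4, 4))  # fixed
  expect_equal(act[pair_index(1, 3, 4)], pair_index(2, 3, 4))  # swapped
  expect_equal(act[pair_index(1, 4, 4)], pair_index(2, 4, 4))
  expect_error(induced_pair_action(c(1, 1, 2)), "bijection")
})

test_that("induced action is a degree-preserving homomorphism", {
  set.seed(21)
  G <- build_group(fragment_spec(1:7, c(3, 2, 1, 1)))
  for (rep in 1:20) {
    g <- G[sample(nrow(G), 1), ]
    h <- G[sample(nrow(G), 1), ]
    ag <- induced_pair_action(g); ah <- induced_pair_action(h)
    expect_equal(induced_pair_action(g[h]), ag[ah])
  }
})

test_that("fragmentation validation applies the appear-together rule", {
  # two-methyl parent symmetry against the 12-atom two-fragment scheme: PASS
  parent <- fragment_spec(c(1, 2, 3, 10, 11, 12), c(3, 3))
  expect_true(validate_fragmentation(parent, nma_fragments_2())$pass)
  expect_true(validate_fragmentation(parent, nma_fragments_3())$pass)
  # glycine three-fragment scheme: PASS under its parent blocks
  gparent <- fragment_spec(c(2, 3, 5, 6, 8, 9), c(2, 2, 2))
  expect_true(validate_fragmentation(gparent, glycine_fragments())$pass)
  # a fragment with atom A and only one of two permuting B atoms: violation
  p2 <- fragment_spec(c(2, 3), c(2))
  bad <- fragment_spec(c(1, 2))          # contains only B atom 2
  rep <- validate_fragmentation(p2, list(bad))
  expect_false(rep$pass)
  expect_equal(nrow(rep$violations), 1)
  expect_match(rep$violations$detail, "missing")
})

test_that("consistent parent blocks are the coarsest fragment-compatible partition", {
  cp <- consistent_parent_blocks(nma_fragments_2(), 12)
  key <- lapply(cp$atom_blocks, sort)
  expect_true(any(vapply(key, identical, logical(1), c(1L, 2L, 3L))))
  expect_true(any(vapply(key, identical, logical(1), c(10L, 11L, 12L))))
  # atoms 4..9 all singletons (they appear in both fragments, distinct blocks)
  expect_equal(sort(lengths(cp$atom_blocks)), c(rep(1L, 6), 3L, 3L))
})

test_that("Burnside counting matches closed forms", {
  # trivial group: all monomials, C(n_vars + d, d)
  expect_equal(burnside_count(fragment_spec(1:4), 3), choose(6 + 3, 3))
  expect_equal(burnside_count(fragment_spec(1:5), 2), choose(10 + 2, 2))
  # constant exclusion removes exactly one orbit
  sp <- fragment_spec(1:4, c(2, 2))
  expect_equal(burnside_count(sp, 3) - burnside_count(sp, 3, include_constant = FALSE), 1)
  # two fully permuting atoms: single variable, d + 1 polynomials
  expect_equal(burnside_count(fragment_spec(1:2, 2), 5), 6)
})
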