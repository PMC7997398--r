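#' Per-variable maxima of the Morse variables over a dataset
#'
#' The scoring vector for pruning and extension: for each retained pair
#' variable, its largest Morse value over all dataset geometries. A
#' polynomial evaluated at this vector bounds how much that polynomial can
#' ever contribute on the sampled region; terms scoring lowest are the
#' cheapest to discard, candidates scoring highest the most valuable to add.
#'
#' @param ds a [pip_dataset()].
#' @param basis a `pip_basis` (defines which variables are retained).
#' @param lambda Morse range parameter (bohr).
#' @return Named numeric vector over `basis$vars_used` (names are parent pair
#'   variable indices), each value in (0, 1).
#' @export
max_morse_values <- function(ds, basis, lambda = 2) {
  stopifnot(inherits(ds, "pip_dataset"), inherits(basis, "pip_basis"))
  if (!length(ds$records)) stop("empty dataset", call. = FALSE)
  mx <- rep.int(0, basis$n_pairs)
  for (rec in ds$records)
    mx <- pmax(mx, morse_variables(rec$geometry, lambda))
  out <- mx[basis$vars_used]
  names(out) <- basis$vars_used
  out
}

# expand maxima (named over vars_used) to a full-length pair-variable vector
maxima_full <- function(basis, maxima) {
  x <- numeric(basis$n_pairs)
  idx <- as.integer(names(maxima))
  if (is.null(names(maxima))) {
    if (length(maxima) == basis$n_pairs) return(as.numeric(maxima))
    if (length(maxima) != length(basis$vars_used))
      stop("maxima must be named by variable index, or match vars_used/n_pairs",
           call. = FALSE)
    idx <- basis$vars_used
  }
  x[idx] <- as.numeric(maxima)
  x
}

#' Prune a basis at the dataset Morse maxima
#'
#' Scores every PIP by its value at the per-variable Morse maxima and removes
#' the `k_remove` lowest-scoring polynomials (ties broken by removing the
#' higher-numbered PIP first). The constant term is never removable. The
#' result is renumbered grade-lexicographically; being a subset of a
#' duplicate-free basis it stays duplicate-free, and it retains every
#' permutational invariance of the original set.
#'
#' @param basis a `pip_basis`.
#' @param maxima output of [max_morse_values()] (or a full-length vector).
#' @param k_remove number of polynomials to remove, `0 <= k_remove <
#'   basis$n_pip`.
#' @return The pruned `pip_basis`, with attribute `scores` giving the removed
#'   PIPs' scores.
#' @export
prune_basis <- function(basis, maxima, k_remove) {
  stopifnot(inherits(basis, "pip_basis"))
  k_remove <- as.integer(k_remove)
  if (k_remove < 0L || k_remove >= basis$n_pip)
    stop("k_remove must be in [0, basis size)", call. = FALSE)
  if (k_remove == 0L) return(basis)
  xmax <- maxima_full(basis, maxima)
  scores <- evaluate_basis(basis, xmax)
  removable <- which(basis$pip_degree > 0L)
  ord <- removable[order(scores[removable], -removable)]
  if (k_remove > length(ord))
    stop("cannot remove ", k_remove, " polynomials: only ", length(ord),
         " non-constant terms", call. = FALSE)
  drop <- ord[seq_len(k_remove)]
  out <- subset_basis(basis, setdiff(seq_len(basis$n_pip), drop))
  attr(out, "scores") <- scores[drop]
  out
}

#' Extend a basis with products of its own polynomials
#'
#' Candidate polynomials are pairwise products of existing PIPs with combined
#' degree up to `target_degree`. Because a product of invariants is invariant
#' but its monomial support may decompose across several orbits of the
#' basis's symmetry group, each product is re-symmetrized: its monomials are
#' canonicalized under the group and split into canonical orbits, candidates
#' whose orbit key already exists in the basis are discarded, the remainder
#' are scored at the Morse maxima, and the `k_add` highest-scoring orbits are
#' added. The result is renumbered, duplicate-free, and retains the
#' permutational invariance of the original set.
#'
#' @param basis a `pip_basis`.
#' @param maxima output of [max_morse_values()].
#' @param target_degree maximum total degree of candidates (>= the basis's
#'   current maximum degree).
#' @param k_add number of polynomials to add.
#' @return The extended `pip_basis`, with attribute `scores` giving the added
#'   PIPs' scores.
#' @export
extend_basis <- function(basis, maxima, target_degree, k_add) {
  stopifnot(inherits(basis, "pip_basis"))
  target_degree <- as.integer(target_degree)
  k_add <- as.integer(k_add)
  if (target_degree < basis$degree_max)
    stop("target_degree must be >= the basis's maximum degree", call. = FALSE)
  base <- basis$n_pairs + 1
  if (base^target_degree >= 2^53)
    stop("encoding overflow at this target degree", call. = FALSE)
  xmax <- maxima_full(basis, maxima)
  G <- basis_group(basis)
  acts <- group_pair_actions(G, basis$n_atoms)

  degs <- basis$pip_degree
  idx_nz <- which(degs > 0L)

  # gather product monomials per total degree
  cand <- vector("list", target_degree)
  for (ai in seq_along(idx_nz)) {
    a <- idx_nz[ai]
    for (b in idx_nz[seq_len(ai)]) {
      k <- degs[a] + degs[b]
      if (k > target_degree) next
      Ma <- basis$mono_vars[basis$mono_pip == a, seq_len(degs[a]), drop = FALSE]
      Mb <- basis$mono_vars[basis$mono_pip == b, seq_len(degs[b]), drop = FALSE]
      ia <- rep(seq_len(nrow(Ma)), times = nrow(Mb))
      ib <- rep(seq_len(nrow(Mb)), each = nrow(Ma))
      prod_rows <- cbind(Ma[ia, , drop = FALSE], Mb[ib, , drop = FALSE])
      prod_rows <- t(apply(prod_rows, 1L, sort))
      cand[[k]] <- rbind(cand[[k]], prod_rows)
    }
  }

  new_keys <- character(0); new_scores <- numeric(0)
  new_orbits <- list(); new_degree <- integer(0); new_rep <- numeric(0)
  for (k in seq_len(target_degree)) {
    Mk <- cand[[k]]
    if (is.null(Mk)) next
    code <- encode_rows(Mk, base)
    keep <- !duplicated(code)
    Mk <- Mk[keep, , drop = FALSE]; code <- code[keep]
    canon <- canonical_codes(Mk, acts, base)
    o <- order(canon, code)
    canon_o <- canon[o]; code_o <- code[o]
    newgrp <- c(TRUE, canon_o[-1L] != canon_o[-length(canon_o)])
    grp <- cumsum(newgrp)
    for (g in seq_len(max(grp))) {
      rows <- o[grp == g]
      codes <- sort(code[rows])
      key <- paste0(k, ":", paste(codes, collapse = ","))
      if (key %in% basis$keys || key %in% new_keys) next
      M <- Mk[rows, , drop = FALSE]
      sc <- sum(apply(M, 1L, function(v) prod(xmax[v])))
      new_keys <- c(new_keys, key)
      new_scores <- c(new_scores, sc)
      new_orbits <- c(new_orbits, list(M))
      new_degree <- c(new_degree, k)
      new_rep <- c(new_rep, codes[1L])
    }
  }
  if (!length(new_keys))
    stop("zero candidates: no new polynomial products up to degree ",
         target_degree, call. = FALSE)
  pick <- order(-new_scores, new_keys)[seq_len(min(k_add, length(new_keys)))]
  if (length(pick) < k_add)
    warning("only ", length(pick), " new candidates available (requested ",
            k_add, ")", call. = FALSE)

  dmax <- max(basis$degree_max, max(new_degree[pick]), 1L)
  pad <- function(M) cbind(M, matrix(0L, nrow(M), dmax - ncol(M)))
  add_mono <- do.call(rbind, lapply(pick, function(i) pad(new_orbits[[i]])))
  add_pip <- rep(basis$n_pip + seq_along(pick),
                 vapply(new_orbits[pick], nrow, integer(1)))
  old_mono <- if (ncol(basis$mono_vars) < dmax)
    cbind(basis$mono_vars,
          matrix(0L, nrow(basis$mono_vars), dmax - ncol(basis$mono_vars)))
    else basis$mono_vars

  out <- basis
  out$degree_max <- dmax
  out$n_pip <- basis$n_pip + length(pick)
  out$pip_degree <- c(basis$pip_degree, new_degree[pick])
  out$mono_vars <- rbind(old_mono, add_mono)
  out$mono_pip <- c(basis$mono_pip, add_pip)
  out$keys <- c(basis$keys, new_keys[pick])
  out$rep_code <- c(basis$rep_code, new_rep[pick])
  out$provenance <- c(basis$provenance, rep.int(list(0L), length(pick)))
  out <- subset_basis(out, seq_len(out$n_pip))   # renumber grade-lex
  attr(out, "scores") <- new_scores[pick]
  out
}
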