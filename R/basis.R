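# --- internal monomial machinery ------------------------------------------
#
# A monomial in the pair variables is represented as a sorted integer vector
# of variable indices with multiplicity (x_3^2 x_7 <-> c(3, 3, 7)); degree-k
# monomials are k-multisets. For fixed degree they are encoded injectively as
# base-B integers (B = n_vars + 1) so that numeric order equals lexicographic
# order on the sorted index vectors; canonicalization takes a running minimum
# of the encoded images over all group elements.

# All k-multisets of 1..n as rows of a matrix, ascending within rows,
# generated (and therefore ordered) lexicographically.
multisets <- function(n, k) {
  stopifnot(n >= 1L, k >= 1L)
  M <- matrix(seq_len(n), ncol = 1L)
  if (k == 1L) return(M)
  for (kk in 2:k) {
    last <- M[, kk - 1L]
    times <- n - last + 1L
    M <- M[rep.int(seq_len(nrow(M)), times), , drop = FALSE]
    newcol <- unlist(lapply(last, function(v) v:n), use.names = FALSE)
    M <- cbind(M, as.integer(newcol))
  }
  M
}

# Row-sort a small-width (<= 4) integer matrix ascending, via sorting networks.
rowsort_small <- function(M) {
  k <- ncol(M)
  swp <- function(a, b) {
    lo <- pmin.int(M[, a], M[, b]); hi <- pmax.int(M[, a], M[, b])
    M[, a] <<- lo; M[, b] <<- hi
  }
  if (k >= 2L) swp(1L, 2L)
  if (k == 3L) { swp(2L, 3L); swp(1L, 2L) }
  if (k == 4L) { swp(3L, 4L); swp(1L, 3L); swp(2L, 4L); swp(2L, 3L) }
  if (k > 4L) M <- t(apply(M, 1L, sort))
  M
}

# Encode sorted rows as base-`base` numbers (doubles; caller guarantees
# base^ncol < 2^53).
encode_rows <- function(M, base) {
  code <- numeric(nrow(M))
  for (c in seq_len(ncol(M))) code <- code * base + M[, c]
  code
}

decode_code <- function(code, base, k) {
  out <- integer(k)
  for (c in k:1) { out[c] <- code %% base; code <- code %/% base }
  out
}

# Canonical (minimal) encoded image of each monomial row under the induced
# pair actions `acts` (one row per group element, already covering identity).
canonical_codes <- function(M, acts, base) {
  k <- ncol(M)
  canon <- encode_rows(M, base)
  for (r in seq_len(nrow(acts))) {
    a <- acts[r, ]
    if (all(a == seq_along(a))) next
    img <- matrix(a[M], ncol = k)
    img <- rowsort_small(img)
    canon <- pmin(canon, encode_rows(img, base))
  }
  canon
}

# --- basis construction ----------------------------------------------------

#' Generate the PIP basis of a fragment by monomial symmetrization
#'
#' Enumerates every monomial of total degree `0..max_degree` in the
#' fragment-internal pair variables, canonicalizes each under the induced
#' action of the fragment's permutation group, and assembles one
#' permutationally invariant polynomial (PIP) per orbit — the PIP being the
#' plain sum of its orbit's monomials. The constant is included as the single
#' degree-0 PIP, the convention under which the basis sizes agree with
#' [burnside_count()]. Variables are expressed in parent pair indices
#' throughout, so bases of different fragments of one parent can be merged
#' directly (see [merge_bases()]).
#'
#' PIPs are numbered grade-lexicographically: by degree, then by their
#' canonically least monomial.
#'
#' @param frag a [fragment_spec()] (>= 2 atoms).
#' @param max_degree maximum total polynomial degree (>= 0).
#' @param n_atoms parent atom count; defaults to the largest listed atom.
#' @return An object of class `pip_basis`; see Details in [merge_bases()] for
#'   the merged variant. Key fields: `n_pip` (basis size), `pip_degree`,
#'   `mono_vars`/`mono_pip` (the orbit monomials of each PIP), `keys`
#'   (canonical orbit keys), `vars_used` (retained parent pair variables),
#'   `sym` (invariance blocks).
#' @examples
#' frag <- fragment_spec(1:3, blocks = 3)   # 3 fully permuting atoms
#' b <- generate_basis(frag, 2)
#' b$n_pip   # orbits of degree <= 2 in 3 pair variables under S3
#' @export
generate_basis <- function(frag, max_degree, n_atoms = max(frag$atoms)) {
  stopifnot(inherits(frag, "fragment_spec"), max_degree >= 0)
  n_atoms <- check_atom_count(n_atoms)
  nf <- length(frag$atoms)
  n_pairs <- (n_atoms * (n_atoms - 1L)) %/% 2L
  base_parent <- n_pairs + 1
  if (base_parent^max(max_degree, 1) >= 2^53)
    stop("encoding overflow: molecule too large for this degree", call. = FALSE)

  # local atom i is frag$atoms[i]; the blocks follow the listing order
  local <- fragment_spec(seq_len(nf), frag$blocks)
  G <- build_group(local, n_atoms = nf)
  acts <- group_pair_actions(G, nf)
  lp <- pair_order(nf)
  nlv <- nrow(lp)
  base_local <- nlv + 1
  local2parent <- pair_index(frag$atoms[lp[, 1L]], frag$atoms[lp[, 2L]], n_atoms)

  deg_list <- list(); mono_list <- list(); pip_list <- list()
  key_list <- list(); rep_list <- list()
  offset <- 0L
  # degree 0: the constant
  deg_list[[1]] <- 0L
  mono_list[[1]] <- matrix(0L, 1L, max(max_degree, 1L))
  pip_list[[1]] <- 1L
  key_list[[1]] <- "0:"
  rep_list[[1]] <- 0
  offset <- 1L

  for (k in seq_len(max_degree)) {
    Mk <- multisets(nlv, k)
    canon <- canonical_codes(Mk, acts, base_local)
    pmat <- rowsort_small(matrix(local2parent[Mk], ncol = k))
    pcode <- encode_rows(pmat, base_parent)
    o <- order(canon, pcode)
    canon_o <- canon[o]; pcode_o <- pcode[o]
    nb <- length(canon_o)
    newgrp <- c(TRUE, canon_o[-1L] != canon_o[-nb])
    grp <- cumsum(newgrp)
    reps <- pcode_o[newgrp]                 # min parent code per orbit
    gord <- order(reps)
    new_id <- integer(length(reps)); new_id[gord] <- seq_along(reps)
    pip_local <- new_id[grp]
    o2 <- order(pip_local)                  # stable: keeps pcode order in-orbit
    rows <- o[o2]
    Pm <- pmat[rows, , drop = FALSE]
    if (ncol(Pm) < max(max_degree, 1L))
      Pm <- cbind(Pm, matrix(0L, nrow(Pm), max(max_degree, 1L) - ncol(Pm)))
    keys_g <- vapply(split(pcode_o, grp),
                     function(v) paste0(k, ":", paste(v, collapse = ",")),
                     character(1))
    deg_list[[k + 1L]] <- rep.int(k, length(reps))
    mono_list[[k + 1L]] <- Pm
    pip_list[[k + 1L]] <- pip_local[o2] + offset
    key_list[[k + 1L]] <- unname(keys_g[gord])
    rep_list[[k + 1L]] <- reps[gord]
    offset <- offset + length(reps)
  }

  basis <- structure(list(
    n_atoms = n_atoms,
    n_pairs = as.integer(n_pairs),
    degree_max = as.integer(max_degree),
    n_pip = offset,
    pip_degree = unlist(deg_list, use.names = FALSE),
    mono_vars = do.call(rbind, mono_list),
    mono_pip = unlist(pip_list, use.names = FALSE),
    keys = unlist(key_list, use.names = FALSE),
    rep_code = unlist(rep_list, use.names = FALSE),
    vars_used = sort(unique(local2parent)),
    sym = frag,
    fragments = list(frag),
    provenance = rep.int(list(1L), offset),
    duplicates = 0L,
    renumbering = NULL
  ), class = "pip_basis")
  basis
}

#' @export
print.pip_basis <- function(x, ...) {
  cat("<pip_basis> ", x$n_pip, " polynomials (degree <= ", x$degree_max,
      "), ", length(x$vars_used), " of ", x$n_pairs,
      " Morse variables retained, ", length(x$fragments), " fragment(s)\n",
      sep = "")
  if (x$duplicates > 0L)
    cat("  merged basis: ", x$duplicates, " duplicated polynomial(s) removed\n",
        sep = "")
  tab <- table(x$pip_degree)
  cat("  per degree: ", paste(names(tab), tab, sep = ":", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate all PIPs of a basis at a Morse vector
#'
#' Direct orbit-sum evaluation: each PIP value is the sum over its orbit
#' monomials of the product of the referenced Morse variables; the degree-0
#' PIP evaluates to 1.
#'
#' @param basis a `pip_basis`.
#' @param morse numeric Morse vector over all parent pair variables (length
#'   `basis$n_pairs`), e.g. from [morse_variables()].
#' @return Numeric vector of length `basis$n_pip`.
#' @export
evaluate_basis <- function(basis, morse) {
  stopifnot(inherits(basis, "pip_basis"))
  if (length(morse) != basis$n_pairs)
    stop("morse vector must cover all ", basis$n_pairs, " parent pair variables",
         call. = FALSE)
  M <- basis$mono_vars
  v <- rep.int(1, nrow(M))
  for (c in seq_len(ncol(M))) {
    idx <- M[, c]
    nz <- idx > 0L
    v[nz] <- v[nz] * morse[idx[nz]]
  }
  as.vector(rowsum(v, basis$mono_pip))
}

# d p_i / d x_l as a sparse n_pip x n_pairs matrix at the Morse vector x
# (requires x > 0 on the variables the basis uses, true for Morse variables).
basis_derivatives <- function(basis, morse) {
  M <- basis$mono_vars
  v <- rep.int(1, nrow(M))
  for (c in seq_len(ncol(M))) {
    idx <- M[, c]
    nz <- idx > 0L
    v[nz] <- v[nz] * morse[idx[nz]]
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (c in seq_len(ncol(M))) {
    idx <- M[, c]
    nz <- which(idx > 0L)
    if (!length(nz)) next
    ii <- c(ii, basis$mono_pip[nz])
    jj <- c(jj, idx[nz])
    xx <- c(xx, v[nz] / morse[idx[nz]])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(basis$n_pip, basis$n_pairs))
}

# Keep a subset of PIPs and renumber grade-lexicographically.
subset_basis <- function(basis, keep) {
  keep <- sort(unique(as.integer(keep)))
  ord <- keep[order(basis$pip_degree[keep], basis$rep_code[keep])]
  new_of_old <- integer(basis$n_pip)
  new_of_old[ord] <- seq_along(ord)
  sel <- basis$mono_pip %in% ord
  mono_pip_new <- new_of_old[basis$mono_pip[sel]]
  mv <- basis$mono_vars[sel, , drop = FALSE]
  o <- order(mono_pip_new)
  out <- basis
  out$n_pip <- length(ord)
  out$pip_degree <- basis$pip_degree[ord]
  out$mono_vars <- mv[o, , drop = FALSE]
  out$mono_pip <- mono_pip_new[o]
  out$keys <- basis$keys[ord]
  out$rep_code <- basis$rep_code[ord]
  out$provenance <- basis$provenance[ord]
  out$vars_used <- sort(unique(out$mono_vars[out$mono_vars > 0L]))
  out$renumbering <- NULL
  out
}

# The invariance group of a basis, as parent-atom permutations.
basis_group <- function(basis) {
  build_group(basis$sym, n_atoms = basis$n_atoms)
}
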