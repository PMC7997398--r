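#' Fragment specification
#'
#' A fragment is an ordered list of parent atom indices together with its
#' permutational symmetry, given as block sizes over that listing (the field's
#' usual notation, e.g. `{3,1,1,1,1,1,1}` for one permuting methyl triple plus
#' six fixed atoms). Atoms inside one block are declared to permute with one
#' another; block sizes of 1 declare no symmetry for that atom. A full
#' molecule is just a fragment covering all parent atoms.
#'
#' @param atoms integer vector of distinct parent atom indices, listed block
#'   by block.
#' @param blocks integer vector of block sizes summing to `length(atoms)`;
#'   default all 1 (no permutational symmetry).
#' @return An object of class `fragment_spec` with elements `atoms`, `blocks`,
#'   and `atom_blocks` (list of parent-atom vectors, one per block).
#' @examples
#' # 9-atom fragment, the first three atoms (a methyl's hydrogens) permute
#' fragment_spec(c(1:9), blocks = c(3, 1, 1, 1, 1, 1, 1))
#' @export
fragment_spec <- function(atoms, blocks = rep(1L, length(atoms))) {
  atoms <- as.integer(atoms); blocks <- as.integer(blocks)
  if (length(atoms) < 2L) stop("a fragment needs at least 2 atoms", call. = FALSE)
  if (anyDuplicated(atoms)) stop("duplicate atom indices in fragment", call. = FALSE)
  if (any(atoms < 1L)) stop("atom indices must be positive", call. = FALSE)
  if (any(blocks < 1L)) stop("block sizes must be >= 1", call. = FALSE)
  if (sum(blocks) != length(atoms))
    stop("block sizes must sum to the number of listed atoms", call. = FALSE)
  ends <- cumsum(blocks)
  starts <- c(1L, head(ends, -1L) + 1L)
  atom_blocks <- mapply(function(s, e) atoms[s:e], starts, ends, SIMPLIFY = FALSE)
  structure(list(atoms = atoms, blocks = blocks, atom_blocks = atom_blocks),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat("<fragment_spec> atoms {", paste(x$atoms, collapse = ", "),
      "}, symmetry {", paste(x$blocks, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# All permutations of 1..k as a k!-row matrix.
perms_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  r <- 0L
  for (pos in seq_len(k)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                 sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Permutation group of a symmetry specification
#'
#' Builds the direct product of symmetric groups acting on each permuting
#' block of a fragment (or parent) specification, as permutations of the full
#' atom range `1..n_atoms` (identity on atoms outside the listing). The group
#' order is the product of the factorials of the block sizes.
#'
#' @param spec a [fragment_spec()] (blocks over listed parent atoms).
#' @param n_atoms total atom count the permutations act on; defaults to the
#'   largest listed atom index.
#' @param max_order guard against accidentally huge groups.
#' @return An integer matrix, one row per group element, each row a
#'   permutation `p` of `1:n_atoms` (atom `i` is sent to `p[i]`).
#' @examples
#' nrow(build_group(fragment_spec(1:9, c(3, 1, 1, 1, 1, 1, 1))))  # 3! = 6
#' @export
build_group <- function(spec, n_atoms = max(spec$atoms), max_order = 1e5) {
  stopifnot(inherits(spec, "fragment_spec"))
  n_atoms <- check_atom_count(n_atoms)
  if (max(spec$atoms) > n_atoms)
    stop("fragment atom index exceeds n_atoms", call. = FALSE)
  ord <- prod(factorial(spec$blocks))
  if (ord > max_order)
    stop("group order ", ord, " exceeds max_order = ", max_order, call. = FALSE)
  nontrivial <- spec$atom_blocks[spec$blocks > 1L]
  id <- seq_len(n_atoms)
  if (!length(nontrivial)) return(matrix(id, 1L, n_atoms))
  per_block <- lapply(nontrivial, function(atoms) {
    P <- perms_of(length(atoms))
    lapply(seq_len(nrow(P)), function(r) atoms[P[r, ]])
  })
  combos <- expand.grid(lapply(per_block, seq_along), KEEP.OUT.ATTRS = FALSE)
  G <- matrix(rep(id, each = nrow(combos)), nrow(combos), n_atoms)
  for (b in seq_along(nontrivial)) {
    images <- do.call(rbind, per_block[[b]])[combos[[b]], , drop = FALSE]
    G[, nontrivial[[b]]] <- images
  }
  storage.mode(G) <- "integer"
  G
}

#' Induced action of an atom permutation on pair variables
#'
#' An atom permutation `p` sends the pair variable of atoms \eqn{(i,j)} to
#' that of \eqn{(p(i), p(j))}; the result is a permutation of the pair
#' variable indices `1..N(N-1)/2`.
#'
#' @param perm integer permutation of `1:n_atoms`.
#' @param n_atoms atom count (defaults to `length(perm)`).
#' @return Integer vector `q`, `q[l]` being the image of pair variable `l`.
#' @export
induced_pair_action <- function(perm, n_atoms = length(perm)) {
  perm <- as.integer(perm)
  if (!setequal(perm, seq_len(n_atoms)) || length(perm) != n_atoms)
    stop("perm must be a bijection of 1:n_atoms", call. = FALSE)
  p <- pair_order(n_atoms)
  pair_index(perm[p[, 1L]], perm[p[, 2L]], n_atoms)
}

# Induced pair actions for all rows of a group matrix: one row per element.
group_pair_actions <- function(G, n_atoms = ncol(G)) {
  t(apply(G, 1L, induced_pair_action, n_atoms = n_atoms))
}

cycle_lengths <- function(q) {
  n <- length(q)
  seen <- logical(n)
  out <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    len <- 0L; t <- s
    while (!seen[t]) { seen[t] <- TRUE; t <- q[t]; len <- len + 1L }
    out <- c(out, len)
  }
  out
}

# Truncated product of power series 1/(1 - t^L) over cycle lengths L:
# coefficient k = number of monomials of degree k fixed by the permutation.
fixed_monomial_counts <- function(cyc, max_degree) {
  coefs <- c(1, numeric(max_degree))
  for (L in cyc) {
    geo <- numeric(max_degree + 1L)
    geo[seq(1L, max_degree + 1L, by = L)] <- 1
    out <- numeric(max_degree + 1L)
    for (k in 0:max_degree)
      out[k + 1L] <- sum(coefs[seq_len(k + 1L)] * rev(geo[seq_len(k + 1L)]))
    coefs <- out
  }
  coefs
}

#' Burnside count of invariant polynomials
#'
#' Counts the orbits of monomials of total degree up to `max_degree` in the
#' \eqn{C(N,2)} pair variables under the induced action of the fragment's
#' permutation group, by Burnside's lemma: the average over group elements of
#' the number of monomials each element fixes, obtained in closed form from
#' the cycle structure of the induced pair permutation. No monomial is ever
#' enumerated, which makes this the independent oracle for the sizes of the
#' bases that [generate_basis()] constructs explicitly.
#'
#' @param spec a [fragment_spec()].
#' @param max_degree maximum total polynomial degree.
#' @param include_constant count the degree-0 orbit (the constant polynomial)?
#'   Default `TRUE`, the convention under which the basis sizes reported for
#'   the NMA and glycine fragmentations are reproduced.
#' @param n_atoms atom count of the space the group acts on; defaults to the
#'   fragment's own atoms, i.e. pair variables internal to the fragment.
#' @return Integer orbit count.
#' @examples
#' # 12-atom molecule, two independently permuting methyl triples, degree <= 3
#' spec <- fragment_spec(1:12, c(3, 3, 1, 1, 1, 1, 1, 1))
#' burnside_count(spec, 3)  # 8040
#' @export
burnside_count <- function(spec, max_degree, include_constant = TRUE,
                           n_atoms = length(spec$atoms)) {
  stopifnot(inherits(spec, "fragment_spec"), max_degree >= 0)
  if (n_atoms == length(spec$atoms)) {
    # act on fragment-internal pairs: relabel atoms to 1..nf
    local <- fragment_spec(match(spec$atoms, sort(spec$atoms)), spec$blocks)
    G <- build_group(local, n_atoms = n_atoms)
  } else {
    G <- build_group(spec, n_atoms = n_atoms)
  }
  total <- 0
  for (r in seq_len(nrow(G))) {
    q <- induced_pair_action(G[r, ], n_atoms)
    total <- total + sum(fixed_monomial_counts(cycle_lengths(q), max_degree))
  }
  cnt <- total / nrow(G)
  cnt <- round(cnt)
  if (!include_constant) cnt <- cnt - 1L
  as.integer(cnt)
}

#' Check a fragmentation against the permutational-consistency rule
#'
#' For the merged basis to stay invariant under a set of parent-level allowed
#' permutations, atoms declared to permute with one another must appear
#' together whenever any of them appears in a fragment, and must then sit in
#' a single permuting block of that fragment. Violations are reported, not
#' raised: deliberately choosing a lower symmetry than the molecule admits is
#' legitimate and common (e.g. ignoring permutations of chemically equivalent
#' carbons).
#'
#' @param parent a [fragment_spec()] describing the parent-level permuting
#'   blocks (over all atoms or a subset).
#' @param fragments list of [fragment_spec()] objects.
#' @return An object of class `pip_validation`: list with logical `pass` and a
#'   data frame `violations` (fragment, block, detail).
#' @export
validate_fragmentation <- function(parent, fragments) {
  stopifnot(inherits(parent, "fragment_spec"))
  if (inherits(fragments, "fragment_spec")) fragments <- list(fragments)
  viol <- list()
  for (f in seq_along(fragments)) {
    frag <- fragments[[f]]
    for (b in seq_along(parent$atom_blocks)) {
      B <- parent$atom_blocks[[b]]
      if (length(B) < 2L) next
      present <- B %in% frag$atoms
      if (!any(present)) next
      if (!all(present)) {
        viol[[length(viol) + 1L]] <- data.frame(
          fragment = f, block = b,
          detail = paste0("atoms {", paste(B[!present], collapse = ","),
                          "} of permuting block {", paste(B, collapse = ","),
                          "} missing from fragment"))
        next
      }
      inside <- vapply(frag$atom_blocks, function(fb) all(B %in% fb), logical(1))
      if (!any(inside))
        viol[[length(viol) + 1L]] <- data.frame(
          fragment = f, block = b,
          detail = paste0("permuting block {", paste(B, collapse = ","),
                          "} split across fragment blocks"))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(fragment = integer(), block = integer(), detail = character())
  structure(list(pass = nrow(violations) == 0L, violations = violations),
            class = "pip_validation")
}

#' @export
print.pip_validation <- function(x, ...) {
  if (x$pass) cat("fragmentation check: PASS\n")
  else {
    cat("fragmentation check: FAIL (", nrow(x$violations), " violation(s))\n", sep = "")
    for (r in seq_len(nrow(x$violations)))
      cat("  fragment ", x$violations$fragment[r], ", block ",
          x$violations$block[r], ": ", x$violations$detail[r], "\n", sep = "")
  }
  invisible(x)
}

#' Largest parent-level symmetry consistent with a fragmentation
#'
#' Two parent atoms may be allowed to permute on the merged surface only if
#' every fragment treats them identically: both absent, or both present in
#' the same permuting block (and, if species are given, they are the same
#' element). This returns the coarsest such partition — the set of allowed
#' parent permutations under which a surface fitted on the merged basis is
#' invariant.
#'
#' @param fragments list of [fragment_spec()].
#' @param n_atoms parent atom count.
#' @param species optional parent species vector; atoms of different species
#'   are never grouped.
#' @return A [fragment_spec()] over `1:n_atoms` whose blocks are the allowed
#'   permuting classes.
#' @export
consistent_parent_blocks <- function(fragments, n_atoms, species = NULL) {
  if (inherits(fragments, "fragment_spec")) fragments <- list(fragments)
  sig <- character(n_atoms)
  for (a in seq_len(n_atoms)) {
    parts <- vapply(fragments, function(f) {
      hit <- which(vapply(f$atom_blocks, function(fb) a %in% fb, logical(1)))
      if (!length(hit)) "-" else as.character(hit[1L])
    }, character(1))
    sp <- if (is.null(species)) "" else species[a]
    sig[a] <- paste(c(sp, parts), collapse = "|")
  }
  classes <- split(seq_len(n_atoms), factor(sig, levels = unique(sig)))
  fragment_spec(unlist(classes, use.names = FALSE),
                blocks = lengths(classes))
}
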