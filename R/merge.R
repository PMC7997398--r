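#' Union of fragment-internal pair variables
#'
#' The fragmented expansion keeps only Morse variables between atoms that
#' share at least one fragment; every other pair is assumed to be at long
#' range, its Morse variable effectively zero, and is dropped from the basis.
#'
#' @param fragments list of [fragment_spec()].
#' @param n_atoms parent atom count.
#' @return List with `retained` (sorted parent pair-variable indices),
#'   `excluded_pairs` (integer matrix of dropped atom pairs, columns `i`,`j`),
#'   and `counts` (retained / excluded / total).
#' @examples
#' fr <- lapply(list(1:3, 2:4, 3:5), fragment_spec)
#' union_variables(fr, 5)$counts
#' @export
union_variables <- function(fragments, n_atoms) {
  if (inherits(fragments, "fragment_spec")) fragments <- list(fragments)
  n_atoms <- check_atom_count(n_atoms)
  retained <- sort(unique(unlist(lapply(fragments, function(f) {
    lp <- pair_order(length(f$atoms))
    pair_index(f$atoms[lp[, 1L]], f$atoms[lp[, 2L]], n_atoms)
  }), use.names = FALSE)))
  allp <- pair_order(n_atoms)
  excluded <- allp[setdiff(seq_len(nrow(allp)), retained), , drop = FALSE]
  list(retained = retained,
       excluded_pairs = excluded,
       counts = c(retained = length(retained), excluded = nrow(excluded),
                  total = nrow(allp)))
}

#' Merge fragment PIP bases with duplicate elimination
#'
#' Concatenates per-fragment PIP bases (all in parent pair indexing), deletes
#' duplicated polynomials, and renumbers the survivors
#' grade-lexicographically. Two PIPs are duplicates exactly when their full
#' orbit monomial sets over parent pair variables are identical — the
#' canonical orbit key — because only identical orbits define identical
#' functions; sharing a representative is not enough when the fragments'
#' symmetry blocks differ. The first fragment in list order keeps its copy;
#' exactly one constant term survives.
#'
#' @param bases list of `pip_basis` objects sharing one parent.
#' @return A merged `pip_basis` with, additionally: `duplicates` (count of
#'   deleted polynomials), `provenance` (per PIP, the fragment indices whose
#'   bases contain it), `renumbering` (per input basis, the map from its
#'   local PIP index to the merged index), and `sym` set to the largest
#'   parent-level symmetry consistent with all fragments
#'   ([consistent_parent_blocks()]), under which every merged PIP is
#'   invariant.
#' @examples
#' f1 <- fragment_spec(1:3, 3); f2 <- fragment_spec(2:4, c(1, 1, 1))
#' m <- merge_bases(list(generate_basis(f1, 2, 4), generate_basis(f2, 2, 4)))
#' m$duplicates
#' @export
merge_bases <- function(bases) {
  if (inherits(bases, "pip_basis")) bases <- list(bases)
  stopifnot(length(bases) >= 1L,
            all(vapply(bases, inherits, logical(1), "pip_basis")))
  n_atoms <- bases[[1L]]$n_atoms
  if (!all(vapply(bases, function(b) b$n_atoms, integer(1)) == n_atoms))
    stop("all bases must share the same parent atom count", call. = FALSE)

  keys <- unlist(lapply(bases, function(b) b$keys), use.names = FALSE)
  src <- rep(seq_along(bases), vapply(bases, function(b) b$n_pip, integer(1)))
  loc <- unlist(lapply(bases, function(b) seq_len(b$n_pip)), use.names = FALSE)
  first <- !duplicated(keys)
  ukeys <- keys[first]
  n_in <- length(keys)

  # provenance: fragments containing each unique key
  key_id <- match(keys, ukeys)
  provenance <- lapply(split(src, key_id), function(s) sort(unique(s)))

  degs <- unlist(lapply(bases, function(b) b$pip_degree), use.names = FALSE)[first]
  reps <- unlist(lapply(bases, function(b) b$rep_code), use.names = FALSE)[first]
  ord <- order(degs, reps)
  merged_of_key <- integer(length(ukeys)); merged_of_key[ord] <- seq_along(ord)

  dmax <- max(vapply(bases, function(b) b$degree_max, integer(1)), 1L)
  pad <- function(M) if (ncol(M) < dmax)
    cbind(M, matrix(0L, nrow(M), dmax - ncol(M))) else M

  # collect monomial rows of the kept copies
  kept_src <- src[first]; kept_loc <- loc[first]
  mono_rows <- vector("list", length(ukeys))
  mono_pips <- vector("list", length(ukeys))
  for (u in seq_along(ukeys)) {
    b <- bases[[kept_src[u]]]
    rows <- which(b$mono_pip == kept_loc[u])
    mono_rows[[u]] <- pad(b$mono_vars[rows, , drop = FALSE])
    mono_pips[[u]] <- rep.int(merged_of_key[u], length(rows))
  }
  mono_vars <- do.call(rbind, mono_rows)
  mono_pip <- unlist(mono_pips, use.names = FALSE)
  o <- order(mono_pip)

  fragments <- unlist(lapply(bases, function(b) b$fragments), recursive = FALSE)
  renumbering <- split(merged_of_key[key_id], src)

  structure(list(
    n_atoms = n_atoms,
    n_pairs = bases[[1L]]$n_pairs,
    degree_max = dmax,
    n_pip = length(ukeys),
    pip_degree = degs[ord],
    mono_vars = mono_vars[o, , drop = FALSE],
    mono_pip = mono_pip[o],
    keys = ukeys[ord],
    rep_code = reps[ord],
    vars_used = sort(unique(unlist(lapply(bases, function(b) b$vars_used)))),
    sym = consistent_parent_blocks(fragments, n_atoms),
    fragments = fragments,
    provenance = unname(provenance[ord]),
    duplicates = as.integer(n_in - length(ukeys)),
    renumbering = unname(renumbering)
  ), class = "pip_basis")
}
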