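#' Canonical ordering of atom pairs
#'
#' Morse variables are indexed by unordered atom pairs \eqn{(i,j)}, \eqn{i<j},
#' in lexicographic order. This ordering is the single source of truth for
#' pair-variable indexing across the package: an \eqn{N}-atom system has
#' \eqn{N(N-1)/2} pair variables.
#'
#' @param n_atoms integer, number of atoms (\eqn{\ge 2}).
#' @return An integer matrix with \eqn{N(N-1)/2} rows and columns `i`, `j`
#'   (1-based atom indices, `i < j`), row `l` being the atoms of pair
#'   variable `l`.
#' @examples
#' pair_order(4)
#' nrow(pair_order(12))  # 66 Morse variables for a 12-atom molecule
#' @seealso [pair_index()]
#' @export
pair_order <- function(n_atoms) {
  n_atoms <- check_atom_count(n_atoms)
  i <- rep.int(seq_len(n_atoms - 1L), times = (n_atoms - 1L):1L)
  j <- unlist(lapply(seq_len(n_atoms - 1L), function(a) (a + 1L):n_atoms),
              use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Pair variable index for an atom pair
#'
#' Inverse of [pair_order()]: maps an unordered atom pair to its 1-based pair
#' variable index under the lexicographic convention. Vectorised over `i`, `j`.
#'
#' @param i,j atom indices, `1 <= i < j <= n_atoms` (order within each pair is
#'   irrelevant; equal indices are an error).
#' @param n_atoms total number of atoms.
#' @return Integer vector of pair variable indices in `1..n_atoms*(n_atoms-1)/2`.
#' @examples
#' pair_index(1, 2, 5)   # 1
#' pair_index(3, 1, 5)   # same as pair_index(1, 3, 5)
#' @export
pair_index <- function(i, j, n_atoms) {
  n_atoms <- check_atom_count(n_atoms)
  i <- as.integer(i); j <- as.integer(j)
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("invalid pair: i and j must differ", call. = FALSE)
  if (any(lo < 1L) || any(hi > n_atoms))
    stop("invalid pair: atom index out of range 1..", n_atoms, call. = FALSE)
  as.integer((lo - 1L) * (2L * n_atoms - lo) / 2L + (hi - lo))
}

check_atom_count <- function(n_atoms) {
  n_atoms <- as.integer(n_atoms)
  if (length(n_atoms) != 1L || is.na(n_atoms) || n_atoms < 2L)
    stop("n_atoms must be a single integer >= 2", call. = FALSE)
  n_atoms
}
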