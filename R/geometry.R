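#' Molecular geometry
#'
#' A light container for one molecular configuration: Cartesian coordinates in
#' bohr plus element labels. Coordinates are stored as an `N x 3` matrix; the
#' flattened 3N-vector convention used for gradients and Hessians is
#' \eqn{(x_1, y_1, z_1, x_2, \dots)}, i.e. `as.vector(t(coords))`.
#'
#' @param coords numeric `N x 3` matrix of coordinates (bohr), or a length-3N
#'   vector in the flattened convention.
#' @param species character vector of length N of element labels.
#' @return An object of class `pip_geometry` with elements `coords`, `species`,
#'   `n_atoms`.
#' @examples
#' g <- geometry(rbind(c(0, 0, 0), c(0, 0, 2)), c("H", "H"))
#' g$n_atoms
#' @export
geometry <- function(coords, species) {
  species <- as.character(species)
  n <- length(species)
  if (is.matrix(coords)) {
    if (ncol(coords) != 3L) stop("coords matrix must have 3 columns", call. = FALSE)
  } else {
    if (length(coords) != 3L * n)
      stop("coords vector must have length 3*length(species)", call. = FALSE)
    coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  }
  if (nrow(coords) != n)
    stop("species length (", n, ") does not match atom count (", nrow(coords), ")",
         call. = FALSE)
  if (n < 2L) stop("a geometry needs at least 2 atoms", call. = FALSE)
  if (!all(is.finite(coords))) stop("all coordinates must be finite", call. = FALSE)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(coords = coords, species = species, n_atoms = n),
            class = "pip_geometry")
}

#' @export
print.pip_geometry <- function(x, ...) {
  cat("<pip_geometry> ", x$n_atoms, " atoms (",
      paste(x$species, collapse = " "), "), coordinates in bohr\n", sep = "")
  invisible(x)
}

#' Apply an atom permutation to a geometry
#'
#' Returns the geometry in which atom `i` carries the coordinates (and label)
#' that atom `perm[i]` had in `geom`. For permutations of identical atoms the
#' species vector is unchanged.
#'
#' @param geom a [geometry()].
#' @param perm integer permutation of `1:n_atoms`.
#' @return A permuted `pip_geometry`.
#' @export
permute_geometry <- function(geom, perm) {
  stopifnot(inherits(geom, "pip_geometry"))
  perm <- as.integer(perm)
  if (length(perm) != geom$n_atoms || anyNA(perm) ||
      !setequal(perm, seq_len(geom$n_atoms)))
    stop("perm must be a permutation of 1:n_atoms", call. = FALSE)
  geometry(geom$coords[perm, , drop = FALSE], geom$species[perm])
}

#' Interatomic distances in canonical pair order
#'
#' @param geom a [geometry()].
#' @return Numeric vector of length \eqn{N(N-1)/2}: the distance (bohr) for
#'   each pair of [pair_order()].
#' @export
pair_distances <- function(geom) {
  stopifnot(inherits(geom, "pip_geometry"))
  p <- pair_order(geom$n_atoms)
  d <- geom$coords[p[, 1L], , drop = FALSE] - geom$coords[p[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Morse variables of a geometry
#'
#' The pair variables feeding every PIP: \eqn{x_l = \exp(-r_l/\lambda)} over
#' interatomic distances \eqn{r_l} in canonical pair order. They lie in
#' \eqn{(0, 1)}, decay exponentially with distance (the premise of
#' fragmentation: pairs of distant atoms contribute essentially zero), and the
#' default range parameter is \eqn{\lambda = 2} bohr.
#'
#' @param geom a [geometry()].
#' @param lambda Morse range parameter in bohr (default 2).
#' @param allow_coincident if `TRUE`, coincident atoms (\eqn{r = 0}, so
#'   \eqn{x = 1}) produce a warning instead of an error; intended for
#'   exploratory evaluation only, never for fitting data.
#' @return Numeric vector of length \eqn{N(N-1)/2}.
#' @examples
#' g <- geometry(rbind(c(0, 0, 0), c(0, 0, 2)), c("H", "H"))
#' morse_variables(g)  # exp(-1)
#' @export
morse_variables <- function(geom, lambda = 2, allow_coincident = FALSE) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  r <- pair_distances(geom)
  if (any(r == 0)) {
    msg <- "degenerate geometry: coincident atoms (pair distance 0)"
    if (allow_coincident) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  exp(-r / lambda)
}

#' Sparse Jacobian of the Morse variables
#'
#' Derivatives \eqn{\partial x_l / \partial a_{j,k}} of each Morse variable
#' with respect to each Cartesian coordinate. The coordinates of atom `j`
#' enter only the \eqn{N-1} variables whose pair contains `j`, so each row has
#' at most 6 structural non-zeros (2 atoms x 3 components):
#' \deqn{\partial x_l/\partial a_{j,k} = -(x_l/\lambda)\,(a_{j,k}-a_{j',k})/r_l}
#' where \eqn{j'} is the partner atom of pair `l`. This structural sparsity is
#' what the per-atom branched gradient evaluation exploits.
#'
#' @inheritParams morse_variables
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense matrix.
#' @return A \eqn{N(N-1)/2 \times 3N} matrix; column \eqn{3(j-1)+k} is
#'   coordinate \eqn{a_{j,k}} in the flattened convention.
#' @export
morse_jacobian <- function(geom, lambda = 2, sparse = TRUE,
                           allow_coincident = FALSE) {
  x <- morse_variables(geom, lambda, allow_coincident)
  p <- pair_order(geom$n_atoms)
  r <- pair_distances(geom)
  np <- nrow(p)
  diff <- geom$coords[p[, 1L], , drop = FALSE] - geom$coords[p[, 2L], , drop = FALSE]
  # d x_l / d a_{i,k} = -(x/lambda) * (a_i - a_j)_k / r ; opposite sign for atom j
  base <- -(x / lambda) / r
  vals <- diff * base            # np x 3, contribution of the first atom
  rows <- rep.int(seq_len(np), 6L)
  cols <- c(3L * (p[, 1L] - 1L) + rep(1:3, each = np),
            3L * (p[, 2L] - 1L) + rep(1:3, each = np))
  xval <- c(as.vector(vals), -as.vector(vals))
  J <- Matrix::sparseMatrix(i = rows, j = cols, x = xval,
                            dims = c(np, 3L * geom$n_atoms))
  if (sparse) J else as.matrix(J)
}
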