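#' Built-in toy molecular systems
#'
#' Two small reference systems for exercising the full pipeline with
#' brute-force-checkable sizes: `"a3bc"`, a 5-atom methyl-like molecule
#' (three permutable A atoms bonded to B, plus C), and `"a2b2cd"`, a 6-atom
#' molecule with two permutable atom pairs (loosely glycine-like: an A2
#' pair, a B2 pair, and two distinct heavy atoms).
#'
#' @param name `"a3bc"` or `"a2b2cd"`.
#' @return List with `species`, reference `geometry` (bohr), `masses` (amu),
#'   and `blocks`, the natural permutational symmetry of the species listing.
#' @examples
#' toy_system("a3bc")$species
#' @export
toy_system <- function(name = c("a3bc", "a2b2cd")) {
  name <- match.arg(name)
  if (name == "a3bc") {
    # three A around B (z-axis symmetric), C below: methyl-like
    th <- 110 * pi / 180; r <- 2.05
    coords <- rbind(
      r * c(sin(th), 0, cos(th)),
      r * c(sin(th) * cos(2 * pi / 3),  sin(th) * sin(2 * pi / 3), cos(th)),
      r * c(sin(th) * cos(4 * pi / 3), -sin(th) * sin(2 * pi / 3), cos(th)),
      c(0, 0, 0),
      c(0, 0, -2.60))
    list(species = c("A", "A", "A", "B", "C"),
         geometry = geometry(coords, c("A", "A", "A", "B", "C")),
         masses = c(1.008, 1.008, 1.008, 12.011, 18.998),
         blocks = fragment_spec(1:5, c(3, 1, 1)))
  } else {
    coords <- rbind(
      c( 1.6,  1.5,  0.9),
      c( 1.6,  1.5, -0.9),
      c(-3.4,  0.8,  1.2),
      c(-3.4,  0.8, -1.2),
      c( 1.0,  0.9,  0.0),
      c(-1.6,  0.0,  0.0))
    list(species = c("A", "A", "B", "B", "C", "D"),
         geometry = geometry(coords, c("A", "A", "B", "B", "C", "D")),
         masses = c(1.008, 1.008, 15.999, 15.999, 14.007, 12.011),
         blocks = fragment_spec(1:6, c(2, 2, 1, 1)))
  }
}

#' Surrogate analytic potential energy surfaces
#'
#' Stand-ins for an ab initio oracle, so that fitting, gradients, pruning and
#' harmonic analysis can be tested end to end against analytic ground truth.
#' Two modes:
#' \describe{
#'   \item{`pairwise`}{\eqn{V = \sum_{pairs} D(1 - e^{-\alpha(r - r_0)})^2},
#'     with well depth D (\eqn{cm^{-1}}), range \eqn{\alpha} (1/bohr) and
#'     equilibrium \eqn{r_0} (bohr) keyed by the unordered species pair —
#'     hence exactly invariant under any permutation of same-species atoms.}
#'   \item{`pip-combo`}{an exact linear combination of a supplied PIP basis
#'     with known coefficients — the parameter-recovery oracle: fitting its
#'     own samples with its own basis must reproduce predictions exactly.}
#' }
#' Parameters are drawn reproducibly from `seed` within ranges typical of
#' covalent wells (D 5000–40000 cm^-1, alpha 0.8–1.6 /bohr, r0 1.8–2.9 bohr).
#'
#' @param species character vector of element labels (>= 2 atoms).
#' @param mode `"pairwise"` or `"pip-combo"`.
#' @param seed integer seed for parameter generation.
#' @param reference optional [geometry()]; in pairwise mode each species
#'   pair's equilibrium \eqn{r_0} is then set to the mean reference distance
#'   of that pair type, so the reference structure sits near the surrogate
#'   minimum (as a fitting dataset's reference would). Without it, \eqn{r_0}
#'   is drawn uniformly from 1.8–2.9 bohr.
#' @param basis,coefficients for `pip-combo`: the basis and its coefficient
#'   vector (coefficients drawn from N(0, 500^2) if omitted).
#' @param lambda Morse range parameter used by `pip-combo` (bohr).
#' @return Object of class `surrogate_pes`.
#' @export
make_surrogate <- function(species, mode = c("pairwise", "pip-combo"),
                           seed = 1L, reference = NULL, basis = NULL,
                           coefficients = NULL, lambda = 2) {
  mode <- match.arg(mode)
  n <- length(species)
  if (n < 2L) stop("need at least 2 atoms", call. = FALSE)
  set.seed(seed)
  if (mode == "pairwise") {
    p <- pair_order(n)
    key <- paste(pmin(species[p[, 1L]], species[p[, 2L]]),
                 pmax(species[p[, 1L]], species[p[, 2L]]), sep = "-")
    ukey <- sort(unique(key))
    r0 <- if (is.null(reference)) stats::runif(length(ukey), 1.8, 2.9) else
      vapply(ukey, function(k) mean(pair_distances(reference)[key == k]),
             numeric(1))
    pars <- data.frame(pair = ukey,
                       D = stats::runif(length(ukey), 5000, 40000),
                       alpha = stats::runif(length(ukey), 0.8, 1.6),
                       r0 = unname(r0))
    m <- match(key, ukey)
    obj <- list(mode = mode, species = species, seed = seed, params = pars,
                D = pars$D[m], alpha = pars$alpha[m], r0 = pars$r0[m])
  } else {
    if (is.null(basis)) stop("pip-combo mode requires a basis", call. = FALSE)
    if (basis$n_atoms != n)
      stop("basis atom count does not match species", call. = FALSE)
    if (is.null(coefficients))
      coefficients <- stats::rnorm(basis$n_pip, 0, 500)
    if (length(coefficients) != basis$n_pip)
      stop("coefficient length must equal basis size", call. = FALSE)
    obj <- list(mode = mode, species = species, seed = seed, basis = basis,
                coefficients = coefficients, lambda = lambda)
  }
  structure(obj, class = "surrogate_pes")
}

#' @export
print.surrogate_pes <- function(x, ...) {
  cat("<surrogate_pes> mode ", x$mode, ", ", length(x$species), " atoms (",
      paste(x$species, collapse = " "), "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Energy and gradient of a surrogate PES
#'
#' @param pes a [make_surrogate()] object.
#' @param geom a [geometry()] with matching species.
#' @return `surrogate_energy`: energy (\eqn{cm^{-1}});
#'   `surrogate_gradient`: 3N gradient (\eqn{cm^{-1}}/bohr), analytic.
#' @export
surrogate_energy <- function(pes, geom) {
  stopifnot(inherits(pes, "surrogate_pes"))
  if (pes$mode == "pairwise") {
    r <- pair_distances(geom)
    e <- exp(-pes$alpha * (r - pes$r0))
    sum(pes$D * (1 - e)^2)
  } else {
    x <- morse_variables(geom, pes$lambda)
    sum(pes$coefficients * evaluate_basis(pes$basis, x))
  }
}

#' @rdname surrogate_energy
#' @export
surrogate_gradient <- function(pes, geom) {
  stopifnot(inherits(pes, "surrogate_pes"))
  n <- geom$n_atoms
  p <- pair_order(n)
  r <- pair_distances(geom)
  if (pes$mode == "pairwise") {
    e <- exp(-pes$alpha * (r - pes$r0))
    dVdr <- 2 * pes$D * pes$alpha * e * (1 - e)
  } else {
    x <- morse_variables(geom, pes$lambda)
    D <- basis_derivatives(pes$basis, x)
    dVdx <- as.vector(Matrix::crossprod(D, pes$coefficients))
    dVdr <- dVdx * (-x / pes$lambda)
  }
  g <- numeric(3L * n)
  diru <- (geom$coords[p[, 1L], , drop = FALSE] -
           geom$coords[p[, 2L], , drop = FALSE]) / r
  contrib <- diru * dVdr
  for (l in seq_len(nrow(p))) {
    i <- p[l, 1L]; j <- p[l, 2L]
    g[3L * (i - 1L) + 1:3] <- g[3L * (i - 1L) + 1:3] + contrib[l, ]
    g[3L * (j - 1L) + 1:3] <- g[3L * (j - 1L) + 1:3] - contrib[l, ]
  }
  g
}

# minimize the surrogate from a reference geometry (analytic gradient)
surrogate_minimum <- function(pes, reference) {
  fn <- function(par) surrogate_energy(pes, geometry(par, reference$species))
  gr <- function(par) surrogate_gradient(pes, geometry(par, reference$species))
  opt <- stats::optim(as.vector(t(reference$coords)), fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  list(geometry = geometry(opt$par, reference$species), energy = opt$value)
}

#' Sample a synthetic fitting dataset from a surrogate PES
#'
#' Emulates the structure of an ab initio fitting set drawn from molecular
#' dynamics below an energy ceiling: geometries are Gaussian displacements of
#' a reference structure, accepted only when the energy relative to the
#' surrogate minimum (located by gradient minimization from the reference)
#' is at most `cutoff`, so most retained configurations cluster near the
#' minimum. Every record carries the analytic gradient. Energies are stored
#' relative to the surrogate minimum.
#'
#' @param pes a [make_surrogate()] object.
#' @param reference a [geometry()] to displace from.
#' @param n number of records.
#' @param sigma per-coordinate Gaussian displacement (bohr).
#' @param cutoff energy ceiling above the surrogate minimum (\eqn{cm^{-1}}).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param max_attempts proposal cap before giving up.
#' @return A [pip_dataset()] with attributes `min_energy` (the subtracted
#'   surrogate minimum) and `min_geometry`.
#' @export
sample_dataset <- function(pes, reference, n, sigma = 0.08, cutoff = 10000,
                           seed = 1L, max_attempts = max(2000L, 200L * n)) {
  stopifnot(inherits(pes, "surrogate_pes"), n >= 1L, sigma > 0)
  set.seed(seed)
  mn <- surrogate_minimum(pes, reference)
  if (cutoff <= 0)
    stop("cutoff must be above the surrogate minimum (relative energy > 0)",
         call. = FALSE)
  recs <- vector("list", n)
  got <- 0L; tries <- 0L
  while (got < n && tries < max_attempts) {
    tries <- tries + 1L
    coords <- reference$coords + matrix(stats::rnorm(3L * reference$n_atoms,
                                                     sd = sigma),
                                        ncol = 3L)
    g <- geometry(coords, reference$species)
    E <- surrogate_energy(pes, g) - mn$energy
    if (E > cutoff) next
    got <- got + 1L
    recs[[got]] <- list(geometry = g, energy = E,
                        gradient = surrogate_gradient(pes, g))
  }
  if (got < n)
    stop("only ", got, "/", n, " geometries accepted after ", tries,
         " proposals; increase sigma or cutoff", call. = FALSE)
  ds <- pip_dataset(recs)
  attr(ds, "min_energy") <- mn$energy
  attr(ds, "min_geometry") <- mn$geometry
  ds
}
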