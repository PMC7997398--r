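# physical constants (CODATA 2018)
PLANCK_H   <- 6.62607015e-34      # J s
SPEED_C_CM <- 2.99792458e10       # cm/s
BOHR_M     <- 5.29177210903e-11   # m
AMU_KG     <- 1.66053906660e-27   # kg

# eigenvalue of the mass-scaled Hessian [cm^-1 / (bohr^2 amu)] -> wavenumber:
# nu~ = sqrt(lambda * h c / (a0^2 amu)) / (2 pi c), signed for imaginary modes
eigval_to_wavenumber <- function(ev) {
  f <- PLANCK_H * SPEED_C_CM / (BOHR_M^2 * AMU_KG)   # s^-2 per (cm^-1/bohr^2/amu)
  sign(ev) * sqrt(abs(ev) * f) / (2 * pi * SPEED_C_CM)
}

#' Minimize a fitted surface from a starting geometry
#'
#' Quasi-Newton (BFGS) minimization on the Cartesian coordinates using the
#' analytic gradient of the fit, polished until the gradient infinity norm is
#' below `tol`.
#'
#' @param fit a [pip_fit()].
#' @param start a [geometry()] to start from.
#' @param tol convergence threshold on \eqn{\max_j |\partial V/\partial a_j|}
#'   (\eqn{cm^{-1}}/bohr).
#' @param max_restarts BFGS restarts before giving up.
#' @param maxit iterations per BFGS run.
#' @return The minimized [geometry()], with attributes `energy` (\eqn{cm^{-1}})
#'   and `grad_norm`. Non-convergence raises an error of class
#'   `pipfrag_no_convergence` carrying the last iterate in its `geometry`
#'   field.
#' @export
minimize_geometry <- function(fit, start, tol = 1e-6, max_restarts = 5L,
                              maxit = 500L) {
  stopifnot(inherits(fit, "pip_fit"), inherits(start, "pip_geometry"))
  ok <- function(par) all(is.finite(par)) && all(abs(par) < 1e3) &&
    min(pair_distances(geometry(par, start$species))) > 0.3
  fn <- function(par) if (!ok(par)) 1e12 else
    evaluate_potential(fit, geometry(par, start$species))
  gr <- function(par) if (!ok(par)) numeric(length(par)) else
    evaluate_gradient(fit, geometry(par, start$species))
  par <- as.vector(t(start$coords))
  # fnscale keeps the first quasi-Newton step at ~0.1 bohr even when the
  # starting gradient is large (a degree-limited fit is unbounded far out)
  fs <- max(1, 10 * max(abs(gr(par))))
  for (k in seq_len(max_restarts)) {
    opt <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-16,
                                       fnscale = fs))
    par <- opt$par
    g <- gr(par)
    if (all(is.finite(g)) && max(abs(g)) < tol) break
  }
  # Newton polish with a pseudo-inverse Hessian (translations/rotations are
  # null directions); quadratic convergence to tight gradient tolerances
  for (k in seq_len(20L)) {
    g <- gr(par)
    if (max(abs(g)) < tol) break
    H <- pes_hessian(fit, geometry(par, start$species))
    sv <- svd(H)
    keep <- sv$d > 1e-8 * max(sv$d)
    step <- -as.vector(sv$v %*% (ifelse(keep, 1 / sv$d, 0) *
                                 crossprod(sv$u, g)))
    if (max(abs(step)) > 0.5) step <- step * (0.5 / max(abs(step)))
    if (fn(par + step) > fn(par) && max(abs(g)) < 1e3 * tol) step <- step / 10
    par <- par + step
  }
  gnorm <- max(abs(gr(par)))
  if (gnorm >= tol) {
    cond <- structure(class = c("pipfrag_no_convergence", "error", "condition"),
                      list(message = paste0("minimization did not reach |grad| < ",
                                            tol, " (reached ", format(gnorm), ")"),
                           call = sys.call(-1),
                           geometry = geometry(par, start$species)))
    stop(cond)
  }
  out <- geometry(par, start$species)
  attr(out, "energy") <- fn(par)
  attr(out, "grad_norm") <- gnorm
  out
}

#' Hessian of a fitted surface
#'
#' Second derivatives by central finite differences of the analytic gradient
#' (one order of differencing less noisy than double-differencing energies),
#' symmetrized as \eqn{(H + H^T)/2}.
#'
#' @param fit a [pip_fit()].
#' @param geom a [geometry()], normally a converged minimum.
#' @param step finite-difference displacement (bohr).
#' @return A symmetric \eqn{3N \times 3N} matrix (\eqn{cm^{-1}}/bohr^2) in the
#'   flattened atom-major coordinate convention, with attribute `asymmetry`
#'   (the max absolute asymmetry before symmetrization).
#' @export
pes_hessian <- function(fit, geom, step = 1e-4) {
  stopifnot(inherits(fit, "pip_fit"), inherits(geom, "pip_geometry"))
  par <- as.vector(t(geom$coords))
  n3 <- length(par)
  H <- matrix(0, n3, n3)
  for (c in seq_len(n3)) {
    pp <- par; pp[c] <- pp[c] + step
    pm <- par; pm[c] <- pm[c] - step
    H[, c] <- (evaluate_gradient(fit, geometry(pp, geom$species)) -
               evaluate_gradient(fit, geometry(pm, geom$species))) / (2 * step)
  }
  asym <- max(abs(H - t(H)))
  H <- (H + t(H)) / 2
  attr(H, "asymmetry") <- asym
  H
}

#' Harmonic frequencies from a Hessian
#'
#' Diagonalizes the mass-scaled Hessian \eqn{M^{-1/2} H M^{-1/2}} and converts
#' its eigenvalues to harmonic wavenumbers. Negative eigenvalues (imaginary
#' modes) are returned as negative wavenumbers of the corresponding
#' magnitude.
#'
#' @param H \eqn{3N \times 3N} Hessian (\eqn{cm^{-1}}/bohr^2).
#' @param masses length-N atomic masses (amu).
#' @return Numeric vector of 3N wavenumbers (\eqn{cm^{-1}}), ascending; at a
#'   nonlinear minimum the lowest 6 (5 for linear molecules) are near zero
#'   (rigid translations and rotations).
#' @export
harmonic_frequencies <- function(H, masses) {
  if (!all(is.finite(H))) stop("non-finite Hessian", call. = FALSE)
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  if (nrow(H) != 3L * length(masses))
    stop("Hessian dimension must be 3 * length(masses)", call. = FALSE)
  w <- rep(1 / sqrt(masses), each = 3L)
  ev <- eigen(H * outer(w, w), symmetric = TRUE, only.values = TRUE)$values
  sort(eigval_to_wavenumber(ev))
}

#' Full harmonic analysis on a fitted surface
#'
#' Minimizes from `start`, builds the Hessian, diagonalizes the mass-scaled
#' Hessian, and separates the 6 (5 for a linear molecule, detected by a
#' moment-of-inertia threshold) near-zero translation/rotation modes from the
#' vibrational ones.
#'
#' @inheritParams minimize_geometry
#' @param masses length-N atomic masses (amu).
#' @param step Hessian finite-difference step (bohr).
#' @param linear_tol relative moment-of-inertia threshold below which the
#'   molecule is treated as linear.
#' @return Object of class `harmonic_result`: `geometry` (the minimum),
#'   `energy`, `hessian`, `frequencies` (the 3N-6 or 3N-5 vibrational
#'   wavenumbers, ascending), `zero_modes` (the removed near-zero
#'   wavenumbers), `linear`.
#' @export
harmonic_analysis <- function(fit, start, masses, tol = 1e-6, step = 1e-4,
                              linear_tol = 1e-8) {
  gmin <- minimize_geometry(fit, start, tol = tol)
  H <- pes_hessian(fit, gmin, step = step)
  freqs <- harmonic_frequencies(H, masses)
  com <- colSums(gmin$coords * masses) / sum(masses)
  cc <- sweep(gmin$coords, 2L, com)
  Imat <- diag(sum(masses * rowSums(cc^2)), 3L) -
    t(cc) %*% (cc * masses)
  iev <- sort(eigen(Imat, symmetric = TRUE, only.values = TRUE)$values)
  linear <- iev[1L] < linear_tol * max(iev[3L], 1)
  nzero <- if (linear) 5L else 6L
  drop <- order(abs(freqs))[seq_len(nzero)]
  structure(list(geometry = gmin, energy = attr(gmin, "energy"),
                 hessian = H, frequencies = sort(freqs[-drop]),
                 zero_modes = sort(freqs[drop]), linear = linear),
            class = "harmonic_result")
}

#' @export
print.harmonic_result <- function(x, ...) {
  cat("<harmonic_result> minimum at E = ", format(x$energy, digits = 8),
      " cm^-1 (", if (x$linear) "linear" else "nonlinear", ")\n", sep = "")
  cat("  ", length(x$frequencies), " vibrational wavenumbers [cm^-1]:\n  ",
      paste(format(round(x$frequencies, 1)), collapse = " "), "\n", sep = "")
  cat("  near-zero modes: ",
      paste(format(round(x$zero_modes, 2)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Mean absolute error between two frequency lists
#'
#' @param reference,test equal-length numeric vectors of wavenumbers in
#'   matched mode order.
#' @return MAE in \eqn{cm^{-1}}.
#' @examples
#' mae_frequencies(c(0, 2), c(1, 1))  # 1
#' @export
mae_frequencies <- function(reference, test) {
  if (length(reference) != length(test))
    stop("frequency lists must have equal length", call. = FALSE)
  mean(abs(reference - test))
}
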