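#' Design matrix for a joint energy/gradient fit
#'
#' Builds the linear system for the expansion \eqn{V = \sum_i c_i p_i(x)}:
#' one row per record energy with entries \eqn{p_i(x(g))}, and, for each
#' record carrying a gradient, 3N rows with entries
#' \eqn{\sum_l (\partial p_i/\partial x_l)(\partial x_l/\partial a_{j,k})},
#' scaled by the gradient weight. With `gradient_weight = 0` the gradient
#' rows are omitted entirely.
#'
#' @param ds a [pip_dataset()].
#' @param basis a `pip_basis` over the same parent atom count.
#' @param lambda Morse range parameter (bohr).
#' @param gradient_weight nonnegative weight multiplying every gradient row
#'   and target.
#' @return List with matrix `A`, target vector `b`, and `row_type`
#'   (`"energy"`/`"gradient"`).
#' @export
design_matrix <- function(ds, basis, lambda = 2, gradient_weight = 1) {
  stopifnot(inherits(ds, "pip_dataset"), inherits(basis, "pip_basis"))
  if (ds$n_atoms != basis$n_atoms)
    stop("dataset has ", ds$n_atoms, " atoms but basis expects ",
         basis$n_atoms, call. = FALSE)
  if (gradient_weight < 0) stop("gradient_weight must be >= 0", call. = FALSE)
  n <- length(ds$records)
  Arows <- vector("list", 2L * n)
  brows <- vector("list", 2L * n)
  trows <- vector("list", 2L * n)
  for (r in seq_len(n)) {
    rec <- ds$records[[r]]
    x <- morse_variables(rec$geometry, lambda)
    Arows[[2L * r - 1L]] <- matrix(evaluate_basis(basis, x), nrow = 1L)
    brows[[2L * r - 1L]] <- rec$energy
    trows[[2L * r - 1L]] <- "energy"
    if (!is.null(rec$gradient) && gradient_weight > 0) {
      D <- basis_derivatives(basis, x)            # n_pip x n_pairs
      J <- morse_jacobian(rec$geometry, lambda)   # n_pairs x 3N
      G <- as.matrix(Matrix::t(D %*% J))          # 3N x n_pip
      Arows[[2L * r]] <- gradient_weight * G
      brows[[2L * r]] <- gradient_weight * rec$gradient
      trows[[2L * r]] <- rep.int("gradient", nrow(G))
    }
  }
  keep <- !vapply(Arows, is.null, logical(1))
  list(A = do.call(rbind, Arows[keep]),
       b = unlist(brows[keep], use.names = FALSE),
       row_type = unlist(trows[keep], use.names = FALSE))
}

#' Fit a permutationally invariant polynomial surface
#'
#' Linear least-squares fit of the PIP expansion \eqn{V = \sum_i c_i p_i(x)}
#' to a dataset of energies and (optionally) Cartesian gradients, solved by
#' singular value decomposition with a relative cutoff, which yields the
#' minimal-norm solution and tolerates the rank deficiency that duplicated
#' or near-redundant basis functions produce — predictions from a
#' duplicate-containing basis and its deduplicated counterpart coincide.
#'
#' @inheritParams design_matrix
#' @param svd_tol relative singular-value cutoff (singular values below
#'   `svd_tol * max(sv)` are treated as zero).
#' @param shift_energies if `TRUE`, the minimum dataset energy is subtracted
#'   before fitting and stored in the result (predictions add it back).
#' @return An object of class `pip_fit`: `coefficients` (\eqn{cm^{-1}},
#'   aligned with the basis), `basis`, `lambda`, `gradient_weight`, `rmse`
#'   (training root-mean-square energy error, \eqn{cm^{-1}}), `rmsg`
#'   (root-mean-square over all fitted gradient components,
#'   \eqn{cm^{-1}}/bohr, `NA` if no gradients), `rank`, `shift`.
#' @seealso [predict.pip_fit()], [evaluate_potential()],
#'   [evaluate_gradient()], [rms_metrics()]
#' @export
pip_fit <- function(ds, basis, lambda = 2, gradient_weight = 1,
                    svd_tol = 1e-10, shift_energies = FALSE) {
  stopifnot(inherits(ds, "pip_dataset"))
  if (!length(ds$records)) stop("empty dataset", call. = FALSE)
  shift <- if (shift_energies) min(energies(ds)) else 0
  dsf <- ds
  if (shift != 0)
    dsf$records <- lapply(ds$records, function(r) { r$energy <- r$energy - shift; r })
  dm <- design_matrix(dsf, basis, lambda, gradient_weight)
  sv <- svd(dm$A)
  keep <- sv$d > svd_tol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  solve_ls <- function(rhs) as.vector(sv$v %*% (dinv * crossprod(sv$u, rhs)))
  coefs <- solve_ls(dm$b)
  # two steps of iterative refinement: recovers the digits the truncated-SVD
  # apply loses on ill-conditioned (duplicate-containing) bases
  for (it in 1:2)
    coefs <- coefs + solve_ls(dm$b - as.vector(dm$A %*% coefs))
  fit <- structure(list(
    coefficients = coefs, basis = basis, lambda = lambda,
    gradient_weight = gradient_weight, svd_tol = svd_tol,
    shift = shift, rank = sum(keep),
    n_energy = sum(dm$row_type == "energy"),
    n_gradient = sum(dm$row_type == "gradient")
  ), class = "pip_fit")
  m <- rms_metrics(fit, ds)
  fit$rmse <- m[["rmse"]]; fit$rmsg <- m[["rmsg"]]
  fit
}

#' @export
print.pip_fit <- function(x, ...) {
  cat("<pip_fit> ", length(x$coefficients), " coefficients (rank ", x$rank,
      "), lambda = ", x$lambda, " bohr, gradient weight = ",
      x$gradient_weight, "\n", sep = "")
  cat("  training RMSE = ", format(x$rmse, digits = 6), " cm^-1",
      if (!is.na(x$rmsg)) paste0(", RMSG = ", format(x$rmsg, digits = 6),
                                 " cm^-1/bohr"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pip_fit <- function(object, ...) {
  b <- object$basis
  cat("Permutationally invariant polynomial fit\n")
  cat("  basis: ", b$n_pip, " PIPs, degree <= ", b$degree_max, ", ",
      length(b$vars_used), "/", b$n_pairs, " Morse variables, ",
      length(b$fragments), " fragment(s)", sep = "")
  if (b$duplicates > 0L) cat(" (", b$duplicates, " duplicates removed)", sep = "")
  cat("\n  data: ", object$n_energy, " energies, ", object$n_gradient,
      " gradient components (weight ", object$gradient_weight, ")\n", sep = "")
  cat("  solver: SVD, relative cutoff ", object$svd_tol, ", rank ",
      object$rank, "/", length(object$coefficients), "\n", sep = "")
  cat("  training RMSE = ", format(object$rmse, digits = 8), " cm^-1\n", sep = "")
  if (!is.na(object$rmsg))
    cat("  training RMSG = ", format(object$rmsg, digits = 8), " cm^-1/bohr\n",
        sep = "")
  if (object$shift != 0)
    cat("  energies shifted by ", object$shift, " cm^-1 before fitting\n", sep = "")
  invisible(object)
}

#' @export
coef.pip_fit <- function(object, ...) object$coefficients

#' Evaluate the fitted potential at a geometry
#'
#' @param fit a [pip_fit()].
#' @param geom a [geometry()] with the parent atom count.
#' @return Energy in \eqn{cm^{-1}}.
#' @export
evaluate_potential <- function(fit, geom) {
  stopifnot(inherits(fit, "pip_fit"))
  x <- morse_variables(geom, fit$lambda)
  sum(fit$coefficients * evaluate_basis(fit$basis, x)) + fit$shift
}

#' Analytic gradient of the fitted potential
#'
#' Computes \eqn{\partial V/\partial a_{j,k} = \sum_i c_i \sum_l
#' (\partial p_i/\partial x_l)(\partial x_l/\partial a_{j,k})}. With
#' `branch = TRUE` (default) the inner sum for atom `j` runs only over the
#' \eqn{N-1} Morse variables whose pair contains `j` — all other terms are
#' structural zeros — which is what makes gradient evaluation cheap for
#' large molecules; `branch = FALSE` performs the dense computation, and the
#' two are numerically identical.
#'
#' @param fit a [pip_fit()].
#' @param geom a [geometry()].
#' @param branch use the per-atom sparse branching (default `TRUE`).
#' @return Numeric vector of 3N gradient components (\eqn{cm^{-1}}/bohr) in
#'   the flattened atom-major convention.
#' @export
evaluate_gradient <- function(fit, geom, branch = TRUE) {
  stopifnot(inherits(fit, "pip_fit"))
  x <- morse_variables(geom, fit$lambda)
  D <- basis_derivatives(fit$basis, x)
  dVdx <- as.vector(Matrix::crossprod(D, fit$coefficients))  # length n_pairs
  n <- geom$n_atoms
  if (!branch) {
    J <- morse_jacobian(geom, fit$lambda, sparse = FALSE)
    return(as.vector(dVdx %*% J))
  }
  p <- pair_order(n)
  r <- pair_distances(geom)
  pref <- -(x / fit$lambda) / r * dVdx
  g <- numeric(3L * n)
  for (j in seq_len(n)) {
    touch <- which(p[, 1L] == j | p[, 2L] == j)   # the N-1 pairs holding atom j
    partner <- ifelse(p[touch, 1L] == j, p[touch, 2L], p[touch, 1L])
    diff <- matrix(geom$coords[j, ], length(touch), 3L, byrow = TRUE) -
      geom$coords[partner, , drop = FALSE]
    g[3L * (j - 1L) + 1:3] <- colSums(diff * pref[touch])
  }
  g
}

#' Training / evaluation RMS metrics
#'
#' Root-mean-square error of the fitted energies and, when gradients are
#' present, of all fitted gradient components, over a dataset.
#'
#' @param fit a [pip_fit()].
#' @param ds a [pip_dataset()].
#' @return Named numeric vector `c(rmse = , rmsg = )`; `rmsg` is `NA` when no
#'   record carries a gradient.
#' @export
rms_metrics <- function(fit, ds) {
  stopifnot(inherits(fit, "pip_fit"), inherits(ds, "pip_dataset"))
  eres <- vapply(ds$records, function(r)
    evaluate_potential(fit, r$geometry) - r$energy, numeric(1))
  gres <- unlist(lapply(ds$records, function(r) {
    if (is.null(r$gradient)) return(NULL)
    evaluate_gradient(fit, r$geometry) - r$gradient
  }), use.names = FALSE)
  c(rmse = sqrt(mean(eres^2)),
    rmsg = if (length(gres)) sqrt(mean(gres^2)) else NA_real_)
}

#' @export
predict.pip_fit <- function(object, newdata, gradient = FALSE, ...) {
  one <- function(g) {
    if (gradient) list(energy = evaluate_potential(object, g),
                       gradient = evaluate_gradient(object, g))
    else evaluate_potential(object, g)
  }
  if (inherits(newdata, "pip_geometry")) return(one(newdata))
  if (inherits(newdata, "pip_dataset")) {
    if (gradient) return(lapply(newdata$records, function(r) one(r$geometry)))
    return(vapply(newdata$records, function(r) one(r$geometry), numeric(1)))
  }
  stop("newdata must be a pip_geometry or pip_dataset", call. = FALSE)
}

#' @export
fitted.pip_fit <- function(object, ...) {
  stop("pip_fit does not store its training data; use predict() on the dataset",
       call. = FALSE)
}

#' @export
residuals.pip_fit <- function(object, ds, ...) {
  stopifnot(inherits(ds, "pip_dataset"))
  predict(object, ds) - energies(ds)
}

#' @export
plot.pip_fit <- function(x, ds, ...) {
  stopifnot(inherits(ds, "pip_dataset"))
  obs <- energies(ds)
  pred <- predict(x, ds)
  graphics::plot(obs, pred, xlab = "reference energy [cm^-1]",
                 ylab = "fitted energy [cm^-1]",
                 main = "PIP fit: fitted vs reference", ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

# polynomial rolling hash (hex), used for the coefficient-file basis checksum
fnv1a <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

basis_checksum <- function(basis) {
  fnv1a(paste(basis$n_atoms, basis$degree_max,
              paste(basis$keys, collapse = ";"), sep = "|"))
}

#' Write / read a coefficient file
#'
#' Plain-text coefficients, one `index value` pair per line, preceded by a
#' header recording the basis checksum, lambda, maximum degree and gradient
#' weight so a coefficient set cannot silently be applied to the wrong basis.
#'
#' @param fit a [pip_fit()].
#' @param path file path.
#' @param basis the `pip_basis` the coefficients belong to (checked against
#'   the stored checksum on read).
#' @return `write_coefficients`: `path` invisibly; `read_coefficients`: a
#'   `pip_fit` (without training metrics).
#' @export
write_coefficients <- function(fit, path) {
  stopifnot(inherits(fit, "pip_fit"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("# pipfrag coefficients"),
    paste0("# basis_checksum ", basis_checksum(fit$basis)),
    paste0("# lambda ", format(fit$lambda, digits = 17)),
    paste0("# degree_max ", fit$basis$degree_max),
    paste0("# gradient_weight ", format(fit$gradient_weight, digits = 17)),
    paste0("# shift ", format(fit$shift, digits = 17))), con)
  writeLines(sprintf("%d %.17g", seq_along(fit$coefficients),
                     fit$coefficients), con)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path, basis) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  getf <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (!length(ln)) stop("coefficient file missing header field ", key, call. = FALSE)
    sub(paste0("^# ", key, " "), "", ln[1L])
  }
  if (getf("basis_checksum") != basis_checksum(basis))
    stop("coefficient file checksum does not match the supplied basis", call. = FALSE)
  parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  coefs <- as.numeric(parts[, 2L])[order(as.integer(parts[, 1L]))]
  if (length(coefs) != basis$n_pip)
    stop("coefficient count does not match basis size", call. = FALSE)
  structure(list(coefficients = coefs, basis = basis,
                 lambda = as.numeric(getf("lambda")),
                 gradient_weight = as.numeric(getf("gradient_weight")),
                 svd_tol = NA_real_, shift = as.numeric(getf("shift")),
                 rank = NA_integer_, n_energy = NA_integer_,
                 n_gradient = NA_integer_, rmse = NA_real_, rmsg = NA_real_),
            class = "pip_fit")
}
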