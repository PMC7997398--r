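#' Dataset of geometries with energies and optional gradients
#'
#' A fitting dataset: a list of records, each holding a [geometry()], an
#' energy in \eqn{cm^{-1}}, and optionally a Cartesian gradient of 3N
#' components in \eqn{cm^{-1}}/bohr (flattened atom-major). All records must
#' share the same atom count and species ordering; the atom numbering of the
#' records is the parent numbering that fragments refer to.
#'
#' @param records list of lists with elements `geometry`, `energy`, and
#'   optionally `gradient`.
#' @return An object of class `pip_dataset`.
#' @export
pip_dataset <- function(records) {
  if (!length(records)) stop("dataset must contain at least one record", call. = FALSE)
  ref <- records[[1L]]$geometry
  if (!inherits(ref, "pip_geometry")) stop("records need a 'geometry' element", call. = FALSE)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    g <- rec$geometry
    if (!inherits(g, "pip_geometry") || g$n_atoms != ref$n_atoms ||
        !identical(g$species, ref$species))
      stop("record ", k, ": all geometries must share one atom count and species order",
           call. = FALSE)
    if (is.null(rec$energy) || !is.finite(rec$energy))
      stop("record ", k, ": missing or non-finite energy", call. = FALSE)
    if (!is.null(rec$gradient) && length(rec$gradient) != 3L * g$n_atoms)
      stop("record ", k, ": gradient must have 3N = ", 3L * g$n_atoms,
           " components", call. = FALSE)
  }
  structure(list(records = records, n_atoms = ref$n_atoms, species = ref$species),
            class = "pip_dataset")
}

#' @export
print.pip_dataset <- function(x, ...) {
  ng <- sum(vapply(x$records, function(r) !is.null(r$gradient), logical(1)))
  e <- energies(x)
  cat("<pip_dataset> ", length(x$records), " records, ", x$n_atoms, " atoms (",
      paste(x$species, collapse = " "), ")\n", sep = "")
  cat("  energies [cm^-1]: ", format(min(e), digits = 6), " .. ",
      format(max(e), digits = 6), "; records with gradients: ", ng, "\n", sep = "")
  invisible(x)
}

#' @export
length.pip_dataset <- function(x) length(x$records)

#' Energies of a dataset
#' @param ds a [pip_dataset()].
#' @return Numeric vector of record energies (\eqn{cm^{-1}}).
#' @export
energies <- function(ds) {
  vapply(ds$records, function(r) r$energy, numeric(1))
}

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Read / write dataset files
#'
#' The dataset file is a concatenation of XYZ-style frames:
#' ```
#' N
#' ENERGY <energy in cm^-1>
#' <El> <x> <y> <z>          (N lines)
#' GRADIENT                  (optional sentinel)
#' <gx> <gy> <gz>            (N lines, cm^-1/bohr, same atom order)
#' ```
#' Coordinates are bohr by default; `units = "angstrom"` converts on read
#' (and back on write). Gradients are always per bohr. Energies are opaque
#' \eqn{cm^{-1}} values (absolute or relative to any reference).
#'
#' @param path file path.
#' @param units `"bohr"` or `"angstrom"` for the coordinate columns.
#' @return `read_dataset`: a [pip_dataset()]. `write_dataset`: `path`, invisibly.
#' @export
read_dataset <- function(path, units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  lines <- readLines(path)
  scale <- if (units == "angstrom") BOHR_PER_ANGSTROM else 1
  recs <- list()
  i <- 1L
  nref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 2L)
      stop("line ", i, ": expected an atom count", call. = FALSE)
    if (is.na(nref)) nref <- n
    if (n != nref)
      stop("line ", i, ": inconsistent atom count (", n, " vs ", nref, ")",
           call. = FALSE)
    if (i + 1L > length(lines)) stop("line ", i + 1L, ": missing energy line", call. = FALSE)
    etoks <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    ei <- suppressWarnings(as.numeric(etoks))
    ei <- ei[!is.na(ei)]
    if (!length(ei)) stop("line ", i + 1L, ": missing energy", call. = FALSE)
    energy <- ei[[1L]]
    if (i + 1L + n > length(lines)) stop("line ", i + 2L, ": truncated frame", call. = FALSE)
    sp <- character(n); xyz <- matrix(0, n, 3L)
    for (a in seq_len(n)) {
      toks <- strsplit(trimws(lines[i + 1L + a]), "\\s+")[[1]]
      if (length(toks) < 4L)
        stop("line ", i + 1L + a, ": malformed atom line", call. = FALSE)
      sp[a] <- toks[1L]
      v <- suppressWarnings(as.numeric(toks[2:4]))
      if (anyNA(v)) stop("line ", i + 1L + a, ": malformed coordinates", call. = FALSE)
      xyz[a, ] <- v
    }
    i <- i + 2L + n
    grad <- NULL
    if (i <= length(lines) && toupper(trimws(lines[i])) == "GRADIENT") {
      i <- i + 1L
      gm <- matrix(0, n, 3L)
      for (a in seq_len(n)) {
        if (i > length(lines))
          stop("line ", i, ": gradient block truncated (need ", n, " lines)",
               call. = FALSE)
        toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        v <- suppressWarnings(as.numeric(toks))
        if (length(v) != 3L || anyNA(v))
          stop("line ", i, ": gradient line must hold exactly 3 numbers",
               call. = FALSE)
        gm[a, ] <- v
        i <- i + 1L
      }
      grad <- as.vector(t(gm))
    }
    recs[[length(recs) + 1L]] <-
      list(geometry = geometry(xyz * scale, sp), energy = energy, gradient = grad)
  }
  if (!length(recs)) stop("no frames found in ", path, call. = FALSE)
  pip_dataset(recs)
}

#' @rdname read_dataset
#' @param ds a [pip_dataset()] to write.
#' @export
write_dataset <- function(ds, path, units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  stopifnot(inherits(ds, "pip_dataset"))
  scale <- if (units == "angstrom") 1 / BOHR_PER_ANGSTROM else 1
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in ds$records) {
    g <- rec$geometry
    writeLines(c(as.character(g$n_atoms),
                 sprintf("ENERGY %.10f", rec$energy)), con)
    writeLines(sprintf("%-3s %18.12f %18.12f %18.12f", g$species,
                       g$coords[, 1] * scale, g$coords[, 2] * scale,
                       g$coords[, 3] * scale), con)
    if (!is.null(rec$gradient)) {
      writeLines("GRADIENT", con)
      gm <- matrix(rec$gradient, ncol = 3L, byrow = TRUE)
      writeLines(sprintf("%18.12f %18.12f %18.12f", gm[, 1], gm[, 2], gm[, 3]), con)
    }
  }
  invisible(path)
}
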