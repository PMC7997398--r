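#' Build a recursive evaluation scheme for a basis
#'
#' Compiles a basis into an ordered instruction list in which every entry is
#' computed from previously computed entries: monomials are factored, where
#' the sub-monomial exists in the basis, as (earlier monomial) x (one Morse
#' variable), and each PIP is the sum of its orbit's monomial entries (the
#' explicit orbit-sum fallback when no factorization is available). The
#' scheme evaluates to exactly the orbit-sum definition of every PIP; it is
#' the serializable artifact standing in for generated evaluation source
#' code.
#'
#' @param basis a `pip_basis`.
#' @return An object of class `pip_scheme`: instruction vectors `type`
#'   (`"const"`, `"var"`, `"prodvar"`, `"prod"`, `"sum"`), `arg1`, `arg2`
#'   (instruction or variable indices; for `"sum"`, `arg1` is a list of
#'   instruction indices), and `pip_entry`, the instruction index holding
#'   each PIP's value.
#' @export
build_evaluation_scheme <- function(basis) {
  stopifnot(inherits(basis, "pip_basis"))
  M <- basis$mono_vars
  nm <- nrow(M)
  deg <- rowSums(M > 0L)
  base <- basis$n_pairs + 1
  # encode each monomial over its nonzero entries only, so that dropping the
  # last (largest) variable is exact integer arithmetic on the code
  codes <- numeric(nm)
  for (c in seq_len(ncol(M))) {
    nz <- M[, c] > 0L
    codes[nz] <- codes[nz] * base + M[nz, c]
  }
  lookup <- new.env(hash = TRUE, parent = emptyenv())

  type <- character(0); arg1 <- list(); arg2 <- integer(0)
  mono_entry <- integer(nm)
  add <- function(ty, a1, a2 = NA_integer_) {
    type[[length(type) + 1L]] <<- ty
    arg1[[length(arg1) + 1L]] <<- a1
    arg2[[length(arg2) + 1L]] <<- a2
    length(type)
  }
  # monomials in stored order (PIPs are degree-ordered, so sub-monomials of
  # lower degree, when present, have already been emitted)
  for (i in seq_len(nm)) {
    vars <- M[i, ][M[i, ] > 0L]
    if (deg[i] == 0L) {
      mono_entry[i] <- add("const", 1)
    } else if (deg[i] == 1L) {
      mono_entry[i] <- add("var", vars)
    } else {
      prefix_code <- (codes[i] - vars[deg[i]]) / base
      hit <- get0(as.character(prefix_code), envir = lookup)
      if (!is.null(hit)) {
        mono_entry[i] <- add("prodvar", hit, vars[deg[i]])
      } else {
        mono_entry[i] <- add("prod", vars)
      }
    }
    assign(as.character(codes[i]), mono_entry[i], envir = lookup)
  }
  pip_entry <- integer(basis$n_pip)
  for (p in seq_len(basis$n_pip)) {
    members <- mono_entry[basis$mono_pip == p]
    pip_entry[p] <- if (length(members) == 1L) members else add("sum", members)
  }
  structure(list(type = type, arg1 = arg1, arg2 = arg2,
                 pip_entry = pip_entry, n_pairs = basis$n_pairs,
                 n_pip = basis$n_pip),
            class = "pip_scheme")
}

#' @export
print.pip_scheme <- function(x, ...) {
  cat("<pip_scheme> ", length(x$type), " instructions for ", x$n_pip,
      " PIPs in ", x$n_pairs, " pair variables\n", sep = "")
  cat("  instruction mix: ",
      paste(names(table(x$type)), table(x$type), sep = ":", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a compiled scheme at a Morse vector
#'
#' @param scheme a `pip_scheme` from [build_evaluation_scheme()].
#' @param morse numeric Morse vector of length `scheme$n_pairs`.
#' @return Numeric vector of PIP values (identical, up to floating-point
#'   reassociation, to [evaluate_basis()] on the originating basis).
#' @export
evaluate_scheme <- function(scheme, morse) {
  stopifnot(inherits(scheme, "pip_scheme"))
  if (length(morse) != scheme$n_pairs)
    stop("morse vector must have length ", scheme$n_pairs, call. = FALSE)
  vals <- numeric(length(scheme$type))
  for (i in seq_along(scheme$type)) {
    vals[i] <- switch(scheme$type[i],
      const   = 1,
      var     = morse[scheme$arg1[[i]]],
      prodvar = vals[scheme$arg1[[i]]] * morse[scheme$arg2[[i]]],
      prod    = prod(morse[scheme$arg1[[i]]]),
      sum     = sum(vals[scheme$arg1[[i]]]))
  }
  vals[scheme$pip_entry]
}

#' Serialize / restore a basis as structured text
#'
#' Writes a `pip_basis` (with its compiled evaluation scheme) to a JSON file:
#' per PIP its index, degree, and orbit exponent maps over parent pair
#' indices, plus the scheme instructions and the fragmentation metadata.
#' `read_basis` reconstructs an equivalent basis object.
#'
#' @param basis a `pip_basis`.
#' @param path file path (`.json`).
#' @return `write_basis`: `path`, invisibly. `read_basis`: a `pip_basis`.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "pip_basis"))
  scheme <- build_evaluation_scheme(basis)
  pips <- lapply(seq_len(basis$n_pip), function(p) {
    rows <- which(basis$mono_pip == p)
    orbit <- lapply(rows, function(r) {
      v <- basis$mono_vars[r, ]
      as.integer(v[v > 0L])
    })
    list(index = p, degree = basis$pip_degree[p], orbit = orbit,
         provenance = basis$provenance[[p]])
  })
  obj <- list(
    format = "pipfrag-basis-1",
    n_atoms = basis$n_atoms,
    degree_max = basis$degree_max,
    duplicates = basis$duplicates,
    fragments = lapply(basis$fragments, function(f)
      list(atoms = f$atoms, blocks = f$blocks)),
    sym = list(atoms = basis$sym$atoms, blocks = basis$sym$blocks),
    pips = pips,
    scheme = list(type = scheme$type,
                  arg1 = scheme$arg1,
                  arg2 = scheme$arg2,
                  pip_entry = scheme$pip_entry)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "pipfrag-basis-1"))
    stop("not a pipfrag basis file: ", path, call. = FALSE)
  n_atoms <- as.integer(obj$n_atoms)
  dmax <- max(as.integer(obj$degree_max), 1L)
  n_pairs <- (n_atoms * (n_atoms - 1L)) %/% 2L
  base <- n_pairs + 1
  fragments <- lapply(obj$fragments, function(f)
    fragment_spec(unlist(f$atoms), unlist(f$blocks)))
  n_pip <- length(obj$pips)
  mono_vars <- list(); mono_pip <- list()
  pip_degree <- integer(n_pip); keys <- character(n_pip)
  rep_code <- numeric(n_pip); provenance <- vector("list", n_pip)
  for (p in seq_len(n_pip)) {
    pip <- obj$pips[[p]]
    pip_degree[p] <- as.integer(pip$degree)
    provenance[[p]] <- as.integer(unlist(pip$provenance))
    orbit <- lapply(pip$orbit, function(v) sort(as.integer(unlist(v))))
    rows <- t(vapply(orbit, function(v) c(v, rep.int(0L, dmax - length(v))),
                     integer(dmax)))
    k <- pip_degree[p]
    codes <- if (k == 0L) 0 else
      sort(encode_rows(rows[, seq_len(k), drop = FALSE], base))
    keys[p] <- paste0(pip_degree[p], ":",
                      if (pip_degree[p] == 0L) "" else paste(codes, collapse = ","))
    rep_code[p] <- if (pip_degree[p] == 0L) 0 else codes[1L]
    mono_vars[[p]] <- rows
    mono_pip[[p]] <- rep.int(p, nrow(rows))
  }
  structure(list(
    n_atoms = n_atoms, n_pairs = as.integer(n_pairs),
    degree_max = as.integer(obj$degree_max),
    n_pip = n_pip, pip_degree = pip_degree,
    mono_vars = do.call(rbind, mono_vars),
    mono_pip = unlist(mono_pip, use.names = FALSE),
    keys = keys, rep_code = rep_code,
    vars_used = sort(unique(unlist(lapply(mono_vars, function(M) M[M > 0L])))),
    sym = fragment_spec(unlist(obj$sym$atoms), unlist(obj$sym$blocks)),
    fragments = fragments,
    provenance = provenance,
    duplicates = as.integer(obj$duplicates),
    renumbering = NULL
  ), class = "pip_basis")
}
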