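# shared builders for the test suite

# random non-degenerate geometry: reference shape plus Gaussian displacement
random_geometry <- function(species, scale = 2.2, jitter = 0.35) {
  n <- length(species)
  repeat {
    coords <- matrix(stats::rnorm(3 * n, sd = scale), ncol = 3) +
      matrix(stats::rnorm(3 * n, sd = jitter), ncol = 3)
    g <- geometry(coords, species)
    if (min(pair_distances(g)) > 0.8) return(g)
  }
}

# the in-paper fragmentation schemes, used across merge/acceptance tests
nma_fragments_2 <- function() list(
  fragment_spec(c(1, 2, 3, 4, 5, 6, 7, 8, 9), c(3, 1, 1, 1, 1, 1, 1)),
  fragment_spec(c(10, 11, 12, 4, 5, 6, 7, 8, 9), c(3, 1, 1, 1, 1, 1, 1)))

nma_fragments_3 <- function() list(
  fragment_spec(c(1, 2, 3, 4, 5, 6, 8), c(3, 1, 1, 1, 1)),
  fragment_spec(c(10, 11, 12, 5, 7, 8, 9), c(3, 1, 1, 1, 1)),
  fragment_spec(c(4, 5, 6, 7, 8, 9)))

nma_full_spec <- function()
  fragment_spec(c(1, 2, 3, 10, 11, 12, 4, 5, 6, 7, 8, 9),
                c(3, 3, 1, 1, 1, 1, 1, 1))

glycine_fragments <- function() list(
  fragment_spec(c(2, 3, 5, 6, 1, 4), c(2, 2, 1, 1)),
  fragment_spec(c(5, 6, 8, 9, 4, 7, 10), c(2, 2, 1, 1, 1)),
  fragment_spec(c(2, 3, 8, 9, 1, 7, 10), c(2, 2, 1, 1, 1)))

glycine_full_spec <- function()
  fragment_spec(c(2, 3, 5, 6, 8, 9, 1, 4, 7, 10), c(2, 2, 2, 1, 1, 1, 1))

# random symmetry spec on n atoms: random block composition
random_blocks <- function(n) {
  sizes <- integer(0); left <- n
  while (left > 0) {
    s <- sample.int(left, 1)
    sizes <- c(sizes, s); left <- left - s
  }
  sizes
}

# random consistent fragmentation of a parent: choose parent blocks, then
# fragments as unions of whole blocks (so the permutational-consistency rule
# holds by construction)
random_fragmentation <- function(n_parent, n_frag = 2) {
  repeat {
    blocks <- random_blocks(n_parent)
    atoms <- sample.int(n_parent)
    ends <- cumsum(blocks); starts <- c(1, head(ends, -1) + 1)
    blist <- mapply(function(s, e) atoms[s:e], starts, ends, SIMPLIFY = FALSE)
    frags <- vector("list", n_frag)
    okall <- TRUE
    for (f in seq_len(n_frag)) {
      take <- which(stats::runif(length(blist)) < 0.7)
      if (length(take) < 1 || sum(lengths(blist[take])) < 2) { okall <- FALSE; break }
      frags[[f]] <- fragment_spec(unlist(blist[take]),
                                  lengths(blist[take]))
    }
    if (!okall) next
    covered <- sort(unique(unlist(lapply(frags, function(f) f$atoms))))
    parent <- fragment_spec(unlist(blist), lengths(blist))
    if (validate_fragmentation(parent, frags)$pass)
      return(list(parent = parent, fragments = frags))
  }
}

# quick full-length Morse vector with all entries usable (for basis algebra
# tests detached from any geometry)
random_morse <- function(n_pairs) stats::runif(n_pairs, 0.05, 0.95)
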