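# Brute-force combinatorial oracle on tiny explicit systems.
#
# A toy system is an explicit arrangement of typed units on a 1-D integer
# line, grouped into chains and free monomers.  Deterministic
# nearest-unvisited walks through such arrangements, enumerated over all
# starting units and over many arrangements, give an operational stand-in
# for the walk ensemble: the log count of distinct type sequences is an
# ordinal proxy for the statistical weight behind the closed-form entropy,
# and explicit bit encodings of the chain census bound the description-length
# estimates.  Everything here is validation-scale only (N <= a few dozen).

# Run code with a private RNG stream, leaving the caller's untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

type_labels <- function(n) {
  if (n == 4L) c("A", "C", "G", "U") else LETTERS[seq_len(n)]
}

#' Build an explicit toy arrangement of monomers and chains
#'
#' Places free monomers and chain molecules in a deterministic
#' seed-controlled order along a 1-D line of consecutive integer sites
#' (chains occupy consecutive sites).  Chain specs may give explicit
#' sequences (defined chains, repeated exactly) or lengths with
#' `random = TRUE` (sequences drawn uniformly over the alphabet under the
#' seed).
#'
#' @param n Alphabet size (type labels are `A C G U` for `n = 4`, otherwise
#'   leading capital letters).
#' @param monomer_counts Integer vector of length `n`: free monomers of each
#'   type.
#' @param chain_specs List of chain specifications; each element is either
#'   `list(seq = "ACGU", copies = 3)` (a defined sequence, possibly repeated)
#'   or `list(length = 4, copies = 2, random = TRUE)` (random sequences).
#' @param seed Integer seed controlling the arrangement (and any random
#'   sequences); the caller's RNG state is untouched.
#' @return A `"toy_system"`: `units` data frame (`site` from 0, `type`,
#'   `chain_id`, 0 marking free monomers), `chains` (list of type vectors),
#'   `n`, `labels`, and the per-type `composition`.
#' @export
build_toy_system <- function(n, monomer_counts = rep(0L, n),
                             chain_specs = list(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    abort_param("n", "must be a single integer >= 1")
  n <- as.integer(n)
  labels <- type_labels(n)
  if (length(monomer_counts) != n || any(monomer_counts < 0) ||
      any(monomer_counts != round(monomer_counts)))
    abort_param("monomer_counts",
                "must be n non-negative integer counts (one per type)")
  with_seed(seed, {
    chains <- list()
    for (spec in chain_specs) {
      copies <- if (is.null(spec$copies)) 1L else as.integer(spec$copies)
      if (copies < 1) abort_param("chain_specs", "copies must be >= 1")
      if (!is.null(spec$seq)) {
        s <- strsplit(spec$seq, "")[[1]]
        if (!all(s %in% labels))
          abort_param("chain_specs",
                      sprintf("sequence '%s' uses letters outside the %d-letter alphabet",
                              spec$seq, n))
        for (i in seq_len(copies)) chains[[length(chains) + 1L]] <- s
      } else if (isTRUE(spec$random)) {
        len <- as.integer(spec$length)
        if (is.na(len) || len < 1)
          abort_param("chain_specs", "random chains need a length >= 1")
        for (i in seq_len(copies))
          chains[[length(chains) + 1L]] <-
            sample(labels, len, replace = TRUE)
      } else {
        abort_param("chain_specs",
                    "each spec needs either `seq` or `length` + `random = TRUE`")
      }
    }
    free <- rep(labels, times = monomer_counts)
    # items: chains as blocks plus individual free monomers, shuffled
    items <- c(chains, as.list(free))
    item_chain <- c(seq_along(chains), rep(0L, length(free)))
    if (length(items) == 0)
      abort_param("monomer_counts", "system must contain at least one unit")
    ord <- sample(seq_along(items))
    types <- unlist(items[ord], use.names = FALSE)
    chain_id <- rep(item_chain[ord], vapply(items[ord], length, 1L))
    units <- data.frame(site = seq_along(types) - 1L, type = types,
                        chain_id = chain_id, stringsAsFactors = FALSE)
    comp <- vapply(labels, function(l) sum(types == l), 0L)
    structure(list(units = units, chains = chains, n = n, labels = labels,
                   composition = comp, N = nrow(units)),
              class = "toy_system")
  })
}

#' Deterministic nearest-unvisited walk through a toy system
#'
#' From the starting unit, each step moves to the unvisited unit at minimal
#' line distance, skipping already-visited units; ties break towards the
#' lower site index.  The walk stops after visiting all `N` units, so the
#' visit list is a permutation of the sites.  Randomness enters only through
#' the choice of start and the arrangement, never the stepping rule.
#'
#' @param system A [build_toy_system()] result.
#' @param start Site index (0-based) of the starting unit.
#' @return A `"walk_record"`: `start`, `sites` (visit order), and `types`
#'   (the walk read as a string over the alphabet).
#' @export
sample_walk <- function(system, start) {
  stopifnot(inherits(system, "toy_system"))
  sites <- system$units$site
  if (!is.numeric(start) || length(start) != 1L || !(start %in% sites))
    abort_param("start", "must be a valid site index of the system")
  N <- system$N
  visited <- logical(N)
  order_out <- integer(N)
  cur <- match(start, sites)
  for (step in seq_len(N)) {
    order_out[step] <- cur
    visited[cur] <- TRUE
    if (step < N) {
      remaining <- which(!visited)
      d <- abs(sites[remaining] - sites[cur])
      # minimal distance, ties to the lower site index
      best <- remaining[order(d, sites[remaining])][1]
      cur <- best
    }
  }
  structure(list(start = start, sites = sites[order_out],
                 types = paste(system$units$type[order_out], collapse = "")),
            class = "walk_record")
}

#' Log statistical weight of the walk ensemble over arrangements
#'
#' Enumerates the deterministic walk from every starting unit of every
#' supplied arrangement, counts the distinct type sequences `D` produced,
#' and returns `ln D` — an ordinal proxy for the variety of the walk
#' ensemble.  All arrangements must share one composition (same per-type
#' unit counts and chain-length multiset).
#'
#' @param systems A list of [build_toy_system()] results with a common
#'   composition, e.g. the same spec built under different seeds.
#' @return `ln D`, dimensionless (units of k).
#' @export
walk_ensemble_log_weight <- function(systems) {
  if (!is.list(systems) || length(systems) == 0)
    abort_param("systems", "must be a non-empty list of toy systems")
  ref <- systems[[1]]
  lens <- function(s) sort(vapply(s$chains, length, 1L))
  seqs <- character(0)
  for (s in systems) {
    stopifnot(inherits(s, "toy_system"))
    if (s$N != ref$N || !identical(lens(s), lens(ref)))
      abort_param("systems", "all arrangements must share one composition/chain spec")
    for (st in s$units$site) seqs <- c(seqs, sample_walk(s, st)$types)
  }
  log(length(unique(seqs)))
}

#' Exact multinomial mixing entropy
#'
#' `ln( N! / prod(N_i!) )` via log-gamma: the exact log count of
#' distinguishable orderings of a multiset, against which the Stirling-limit
#' mixing term `N * sum(r ln(1/r))` converges (within 1% by N = 1e4).
#'
#' @param counts Non-negative integer counts per type, total > 0.
#' @return Entropy in units of k.
#' @export
multinomial_mixing_entropy <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || sum(counts) <= 0)
    abort_param("counts", "must be non-negative with a positive total")
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
}

#' Concrete minimal bit encoding of a toy chain census
#'
#' Computes both encoding strategies explicitly on an enumerable system and
#' returns the smaller: (a) one counter of `ceiling(log2(1 + max count))`
#' bits for each of the `n^L` possible sequences; (b) every chain sequence
#' spelled out at `ceiling(log2 n)` bits per unit.  Free monomers are listed
#' explicitly under either strategy.  Requires all chains to share one
#' length `L` with `n^L <= 1e6`.
#'
#' @param system A [build_toy_system()] result.
#' @return Total bits (strategy minimum plus the monomer listing).
#' @export
explicit_encoding_length <- function(system) {
  stopifnot(inherits(system, "toy_system"))
  bits_per_unit <- max(1, ceiling(log2(system$n)))
  mono <- sum(system$units$chain_id == 0)
  mono_bits <- mono * bits_per_unit
  if (length(system$chains) == 0) return(mono_bits)
  lens <- vapply(system$chains, length, 1L)
  if (length(unique(lens)) != 1L)
    abort_param("system", "all chains must share one length")
  L <- lens[1]
  n_perm <- system$n^L
  if (n_perm > 1e6)
    abort_param("system", "n^L too large to enumerate (limit 1e6)")
  census <- table(vapply(system$chains, paste, "", collapse = ""))
  counter_bits <- ceiling(log2(1 + max(census)))
  bits_a <- n_perm * counter_bits
  bits_b <- sum(lens) * bits_per_unit
  mono_bits + min(bits_a, bits_b)
}
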