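# Minimal-description-length complexity estimates, in bits.
#
# Two encoding strategies for the chain census:
#   (a) permutation list: enumerate all n^L possible sequences and store, for
#       each, how many chains carry it -> c1 ~ n^L * log2(#chains);
#   (b) explicit list: write out every chain sequence -> c2 ~ (total chain
#       units) * log2 n.
# The system's complexity is min(c1, c2).  n^L overflows double precision
# quickly, so every estimate also carries its decimal log, computed in the
# log domain; comparisons use the logs.

log2n <- function(n) if (n <= 1) 0 else log2(n)

# log10(10^a + 10^b), safe for -Inf and very large magnitudes.
log10_sum <- function(a, b) {
  if (is.infinite(a) && a < 0) return(b)
  if (is.infinite(b) && b < 0) return(a)
  m <- max(a, b)
  m + log10(10^(a - m) + 10^(b - m))
}

new_complexity_estimate <- function(c1, c2, log10_c1, log10_c2) {
  strategy <- if (log10_c1 <= log10_c2) "a" else "b"   # ties resolve to (a)
  structure(
    list(c1_bits = c1, c2_bits = c2,
         c_bits = if (strategy == "a") c1 else c2,
         log10_c1 = log10_c1, log10_c2 = log10_c2,
         log10_c = min(log10_c1, log10_c2),
         strategy = strategy),
    class = "complexity_estimate")
}

check_cx_args <- function(n, L = NULL, N = NULL, M = NULL, p = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    abort_param("n", "must be a single number >= 1")
  if (!is.null(L) && (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1))
    abort_param("L", "must be a single number >= 1")
  if (!is.null(N) && (!is.numeric(N) || length(N) != 1L || is.na(N) || N <= 0))
    abort_param("N", "must be a single positive number")
  if (!is.null(M) && (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 0))
    abort_param("M", "must be a single number >= 0")
  if (!is.null(p) && (!is.numeric(p) || length(p) != 1L || is.na(p) ||
                      p < 0 || p > 1))
    abort_param("p", "must be a single number in [0, 1]")
}

# Decimal log of the strategy-(a) census term n^L * log2(count).
# count <= 1 (an empty or single-entry census) is freely compressible and
# clamped to zero cost, which keeps the p -> 0 limit at the defined-chain
# cost instead of diverging to -Inf.
log10_census_a <- function(n, L, count) {
  if (n <= 1 || count <= 1) return(-Inf)
  L * log10(n) + log10(log2(count))
}

#' Description length of one fully defined chain
#'
#' `c = L * log2(n)` bits: the cost of spelling out a single sequence of `L`
#' units over an `n`-letter alphabet (2 bits per unit for RNA's `n = 4`).
#'
#' @param L Chain length in units (>= 1, fractional allowed).
#' @param n Alphabet size (>= 1).
#' @return Description length in bits.
#' @export
defined_chain_complexity <- function(L, n) {
  check_cx_args(n, L = L)
  L * log2n(n)
}

#' Strategy-(a) complexity of a fully random chain population
#'
#' Permutation-census encoding: list all `n^L` possible length-`L` sequences
#' and store for each an integer up to the chain count `N/L`, giving
#' `c1 ~ n^L * log2(N/L)` bits.  A census with at most one chain
#' (`N/L <= 1`) costs nothing and returns 0 with a warning.
#'
#' @param n Alphabet size (>= 1).
#' @param L Chain length (>= 1).
#' @param N Total number of units (> 0).
#' @return Bits (`Inf` once `n^L` exceeds double range; use
#'   [system_complexity()] for the overflow-safe log-scale representation).
#' @export
c1_random <- function(n, L, N) {
  check_cx_args(n, L = L, N = N)
  if (N / L <= 1) {
    warning("degenerate chain census (N/L <= 1): complexity clamped to 0")
    return(0)
  }
  if (n <= 1) return(0)
  n^L * log2(N / L)
}

#' Strategy-(b) complexity: explicit list of every chain sequence
#'
#' `c2 ~ N * log2(n)` bits: all chains together contain `N` units, each
#' costing `log2 n` bits to spell out.
#'
#' @inheritParams c1_random
#' @return Bits.
#' @export
c2_explicit <- function(N, n) {
  check_cx_args(n, N = N)
  N * log2n(n)
}

#' Strategy-(a) complexity of a mixed defined/random population
#'
#' A fraction `p` of the chains is random and `1 - p` share one defined
#' sequence; free monomers at spacing `M` dilute the census.  The defined
#' sequence costs `L*log2(n)` bits and the random census costs
#' `n^L * log2(p*N/(L+M))` bits:
#' `c1 ~ L*log2(n) + n^L * log2(p*N/(L+M))`.
#' When `p = 0` or the census count `p*N/(L+M)` is at most 1, the census term
#' is clamped to 0 and the result degrades gracefully to the defined-chain
#' cost.
#'
#' @inheritParams c1_random
#' @param p Random-chain fraction in `[0, 1]`.
#' @param M Mean monomer spacing (>= 0).
#' @return Bits.
#' @export
c1_mixed <- function(n, L, p, N, M = 0) {
  check_cx_args(n, L = L, N = N, M = M, p = p)
  complexity_from_lengths(n, L, L, L, p, N, M)$c1_bits
}

#' Strategy-(b) complexity of a mixed defined/random population
#'
#' `c2 ~ L*log2(n) + L * (p*N/(L+M)) * log2(n)`: one defined sequence plus an
#' explicit listing of the `p*N/(L+M)` random chains of `L` units each.
#' With `M = 0` this is exactly the monomer-free form
#' `L*log2(n) + p*N*log2(n)`.
#'
#' @inheritParams c1_mixed
#' @return Bits.
#' @export
c2_mixed <- function(n, L, p, N, M = 0) {
  check_cx_args(n, L = L, N = N, M = M, p = p)
  complexity_from_lengths(n, L, L, L, p, N, M)$c2_bits
}

# Shared core: complexity of a population whose defined and random chains may
# have different mean lengths.  The defined term uses the defined length, the
# census exponent uses the random length, and the census count uses the
# effective mean length L_bar.  With all three equal this is exactly the
# c1_mixed/c2_mixed pair.
complexity_from_lengths <- function(n, L_def, L_rand, L_bar, p, N, M) {
  count <- if (p > 0) p * N / (L_bar + M) else 0
  def_bits <- L_def * log2n(n)
  l10_def <- log10(def_bits)
  l10_a <- log10_census_a(n, L_rand, count)
  log10_c1 <- log10_sum(l10_def, l10_a)
  c1 <- def_bits + if (is.finite(l10_a)) 10^l10_a else 0    # Inf-safe
  c2_census <- if (count > 1) L_rand * count * log2n(n) else 0
  c2 <- def_bits + c2_census
  log10_c2 <- log10_sum(l10_def, log10(c2_census))
  new_complexity_estimate(c1, c2, log10_c1, log10_c2)
}

#' System complexity: the smaller of the two encoding strategies
#'
#' Evaluates both [c1_mixed()] (permutation census) and [c2_mixed()]
#' (explicit sequence list) and returns the minimum with its strategy label.
#' The comparison is performed on decimal logs, so it remains correct when
#' either estimate overflows double precision; the log-scale value
#' (`log10_c`) is always finite and safe.  Ties resolve to strategy `"a"`.
#'
#' @inheritParams c1_mixed
#' @return A `"complexity_estimate"` with fields `c1_bits`, `c2_bits`,
#'   `c_bits`, `log10_c1`, `log10_c2`, `log10_c`, `strategy`.
#' @examples
#' system_complexity(n = 4, L = 20, p = 0.5, N = moles_to_units(1), M = 10)
#' @export
system_complexity <- function(n, L, p, N, M = 0) {
  check_cx_args(n, L = L, N = N, M = M, p = p)
  complexity_from_lengths(n, L, L, L, p, N, M)
}

#' @export
print.complexity_estimate <- function(x, ...) {
  fmt <- function(v, l10) {
    if (is.finite(v)) sprintf("%.6g", v) else sprintf("10^%.6g", l10)
  }
  cat("Description-length complexity estimate\n")
  cat(sprintf("  c1 (permutation census) : %s bit\n", fmt(x$c1_bits, x$log10_c1)))
  cat(sprintf("  c2 (explicit sequences) : %s bit\n", fmt(x$c2_bits, x$log10_c2)))
  cat(sprintf("  c  = min = %s bit  (strategy %s, log10 c = %.6g)\n",
              fmt(x$c_bits, x$log10_c), x$strategy, x$log10_c))
  invisible(x)
}
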