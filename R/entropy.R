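# Sequential entropy of the walk ensemble.
#
# S_r/k = W * [ M * sum_i r_i ln(1/r_i)          (monomer mixing)
#             + sum_j a_j ln(1/a_j)              (chain-contact variety)
#             + (L/2) * sum_k p_k ln(1/p_k) ]    (sequence predictability)
# with W = N / (M + L/2), the expected number of chain encounters per walk.
# This grouping reproduces all four limiting closed forms exactly
# (pure monomer, crystals, random chains, defined chains).

# x * ln(1/x) with the continuous extension 0 * ln(1/0) == 0.
xlog1x <- function(x) ifelse(x > 0, -x * log(x), 0)

new_entropy_breakdown <- function(term_mixing, term_contact, term_sequence, W) {
  S_r_k <- term_mixing + term_contact + term_sequence
  structure(
    list(term_mixing = term_mixing, term_contact = term_contact,
         term_sequence = term_sequence, W = W,
         S_r_k = S_r_k, S_r_JK = S_r_k * .kB,
         order_KJ = if (S_r_k > 0) 1 / (S_r_k * .kB) else Inf),
    class = "entropy_breakdown")
}

#' Sequential entropy with explicit composition, accessibility and
#' predictability profiles
#'
#' Evaluates the general three-term sequential entropy of the walk ensemble
#' for a state carrying explicit `r`, `a` and `pk` profiles:
#' mixing term `k*M*W*sum(r*ln(1/r))`, contact term `k*W*sum(a*ln(1/a))`,
#' sequence term `k*(L/2)*W*sum(pk*ln(1/pk))`, with `W = N/(M + L/2)`.
#' Zero profile entries contribute nothing (`0*ln(1/0) == 0`).
#'
#' @param state A [system_state()] whose `pk` profile is set (composition and
#'   accessibility may be uniform-flagged, in which case the exact `ln n` /
#'   `ln L` reductions are used for those terms).
#' @return An `"entropy_breakdown"`: the three terms and total in units of k
#'   (`term_mixing`, `term_contact`, `term_sequence`, `S_r_k`), the total in
#'   J/K (`S_r_JK`), the order `order_KJ = 1/S_r_JK`, and `W`.
#' @export
entropy_general <- function(state) {
  stopifnot(inherits(state, "system_state"))
  if (is.null(state$pk))
    stop("state has no `pk` profile; use entropy_two_level() or ",
         "entropy_uniform() for the two-level/uniform reductions",
         call. = FALSE)
  W <- state$W
  mix <- W * state$M * sum(xlog1x(state$r))
  contact <- if (state$uniform_a) W * log(state$L) else W * sum(xlog1x(state$a))
  seqt <- W * (state$L / 2) * sum(xlog1x(state$pk))
  new_entropy_breakdown(mix, contact, seqt, W)
}

#' Sequential entropy for a two-level chain population
#'
#' A fraction `p` of the chains is fully random (`pk` uniform at `1/n`) and
#' the fraction `1 - p` shares one fully defined sequence (`pk = c(1, 0, ...)`,
#' which carries no sequence entropy).  The sequence term then reduces to
#' `k * p * (L/2) * W * ln n`; mixing and contact terms are as in
#' [entropy_general()].
#'
#' @param state A [system_state()]; its `pk` profile, if any, is ignored.
#' @param p Random-chain fraction; defaults to `state$p`.
#' @inherit entropy_general return
#' @export
entropy_two_level <- function(state, p = state$p) {
  stopifnot(inherits(state, "system_state"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    abort_param("p", "must be a single number in [0, 1]")
  W <- state$W
  mix <- W * state$M * sum(xlog1x(state$r))
  contact <- if (state$uniform_a) W * log(state$L) else W * sum(xlog1x(state$a))
  seqt <- p * (state$L / 2) * W * log(state$n)
  new_entropy_breakdown(mix, contact, seqt, W)
}

#' Sequential entropy for the fully uniform system
#'
#' The uniform-composition, uniform-accessibility, two-level closed form
#' `S_r/k = W * (M ln n + ln L + p (L/2) ln n)` with `W = N/(M + L/2)`.
#' This is the workhorse used by the parameter sweeps and the evolution
#' simulator.
#'
#' @param n Alphabet size (integer >= 1).
#' @param N Total number of units (> 0); see also [moles_to_units()].
#' @param L Mean chain length (>= 1, fractional allowed).
#' @param M Mean monomer spacing (>= 0).
#' @param p Random-chain fraction in `[0, 1]`.
#' @inherit entropy_general return
#' @examples
#' # Pure monomer limit, one mole of 4 types: S_r = k N ln 4 = 11.526 J/(K mol)
#' entropy_uniform(n = 4, N = moles_to_units(1), L = 1, M = 0, p = 1)$S_r_JK
#' @export
entropy_uniform <- function(n, N, L, M, p) {
  st <- make_uniform_state(n, N = N, L = L, M = M, p = p)
  entropy_two_level(st)
}

#' Closed-form sequential entropy of the four limiting cases
#'
#' The four characteristic states of a monomer/oligomer mixture and their
#' closed forms (in units of k):
#' * `"pure_monomer"`: monomers only (`L = 1`, `p = 1`) — `N ln n`;
#' * `"crystals"`: single-type blocks, no monomer — `(2N/L) ln L`;
#' * `"random_chains"`: random chains, no monomer — `(2N/L) ln L + N ln n`;
#' * `"defined_chains"`: one shared defined sequence, no monomer —
#'   `(2N/L) ln L`.
#'
#' @param case One of `"pure_monomer"`, `"crystals"`, `"random_chains"`,
#'   `"defined_chains"`.
#' @param n Alphabet size (ignored for `"crystals"` and `"defined_chains"`,
#'   whose forms are n-free).
#' @param N Total units (> 0).
#' @param L Mean chain length (>= 1); required for all cases but
#'   `"pure_monomer"`.
#' @return Entropy in units of k (multiply by 1.380649e-23 for J/K).
#' @export
limiting_case_entropy <- function(case = c("pure_monomer", "crystals",
                                           "random_chains", "defined_chains"),
                                  n, N, L = NULL) {
  case <- match.arg(case)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N <= 0)
    abort_param("N", "must be a single positive number")
  if (case == "pure_monomer") {
    if (!is.numeric(n) || n < 1) abort_param("n", "must be >= 1")
    return(N * log(n))
  }
  if (is.null(L) || !is.numeric(L) || length(L) != 1L || is.na(L) || L < 1)
    abort_param("L", "must be a single number >= 1 for chain/crystal cases")
  contact <- (2 * N / L) * log(L)
  switch(case,
         crystals = contact,
         defined_chains = contact,
         random_chains = {
           if (!is.numeric(n) || n < 1) abort_param("n", "must be >= 1")
           contact + N * log(n)
         })
}

#' Order of the system: reciprocal sequential entropy
#'
#' @param S_r_JK Sequential entropy in J/K (> 0).
#' @return Order in K/J, `1 / S_r_JK`.
#' @export
order_parameter <- function(S_r_JK) {
  if (!is.numeric(S_r_JK) || length(S_r_JK) != 1L || is.na(S_r_JK) ||
      S_r_JK < 0)
    abort_param("S_r_JK", "must be a single non-negative number")
  if (S_r_JK == 0)
    stop("sequential entropy is zero: the system has a single microstate ",
         "and infinite order; handle this degenerate case explicitly",
         call. = FALSE)
  1 / S_r_JK
}

#' Entropy gap between random ("dead") and defined ("living") chains
#'
#' The difference between the random-chain and defined-chain limiting cases
#' at equal chain length: `Delta S_r = k N ln n`, the monomer mixing entropy.
#' It measures the thermodynamic driving force towards losing sequence
#' definition.
#'
#' @param n Alphabet size (>= 1).
#' @param N Total units (> 0).
#' @return Entropy gap in units of k.
#' @export
living_dead_gap <- function(n, N) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    abort_param("n", "must be a single number >= 1")
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N <= 0)
    abort_param("N", "must be a single positive number")
  N * log(n)
}

#' Convert an entropy in units of k to J/K
#'
#' @param S_k Entropy in units of the Boltzmann constant.
#' @return Entropy in J/K (J/(K mol) when the system holds one mole of units).
#' @export
entropy_k_to_JK <- function(S_k) S_k * .kB

#' @export
print.entropy_breakdown <- function(x, ...) {
  cat("Sequential entropy of the walk ensemble\n")
  cat(sprintf("  mixing term   : %.6g k\n", x$term_mixing))
  cat(sprintf("  contact term  : %.6g k\n", x$term_contact))
  cat(sprintf("  sequence term : %.6g k\n", x$term_sequence))
  cat(sprintf("  S_r = %.6g k = %.6g J/K   (order 1/S_r = %.6g K/J)\n",
              x$S_r_k, x$S_r_JK, x$order_KJ))
  invisible(x)
}
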