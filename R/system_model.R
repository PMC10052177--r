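# Physical constants used throughout: entropies are computed dimensionless
# (units of k) and converted once at the end.
.kB <- 1.380649e-23      # Boltzmann constant, J/K (exact, SI 2019)
.NA <- 6.02214076e23     # Avogadro constant, 1/mol (exact, SI 2019)

.tol_sum <- 1e-12

abort_param <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Convert an amount in moles to an absolute number of units
#'
#' Multiplies by the Avogadro constant (6.02214076e23 per mole).  The
#' mean-field model works with absolute unit counts `N`; this helper lets
#' mole-scale systems ("one mol of units") be specified naturally.
#'
#' @param moles Non-negative amount in moles.
#' @return The corresponding number of units (a double; exact integer
#'   representation is not attempted at this scale).
#' @examples
#' moles_to_units(1)   # 6.02214076e23
#' @export
moles_to_units <- function(moles) {
  if (!is.numeric(moles) || length(moles) != 1L || is.na(moles) || moles < 0)
    abort_param("moles", "must be a single non-negative number")
  moles * .NA
}

#' Monomer alphabet with relative composition
#'
#' An alphabet is the set of `n` distinct monomer types together with their
#' relative contributions `r` (fractions summing to 1).  For RNA, `n = 4`
#' and equal composition gives `r = c(0.25, 0.25, 0.25, 0.25)`.
#'
#' @param n Number of distinct monomer types (integer >= 1).
#' @param r Optional numeric vector of `n` relative contributions in
#'   `[0, 1]` summing to 1.  Omitted means uniform composition `1/n`.
#' @return An object of class `"seq_alphabet"` with fields `n`, `r`, and
#'   `uniform` (flag: was `r` left implicit).
#' @export
alphabet <- function(n, r = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    abort_param("n", "must be a single integer >= 1")
  n <- as.integer(n)
  uniform <- is.null(r)
  if (uniform) {
    r <- rep(1 / n, n)
  } else {
    if (!is.numeric(r) || length(r) != n)
      abort_param("r", sprintf("must be a numeric vector of length n = %d", n))
    if (any(is.na(r)) || any(r < 0) || any(r > 1))
      abort_param("r", "entries must lie in [0, 1]")
    if (abs(sum(r) - 1) > .tol_sum)
      abort_param("r", sprintf("must sum to 1 (got %.15g)", sum(r)))
  }
  structure(list(n = n, r = r, uniform = uniform), class = "seq_alphabet")
}

#' Mean-field state of a monomer/oligomer mixture
#'
#' The parameter tuple describing a mixture of free monomers and oligomer
#' chains at one instant, as seen by the ensemble of nearest-neighbour walks
#' through the system:
#'
#' * `n`, `r` — alphabet size and composition (see [alphabet()]);
#' * `N` — total number of units (monomers plus chain units); accepts
#'   absolute counts or moles via `N_moles`;
#' * `L` — mean chain length in units (>= 1; fractional values permitted,
#'   all closed forms are continuous in `L`; `L = 1` means monomers only);
#' * `M` — mean number of free monomers encountered between two chain
#'   contacts on a walk (>= 0);
#' * `p` — fraction of chains with fully random sequences; the remaining
#'   `1 - p` share one fully defined sequence;
#' * `pk` — optional predictability profile: `pk[k]` is the probability that
#'   the k-th most likely unit type occupies a chain position (non-increasing,
#'   sums to 1); `c(1, 0, ...)` is fully defined, uniform is fully random;
#' * `a` — optional accessibility profile over `ceiling(L)` chain positions
#'   (non-negative, sums to 1); uniform accessibility needs no profile.
#'
#' The derived quantity `W = N / (M + L/2)` is the expected number of chain
#' encounters along one walk and is attached to the returned state.
#'
#' @param n Alphabet size, or a `"seq_alphabet"` object.
#' @param N Total number of units (> 0).  Exactly one of `N`, `N_moles`.
#' @param L Mean chain length (>= 1).
#' @param M Mean monomer spacing between chain encounters (>= 0).
#' @param p Random-chain fraction in `[0, 1]`.
#' @param r Optional composition vector, passed to [alphabet()].
#' @param pk Optional predictability profile (length `n`).
#' @param a Optional accessibility profile (length `ceiling(L)`).
#' @param N_moles Alternative to `N`: amount of units in moles.
#' @return An object of class `"system_state"`.
#' @seealso [make_uniform_state()] for the fully uniform convenience form.
#' @export
system_state <- function(n, N = NULL, L = 1, M = 0, p = 1,
                         r = NULL, pk = NULL, a = NULL, N_moles = NULL) {
  ab <- if (inherits(n, "seq_alphabet")) n else alphabet(n, r)
  if (is.null(N) == is.null(N_moles))
    abort_param("N", "exactly one of `N` (units) or `N_moles` must be given")
  if (!is.null(N_moles)) N <- moles_to_units(N_moles)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N <= 0)
    abort_param("N", "must be a single positive number")
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1)
    abort_param("L", "must be a single number >= 1")
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 0)
    abort_param("M", "must be a single number >= 0")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    abort_param("p", "must be a single number in [0, 1]")
  if (!is.null(pk)) {
    if (!is.numeric(pk) || length(pk) != ab$n)
      abort_param("pk", sprintf("must have length n = %d", ab$n))
    if (any(is.na(pk)) || any(pk < 0) || any(pk > 1))
      abort_param("pk", "entries must lie in [0, 1]")
    if (any(diff(pk) > .tol_sum))
      abort_param("pk", "must be non-increasing (pk[1] is the most likely unit)")
    if (abs(sum(pk) - 1) > .tol_sum)
      abort_param("pk", sprintf("must sum to 1 (got %.15g)", sum(pk)))
  }
  if (!is.null(a)) {
    slots <- ceiling(L)
    if (!is.numeric(a) || length(a) != slots)
      abort_param("a", sprintf("must have length ceiling(L) = %d", slots))
    if (any(is.na(a)) || any(a < 0))
      abort_param("a", "entries must be >= 0")
    if (abs(sum(a) - 1) > .tol_sum)
      abort_param("a", sprintf("must sum to 1 (got %.15g)", sum(a)))
  }
  structure(
    list(alphabet = ab, n = ab$n, r = ab$r, N = N, L = L, M = M, p = p,
         pk = pk, a = a,
         uniform_r = ab$uniform, uniform_a = is.null(a),
         W = N / (M + L / 2)),
    class = "system_state")
}

#' Fully uniform mean-field state
#'
#' Convenience constructor for the common case of equal monomer composition
#' (`r_i = 1/n`) and uniform chain-site accessibility (`a_j = 1/L`).  The
#' profiles are left unset and flagged uniform; the entropy closed forms then
#' use `ln n` and `ln L` exactly rather than profile sums.
#'
#' @inheritParams system_state
#' @return A `"system_state"` with `uniform_r` and `uniform_a` set.
#' @examples
#' make_uniform_state(n = 4, N = moles_to_units(1), L = 1, M = 0, p = 1)
#' @export
make_uniform_state <- function(n, N = NULL, L = 1, M = 0, p = 1,
                               N_moles = NULL) {
  system_state(n, N = N, L = L, M = M, p = p, N_moles = N_moles)
}

#' @export
print.system_state <- function(x, ...) {
  cat("Mean-field monomer/oligomer system state\n")
  cat(sprintf("  n = %d types%s, N = %.6g units (%.6g mol)\n",
              x$n, if (x$uniform_r) " (uniform composition)" else "",
              x$N, x$N / .NA))
  cat(sprintf("  L = %.6g, M = %.6g, p = %.6g;  W = N/(M + L/2) = %.6g\n",
              x$L, x$M, x$p, x$W))
  if (!is.null(x$pk)) cat("  pk =", format(x$pk, digits = 4), "\n")
  if (!is.null(x$a))  cat("  a  =", format(x$a, digits = 4), "\n")
  invisible(x)
}
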