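# Deterministic mutation/selection simulator.
#
# Between events, selection removes random chains at a constant rate
# dp/dt (p is piecewise linear; integration is exact and dt only sets the
# output resolution).  Every `mutation_period` time units a mutation event
# fires: a fraction f of the defined chains loses its sequence (those chains
# become random, p <- p + f*(1 - p)) while the defined sequence gains
# `length_increment` units.  Defined chains are `length_ratio` times as long
# as random chains (default 2); the effective mean chain length seen by a
# walk is the number-weighted L_bar = p*L_rand + (1-p)*L_def.
#
# Order at each recorded state comes from the uniform sequential entropy at
# (L_bar, p); complexity from the two-length population mapping in
# complexity_from_lengths(): the defined term uses L_def, the census
# exponent uses L_rand, the census count uses L_bar.  No random numbers
# anywhere: identical configs give bit-identical trajectories.

#' Configuration for the mutation/selection simulator
#'
#' @param duration Total simulated time (default 50 time units).
#' @param selection_rate Constant dp/dt during selection (default -0.01 per
#'   time unit; negative means random chains are selected away).
#' @param mutation_period Time between mutation events (default 5).
#' @param loss_fraction Fraction `f` of defined chains lost (converted back
#'   to random chains) at each mutation event, in `[0, 1]`.
#' @param length_increment Units added to the defined chain per mutation
#'   event (default 1).
#' @param length_ratio Defined-to-random mean length ratio (default 2:
#'   defined chains are on average twice as long as random chains).
#' @param dt Output resolution in time units (default 1); integration of the
#'   piecewise-linear p is exact regardless of dt.
#' @param p0 Initial random-chain fraction (default 1).
#' @param L_def0 Initial defined-chain mean length (default 20).
#' @param M Mean monomer spacing, held constant (default 10).
#' @param n Alphabet size (default 4). @param N Total units (default 1 mol).
#' @return An `"evolution_config"` list.
#' @export
evolution_config <- function(duration = 50, selection_rate = -0.01,
                             mutation_period = 5, loss_fraction = 0.3,
                             length_increment = 1, length_ratio = 2,
                             dt = 1, p0 = 1, L_def0 = 20, M = 10,
                             n = 4, N = moles_to_units(1)) {
  if (!is.numeric(duration) || duration < 0)
    abort_param("duration", "must be >= 0")
  if (!is.numeric(mutation_period) || mutation_period <= 0)
    abort_param("mutation_period", "must be > 0")
  if (!is.numeric(loss_fraction) || loss_fraction < 0 || loss_fraction > 1)
    abort_param("loss_fraction", "must lie in [0, 1]")
  if (!is.numeric(length_ratio) || length_ratio <= 0)
    abort_param("length_ratio", "must be > 0")
  if (!is.numeric(dt) || dt <= 0) abort_param("dt", "must be > 0")
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) abort_param("p0", "must be in [0, 1]")
  if (!is.numeric(L_def0) || L_def0 < 1) abort_param("L_def0", "must be >= 1")
  if (!is.numeric(length_increment) || length_increment < 0)
    abort_param("length_increment", "must be >= 0")
  if (!is.numeric(M) || M < 0) abort_param("M", "must be >= 0")
  if (!is.numeric(n) || n < 1) abort_param("n", "must be >= 1")
  if (!is.numeric(N) || N <= 0) abort_param("N", "must be > 0")
  structure(list(duration = duration, selection_rate = selection_rate,
                 mutation_period = mutation_period,
                 loss_fraction = loss_fraction,
                 length_increment = length_increment,
                 length_ratio = length_ratio, dt = dt, p0 = p0,
                 L_def0 = L_def0, M = M, n = n, N = N),
            class = "evolution_config")
}

new_evolution_state <- function(t, p, L_def, length_ratio) {
  structure(list(t = t, p = p, L_def = L_def,
                 L_rand = L_def / length_ratio,
                 length_ratio = length_ratio),
            class = "evolution_state")
}

#' One selection step: linear decrease of the random-chain fraction
#'
#' `p <- clamp(p + rate*dt, 0, 1)`; chain lengths are untouched and time
#' advances by `dt`.
#'
#' @param state An `"evolution_state"`.
#' @param dt Step size (> 0). @param rate dp/dt.
#' @return The advanced state.
#' @export
step_selection <- function(state, dt, rate) {
  stopifnot(inherits(state, "evolution_state"))
  if (!is.numeric(dt) || dt <= 0) abort_param("dt", "must be > 0")
  state$p <- min(max(state$p + rate * dt, 0), 1)
  state$t <- state$t + dt
  state
}

#' One mutation event: sequence loss plus sequence growth
#'
#' A fraction `f` of the defined chains loses its shared sequence and joins
#' the random pool (`p <- p + f*(1 - p)`; monomer spacing is untouched),
#' while the surviving defined sequence gains `length_increment` units;
#' random-chain length follows through the fixed length ratio.  Time does
#' not advance (the event is instantaneous).
#'
#' @param state An `"evolution_state"`.
#' @param f Loss fraction in `[0, 1]`.
#' @param length_increment Units added to the defined chain (default 1).
#' @return The mutated state.
#' @export
apply_mutation <- function(state, f, length_increment = 1) {
  stopifnot(inherits(state, "evolution_state"))
  if (!is.numeric(f) || f < 0 || f > 1) abort_param("f", "must be in [0, 1]")
  state$p <- state$p + f * (1 - state$p)
  state$L_def <- state$L_def + length_increment
  state$L_rand <- state$L_def / state$length_ratio
  state
}

evolution_metrics <- function(state, cfg) {
  L_bar <- state$p * state$L_rand + (1 - state$p) * state$L_def
  ent <- entropy_uniform(n = cfg$n, N = cfg$N, L = L_bar, M = cfg$M,
                         p = state$p)
  cx <- complexity_from_lengths(cfg$n, state$L_def, state$L_rand, L_bar,
                                state$p, cfg$N, cfg$M)
  data.frame(t = state$t, p = state$p, L_def = state$L_def,
             L_rand = state$L_rand, L_bar = L_bar,
             S_r_JK = ent$S_r_JK, order_KJ = ent$order_KJ,
             c1_bits = cx$c1_bits, c2_bits = cx$c2_bits, c_bits = cx$c_bits,
             log10_c = cx$log10_c, stringsAsFactors = FALSE)
}

#' Run the periodic mutation/selection simulation
#'
#' Alternates exact piecewise-linear selection with instantaneous mutation
#' events at multiples of `mutation_period`, for `duration` time units.
#' States are recorded every `dt`; at each event both the pre-mutation state
#' (phase `"cycle_end"`, the end of a selection period) and the post-mutation
#' state (phase `"mutation"`) are recorded at the same time stamp.  Ordinary
#' recorded states carry phase `"selection"`.
#'
#' @param config An [evolution_config()].
#' @return An `"evolution_trajectory"` data frame with columns `t`, `phase`,
#'   `p`, `L_def`, `L_rand`, `L_bar`, `S_r_JK`, `order_KJ`, `c1_bits`,
#'   `c2_bits`, `c_bits`, `log10_c`.
#' @examples
#' traj <- run_evolution(evolution_config(loss_fraction = 0.3))
#' tail(traj)
#' @export
run_evolution <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  state <- new_evolution_state(0, config$p0, config$L_def0,
                               config$length_ratio)
  rows <- list(cbind(evolution_metrics(state, config),
                     phase = "selection", stringsAsFactors = FALSE))
  if (config$duration > 0) {
    eps <- 1e-9
    times <- seq(config$dt, config$duration, by = config$dt)
    if (length(times) == 0 || abs(times[length(times)] - config$duration) > eps)
      times <- c(times, config$duration)
    for (tt in times) {
      state <- step_selection(state, tt - state$t, config$selection_rate)
      at_event <- abs(tt %% config$mutation_period) < eps ||
        abs(tt %% config$mutation_period - config$mutation_period) < eps
      # the final state always closes a selection period, even when the
      # duration is not a multiple of the mutation period
      is_last <- abs(tt - config$duration) < eps
      rows[[length(rows) + 1L]] <-
        cbind(evolution_metrics(state, config),
              phase = if (at_event || is_last) "cycle_end" else "selection",
              stringsAsFactors = FALSE)
      if (at_event) {
        state <- apply_mutation(state, config$loss_fraction,
                                config$length_increment)
        rows[[length(rows) + 1L]] <-
          cbind(evolution_metrics(state, config),
                phase = "mutation", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("t", "phase", "p", "L_def", "L_rand", "L_bar", "S_r_JK",
                 "order_KJ", "c1_bits", "c2_bits", "c_bits", "log10_c")]
  rownames(out) <- NULL
  class(out) <- c("evolution_trajectory", "data.frame")
  attr(out, "config") <- config
  out
}

#' End-of-selection-period states of a trajectory
#'
#' Returns the rows recorded immediately before each mutation event (phase
#' `"cycle_end"`), in time order — the "circles" marking per-cycle progress
#' in order and complexity.
#'
#' @param trajectory An `"evolution_trajectory"` from [run_evolution()].
#' @return The subset of cycle-end rows.
#' @export
end_of_cycle_points <- function(trajectory) {
  stopifnot(inherits(trajectory, "data.frame"))
  if (nrow(trajectory) == 0)
    stop("empty trajectory", call. = FALSE)
  out <- trajectory[trajectory$phase == "cycle_end", , drop = FALSE]
  out[order(out$t), , drop = FALSE]
}
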