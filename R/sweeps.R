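# Order/complexity diagrams: tabulated parameter sweeps pairing the uniform
# sequential entropy with the min(c1, c2) complexity estimate at every grid
# point.  Grids default to the documented half-open protocols (p from 1.00
# down to 0.05 in steps of 0.05; L from 1 to 10.5 in steps of 0.5; M from 20
# down to 0 in steps of 1) and rows preserve sweep direction.

sweep_point <- function(param_name, value, n, N, L, M, p) {
  ent <- entropy_uniform(n = n, N = N, L = L, M = M, p = p)
  cx <- system_complexity(n = n, L = L, p = p, N = N, M = M)
  data.frame(param_name = param_name, param_value = value,
             S_r_JK = ent$S_r_JK, order_KJ = ent$order_KJ,
             c1_bits = cx$c1_bits, c2_bits = cx$c2_bits, c_bits = cx$c_bits,
             log10_c = cx$log10_c, strategy = cx$strategy,
             stringsAsFactors = FALSE)
}

as_sweep <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_points", "data.frame")
  out
}

#' Sweep the random-chain fraction p
#'
#' Order/complexity trajectory as sequence definition spreads through the
#' chain population: `p` runs from 1.00 down to 0.05 in steps of 0.05 at
#' fixed `L = 20`, `M = 10`, one mole of units, `n = 4`.  Order rises and
#' complexity falls monotonically along the default grid — gaining order by
#' pure selection costs complexity.
#'
#' @param p_grid Grid of random-chain fractions (default
#'   `seq(1, 0.05, by = -0.05)`).
#' @param n Alphabet size. @param N Total units. @param L Mean chain length.
#' @param M Mean monomer spacing.
#' @return A `"sweep_points"` data frame with columns `param_name`,
#'   `param_value`, `S_r_JK`, `order_KJ`, `c1_bits`, `c2_bits`, `c_bits`,
#'   `log10_c`, `strategy`, one row per grid point in grid order.
#' @export
sweep_random_fraction <- function(p_grid = seq(1, 0.05, by = -0.05),
                                  n = 4, N = moles_to_units(1),
                                  L = 20, M = 10) {
  if (length(p_grid) == 0 || any(p_grid < 0) || any(p_grid > 1))
    abort_param("p_grid", "values must lie in [0, 1]")
  as_sweep(lapply(p_grid, function(p)
    sweep_point("p", p, n = n, N = N, L = L, M = M, p = p)))
}

#' Sweep the mean chain length L
#'
#' Order/complexity trajectory as polymerisation proceeds: `L` runs from 1
#' (monomers only) to 10.5 in steps of 0.5 at fixed `p = 0.5`, `M = 10`, one
#' mole of units, `n = 4`.  Complexity climbs by six decades across the
#' default grid; order first dips (mixing entropy of more component types)
#' and then recovers once chains dominate.
#'
#' @param L_grid Grid of mean chain lengths (default `seq(1, 10.5, by = 0.5)`).
#' @param n Alphabet size. @param N Total units. @param p Random-chain
#'   fraction. @param M Mean monomer spacing.
#' @inherit sweep_random_fraction return
#' @export
sweep_chain_length <- function(L_grid = seq(1, 10.5, by = 0.5),
                               n = 4, N = moles_to_units(1),
                               p = 0.5, M = 10) {
  if (length(L_grid) == 0 || any(L_grid < 1))
    abort_param("L_grid", "values must be >= 1")
  as_sweep(lapply(L_grid, function(L)
    sweep_point("L", L, n = n, N = N, L = L, M = M, p = p)))
}

#' Sweep the monomer spacing M
#'
#' Order/complexity trajectory as free monomer is consumed: `M` runs from 20
#' down to 0 (no residual monomer) in steps of 1 at fixed `L = 20`,
#' `p = 0.5`, one mole of units, `n = 4`.  Order and complexity rise
#' together as `M` falls — the near-diagonal trajectory of productive
#' polymerisation.
#'
#' @param M_grid Grid of monomer spacings (default `seq(20, 0, by = -1)`).
#' @param n Alphabet size. @param N Total units. @param L Mean chain length.
#' @param p Random-chain fraction.
#' @inherit sweep_random_fraction return
#' @export
sweep_monomer_spacing <- function(M_grid = seq(20, 0, by = -1),
                                  n = 4, N = moles_to_units(1),
                                  L = 20, p = 0.5) {
  if (length(M_grid) == 0 || any(M_grid < 0))
    abort_param("M_grid", "values must be >= 0")
  as_sweep(lapply(M_grid, function(M)
    sweep_point("M", M, n = n, N = N, L = L, M = M, p = p)))
}

#' Write a sweep table to CSV or JSON
#'
#' Columns are written exactly as produced by the sweep functions
#' (`param_name, param_value, S_r_JK, order_KJ, c1_bits, c2_bits, c_bits,
#' log10_c, strategy`), preserving sweep direction, at full double precision.
#'
#' @param points A `"sweep_points"` data frame (non-empty).
#' @param path Output file path.
#' @param format `"csv"` (RFC-4180 style, header row) or `"json"` (array of
#'   row objects).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(points, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(points) || nrow(points) == 0)
    abort_param("points", "must be a non-empty sweep data frame")
  if (format == "csv") {
    utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(points, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Plot a sweep as an order-versus-complexity diagram
#'
#' Complexity (bits, decimal-log axis) against order (K/J), connected in
#' sweep order.  Purely a convenience for eyeballing trajectories; nothing
#' downstream depends on it.
#'
#' @param points A `"sweep_points"` data frame.
#' @param ... Passed to [graphics::plot()].
#' @return `points`, invisibly.
#' @export
plot_sweep <- function(points, ...) {
  graphics::plot(points$log10_c, points$order_KJ, type = "b",
                 xlab = "log10 complexity (bit)", ylab = "order 1/S_r (K/J)",
                 ...)
  invisible(points)
}
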