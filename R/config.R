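# Config files mirror the CLI flags: keys n, r (optional), exactly one of
# N_units / N_moles, L, M, p, pk (optional), a (optional).  YAML or JSON by
# file extension.

.config_keys <- c("n", "r", "N_units", "N_moles", "L", "M", "p", "pk", "a")

#' Read a model configuration from YAML or JSON
#'
#' Accepts the keys `n`, `r`, `N_units` or `N_moles` (exactly one), `L`,
#' `M`, `p`, `pk`, `a`; anything else is an error.  Values are returned as a
#' plain named list; see [config_to_state()] to validate and build a state.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("malformed config file", call. = FALSE)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0)
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (!is.null(cfg$N_units) && !is.null(cfg$N_moles))
    stop("config must give exactly one of N_units / N_moles", call. = FALSE)
  cfg
}

#' Write a model configuration to YAML or JSON
#'
#' @param config Named list of configuration values (validated against the
#'   known keys).
#' @param path Output path; format chosen by extension as in [load_config()].
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown) > 0)
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(config, path)
  else
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a system state from a configuration list
#'
#' @param config List as returned by [load_config()].
#' @return A [system_state()].
#' @export
config_to_state <- function(config) {
  system_state(n = config$n, N = config$N_units, L = config$L %||% 1,
               M = config$M %||% 0, p = config$p %||% 1, r = config$r,
               pk = config$pk, a = config$a, N_moles = config$N_moles)
}

#' Configuration list for a system state
#'
#' Inverse of [config_to_state()]: uniform-flagged profiles are omitted, so
#' a state built by [make_uniform_state()] round-trips to the same compact
#' config.
#'
#' @param state A [system_state()].
#' @return Named list suitable for [write_config()].
#' @export
state_to_config <- function(state) {
  stopifnot(inherits(state, "system_state"))
  cfg <- list(n = state$n, N_units = state$N, L = state$L, M = state$M,
              p = state$p)
  if (!state$uniform_r) cfg$r <- state$r
  if (!is.null(state$pk)) cfg$pk <- state$pk
  if (!is.null(state$a)) cfg$a <- state$a
  cfg
}

`%||%` <- function(x, y) if (is.null(x)) y else x
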