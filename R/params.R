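#' Model parameters for a collapse-driven community
#'
#' Bundles the configuration of one simulation: the number of species slots
#' \code{N} (kept strictly constant; every extinction is immediately followed
#' by the introduction of a new species), the newcomer size \code{gamma}
#' (fraction of the carrying capacity, which is fixed at 1), the model
#' variant, and variant-specific scalars.
#'
#' @param N integer >= 2, number of species slots.
#' @param gamma newcomer population fraction, 0 < gamma < 1. In the
#'   interconnected-environments reading this is the diffusion influx that
#'   re-seeds a collapsed local population.
#' @param variant one of \code{"basic"}, \code{"neutral_drift"},
#'   \code{"exp_fluct"}, \code{"interconnected"}, \code{"ktw"},
#'   \code{"ktl"}, \code{"fitness"}, \code{"resilience"}.
#' @param variant_params named list of variant-specific scalars; see
#'   \code{\link{variant_config}} for the recognised keys and defaults.
#' @param equalize_at_wave_start logical; if \code{TRUE}, run the simplified
#'   model in which all populations are reset to \code{1/N} at the start of
#'   every wave (the history-free limit with tail exponent 2).
#' @param seed optional integer RNG seed stored with the parameters and used
#'   by \code{\link{simulate_community}} when no explicit seed is given.
#'
#' @return an object of class \code{"model_params"}.
#' @examples
#' p <- model_params(N = 100, gamma = 1e-9)
#' p_ktw <- model_params(N = 100, gamma = 1e-9, variant = "ktw",
#'                       variant_params = list(sigma = 1))
#' @export
model_params <- function(N, gamma, variant = "basic",
                         variant_params = list(),
                         equalize_at_wave_start = FALSE,
                         seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 2 || N != round(N))
    stop("N must be a single integer >= 2")
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma <= 0 || gamma >= 1)
    stop("gamma must satisfy 0 < gamma < 1")
  vc <- variant_config(variant, variant_params)
  structure(list(N = as.integer(N), gamma = gamma,
                 carrying_capacity = 1,
                 variant = vc$name, variant_params = vc,
                 equalize_at_wave_start = isTRUE(equalize_at_wave_start),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Collapse-driven community model\n")
  cat(sprintf("  variant: %s   N = %d   gamma = %g\n",
              x$variant, x$N, x$gamma))
  if (x$equalize_at_wave_start)
    cat("  simplified mode: populations equalized to 1/N at wave starts\n")
  vp <- x$variant_params
  extras <- setdiff(names(vp), "name")
  if (length(extras))
    cat("  ", paste(vapply(extras, function(k)
      sprintf("%s = %s", k, paste(format(vp[[k]]), collapse = ":")),
      character(1)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.divwave_variants <- c("basic", "neutral_drift", "exp_fluct",
                       "interconnected", "ktw", "ktl", "fitness",
                       "resilience")

#' Variant configuration
#'
#' Validates and completes the variant-specific scalars layered on the basic
#' collapse model. Recognised keys by variant:
#' \describe{
#'   \item{neutral_drift}{\code{r}: drift rate per collapse interval
#'     (default \code{1e-7}); \code{drift_law}: \code{"linear"} for steps
#'     \eqn{\pm r P(1-P)} or \code{"sqrt"} for \eqn{\pm r \sqrt{P(1-P)}}
#'     (default \code{"linear"}, following the published update rule).}
#'   \item{exp_fluct}{\code{n}: multiplicative fluctuation amplitude in
#'     (0, 1); published values 0.02, 0.1, 0.5 (default 0.1).}
#'   \item{ktw}{\code{sigma} >= 0: Kill-the-Winner exponent, collapse weight
#'     proportional to \eqn{P^\sigma}; published values 0.01, 0.2, 1
#'     (default 1).}
#'   \item{ktl}{\code{sigma}: fixed at -0.2 (Kill-the-Loser; collapse weight
#'     declines with size as \eqn{P^{-0.2}}).}
#'   \item{fitness}{\code{omega_range}, \code{c_range}: log-uniform sampling
#'     ranges for the per-species growth rate and collapse weight, both
#'     defaulting to \code{c(0.1, 1)}; \code{resample_on_replace}: whether a
#'     newcomer draws fresh traits (default \code{TRUE}).}
#'   \item{resilience}{\code{omega_range} (default \code{c(0.1, 1)}) and
#'     \code{gamma_i_range} (default \code{c(1e-9, 1e-2)}): log-uniform
#'     ranges for the growth rate and per-species survivor ratio; species
#'     identities are permanent (a collapse shrinks \eqn{P_i} to
#'     \eqn{\gamma_i P_i} instead of replacing the species).}
#' }
#' \code{interconnected} takes no parameters: its update rule coincides with
#' the basic model, with \code{gamma} reinterpreted as diffusion influx from
#' neighbouring environments.
#'
#' @param name variant name (see \code{\link{model_params}}).
#' @param params named list of overrides for the keys above.
#' @return a named list with class \code{"variant_config"}; always contains
#'   \code{name} plus the variant's completed parameters.
#' @export
variant_config <- function(name = "basic", params = list()) {
  name <- match.arg(name, .divwave_variants)
  if (!is.list(params))
    stop("variant_params must be a list")
  defaults <- switch(name,
    basic = list(),
    interconnected = list(),
    neutral_drift = list(r = 1e-7, drift_law = "linear"),
    exp_fluct = list(n = 0.1),
    ktw = list(sigma = 1),
    ktl = list(sigma = -0.2),
    fitness = list(omega_range = c(0.1, 1), c_range = c(0.1, 1),
                   resample_on_replace = TRUE),
    resilience = list(omega_range = c(0.1, 1),
                      gamma_i_range = c(1e-9, 1e-2)))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop(sprintf("variant '%s' does not accept parameter(s): %s",
                 name, paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, params)
  if (name == "neutral_drift") {
    if (cfg$r < 0) stop("drift rate r must be >= 0")
    cfg$drift_law <- match.arg(cfg$drift_law, c("linear", "sqrt"))
  }
  if (name == "exp_fluct" && (cfg$n < 0 || cfg$n >= 1))
    stop("fluctuation amplitude n must be in [0, 1)")
  if (name == "ktw" && cfg$sigma < 0)
    stop("KtW exponent sigma must be >= 0")
  if (name == "ktl" && cfg$sigma >= 0)
    stop("KtL exponent sigma must be negative")
  for (k in c("omega_range", "c_range", "gamma_i_range")) {
    if (!is.null(cfg[[k]])) {
      rg <- cfg[[k]]
      if (length(rg) != 2 || any(rg <= 0) || rg[1] >= rg[2])
        stop(sprintf("%s must be a positive increasing pair", k))
    }
  }
  structure(c(list(name = name), cfg), class = "variant_config")
}

#' Per-species fitness traits
#'
#' Container for heterogeneous species traits used by the fitness and
#' resilience variants: growth rate \code{omega} (used during the fast
#' repopulation of freed-up carrying capacity), collapse weight \code{c}
#' (relative probability of being the next victim), and survivor ratio
#' \code{gamma_i} (fraction of the population surviving a collapse).
#'
#' @param omega numeric vector of growth rates, all > 0.
#' @param c numeric vector of collapse weights, all >= 0, or \code{NULL}.
#' @param gamma_i numeric vector of survivor ratios in (0, 1), or
#'   \code{NULL}.
#' @return a data.frame of class \code{"species_params"}.
#' @seealso \code{\link{sample_species_params}}
#' @export
species_params <- function(omega, c = NULL, gamma_i = NULL) {
  if (any(omega <= 0)) stop("omega must be > 0")
  n <- length(omega)
  if (!is.null(c) && (length(c) != n || any(c < 0)))
    stop("c must be >= 0 and match length(omega)")
  if (!is.null(gamma_i) &&
      (length(gamma_i) != n || any(gamma_i <= 0) || any(gamma_i >= 1)))
    stop("gamma_i must lie in (0, 1) and match length(omega)")
  out <- data.frame(omega = omega)
  out$c <- if (is.null(c)) NA_real_ else c
  out$gamma_i <- if (is.null(gamma_i)) NA_real_ else gamma_i
  class(out) <- c("species_params", "data.frame")
  out
}
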