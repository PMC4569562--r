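#' Neutral drift between collapses
#'
#' Perturbs every population by an incremental drift step
#' \eqn{P_i \to P_i \pm r P_i (1 - P_i)} with independent equiprobable
#' signs, then renormalizes to the carrying capacity. This layers the
#' classic community-drift picture of neutral biodiversity theory on top of
#' the collapse dynamics. \code{drift_law = "sqrt"} instead uses magnitude
#' \eqn{r \sqrt{P_i (1 - P_i)}}, the demographic-noise scaling; the default
#' follows the published linear rule. Signs are drawn slot-by-slot
#' (one uniform per species, in index order).
#'
#' @param state a saturated \code{community_state}.
#' @param r drift rate per collapse interval, >= 0.
#' @param drift_law \code{"linear"} or \code{"sqrt"}.
#' @return the updated, renormalized state.
#' @export
neutral_drift_update <- function(state, r, drift_law = c("linear", "sqrt")) {
  drift_law <- match.arg(drift_law)
  if (r < 0) stop("drift rate r must be >= 0")
  P <- state$populations
  if (r > 0) {
    u <- runif(length(P))
    mag <- if (drift_law == "linear") r * P * (1 - P)
           else r * sqrt(P * (1 - P))
    P <- P + ifelse(u < 0.5, -mag, mag)
    P[P < 0] <- 0
    state$populations <- P * (1 / sum(P))
  } else {
    runif(length(P))  # keep the RNG stream aligned with r > 0 runs
  }
  state
}

#' Multiplicative abundance fluctuations between collapses
#'
#' Applies one slow multiplicative adjustment
#' \eqn{P_i \to P_i (1 \pm n \Omega_i)} with independent equiprobable signs
#' (\eqn{\Omega_i = 1} when the variant carries no per-species rates), then
#' renormalizes so the community stays at the carrying capacity.
#'
#' @param state a saturated \code{community_state}.
#' @param n fluctuation amplitude in [0, 1); amplitudes >= 1 are rejected
#'   because they would allow non-positive populations.
#' @return the updated, renormalized state.
#' @export
exp_fluct_update <- function(state, n) {
  if (n < 0 || n >= 1) stop("fluctuation amplitude n must be in [0, 1)")
  P <- state$populations
  u <- runif(length(P))
  omega <- if (!is.null(state$params_ref)) state$params_ref$omega
           else rep(1, length(P))
  if (n > 0) {
    P <- P * ifelse(u < 0.5, 1 - n * omega, 1 + n * omega)
    state$populations <- P * (1 / sum(P))
  }
  state
}

#' Sample per-species fitness traits
#'
#' Draws the heterogeneous traits required by a variant, log-uniformly over
#' the configured ranges: growth rate omega (fitness, resilience), collapse
#' weight c (fitness), survivor ratio gamma_i (resilience). Draws are
#' consumed field-by-field (all omega, then all c or gamma_i), each field
#' as one \code{runif(count)} block.
#'
#' @param variant a \code{\link{variant_config}} (or a
#'   \code{\link{model_params}}, whose variant config is used).
#' @param count number of species to sample.
#' @return a \code{\link{species_params}} data frame, or \code{NULL} for
#'   homogeneous variants.
#' @export
sample_species_params <- function(variant, count) {
  if (inherits(variant, "model_params")) variant <- variant$variant_params
  stopifnot(inherits(variant, "variant_config"))
  rlog <- function(range, k)
    exp(runif(k, log(range[1]), log(range[2])))
  switch(variant$name,
    fitness = species_params(omega = rlog(variant$omega_range, count),
                             c = rlog(variant$c_range, count)),
    resilience = species_params(omega = rlog(variant$omega_range, count),
                                gamma_i = rlog(variant$gamma_i_range,
                                               count)),
    NULL)
}

#' Compose the step policy for a model variant
#'
#' Returns the policy bundle that \code{\link{simulate_community}} and the
#' compiled engine share: victim-selection rule, collapse mode, growth mode,
#' and the optional between-collapse update. \code{interconnected} is an
#' alias of \code{basic} (the published diffusion-reseeding rule coincides
#' with uniform victim choice plus reseeding at size gamma, reinterpreted as
#' influx from neighbouring environments).
#'
#' @param params a \code{\link{model_params}} object.
#' @return a list with elements \code{victim_policy}, \code{sigma},
#'   \code{collapse_mode}, \code{growth_mode}, \code{update_kind},
#'   \code{update_rate}, \code{drift_law}, \code{needs_species_params},
#'   \code{resample_on_replace}.
#' @export
make_variant <- function(params) {
  stopifnot(inherits(params, "model_params"))
  vc <- params$variant_params
  pol <- list(victim_policy = "uniform", sigma = 0,
              collapse_mode = "replace_with_newcomer",
              growth_mode = "common",
              update_kind = "none", update_rate = 0, drift_law = "linear",
              needs_species_params = FALSE, resample_on_replace = FALSE)
  switch(params$variant,
    basic = , interconnected = NULL,
    neutral_drift = {
      pol$update_kind <- "drift"; pol$update_rate <- vc$r
      pol$drift_law <- vc$drift_law
    },
    exp_fluct = {
      pol$update_kind <- "fluct"; pol$update_rate <- vc$n
    },
    ktw = , ktl = {
      pol$victim_policy <- "power_weighted"; pol$sigma <- vc$sigma
    },
    fitness = {
      pol$victim_policy <- "fitness_c"
      pol$growth_mode <- "per_species"
      pol$needs_species_params <- TRUE
      pol$resample_on_replace <- isTRUE(vc$resample_on_replace)
    },
    resilience = {
      pol$collapse_mode <- "shrink_by_gamma_i"
      pol$growth_mode <- "per_species"
      pol$needs_species_params <- TRUE
    })
  pol
}
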