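#' Initialise a community state
#'
#' Creates the uniform initial condition: \code{N} species, each at
#' population \code{1/N}, so the community starts exactly at the carrying
#' capacity with maximal diversity. For heterogeneous variants the
#' per-species traits are drawn here (log-uniformly, consuming the current
#' RNG stream field-by-field: omega first, then c or gamma_i).
#'
#' @param params a \code{\link{model_params}} object.
#' @return an object of class \code{"community_state"} with elements
#'   \code{populations}, \code{species_id}, \code{birth_step},
#'   \code{n_substantial_at_birth}, \code{step}, \code{next_id}, and
#'   \code{params_ref} (a \code{\link{species_params}} data frame, or
#'   \code{NULL} for homogeneous variants).
#' @examples
#' s <- init_community(model_params(N = 4, gamma = 1e-4))
#' s$populations  # 0.25 0.25 0.25 0.25
#' @export
init_community <- function(params) {
  stopifnot(inherits(params, "model_params"))
  N <- params$N
  sp <- if (params$variant %in% c("fitness", "resilience"))
    sample_species_params(params$variant_params, N) else NULL
  structure(list(populations = rep(1 / N, N),
                 species_id = 0:(N - 1L),
                 birth_step = rep(0L, N),
                 n_substantial_at_birth = rep(N, N),
                 step = 0L,
                 next_id = N,
                 params_ref = sp),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  N <- length(x$populations)
  cat(sprintf("community_state: N = %d, step = %d, sum(P) = %.12f, D = %.3f\n",
              N, x$step, sum(x$populations), diversity(x$populations)))
  invisible(x)
}

#' Select the next collapse victim
#'
#' Draws the index of the population that collapses at this step. Selection
#' probability is uniform (the basic model: extinction probability
#' independent of population size), proportional to \eqn{P_i^\sigma}
#' (Kill-the-Winner for \eqn{\sigma > 0}, Kill-the-Loser for
#' \eqn{\sigma < 0}), or proportional to a per-species collapse weight
#' \eqn{c_i} (fitness variant).
#'
#' The draw consumes exactly one uniform \code{u}: uniform policy picks slot
#' \code{floor(u*N) + 1}; weighted policies pick the first slot whose
#' cumulative weight exceeds \code{u * sum(w)}. With equal weights the two
#' rules coincide, which makes policy degeneracies (\eqn{\sigma = 0}, equal
#' \eqn{c_i}) exact.
#'
#' @param state a \code{community_state}.
#' @param policy \code{"uniform"}, \code{"power_weighted"}, or
#'   \code{"fitness_c"}.
#' @param sigma exponent for \code{"power_weighted"}.
#' @return integer victim index in \code{1..N}.
#' @export
select_victim <- function(state, policy = c("uniform", "power_weighted",
                                            "fitness_c"), sigma = 0) {
  policy <- match.arg(policy)
  P <- state$populations
  N <- length(P)
  u <- runif(1)
  if (policy == "uniform" || (policy == "power_weighted" && sigma == 0))
    return(min(N, floor(u * N) + 1L))
  w <- if (policy == "power_weighted") {
    if (sigma < 0 && any(P <= 0))
      stop("power-weighted selection with negative exponent requires strictly positive populations")
    P^sigma
  } else {
    if (is.null(state$params_ref)) stop("fitness_c policy needs params_ref")
    state$params_ref$c
  }
  acc <- cumsum(w)
  v <- which(acc > u * acc[N])[1]
  if (is.na(v)) N else v
}

#' Apply one collapse to a saturated state
#'
#' Removes (or shrinks) the victim population, leaving the state below the
#' carrying capacity until \code{\link{saturate}} is applied. In
#' \code{"replace_with_newcomer"} mode the victim's slot is taken over by a
#' brand-new species seeded at population \code{gamma}; in
#' \code{"shrink_by_gamma_i"} mode (resilience variant) the same species
#' survives with population \eqn{\gamma_i P_i}.
#'
#' @param state a saturated \code{community_state}.
#' @param victim integer index in \code{1..N}.
#' @param mode \code{"replace_with_newcomer"} or \code{"shrink_by_gamma_i"}.
#' @param gamma newcomer size (replace mode).
#' @param substantial_threshold populations above this count as
#'   "substantial" when recording the newcomer's birth context.
#' @param resample optional function \code{function(state, victim)}
#'   returning updated \code{params_ref} for the newcomer's traits.
#' @return list with the unsaturated \code{state} and the
#'   \code{collapse_event} stub (victim, pre-collapse size, substantial
#'   count); the wave flag and rescale factor are filled in by
#'   \code{\link{step_community}}.
#' @export
apply_collapse <- function(state, victim,
                           mode = c("replace_with_newcomer",
                                    "shrink_by_gamma_i"),
                           gamma = NULL, substantial_threshold = 1e-10,
                           resample = NULL) {
  mode <- match.arg(mode)
  P <- state$populations
  pre <- P[victim]
  nsub <- sum(P > substantial_threshold)
  event <- list(step = state$step + 1L,
                victim_index = victim,
                victim_species_id = state$species_id[victim],
                victim_birth_step = state$birth_step[victim],
                victim_n_substantial_at_birth =
                  state$n_substantial_at_birth[victim],
                pre_collapse_size = pre)
  if (mode == "replace_with_newcomer") {
    if (is.null(gamma)) stop("replace mode needs gamma")
    state$populations[victim] <- gamma
    state$species_id[victim] <- state$next_id
    state$next_id <- state$next_id + 1L
    state$birth_step[victim] <- state$step + 1L
    state$n_substantial_at_birth[victim] <- nsub
    if (!is.null(resample)) state$params_ref <- resample(state, victim)
  } else {
    if (is.null(state$params_ref) || all(is.na(state$params_ref$gamma_i)))
      stop("shrink mode needs per-species gamma_i in params_ref")
    state$populations[victim] <- pre * state$params_ref$gamma_i[victim]
  }
  list(state = state, event = event)
}

#' Saturate: instantaneous regrowth to the carrying capacity
#'
#' Brings an unsaturated state (total population below 1) back to the
#' carrying capacity. With a common growth rate all populations are simply
#' multiplied by \code{1/sum(P)}. With per-species rates \eqn{\Omega_i} the
#' endpoint of the logistic competition \eqn{dP_i/dt = \Omega_i P_i (1 -
#' \sum_j P_j)} is computed exactly: populations become
#' \eqn{P_i e^{\Omega_i A}} where the scalar \eqn{A \ge 0} solves
#' \eqn{\sum_i P_i e^{\Omega_i A} = 1} (monotone root, solved to relative
#' tolerance 1e-12 rather than by error-prone ODE integration).
#'
#' @param state an unsaturated \code{community_state} with
#'   \code{0 < sum(P) <= 1}.
#' @param omega either \code{NULL} (common rate) or a numeric vector of
#'   per-species growth rates.
#' @param allow_excess permit a total slightly above the carrying capacity
#'   and contract back to it. A total above 1 can arise legitimately in the
#'   fluctuation variants when a victim smaller than gamma is replaced by a
#'   newcomer at gamma; the logistic competition then has a negative
#'   \eqn{1 - \sum_j P_j} and shrinks populations to capacity, which the
#'   common rescale reproduces. Off by default so that plain dynamics
#'   violating the saturation contract still raise an error.
#' @return list with the saturated \code{state} and the scalar
#'   \code{rescale_factor} \code{1/sum(P)} (the common multiplicative factor;
#'   for per-species growth it is reported from the same pre-growth total).
#' @examples
#' s <- init_community(model_params(N = 2, gamma = 0.1))
#' s$populations <- c(0.1, 0.5)
#' saturate(s)$state$populations  # 1/6, 5/6
#' @export
saturate <- function(state, omega = NULL, allow_excess = FALSE) {
  P <- state$populations
  s <- sum(P)
  if (s <= 0) stop("total population is zero: all species extinct")
  if (s > 1 + 1e-9 && !allow_excess)
    stop("total population exceeds the carrying capacity")
  rescale <- 1 / s
  if (is.null(omega)) {
    state$populations <- P * rescale
  } else {
    A <- solve_growth_scalar_cpp(P, omega)
    Pn <- P * exp(omega * A)
    state$populations <- Pn * (1 / sum(Pn))
  }
  list(state = state, rescale_factor = rescale)
}

#' Reset all populations to 1/N (simplified model)
#'
#' The history-free limit: at the start of a wave every species is set to
#' the same abundance \code{1/N}, erasing the memory carried by the lower
#' peak of the abundance distribution. Species identities are preserved.
#'
#' @param state a \code{community_state}.
#' @return the equalized state (sum exactly 1, diversity exactly N).
#' @export
equalize_populations <- function(state) {
  N <- length(state$populations)
  state$populations <- rep(1 / N, N)
  state
}

#' Advance the community by one collapse event (reference stepper)
#'
#' Pure-R composition of the per-step pipeline: optional between-collapse
#' update (drift/fluctuation variants), victim selection, collapse,
#' saturation (or equalization at wave starts in the simplified model).
#' One call consumes the RNG in the same fixed order as the compiled
#' engine, so trajectories from the two steppers are identical for a given
#' seed. This function is the readable reference; use
#' \code{\link{simulate_community}} for production runs.
#'
#' @param state a saturated \code{community_state}.
#' @param params a \code{\link{model_params}} object.
#' @param wave_threshold a collapse of a population above this size marks a
#'   wave boundary (default \code{1 - 1/N}).
#' @param substantial_threshold cut for the "substantial population" count
#'   recorded at each newcomer's birth.
#' @return list(state, event) where \code{event} is a one-step
#'   \code{collapse_event} record.
#' @export
step_community <- function(state, params,
                           wave_threshold = 1 - 1 / params$N,
                           substantial_threshold = 1e-10) {
  stopifnot(inherits(params, "model_params"))
  vc <- params$variant_params
  variant <- params$variant
  N <- params$N

  if (variant == "neutral_drift")
    state <- neutral_drift_update(state, vc$r, drift_law = vc$drift_law)
  else if (variant == "exp_fluct")
    state <- exp_fluct_update(state, vc$n)

  pol <- switch(variant,
                ktw = , ktl = "power_weighted",
                fitness = "fitness_c",
                "uniform")
  victim <- select_victim(state, pol,
                          sigma = if (pol == "power_weighted") vc$sigma else 0)

  mode <- if (variant == "resilience") "shrink_by_gamma_i"
          else "replace_with_newcomer"
  resample <- NULL
  if (variant == "fitness" && isTRUE(vc$resample_on_replace)) {
    resample <- function(st, v) {
      pr <- st$params_ref
      pr$omega[v] <- exp(runif(1, log(vc$omega_range[1]),
                               log(vc$omega_range[2])))
      pr$c[v] <- exp(runif(1, log(vc$c_range[1]), log(vc$c_range[2])))
      pr
    }
  }
  cl <- apply_collapse(state, victim, mode, gamma = params$gamma,
                       substantial_threshold = substantial_threshold,
                       resample = resample)
  state <- cl$state
  event <- cl$event
  event$is_wave_boundary <- event$pre_collapse_size > wave_threshold

  pre_saturation <- state$populations  # Fig-3 "green" observable
  if (params$equalize_at_wave_start && event$is_wave_boundary) {
    event$rescale_factor <- 1 / sum(state$populations)
    state <- equalize_populations(state)
  } else {
    omega <- if (variant %in% c("fitness", "resilience"))
      state$params_ref$omega else NULL
    st <- saturate(state, omega,
                   allow_excess = variant %in% c("neutral_drift",
                                                 "exp_fluct"))
    state <- st$state
    event$rescale_factor <- st$rescale_factor
  }
  state$step <- state$step + 1L
  attr(event, "pre_saturation_populations") <- pre_saturation
  class(event) <- "collapse_event"
  list(state = state, event = event)
}
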