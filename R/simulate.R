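#' Simulate a collapse-driven community
#'
#' Runs the discrete collapse dynamics for \code{n_steps} events from the
#' uniform initial condition, feeding every step to the requested streaming
#' recorders. One step is one collapse: victim selection, removal (or
#' shrinkage), reseeding, and instantaneous saturation back to the carrying
#' capacity. Time is measured in collapse events throughout.
#'
#' The default engine is compiled; \code{engine = "r"} runs the pure-R
#' reference stepper (\code{\link{step_community}}), which consumes the RNG
#' identically and therefore produces the same trajectory for the same
#' seed — this equivalence is part of the package's test contract.
#'
#' Aggregated recorders (\code{"sad"}, \code{"snapshots"},
#' \code{"species_stats"}) discard the first \code{burn_in} steps, since the
#' uniform initial condition is not representative of the steady state;
#' per-step recorders (\code{"events"}, \code{"diversity"}) keep everything
#' so that transients remain inspectable.
#'
#' @param params a \code{\link{model_params}} object.
#' @param n_steps number of collapse events to simulate (>= 1).
#' @param seed integer RNG seed; defaults to \code{params$seed}. A seed must
#'   be available from one of the two, so every run is reproducible.
#' @param burn_in steps excluded from aggregated statistics (default
#'   \code{10 * N}, capped at half the run for short exploratory runs).
#' @param record character vector of recorders to enable, from
#'   \code{"events"}, \code{"diversity"}, \code{"sad"}, \code{"snapshots"},
#'   \code{"species_stats"}.
#' @param sad_bins_per_decade log10 bin resolution of the abundance
#'   histograms (default 5).
#' @param sad_support numeric pair: population range covered by the
#'   histograms. Defaults to \code{c(gamma/10, 1)}; the resilience variant,
#'   whose populations can shrink below gamma_i repeatedly, defaults to a
#'   support extended well below \code{min(gamma_i_range)}. Out-of-support
#'   values are clamped into the edge bins so counts are conserved.
#' @param wave_threshold collapses above this size mark wave boundaries
#'   (default \code{1 - 1/N}).
#' @param substantial_threshold cut used for the "number of substantial
#'   populations" recorded at each species' birth (default 1e-10).
#' @param engine \code{"cpp"} (default) or \code{"r"} (reference stepper).
#' @return an object of class \code{"divwave_run"}: a list with the run
#'   configuration, the enabled recorder outputs (\code{events} and
#'   \code{diversity} data frames, \code{sad}/\code{green}/\code{red}
#'   \code{\link{sad_histogram}} objects, \code{species_stats} data frame),
#'   and the \code{final} community state.
#' @examples
#' run <- simulate_community(model_params(N = 50, gamma = 1e-6), 2000,
#'                           seed = 1)
#' detect_waves(run$events, N = 50)
#' @export
simulate_community <- function(params, n_steps, seed = params$seed,
                               burn_in = min(10L * params$N,
                                             n_steps %/% 2L),
                               record = c("events", "diversity", "sad",
                                          "snapshots"),
                               sad_bins_per_decade = 5,
                               sad_support = NULL,
                               wave_threshold = 1 - 1 / params$N,
                               substantial_threshold = 1e-10,
                               engine = c("cpp", "r")) {
  stopifnot(inherits(params, "model_params"))
  engine <- match.arg(engine)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (is.null(seed)) stop("a seed is required (argument or params$seed)")
  if (burn_in < 0 || burn_in >= n_steps)
    stop("need n_steps > burn_in >= 0")
  record <- match.arg(record, c("events", "diversity", "sad", "snapshots",
                                "species_stats"), several.ok = TRUE)
  if (engine == "r" && "species_stats" %in% record)
    stop("the species_stats recorder requires the compiled engine")
  pol <- make_variant(params)
  if (is.null(sad_support)) {
    lo <- if (params$variant == "resilience")
      log10(params$variant_params$gamma_i_range[1]) * 2
    else log10(params$gamma) - 1
    sad_support <- c(10^lo, 1)
  }
  edges <- sad_bin_edges(sad_support, sad_bins_per_decade)

  set.seed(as.integer(seed))
  state0 <- init_community(params)
  sp <- state0$params_ref

  out <- if (engine == "cpp") {
    res <- sim_engine_cpp(
      N = params$N, gamma_ = params$gamma, n_steps = as.integer(n_steps),
      burn_in = as.integer(burn_in),
      victim_policy = match(pol$victim_policy,
                            c("uniform", "power_weighted", "fitness_c")) - 1L,
      sigma = pol$sigma,
      collapse_mode = match(pol$collapse_mode,
                            c("replace_with_newcomer",
                              "shrink_by_gamma_i")) - 1L,
      growth_mode = match(pol$growth_mode, c("common", "per_species")) - 1L,
      equalize_at_wave_start = params$equalize_at_wave_start,
      update_kind = match(pol$update_kind, c("none", "drift", "fluct")) - 1L,
      update_rate = pol$update_rate,
      drift_law = match(pol$drift_law, c("linear", "sqrt")) - 1L,
      omega_in = if (!is.null(sp)) sp$omega else numeric(0),
      c_in = if (!is.null(sp) && !all(is.na(sp$c))) sp$c else numeric(0),
      gamma_i_in = if (!is.null(sp) && !all(is.na(sp$gamma_i)))
        sp$gamma_i else numeric(0),
      resample_on_replace = pol$resample_on_replace,
      omega_lo = params$variant_params$omega_range[1] %||% 0.1,
      omega_hi = params$variant_params$omega_range[2] %||% 1,
      c_lo = params$variant_params$c_range[1] %||% 0.1,
      c_hi = params$variant_params$c_range[2] %||% 1,
      wave_threshold = wave_threshold,
      substantial_threshold = substantial_threshold,
      sad_lo = edges[1], sad_w = edges[2] - edges[1],
      sad_nbins = length(edges) - 1L,
      record_events = "events" %in% record,
      record_diversity = "diversity" %in% record,
      record_sad = "sad" %in% record,
      record_snapshots = "snapshots" %in% record,
      record_species_stats = "species_stats" %in% record)
    res
  } else {
    .sim_engine_r(state0, params, n_steps, burn_in, record, edges,
                  wave_threshold, substantial_threshold)
  }

  run <- list(params = params, n_steps = as.integer(n_steps),
              burn_in = as.integer(burn_in), seed = as.integer(seed),
              wave_threshold = wave_threshold,
              substantial_threshold = substantial_threshold,
              engine = engine)
  if ("events" %in% record) run$events <- as.data.frame(out$events)
  if ("diversity" %in% record) run$diversity <- as.data.frame(out$diversity)
  if ("sad" %in% record)
    run$sad <- sad_histogram(edges, counts = out$sad_counts,
                             n_snapshots = out$sad_n)
  if ("snapshots" %in% record) {
    run$green <- sad_histogram(edges, counts = out$green_counts,
                               n_snapshots = out$snap_n)
    run$red <- sad_histogram(edges, counts = out$red_counts,
                             n_snapshots = out$snap_n)
  }
  if ("species_stats" %in% record) {
    ss <- as.data.frame(out$species_stats)
    ss$mean_P <- ss$sum_P / pmax(ss$n_obs, 1L)
    run$species_stats <- ss
  }
  fin <- out$final
  run$final <- structure(list(populations = fin$populations,
                              species_id = fin$species_id,
                              birth_step = fin$birth_step,
                              n_substantial_at_birth =
                                fin$n_substantial_at_birth,
                              step = fin$step, next_id = fin$next_id,
                              params_ref = if (!is.null(sp))
                                species_params(
                                  omega = fin$omega,
                                  c = if (length(fin$c)) fin$c else NULL,
                                  gamma_i = if (length(fin$gamma_i))
                                    fin$gamma_i else NULL)
                              else NULL),
                         class = "community_state")
  class(run) <- "divwave_run"
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.divwave_run <- function(x, ...) {
  cat(sprintf("divwave run: variant '%s', N = %d, gamma = %g\n",
              x$params$variant, x$params$N, x$params$gamma))
  cat(sprintf("  %d collapse steps (burn-in %d), seed %d, engine %s\n",
              x$n_steps, x$burn_in, x$seed, x$engine))
  if (!is.null(x$events))
    cat(sprintf("  %d wave boundaries\n", sum(x$events$is_wave_boundary)))
  invisible(x)
}

# Pure-R engine: loops step_community() and mirrors the compiled recorders.
# Intentionally naive; used for small-n validation of the compiled path.
.sim_engine_r <- function(state, params, n_steps, burn_in, record, edges,
                          wave_threshold, substantial_threshold) {
  N <- params$N
  nb <- length(edges) - 1L
  sad_counts <- numeric(nb); sad_n <- 0
  green <- numeric(nb); red <- numeric(nb); snap_n <- 0
  ev <- vector("list", n_steps)
  D <- numeric(n_steps); pmax_t <- numeric(n_steps)
  bin_of <- function(P) {
    b <- floor((log10(pmax(P, .Machine$double.xmin)) - edges[1]) /
                 (edges[2] - edges[1]))
    pmin(pmax(b, 0), nb - 1) + 1
  }
  for (t in seq_len(n_steps)) {
    st <- step_community(state, params, wave_threshold,
                         substantial_threshold)
    state <- st$state
    e <- st$event
    aggregate <- t > burn_in
    if ("snapshots" %in% record && e$is_wave_boundary && aggregate) {
      pre <- attr(e, "pre_saturation_populations")
      for (b in bin_of(pre)) green[b] <- green[b] + 1
      for (b in bin_of(state$populations)) red[b] <- red[b] + 1
      snap_n <- snap_n + 1
    }
    if ("sad" %in% record && aggregate) {
      for (b in bin_of(state$populations))
        sad_counts[b] <- sad_counts[b] + 1
      sad_n <- sad_n + 1
    }
    if ("diversity" %in% record) {
      D[t] <- diversity(state$populations)
      pmax_t[t] <- max(state$populations)
    }
    attr(e, "pre_saturation_populations") <- NULL
    ev[[t]] <- e
  }
  events <- do.call(rbind, lapply(ev, function(e)
    as.data.frame(unclass(e), stringsAsFactors = FALSE)))
  events <- events[, c("step", "victim_index", "victim_species_id",
                       "victim_birth_step",
                       "victim_n_substantial_at_birth",
                       "pre_collapse_size", "rescale_factor",
                       "is_wave_boundary")]
  pr <- state$params_ref
  list(events = events,
       diversity = data.frame(step = seq_len(n_steps), D = D,
                              P_max = pmax_t),
       sad_counts = sad_counts, sad_n = sad_n,
       green_counts = green, red_counts = red, snap_n = snap_n,
       species_stats = NULL,
       final = c(unclass(state),
                 list(omega = if (!is.null(pr)) pr$omega else numeric(0),
                      c = if (!is.null(pr) && !all(is.na(pr$c)))
                        pr$c else numeric(0),
                      gamma_i = if (!is.null(pr) &&
                                    !all(is.na(pr$gamma_i)))
                        pr$gamma_i else numeric(0))))
}
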