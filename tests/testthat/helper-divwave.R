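# Shared fixtures, all generated in code.

# Inverse-CDF sampler for a Pareto density ~ P^-tau truncated to [lo, hi].
rpower_trunc <- function(n, tau, lo, hi) {
  u <- runif(n)
  if (abs(tau - 1) < 1e-12) return(lo * (hi / lo)^u)
  a <- lo^(1 - tau)
  b <- hi^(1 - tau)
  (a + u * (b - a))^(1 / (1 - tau))
}

# Bin raw samples into a sad_histogram (vectorised accumulate).
hist_from_samples <- function(x, support, bins_per_decade = 5) {
  h <- sad_histogram(sad_bin_edges(support, bins_per_decade))
  e <- h$log10_bin_edges
  nb <- length(e) - 1L
  b <- floor((log10(x) - e[1]) / (e[2] - e[1]))
  b <- pmin(pmax(b, 0), nb - 1) + 1
  h$counts <- tabulate(b, nb)
  h$n_snapshots <- 1
  h
}

# Pool time-aggregated histograms over several independent seeds.
pooled_sad <- function(params, seeds, n_steps, ...) {
  h <- NULL
  for (s in seeds) {
    run <- simulate_community(params, n_steps, seed = s, record = "sad",
                              ...)
    if (is.null(h)) h <- run$sad
    else {
      h$counts <- h$counts + run$sad$counts
      h$n_snapshots <- h$n_snapshots + run$sad$n_snapshots
    }
  }
  h
}

# Hand-built saturated community state for unit-level operation tests.
make_state <- function(populations, species_id = seq_along(populations) - 1L,
                       step = 0L, params_ref = NULL) {
  structure(list(populations = populations,
                 species_id = as.integer(species_id),
                 birth_step = rep(0L, length(populations)),
                 n_substantial_at_birth = rep(length(populations),
                                              length(populations)),
                 step = as.integer(step),
                 next_id = max(species_id) + 1L,
                 params_ref = params_ref),
            class = "community_state")
}
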