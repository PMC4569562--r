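#' Inverse Simpson diversity
#'
#' \eqn{D = 1 / \sum_i P_i^2}, ranging from 1 (one species holds the whole
#' carrying capacity) to \code{N} (all species equally abundant). The
#' diversity trace is the primary signature of the wave dynamics: it jumps
#' to ~N when a dominant species collapses and then decays as
#' \eqn{e^{-t/N}}.
#'
#' @param populations numeric vector of population fractions (or a
#'   \code{community_state}).
#' @return the scalar diversity.
#' @examples
#' diversity(c(1, 0, 0))        # 1
#' diversity(rep(0.25, 4))      # 4
#' @export
diversity <- function(populations) {
  if (inherits(populations, "community_state"))
    populations <- populations$populations
  q <- sum(populations^2)
  if (q == 0) stop("all populations are zero")
  1 / q
}

#' Log-binned abundance histogram
#'
#' Container for the (time-aggregated or snapshot) species abundance
#' distribution: counts of species-step observations in log10 population
#' bins. The density \eqn{\pi(P) = d\,\mathrm{Prob}(P_i > P) / d\log_{10}P}
#' is obtained with \code{\link{sad_density}} and integrates to 1 over
#' \eqn{\log_{10} P}.
#'
#' @param edges increasing numeric vector of log10 bin edges, or the result
#'   of \code{\link{sad_bin_edges}}.
#' @param counts optional initial per-bin counts (default all 0).
#' @param n_snapshots number of state snapshots already aggregated.
#' @return an object of class \code{"sad_histogram"}.
#' @export
sad_histogram <- function(edges, counts = NULL, n_snapshots = 0) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  nb <- length(edges) - 1L
  if (is.null(counts)) counts <- numeric(nb)
  if (length(counts) != nb) stop("counts must have length(edges) - 1")
  structure(list(log10_bin_edges = edges, counts = counts,
                 n_snapshots = n_snapshots),
            class = "sad_histogram")
}

#' Log10 bin edges over a population range
#'
#' @param support numeric pair c(P_low, P_high), P_low > 0.
#' @param bins_per_decade bins per factor of 10 (default 5).
#' @return numeric vector of log10 edges spanning at least the support.
#' @export
sad_bin_edges <- function(support, bins_per_decade = 5) {
  if (length(support) != 2 || support[1] <= 0 || support[1] >= support[2])
    stop("support must be an increasing positive pair")
  w <- 1 / bins_per_decade
  lo <- log10(support[1])
  hi <- log10(support[2])
  seq(lo, lo + w * ceiling((hi - lo) / w - 1e-9), by = w)
}

#' @export
print.sad_histogram <- function(x, ...) {
  cat(sprintf("sad_histogram: %d bins on log10 P in [%g, %g], %g snapshots, %g counts\n",
              length(x$counts), x$log10_bin_edges[1],
              x$log10_bin_edges[length(x$log10_bin_edges)],
              x$n_snapshots, sum(x$counts)))
  invisible(x)
}

#' Accumulate one community snapshot into a histogram
#'
#' Each of the current populations increments its log10 bin; values outside
#' the histogram support are clamped into the edge bins so that the total
#' count after k snapshots of an N-species community is exactly k*N.
#'
#' @param histogram a \code{\link{sad_histogram}}.
#' @param state a \code{community_state} or a numeric population vector.
#' @return the updated histogram.
#' @export
accumulate_sad <- function(histogram, state) {
  P <- if (inherits(state, "community_state")) state$populations else state
  if (any(P <= 0)) stop("cannot log-bin non-positive populations")
  e <- histogram$log10_bin_edges
  nb <- length(e) - 1L
  b <- floor((log10(P) - e[1]) / (e[2] - e[1]))
  b <- pmin(pmax(b, 0), nb - 1) + 1
  tb <- tabulate(b, nbins = nb)
  histogram$counts <- histogram$counts + tb
  histogram$n_snapshots <- histogram$n_snapshots + 1
  histogram
}

#' Normalised log-binned density
#'
#' @param histogram a \code{\link{sad_histogram}}.
#' @return data.frame with bin edges, centers (log10), counts and the
#'   density pi(P) normalised to integrate to 1 over log10 P.
#' @export
sad_density <- function(histogram) {
  e <- histogram$log10_bin_edges
  w <- diff(e)
  total <- sum(histogram$counts)
  data.frame(log10_low = e[-length(e)], log10_high = e[-1],
             log10_center = (e[-length(e)] + e[-1]) / 2,
             count = histogram$counts,
             density = if (total > 0) histogram$counts / (total * w)
                       else rep(NA_real_, length(w)))
}

#' Snapshot abundance distributions at wave boundaries
#'
#' Extracts the two special distributions aggregated only at wave-boundary
#' events: the "green" phase (immediately after the dominant species was
#' eliminated, before the freed-up biomass was redistributed — populations
#' mostly between gamma and gamma*N) and the "red" phase (immediately after
#' the common rescale by ~N — populations between ~N*gamma and 1). The two
#' phases differ by the boundary event's rescale factor, a pure shift in
#' log space.
#'
#' @param run a \code{\link{simulate_community}} result with the
#'   \code{"snapshots"} recorder enabled.
#' @param phase \code{"pre_rescale_at_wave_end"} (green) or
#'   \code{"post_rescale_at_wave_start"} (red).
#' @return a \code{\link{sad_histogram}}.
#' @export
snapshot_sad <- function(run, phase = c("pre_rescale_at_wave_end",
                                        "post_rescale_at_wave_start")) {
  phase <- match.arg(phase)
  h <- if (phase == "pre_rescale_at_wave_end") run$green else run$red
  if (is.null(h))
    stop("run was simulated without the 'snapshots' recorder")
  if (h$n_snapshots == 0)
    warning("no wave boundaries occurred after burn-in; histogram is empty")
  h
}

#' Segment a run into diversity waves
#'
#' A wave boundary is a collapse of a dominating population: an event whose
#' pre-collapse size exceeds \code{threshold} (default \code{1 - 1/N}).
#' The interval between consecutive boundaries is one diversity wave; its
#' duration is measured in collapse events.
#'
#' @param events event data frame from \code{\link{simulate_community}}
#'   (columns \code{step}, \code{pre_collapse_size}, ...).
#' @param N number of species slots.
#' @param threshold boundary threshold on the pre-collapse size.
#' @return an object of class \code{"wave_stats"}: list with
#'   \code{boundaries} (boundary step indices), \code{durations}
#'   (successive differences), \code{threshold}, \code{N}.
#' @export
detect_waves <- function(events, N, threshold = 1 - 1 / N) {
  if (is.null(events) || nrow(events) == 0)
    return(structure(list(boundaries = integer(0), durations = numeric(0),
                          threshold = threshold, N = N),
                     class = "wave_stats"))
  b <- events$step[events$pre_collapse_size > threshold]
  structure(list(boundaries = b, durations = diff(b),
                 threshold = threshold, N = N),
            class = "wave_stats")
}

#' @export
print.wave_stats <- function(x, ...) {
  cat(sprintf("wave_stats: %d boundaries (threshold %.4g), mean duration %.1f steps\n",
              length(x$boundaries), x$threshold,
              if (length(x$durations)) mean(x$durations) else NA))
  invisible(x)
}

#' Wave-level summary statistics
#'
#' Computes, per complete wave: the duration and the e-folding decay
#' constant of the diversity, obtained by least squares on
#' \eqn{\ln D(t)} over the wave interior (a fraction \code{trim} is
#' discarded at each end to avoid boundary transients). The expectation is
#' a mean duration of about \eqn{N \ln N} and decay constants near \code{N}.
#' If \code{events} are supplied, the wave-start survivor curve
#' \eqn{N_{surv}(t)} (species alive at the wave start not yet collapsed at
#' t) is pooled across waves and fitted to \eqn{N e^{-t/N}}.
#'
#' @param waves a \code{\link{detect_waves}} result.
#' @param diversity_trace data frame with columns \code{step}, \code{D}.
#' @param events optional event data frame (enables the survivor fit).
#' @param trim fraction trimmed at each wave end for the decay fit.
#' @param min_waves minimum number of complete waves required.
#' @return list with \code{n_waves}, \code{mean_duration},
#'   \code{median_duration}, per-wave \code{decay_constants},
#'   \code{median_decay_constant}, and (with events) \code{survivor_rate}
#'   (fitted e-folding rate of the survivor curve, to compare with
#'   \code{1/N}) and \code{survivor_curve} (pooled mean over waves).
#' @export
wave_statistics <- function(waves, diversity_trace, events = NULL,
                            trim = 0.05, min_waves = 5) {
  stopifnot(inherits(waves, "wave_stats"))
  b <- waves$boundaries
  if (length(b) < min_waves + 1)
    stop(sprintf("only %d complete waves; need >= %d (run longer)",
                 max(length(b) - 1, 0), min_waves))
  decay <- rep(NA_real_, length(b) - 1)
  for (k in seq_len(length(b) - 1)) {
    t0 <- b[k]; t1 <- b[k + 1]
    len <- t1 - t0
    lo <- t0 + max(1, ceiling(trim * len))
    hi <- t1 - max(1, ceiling(trim * len))
    if (hi - lo < 5) next
    idx <- which(diversity_trace$step >= lo & diversity_trace$step <= hi)
    if (length(idx) < 5) next
    fit <- lm(log(diversity_trace$D[idx]) ~ diversity_trace$step[idx])
    sl <- coef(fit)[2]
    if (is.finite(sl) && sl < 0) decay[k] <- -1 / sl
  }
  out <- list(n_waves = length(b) - 1,
              mean_duration = mean(waves$durations),
              median_duration = median(waves$durations),
              decay_constants = decay,
              median_decay_constant = median(decay, na.rm = TRUE))
  if (!is.null(events)) {
    sc <- survivor_curve(events, waves)
    out$survivor_curve <- sc
    ok <- sc$n_surv > 0 & sc$t <= 2 * waves$N
    fit <- lm(log(sc$n_surv[ok]) ~ sc$t[ok])
    out$survivor_rate <- -unname(coef(fit)[2])
  }
  out
}

#' Pooled wave-start survivor curve
#'
#' For each complete wave, counts how many of the species alive at the wave
#' start have not yet collapsed t steps later, then averages across waves.
#' Under uniform victim selection each incumbent is hit with probability
#' 1/N per step, so the curve decays as \eqn{N e^{-t/N}}.
#'
#' @param events event data frame (needs \code{victim_birth_step}).
#' @param waves a \code{\link{detect_waves}} result.
#' @return data.frame with columns \code{t} (steps since wave start) and
#'   \code{n_surv} (mean surviving incumbents over waves covering t).
#' @export
survivor_curve <- function(events, waves) {
  b <- waves$boundaries
  N <- waves$N
  if (length(b) < 2) stop("need at least one complete wave")
  tmax <- max(waves$durations)
  acc <- numeric(tmax + 1)
  cov <- numeric(tmax + 1)
  for (k in seq_len(length(b) - 1)) {
    t0 <- b[k]; t1 <- b[k + 1]
    ev <- events[events$step > t0 & events$step <= t1, ]
    # incumbents: born at or before the wave start
    kills <- ev$step[ev$victim_birth_step <= t0]
    dur <- t1 - t0
    ns <- N - cumsum(tabulate(kills - t0, nbins = dur))
    idx <- seq_len(dur + 1)
    acc[idx] <- acc[idx] + c(N, ns)
    cov[idx] <- cov[idx] + 1
  }
  data.frame(t = 0:tmax, n_surv = acc / pmax(cov, 1))[cov > 0, ]
}

#' Fit the power-law tail exponent of an abundance distribution
#'
#' Estimates \eqn{\tau}, the exponent of the abundance distribution on the
#' linear scale, \eqn{d\,\mathrm{Prob}(P_i > P)/dP \propto P^{-\tau}}. On
#' the log-binned density the corresponding slope is \eqn{-(\tau - 1)}, so
#' \code{tau = 1 - slope}.
#'
#' Two estimators are provided. \code{"logbin_ls"} takes a
#' \code{\link{sad_histogram}} and fits the least-squares slope of
#' \eqn{\log_{10} \pi} vs \eqn{\log_{10} P} over the non-empty bins whose
#' centers fall in \code{fit_range}. \code{"mle"} takes a vector of raw
#' abundance samples and maximises the likelihood of a Pareto density
#' truncated to \code{fit_range} (a Hill-type estimator, used as an
#' independent cross-check of the binned fit).
#'
#' @param x a \code{sad_histogram} (\code{method = "logbin_ls"}) or a
#'   numeric sample vector (\code{method = "mle"}).
#' @param fit_range numeric pair of population sizes; the canonical tail
#'   window is \code{c(1/N, 1)}.
#' @param method \code{"logbin_ls"} or \code{"mle"}.
#' @return an object of class \code{"tail_fit"}: list with \code{tau},
#'   \code{slope} (= 1 - tau), \code{stderr}, \code{fit_range},
#'   \code{method}, and \code{n_used} (bins or samples).
#' @examples
#' # tau = 2 synthetic sample via inverse-CDF
#' u <- runif(1e4); a <- 1e-3
#' x <- a / (1 - u * (1 - a))       # density ~ P^-2 on [a, 1]
#' fit_powerlaw_tail(x, c(a, 1), method = "mle")
#' @export
fit_powerlaw_tail <- function(x, fit_range, method = c("logbin_ls", "mle")) {
  method <- match.arg(method)
  if (length(fit_range) != 2 || fit_range[1] <= 0 ||
      fit_range[1] >= fit_range[2])
    stop("fit_range must be an increasing positive pair")
  if (method == "logbin_ls") {
    if (!inherits(x, "sad_histogram"))
      stop("logbin_ls needs a sad_histogram")
    d <- sad_density(x)
    sel <- d$count > 0 & d$log10_center >= log10(fit_range[1]) &
      d$log10_center <= log10(fit_range[2])
    if (sum(sel) < 4)
      stop(sprintf("only %d non-empty bins in [%g, %g]; need >= 4",
                   sum(sel), fit_range[1], fit_range[2]))
    fit <- lm(log10(density) ~ log10_center, data = d[sel, ])
    slope <- unname(coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    structure(list(tau = 1 - slope, slope = slope, stderr = se,
                   fit_range = fit_range, method = method,
                   n_used = sum(sel)),
              class = "tail_fit")
  } else {
    if (!is.numeric(x)) stop("mle needs a numeric sample vector")
    s <- x[x >= fit_range[1] & x <= fit_range[2]]
    if (length(s) < 10)
      stop(sprintf("only %d samples in [%g, %g]; need >= 10",
                   length(s), fit_range[1], fit_range[2]))
    a <- fit_range[1]; b <- fit_range[2]
    mls <- mean(log(s))
    nll <- function(tau) {
      logZ <- if (abs(tau - 1) < 1e-8) log(log(b / a))
              else log((b^(1 - tau) - a^(1 - tau)) / (1 - tau))
      tau * mls + logZ
    }
    opt <- optimize(nll, c(0.01, 10))
    # curvature-based standard error
    h <- 1e-4
    d2 <- (nll(opt$minimum + h) - 2 * nll(opt$minimum) +
             nll(opt$minimum - h)) / h^2
    se <- if (d2 > 0) 1 / sqrt(length(s) * d2) else NA_real_
    structure(list(tau = opt$minimum, slope = 1 - opt$minimum, stderr = se,
                   fit_range = fit_range, method = method,
                   n_used = length(s)),
              class = "tail_fit")
  }
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("tail_fit (%s): tau = %.3f (slope %.3f, se %.3g) on [%g, %g], n = %d\n",
              x$method, x$tau, x$slope, x$stderr,
              x$fit_range[1], x$fit_range[2], x$n_used))
  invisible(x)
}

#' Locate the two peaks of a bimodal abundance distribution and the slope
#' between them
#'
#' The time-aggregated distribution is bimodal: a lower peak of recently
#' collapsed / newly seeded populations (around gamma..gamma*N) and an
#' upper peak of not-yet-collapsed populations (around 1/N..1). When the
#' peaks are well separated the connecting region is a power law whose
#' log-binned slope has the same magnitude \eqn{\tau - 1} as the tail but
#' the opposite sign.
#'
#' Between the two modes the density passes through a minimum (the dip);
#' the "connecting region" whose slope carries a single sign is the rising
#' segment from that dip up to the upper peak, and that is what this
#' function fits (a window straddling the dip would mix the falling flank
#' of the lower peak with the rising segment and average their slopes
#' away).
#'
#' @param histogram a \code{\link{sad_histogram}}.
#' @param split log10 population separating the lower- and upper-peak
#'   search windows; defaults to the geometric midpoint
#'   \code{(log10(support_low) + log10(1/N))/2} implied by the histogram
#'   support when \code{N} is given, otherwise the support midpoint.
#' @param N number of species (used for the default split).
#' @param trim_bins bins skipped next to the dip and next to the upper
#'   peak before fitting (default 2, avoiding their curvature).
#' @return list with \code{lower_peak}, \code{dip}, \code{upper_peak}
#'   (log10 centers), \code{slope}, \code{stderr}, \code{n_used}.
#' @export
interpeak_slope <- function(histogram, split = NULL, N = NULL,
                            trim_bins = 2) {
  d <- sad_density(histogram)
  if (is.null(split)) {
    lo <- d$log10_center[1]
    hi <- if (!is.null(N)) -log10(N) else d$log10_center[nrow(d)]
    split <- (lo + hi) / 2
  }
  low <- d[d$log10_center <= split & d$count > 0, ]
  up <- d[d$log10_center > split & d$count > 0, ]
  if (nrow(low) == 0 || nrow(up) == 0)
    stop("could not locate two peaks on either side of the split")
  lp <- low$log10_center[which.max(low$density)]
  upk <- up$log10_center[which.max(up$density)]
  mid <- d[d$log10_center > lp & d$log10_center < upk & d$count > 0, ]
  if (nrow(mid) == 0) stop("no non-empty bins between the peaks")
  dip <- mid$log10_center[which.min(mid$density)]
  w <- d$log10_high[1] - d$log10_low[1]
  sel <- d$log10_center > dip + trim_bins * w &
    d$log10_center < upk - trim_bins * w & d$count > 0
  if (sum(sel) < 4)
    stop("fewer than 4 non-empty bins between the dip and the upper peak")
  fit <- lm(log10(density) ~ log10_center, data = d[sel, ])
  list(lower_peak = lp, dip = dip, upper_peak = upk,
       slope = unname(coef(fit)[2]),
       stderr = summary(fit)$coefficients[2, 2],
       n_used = sum(sel))
}

#' Jump series: cross-wave memory observable
#'
#' For every collapse of a substantial population
#' (\code{pre_collapse_size > substantial_threshold}), records the jump
#' \eqn{-\ln(1 - P_{collapsed})} experienced by the logarithm of all
#' surviving populations, together with the time since the current wave
#' started and the number of substantial populations present when the
#' victim was originally seeded (the colour variable revealing which
#' sub-peak of the previous wave the victim belonged to). The binned mean
#' jump grows as \eqn{e^{t/N}/N} within a wave.
#'
#' @param events event data frame from \code{\link{simulate_community}}.
#' @param waves optional \code{\link{detect_waves}} result (computed from
#'   the events if omitted; requires \code{N} in that case).
#' @param substantial_threshold inclusion cut on the pre-collapse size.
#' @param N species count, used only when \code{waves} is omitted.
#' @return data.frame with columns \code{step}, \code{t_in_wave} (steps
#'   since the last wave boundary; NA before the first boundary),
#'   \code{jump}, \code{n_substantial_at_birth}.
#' @export
jump_series <- function(events, waves = NULL, substantial_threshold = 1e-10,
                        N = NULL) {
  if (is.null(waves)) {
    if (is.null(N)) stop("supply either waves or N")
    waves <- detect_waves(events, N)
  }
  ev <- events[events$pre_collapse_size > substantial_threshold, ]
  b <- waves$boundaries
  idx <- if (length(b)) findInterval(ev$step - 1, b) else
    rep(0L, nrow(ev))
  last_b <- ifelse(idx == 0, NA_integer_, b[pmax(idx, 1L)])
  data.frame(step = ev$step,
             t_in_wave = ev$step - last_b,
             jump = -log1p(-ev$pre_collapse_size),
             n_substantial_at_birth = ev$victim_n_substantial_at_birth)
}

#' Mean population as a function of fitness traits
#'
#' Bins species by their traits (log-spaced) and reports the mean
#' time-averaged population per cell, reproducing the fitness-heatmap view:
#' species with larger growth rates and larger survivor ratios carry
#' systematically larger populations. Also returns the 1-D marginals.
#'
#' @param species_stats data frame from a run with the
#'   \code{"species_stats"} recorder (columns \code{omega}, \code{c} or
#'   \code{gamma_i}, \code{mean_P}, \code{n_obs}).
#' @param x,y trait column names for the two axes (default \code{"omega"}
#'   and \code{"gamma_i"}; use \code{y = "c"} for the fitness variant).
#' @param n_bins number of log-spaced bins per axis.
#' @return list with \code{grid} (x-bin by y-bin matrix of mean
#'   \code{mean_P}, \code{NA} for empty cells), \code{x_breaks},
#'   \code{y_breaks}, and marginal data frames \code{marginal_x},
#'   \code{marginal_y}.
#' @export
fitness_population_map <- function(species_stats, x = "omega",
                                   y = "gamma_i", n_bins = 10) {
  for (col in c(x, y, "mean_P"))
    if (is.null(species_stats[[col]]) || all(is.na(species_stats[[col]])))
      stop(sprintf("species_stats lacks usable column '%s'", col))
  xs <- species_stats[[x]]; ys <- species_stats[[y]]
  xb <- exp(seq(log(min(xs)), log(max(xs)), length.out = n_bins + 1))
  yb <- exp(seq(log(min(ys)), log(max(ys)), length.out = n_bins + 1))
  xi <- pmin(pmax(findInterval(xs, xb, rightmost.closed = TRUE), 1), n_bins)
  yi <- pmin(pmax(findInterval(ys, yb, rightmost.closed = TRUE), 1), n_bins)
  grid <- matrix(NA_real_, n_bins, n_bins)
  agg <- tapply(species_stats$mean_P, list(xi, yi), mean)
  grid[cbind(as.integer(rep(rownames(agg), ncol(agg))),
             as.integer(rep(colnames(agg), each = nrow(agg))))] <-
    as.vector(agg)
  mx <- tapply(species_stats$mean_P, xi, mean)
  my <- tapply(species_stats$mean_P, yi, mean)
  list(grid = grid, x_breaks = xb, y_breaks = yb,
       marginal_x = data.frame(bin = as.integer(names(mx)),
                               center = sqrt(xb[-length(xb)] * xb[-1])[
                                 as.integer(names(mx))],
                               mean_P = as.numeric(mx)),
       marginal_y = data.frame(bin = as.integer(names(my)),
                               center = sqrt(yb[-length(yb)] * yb[-1])[
                                 as.integer(names(my))],
                               mean_P = as.numeric(my)))
}
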