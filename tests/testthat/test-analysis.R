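test_that("inverse Simpson diversity has its closed-form values", {
  expect_equal(diversity(c(1, 0, 0)), 1)
  expect_equal(diversity(c(0.5, 0.3, 0.2)), 1 / 0.38)
  for (N in c(2, 10, 1000)) expect_equal(diversity(rep(1 / N, N)), N)
  expect_error(diversity(c(0, 0)), "zero")
})

test_that("histogram accumulation conserves counts", {
  h <- sad_histogram(sad_bin_edges(c(1e-6, 1), 5))
  # three populations inside one bin
  h1 <- accumulate_sad(h, c(2.1e-3, 2.2e-3, 2.3e-3))
  expect_equal(sum(h1$counts), 3)
  expect_equal(max(h1$counts), 3)
  expect_equal(h1$n_snapshots, 1)
  # k snapshots of N populations: total count k*N, even with values
  # outside the support (clamped into edge bins)
  set.seed(1)
  for (k in 1:5) h <- accumulate_sad(h, 10^runif(7, -8, 0.5))
  expect_equal(sum(h$counts), 5 * 7)
  expect_error(accumulate_sad(h, c(0.1, 0)), "non-positive")
})

test_that("log-uniform samples give a flat log-binned density", {
  set.seed(2)
  x <- 10^runif(2e5, -3, 0)
  h <- hist_from_samples(x, c(1e-3, 1), 5)
  d <- sad_density(h)
  # every bin density ~ 1/3 (flat over 3 decades), binomial error
  expect_equal(d$density, rep(1 / 3, nrow(d)), tolerance = 0.05)
  # and the fitted exponent is tau = 1 (slope 0)
  fit <- fit_powerlaw_tail(h, c(1e-3, 1))
  expect_equal(fit$slope, 0, tolerance = 0.02)
  expect_equal(fit$tau, 1, tolerance = 0.02)
})

test_that("tail estimators recover a known exponent", {
  set.seed(3)
  x <- rpower_trunc(1e6, 2, 1e-3, 1)
  h <- hist_from_samples(x, c(1e-3, 1), 5)
  ls <- fit_powerlaw_tail(h, c(1e-3, 1))
  ml <- fit_powerlaw_tail(x, c(1e-3, 1), method = "mle")
  expect_equal(ls$tau, 2, tolerance = 0.05)
  expect_equal(ml$tau, 2, tolerance = 0.05)
  expect_lt(abs(ls$tau - ml$tau), 0.1)
  expect_equal(ls$slope, 1 - ls$tau)

  # a second exponent, to make sure nothing is hard-wired
  set.seed(4)
  x7 <- rpower_trunc(2e5, 1.7, 1e-4, 1)
  h7 <- hist_from_samples(x7, c(1e-4, 1), 5)
  expect_equal(fit_powerlaw_tail(h7, c(1e-4, 1))$tau, 1.7,
               tolerance = 0.05)
  expect_equal(fit_powerlaw_tail(x7, c(1e-4, 1), method = "mle")$tau, 1.7,
               tolerance = 0.05)

  expect_error(fit_powerlaw_tail(h, c(0.5, 1)), "non-empty bins|need")
  expect_error(fit_powerlaw_tail(h, c(1, 0.1)), "increasing")
})

test_that("wave boundaries follow the dominance threshold", {
  ev <- data.frame(step = c(10L, 20L, 30L, 40L),
                   pre_collapse_size = c(0.5, 0.999, 0.2, 0.96),
                   victim_birth_step = c(0L, 0L, 25L, 0L))
  w <- detect_waves(ev, N = 20)  # threshold 1 - 1/20 = 0.95
  expect_equal(w$boundaries, c(20L, 40L))
  expect_equal(w$durations, 20L)
  # all events below threshold: no boundaries
  w0 <- detect_waves(ev, N = 2)  # threshold 0.5
  expect_equal(w0$boundaries, c(20L, 40L))
  w1 <- detect_waves(ev[ev$pre_collapse_size < 0.9, ], N = 20)
  expect_length(w1$boundaries, 0)
  expect_length(detect_waves(ev[0, ], N = 20)$boundaries, 0)
})

test_that("wave statistics recover a constructed exponential decay", {
  # synthetic diversity trace: waves of length 500, D = 100 exp(-t/150)
  N <- 100
  b <- seq(500, 5000, by = 500)
  steps <- 1:5000
  t_in <- steps - b[pmax(findInterval(steps - 1, b), 1)]
  t_in[steps <= 500] <- steps[steps <= 500]
  D <- 100 * exp(-t_in / 150)
  ev <- data.frame(step = b, pre_collapse_size = 0.999,
                   victim_birth_step = 0L)
  w <- detect_waves(ev, N)
  ws <- wave_statistics(w, data.frame(step = steps, D = D), min_waves = 5)
  expect_equal(ws$median_decay_constant, 150, tolerance = 0.02)
  expect_equal(ws$mean_duration, 500)
  expect_error(wave_statistics(detect_waves(ev[1:3, ], N),
                               data.frame(step = steps, D = D)),
               "complete waves")
})

test_that("survivor curve matches a brute-force count", {
  # two waves; victims listed with their birth steps
  ev <- data.frame(step = c(5L, 10L, 12L, 15L, 20L, 22L, 25L, 30L),
                   pre_collapse_size = c(0.99, 0.1, 0.1, 0.1, 0.99,
                                         0.1, 0.1, 0.99),
                   victim_birth_step = c(0L, 2L, 11L, 3L, 9L,
                                         21L, 18L, 24L))
  N <- 5
  w <- detect_waves(ev, N, threshold = 0.95)  # boundaries 5, 20, 30
  sc <- survivor_curve(ev, w)
  # wave 1 (steps 6..20): incumbents = born <= 5; kills at t = 5 (birth 3)
  # and t = 15 (birth 9 > 5? no -> not incumbent)... brute force:
  brute <- function(t0, t1) {
    ev_w <- ev[ev$step > t0 & ev$step <= t1, ]
    sapply(0:(t1 - t0), function(t)
      N - sum(ev_w$victim_birth_step <= t0 & ev_w$step <= t0 + t))
  }
  b1 <- brute(5, 20); b2 <- brute(20, 30)
  pooled <- sapply(0:15, function(t) {
    vals <- c(if (t <= 15) b1[t + 1], if (t <= 10) b2[t + 1])
    mean(vals)
  })
  expect_equal(sc$n_surv, pooled)
})

test_that("jump series filters, assigns waves, and transforms sizes", {
  ev <- data.frame(step = c(5L, 8L, 12L, 20L),
                   pre_collapse_size = c(0.999, 1e-12, 0.5, 1 - 1 / 20),
                   victim_birth_step = 0L,
                   victim_n_substantial_at_birth = c(3L, 4L, 5L, 6L))
  w <- detect_waves(ev, N = 20)  # boundaries at 5 and 20
  js <- jump_series(ev, w, substantial_threshold = 1e-10)
  # the 1e-12 event is excluded
  expect_equal(js$step, c(5L, 12L, 20L))
  # event at 12 is 7 steps into the wave that started at 5
  expect_equal(js$t_in_wave, c(NA, 7L, 15L))
  # jump of a dominant with P = 1 - 1/N is exactly log(N)
  expect_equal(js$jump[3], log(20))
  expect_equal(js$jump[2], -log(0.5))
  expect_equal(js$n_substantial_at_birth, c(3L, 5L, 6L))
})

test_that("inter-peak slope is recovered from a constructed bimodal density", {
  # piecewise power-law density on log10 P in [-10, 0]:
  # lower peak flank falling at -0.8 from -10 to -7, rising connector at
  # +0.6 from -7 to -3, tail falling at -0.6 from -3 to 0
  edges <- sad_bin_edges(c(1e-10, 1), 5)
  ctr <- (edges[-length(edges)] + edges[-1]) / 2
  logd <- ifelse(ctr < -7, -0.8 * (ctr + 10) + 4,
          ifelse(ctr < -3, 0.6 * (ctr + 7) + 4 - 0.8 * 3,
                 -0.6 * (ctr + 3) + 4 - 2.4 + 2.4))
  counts <- round(10^logd)
  h <- sad_histogram(edges, counts = counts, n_snapshots = 1)
  ip <- interpeak_slope(h, N = 1000)
  expect_equal(ip$lower_peak, ctr[1], tolerance = 0.2)
  expect_equal(ip$dip, -7, tolerance = 0.3)
  expect_equal(ip$upper_peak, -3, tolerance = 0.3)
  expect_equal(ip$slope, 0.6, tolerance = 0.02)
})

test_that("fitness map reproduces brute-force cell means and partitions", {
  set.seed(5)
  n <- 400
  ss <- data.frame(omega = exp(runif(n, log(0.1), log(1))),
                   gamma_i = exp(runif(n, log(1e-9), log(1e-2))),
                   mean_P = runif(n), n_obs = 100L)
  fm <- fitness_population_map(ss, n_bins = 5)
  xi <- pmin(pmax(findInterval(ss$omega, fm$x_breaks,
                               rightmost.closed = TRUE), 1), 5)
  yi <- pmin(pmax(findInterval(ss$gamma_i, fm$y_breaks,
                               rightmost.closed = TRUE), 1), 5)
  for (i in 1:5) for (j in 1:5) {
    sel <- xi == i & yi == j
    if (any(sel)) expect_equal(fm$grid[i, j], mean(ss$mean_P[sel]))
    else expect_true(is.na(fm$grid[i, j]))
  }
  # every species contributes to exactly one cell
  expect_equal(sum(table(xi, yi)), n)
  expect_error(fitness_population_map(ss[, c("omega", "mean_P")]),
               "lacks usable column")
})

test_that("snapshot distributions behave at wave boundaries", {
  # equalized-start runs concentrate the red phase at exactly 1/N
  N <- 100
  p <- model_params(N, 1e-9, equalize_at_wave_start = TRUE)
  run <- simulate_community(p, 5e4, seed = 31)
  red <- snapshot_sad(run, "post_rescale_at_wave_start")
  expect_gt(red$n_snapshots, 5)
  d <- sad_density(red)
  top <- which.max(d$count)  # the single bin holding 1/N
  expect_equal(d$count[top], sum(d$count))
  expect_lt(abs(d$log10_center[top] - log10(1 / N)), 0.25)

  # basic run: green phase capped well below 1/N, red phase reaches high
  p2 <- model_params(N, 1e-9)
  run2 <- simulate_community(p2, 2e5, seed = 32)
  g <- sad_density(snapshot_sad(run2, "pre_rescale_at_wave_end"))
  r <- sad_density(snapshot_sad(run2, "post_rescale_at_wave_start"))
  cum <- cumsum(g$count) / sum(g$count)
  p99 <- g$log10_high[which(cum >= 0.99)[1]]
  expect_lt(p99, log10(10 / N))
  expect_gt(max(r$log10_high[r$count > 0]), log10(0.1))

  expect_error(snapshot_sad(list(a = 1), "pre_rescale_at_wave_end"),
               "snapshots")
})

test_that("mean jump grows like exp(t/N)/N within waves", {
  # in the equalized-start model the law is exact: the surviving
  # populations all have size 1/N_surv(t) = exp(t/N)/N, so the mean jump
  # follows both the rate and the absolute level of exp(t/N)/N
  N <- 100
  binned_jumps <- function(run) {
    w <- detect_waves(run$events, N)
    js <- jump_series(run$events, w, substantial_threshold = 1e-8)
    js <- js[!is.na(js$t_in_wave) & js$t_in_wave <= 4 * N, ]
    bins <- cut(js$t_in_wave, breaks = seq(0, 4 * N, by = N / 4))
    m <- tapply(js$jump, bins, mean)
    cnt <- tapply(js$jump, bins, length)
    tt <- seq(N / 8, 4 * N - N / 8, by = N / 4)
    ok <- !is.na(m) & m > 0 & cnt >= 10
    list(t = tt[ok], m = unname(m[ok]))
  }
  rq <- simulate_community(model_params(N, 1e-9,
                                        equalize_at_wave_start = TRUE),
                           2e5, seed = 33, record = "events")
  bj <- binned_jumps(rq)
  rate <- coef(lm(log(bj$m) ~ bj$t))[2]
  expect_equal(unname(1 / rate), N, tolerance = 0.2)
  expect_equal(median(bj$m / (exp(bj$t / N) / N)), 1, tolerance = 0.2)

  # the basic model keeps the exponential growth, with an effective rate
  # of order 1/N (slowed by the unequal wave starts, like the diversity
  # decay)
  rb <- simulate_community(model_params(N, 1e-9), 2e5, seed = 33,
                           record = "events")
  bb <- binned_jumps(rb)
  rate_b <- coef(lm(log(bb$m) ~ bb$t))[2]
  expect_gt(rate_b, 0)
  expect_gt(1 / rate_b, 0.5 * N)
  expect_lt(1 / rate_b, 2.5 * N)
})

test_that("diversity jumps abruptly at wave boundaries", {
  # at gamma ~ 0.01/N the redistribution re-levels all populations and
  # diversity jumps to ~N at every boundary
  N <- 20
  run <- simulate_community(model_params(N, 1e-4), 1e5, seed = 34,
                            record = c("events", "diversity"))
  w <- detect_waves(run$events, N)
  expect_gt(length(w$boundaries), 10)
  D0 <- run$diversity$D[w$boundaries]
  expect_gt(mean(D0 > 0.1 * N), 0.8)
  expect_true(all(run$diversity$D >= 1 - 1e-9 &
                  run$diversity$D <= N + 1e-9))
  # deep in the small-gamma regime the jump is still abrupt (>3x) even
  # though the redistributed populations are no longer near-equal
  run2 <- simulate_community(model_params(100, 1e-9), 1e5, seed = 35,
                             record = c("events", "diversity"))
  w2 <- detect_waves(run2$events, 100)
  b2 <- w2$boundaries
  ratio <- run2$diversity$D[b2] / run2$diversity$D[pmax(b2 - 1, 1)]
  expect_gt(mean(ratio > 3), 0.8)
})
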