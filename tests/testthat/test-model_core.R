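test_that("initial community is uniform at the carrying capacity", {
  for (N in c(2L, 4L, 37L)) {
    s <- init_community(model_params(N, 1e-6))
    expect_equal(s$populations, rep(1 / N, N))
    expect_equal(sum(s$populations), 1)
    expect_equal(diversity(s), N)
    expect_equal(sort(s$species_id), 0:(N - 1L))
    expect_equal(s$birth_step, rep(0L, N))
  }
})

test_that("uniform victim selection is unbiased", {
  set.seed(1)
  s <- make_state(c(0.2, 0.3, 0.5))
  draws <- replicate(1e5, select_victim(s, "uniform"))
  tab <- tabulate(draws, 3)
  expect_gt(chisq.test(tab)$p.value, 1e-4)  # consistent with 1/3 each
})

test_that("power-weighted selection matches enumerated weights", {
  # sigma = 1: victim probability proportional to population size
  set.seed(2)
  s <- make_state(c(0.9, 0.1))
  draws <- replicate(2e4, select_victim(s, "power_weighted", sigma = 1))
  expect_equal(mean(draws == 1), 0.9, tolerance = 0.02)

  # sigma = -0.2 (Kill-the-Loser): oracle = brute-force normalized weights
  set.seed(3)
  P <- c(0.64, 0.32, 0.04)
  w <- P^-0.2 / sum(P^-0.2)
  s <- make_state(P)
  draws <- replicate(1e5, select_victim(s, "power_weighted", sigma = -0.2))
  tab <- tabulate(draws, 3) / 1e5
  expect_equal(tab, w, tolerance = 0.02)
  expect_gt(chisq.test(tabulate(draws, 3), p = w)$p.value, 1e-4)
})

test_that("sigma = 0 weighting is exactly the uniform rule", {
  s <- make_state(c(0.7, 0.2, 0.1))
  set.seed(4); a <- replicate(100, select_victim(s, "uniform"))
  set.seed(4); b <- replicate(100, select_victim(s, "power_weighted",
                                                 sigma = 0))
  expect_identical(a, b)
})

test_that("negative-exponent weighting rejects zero populations", {
  s <- make_state(c(0.5, 0.5, 0))
  set.seed(5)
  expect_error(select_victim(s, "power_weighted", sigma = -0.2),
               "strictly positive")
})

test_that("collapse replaces the victim with a fresh newcomer at gamma", {
  s <- make_state(c(0.5, 0.5))
  out <- apply_collapse(s, 1L, "replace_with_newcomer", gamma = 0.1)
  expect_equal(out$state$populations, c(0.1, 0.5))
  expect_equal(out$event$pre_collapse_size, 0.5)
  expect_equal(out$event$victim_species_id, 0L)
  # the newcomer's id has never been used before
  expect_false(out$state$species_id[1] %in% s$species_id)
  expect_equal(out$state$birth_step[1], 1L)
  # repeated collapses keep producing unseen ids
  seen <- s$species_id
  st <- s
  for (i in 1:20) {
    st <- apply_collapse(st, 1L + i %% 2, gamma = 0.1)$state
    newest <- st$species_id[1 + i %% 2]
    expect_false(newest %in% seen)
    seen <- c(seen, newest)
  }
})

test_that("resilience collapse shrinks the victim in place", {
  sp <- species_params(omega = c(1, 1), gamma_i = c(0.01, 0.5))
  s <- make_state(c(0.9, 0.1), params_ref = sp)
  out <- apply_collapse(s, 1L, "shrink_by_gamma_i")
  expect_equal(out$state$populations, c(0.009, 0.1))
  expect_identical(out$state$species_id, s$species_id)  # same species
})

test_that("common-rate saturation rescales to the carrying capacity", {
  s <- make_state(c(0.5, 0.5))
  s$populations <- c(0.1, 0.5)
  out <- saturate(s)
  expect_equal(out$state$populations, c(1 / 6, 5 / 6))
  expect_equal(out$rescale_factor, 1 / 0.6)
  # saturated input is a fixed point
  out2 <- saturate(out$state)
  expect_equal(out2$state$populations, out$state$populations)
  expect_equal(out2$rescale_factor, 1, tolerance = 1e-12)
  # degenerate inputs
  s$populations <- c(0, 0)
  expect_error(saturate(s), "zero")
  s$populations <- c(0.9, 0.9)
  expect_error(saturate(s), "exceeds")
})

test_that("per-species saturation solves the logistic endpoint exactly", {
  # equal rates reduce to the common rescale (A = ln 5 here)
  s <- make_state(c(0.5, 0.5))
  s$populations <- c(0.1, 0.1)
  out <- saturate(s, omega = c(1, 1))
  expect_equal(out$state$populations, c(0.5, 0.5), tolerance = 1e-10)

  # Omega = (1, 2): with x = e^A, 0.1 x + 0.1 x^2 = 1, so x = (-1+sqrt(41))/2
  x <- (-1 + sqrt(41)) / 2
  out2 <- saturate(s, omega = c(1, 2))
  expect_equal(out2$state$populations, c(0.1 * x, 0.1 * x^2),
               tolerance = 1e-10)
  expect_equal(sum(out2$state$populations), 1, tolerance = 1e-12)

  # cross-check against fine-step numerical integration of the ODE system
  P <- c(0.1, 0.1); omega <- c(1, 2); dt <- 1e-4
  for (i in 1:2e5) {
    k1 <- omega * P * (1 - sum(P))
    k2 <- omega * (P + dt / 2 * k1) * (1 - sum(P + dt / 2 * k1))
    k3 <- omega * (P + dt / 2 * k2) * (1 - sum(P + dt / 2 * k2))
    k4 <- omega * (P + dt * k3) * (1 - sum(P + dt * k3))
    P <- P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (1 - sum(P) < 1e-12) break
  }
  expect_equal(out2$state$populations, P, tolerance = 1e-6)

  # random heterogeneous cases: endpoint sums to 1, order preserved
  set.seed(6)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    s <- make_state(rep(1 / n, n))
    s$populations <- runif(n, 1e-8, 1 / n)
    om <- runif(n, 0.1, 1)
    out <- saturate(s, omega = om)
    expect_equal(sum(out$state$populations), 1, tolerance = 1e-12)
    expect_true(all(out$state$populations >= s$populations))
  }
})

test_that("equalization resets all abundances to 1/N, keeping identities", {
  s <- make_state(c(0.96, 0.01, 0.01, 0.01, 0.01),
                  species_id = c(7L, 3L, 9L, 11L, 2L))
  e <- equalize_populations(s)
  expect_equal(e$populations, rep(0.2, 5))
  expect_equal(diversity(e), 5)
  expect_equal(sum(e$populations), 1)
  expect_identical(e$species_id, s$species_id)
})

test_that("one step composes collapse and redistribution", {
  # dominant collapse: survivors boosted by ~1/(1 - P_max)
  p <- model_params(10, 1e-6)
  s <- make_state(c(0.99, rep(0.01 / 9, 9)))
  set.seed(7)
  repeat {  # find the draw that hits the dominant slot
    st <- step_community(s, p)
    if (st$event$victim_index == 1) break
  }
  expect_true(st$event$is_wave_boundary)
  expect_equal(st$event$pre_collapse_size, 0.99)
  expect_equal(st$event$rescale_factor, 1 / (1 - 0.99 + 1e-6),
               tolerance = 1e-9)
  expect_equal(st$event$rescale_factor, 100, tolerance = 0.01)
  expect_equal(sum(st$state$populations), 1, tolerance = 1e-12)

  # red phase = green phase times the common rescale factor
  green <- attr(st$event, "pre_saturation_populations")
  expect_equal(green * st$event$rescale_factor, st$state$populations,
               tolerance = 1e-12)
})

test_that("simulation runs are deterministic and conserve the capacity", {
  p <- model_params(30, 1e-6)
  a <- simulate_community(p, 400, seed = 11, burn_in = 10)
  b <- simulate_community(p, 400, seed = 11, burn_in = 10)
  expect_identical(a$events, b$events)
  expect_identical(a$final$populations, b$final$populations)
  expect_equal(nrow(a$events), 400)
  expect_equal(a$events$step, 1:400)
  expect_equal(sum(a$final$populations), 1, tolerance = 1e-9)
  # diversity trace implies sum = 1 at every step: D within [1, N]
  expect_true(all(a$diversity$D >= 1 - 1e-9 & a$diversity$D <= 30 + 1e-9))
  # per-step conservation, checked exhaustively on the reference stepper
  st <- init_community(p)
  set.seed(11)
  for (i in 1:200) {
    st <- step_community(st, p)$state
    expect_lt(abs(sum(st$populations) - 1), 1e-9)
  }
})

test_that("compiled and reference steppers produce identical trajectories", {
  cases <- list(
    list(variant = "basic", vp = list()),
    list(variant = "neutral_drift", vp = list(r = 1e-3)),
    list(variant = "exp_fluct", vp = list(n = 0.1)),
    list(variant = "ktw", vp = list(sigma = 0.7)),
    list(variant = "ktl", vp = list()),
    list(variant = "fitness", vp = list()),
    list(variant = "resilience", vp = list()))
  for (cs in cases) {
    p <- model_params(10, 1e-5, variant = cs$variant, variant_params = cs$vp)
    a <- simulate_community(p, 1000, seed = 13, burn_in = 10,
                            engine = "cpp",
                            record = c("events", "diversity"))
    b <- simulate_community(p, 1000, seed = 13, burn_in = 10,
                            engine = "r",
                            record = c("events", "diversity"))
    expect_equal(a$events, b$events, tolerance = 0, info = cs$variant)
    expect_identical(a$final$populations, b$final$populations)
    expect_identical(a$final$species_id, b$final$species_id)
    expect_identical(a$diversity$D, b$diversity$D)
  }
})

test_that("newcomer lands near gamma * N after a dominant collapse", {
  # rescale factor 1/(1 - P_max + gamma) ~ N when P_max = 1 - 1/N, gamma << 1/N
  N <- 50; gamma <- 1e-8
  p <- model_params(N, gamma)
  s <- make_state(c(1 - 1 / N, rep(1 / (N * (N - 1)), N - 1)))
  set.seed(8)
  repeat {
    st <- step_community(s, p)
    if (st$event$victim_index == 1) break
  }
  newcomer <- st$state$populations[1]
  expect_equal(newcomer, gamma * N, tolerance = 0.05)
})
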