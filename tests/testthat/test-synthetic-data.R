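test_that("Gillespie simulation conserves S + I + R and absorbs at i = 0", {
  cfg <- model_config(50, 45, 5, beta_log0_mean = log(1.7 / 50))
  th <- static_params(1, 0.5, 1)
  sim <- simulate_mjp(cfg, th, t_end = 2, seed = 21)
  expect_true(all(sim$states[, "s"] == round(sim$states[, "s"])))
  expect_true(all(sim$states[, "s"] + sim$states[, "i"] <= 50))
  expect_true(all(sim$states[, c("s", "i")] >= 0))
  # event log consistency: each infestation lowers s by one
  n_inf <- sum(sim$events$type == "infestation")
  expect_equal(45 - sim$states[nrow(sim$states), "s"], n_inf,
               ignore_attr = TRUE)

  # no infesteds: nothing ever happens
  sim0 <- simulate_mjp(model_config(50, 50, 0, beta_log0_mean = -4),
                       th, t_end = 2, seed = 22)
  expect_equal(nrow(sim0$events), 0)
  expect_equal(sim0$states[nrow(sim0$states), c("s", "i")], c(s = 50, i = 0))

  expect_error(simulate_mjp(cfg, th, t_end = -1), "t_end")
})

test_that("MJP ensemble mean and variance track the LNA moments", {
  # N = 50, s0 = 45, i0 = 5, gamma = 1, sigma = 0, R0 = 1.7 at time 0.
  # The LNA mean solves the mean-field ODE, which carries an O(1/N) bias
  # relative to the exact jump-process mean, so comparisons use relative
  # tolerances (5% mean, 10% variance) rather than Monte-Carlo error.
  bl <- log(1.7 / 50)
  cfg <- model_config(50, 45, 5, beta_log0_mean = bl, beta_log0_sd = 0)
  th <- static_params(1, 0, 1)
  ens <- simulate_mjp_ensemble(cfg, th, t_end = 1, n_rep = 2e4,
                               out_times = c(0.5, 1), seed = 23)
  expect_true(all(ens$s + ens$i <= 50 & ens$s >= 0 & ens$i >= 0))

  st <- lna_state(c(45, 5, bl), matrix(0, 3, 3))
  half <- lna_integrate(st, th, 0.5)
  full <- lna_integrate(half, th, 0.5)
  # dt = 0.5: variance of I within 10% relative
  expect_equal(half$V[2, 2], var(ens$i[, 1]), tolerance = 0.1)
  expect_equal(full$V[2, 2], var(ens$i[, 2]), tolerance = 0.1)
  expect_equal(half$eta[["i"]], mean(ens$i[, 1]), tolerance = 0.05)
  expect_equal(full$eta[["i"]], mean(ens$i[, 2]), tolerance = 0.05)
})

test_that("SDE simulation: deterministic limit and Brownian variance law", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8)
  th0 <- static_params(1, 0, 1)

  # sigma = 0, demographic noise off: matches the Runge-Kutta ODE solution
  sim <- simulate_sde(cfg, th0, t_end = 4, dt = 1 / 365, seed = 31,
                      demographic_noise = FALSE)
  ode <- sir_ode(4900, 100, exp(-8), 1, times = c(0, 2, 4))
  at <- opmsir:::state_at(sim, c(2, 4))
  expect_equal(at[, "s"], ode[2:3, "s"], tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(at[, "i"], ode[2:3, "i"], tolerance = 1e-3, ignore_attr = TRUE)

  # Var(beta_log_t - beta_log_0) = sigma^2 t within 3 standard errors
  th <- static_params(1, 0.75, 1)
  set.seed(32)
  n_rep <- 2000
  dbl <- replicate(n_rep, {
    s <- simulate_sde(cfg, th, t_end = 1, dt = 1 / 50)
    s$states[nrow(s$states), "beta_log"] - (-8)
  })
  v <- var(dbl)
  se <- v * sqrt(2 / (n_rep - 1))
  expect_lt(abs(v - 0.75^2), 3 * se)

  # ensemble mean of s + i is nonincreasing when gamma > 0
  set.seed(33)
  tot <- rowMeans(replicate(200, {
    s <- simulate_sde(cfg, th, t_end = 3, dt = 1 / 50)
    at <- opmsir:::state_at(s, 0:3)
    at[, "s"] + at[, "i"]
  }))
  expect_true(all(diff(tot) < 0))
})

test_that("observation model has mean-proportional variance and clipped counts", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8)
  th <- static_params(1, 0.5, 1)
  sim <- simulate_sde(cfg, th, t_end = 7, dt = 1 / 100, seed = 41)

  # noise-free: y equals s + i exactly
  obs0 <- observe(sim, 0:7, sigma_e = 0, seed = 42)
  at <- opmsir:::state_at(sim, 0:7)
  expect_equal(obs0$y, at[, "s"] + at[, "i"], ignore_attr = TRUE)

  # empirical variance of y at a fixed state matches sigma_e^2 (s + i)
  set.seed(43)
  n_rep <- 1e4
  ys <- replicate(n_rep, observe(sim, c(2, 3), sigma_e = 1.5)$y[2])
  mu <- sum(opmsir:::state_at(sim, 3)[, c("s", "i")])
  v_target <- 1.5^2 * mu
  se <- v_target * sqrt(2 / (n_rep - 1))
  expect_lt(abs(var(ys) - v_target), 3 * se)

  # counts always within [0, N] even with absurd noise
  obs_wild <- observe(sim, 0:7, sigma_e = 50, seed = 44)
  expect_true(all(obs_wild$r_cumulative >= 0 & obs_wild$r_cumulative <= 5e3))

  expect_error(observe(sim, c(0, 9), 1), "span")
})

test_that("fixture generation is deterministic, shaped, and well-bounded", {
  fx <- generate_fixture("bushy-like", seed = 7)
  expect_s3_class(fx$obs, "observation_series")
  expect_equal(nrow(fx$obs), 8)
  expect_equal(fx$obs$t, 0:7)
  expect_equal(fx$truth$true_params[["sigma"]], 0.75)
  expect_equal(fx$truth$config$n_population, 5e3)

  # same seed, same fixture; different seed, different data
  fx2 <- generate_fixture("bushy-like", seed = 7)
  expect_identical(fx$obs$r_cumulative, fx2$obs$r_cumulative)
  fx3 <- generate_fixture("bushy-like", seed = 8)
  expect_false(identical(fx$obs$r_cumulative, fx3$obs$r_cumulative))

  # richmond-like: invariants of the truth path
  fr <- generate_fixture("richmond-like", seed = 9)
  expect_equal(fr$truth$config$n_population, 4e4)
  expect_true(all(fr$truth$states[, "s"] >= 0))
  expect_true(all(fr$truth$states[, "i"] >= 0))
  expect_true(all(fr$truth$states[, "s"] + fr$truth$states[, "i"] <= 4e4))

  # final cumulative removals strictly positive and at most N, across seeds
  finals <- vapply(1:20, function(s) {
    fx <- generate_fixture("bushy-like", seed = s, dt = 1 / 100)
    fx$obs$r_cumulative[8]
  }, numeric(1))
  expect_true(all(finals > 0 & finals <= 5e3))
})

test_that("observation series validates its grid and bounds", {
  expect_error(observation_series(c(2013, 2015), c(0, 5)), "unit spacing")
  expect_error(observation_series(c(2014, 2013), c(0, 5)), "increasing")
  expect_error(observation_series(2013:2014, c(-1, 5)), "negative")
  expect_error(observation_series(2013:2014, c(0, 600), n_population = 500),
               "exceeds N")
  obs <- observation_series(2013:2020, c(5, 30, 80, 200, 380, 600, 850, 1100),
                            n_population = 5e3)
  expect_equal(obs$y, 5e3 - obs$r_cumulative)
  expect_equal(obs$t, 0:7)
})
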