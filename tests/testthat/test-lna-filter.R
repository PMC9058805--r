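make_state <- function(seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  V <- crossprod(A) * diag(c(100, 100, 0.1)) %*% diag(3)  # mixed scales
  V <- (V + t(V)) / 2
  lna_state(c(runif(1, 1e3, 5e3), runif(1, 10, 500), runif(1, -10, -6)),
            crossprod(A))
}

test_that("moment integration: identity at dt = 0 and absorbing fixed point", {
  th <- static_params(1, 0.5, 1)
  st <- lna_state(c(4000, 100, -8), diag(c(1, 2, 0.25)))
  expect_identical(lna_integrate(st, th, 0), st)

  # i = 0, sigma = 0, V = 0: nothing moves
  th0 <- static_params(1, 0, 1)
  st0 <- lna_state(c(4000, 0, -8), matrix(0, 3, 3))
  out <- lna_integrate(st0, th0, 2.5)
  expect_equal(out$eta, st0$eta, tolerance = 1e-10)
  expect_equal(out$V, matrix(0, 3, 3), tolerance = 1e-12)
})

test_that("compiled moment RHS agrees with the plain-R reference", {
  parms <- list(gamma = 0.8, sigma2 = 0.36, fundamental = TRUE)
  set.seed(3)
  for (k in 1:20) {
    y <- c(runif(1, 0, 5e3), runif(1, 0, 500), runif(1, -11, -6),
           rnorm(6, 0, 50), rnorm(9))
    r_rhs <- opmsir:::lna_rhs(0, y, parms)[[1]]
    sol <- deSolve::ode(y, c(0, 1e-9), func = "lna_derivs",
                        parms = c(0.8, 0.36), dllname = "opmsir",
                        initfunc = "lna_initmod", method = "lsoda")
    c_rhs <- (sol[2, -1] - y) / 1e-9
    expect_equal(unname(c_rhs), r_rhs, tolerance = 1e-5)
  }
})

test_that("integrated covariance stays symmetric PSD across random states", {
  th <- static_params(1.2, 0.6, 1)
  set.seed(4)
  for (k in 1:20) {
    s0 <- runif(1, 500, 4500)
    i0 <- runif(1, 5, 400)
    st <- lna_state(c(s0, i0, runif(1, -10, -7)),
                    diag(c(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 0.5))))
    out <- lna_integrate(st, th, runif(1, 0.1, 1))
    expect_identical(out$V, t(out$V))
    expect_psd(out$V)
  }
})

test_that("Gaussian observation update behaves as a conjugate update", {
  # known state (V = 0): gain is zero and the predictive is the pure
  # observation density
  st <- lna_state(c(4000, 100, -8), matrix(0, 3, 3))
  up <- kalman_update(st, y = 4050, sigma_e = 1)
  expect_equal(up$posterior$eta, st$eta)
  expect_equal(up$log_predictive, dnorm(4050, 4100, sqrt(4100), log = TRUE))

  # uninformative observation: posterior reverts to the prior
  stv <- lna_state(c(4000, 100, -8), diag(c(400, 100, 0.25)))
  up2 <- kalman_update(stv, y = 3000, sigma_e = 1e6)
  expect_equal(up2$posterior$eta, stv$eta, tolerance = 1e-4)
  expect_equal(up2$posterior$V, stv$V, tolerance = 1e-4)

  # posterior variance never exceeds prior variance (PSD ordering)
  set.seed(5)
  for (k in 1:100) {
    A <- matrix(rnorm(9), 3) * c(20, 20, 0.5)
    st <- lna_state(c(runif(1, 1e3, 5e3), runif(1, 10, 500),
                      runif(1, -10, -6)), crossprod(A))
    up <- kalman_update(st, sum(st$eta[1:2]) + rnorm(1, 0, 50),
                        sigma_e = runif(1, 0.2, 3))
    expect_psd(st$V - up$posterior$V, tol = 1e-6)
  }
})

test_that("forward filter: closed-form first term and translation invariance", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8, beta_log0_sd = 0)
  th <- static_params(1, 0.3, 1.2)
  fx <- generate_fixture("custom", seed = 51, config = cfg, params = th)

  fr <- lna_filter(th, cfg, fx$obs)
  # with beta_log0_sd = 0 the time-0 update has V0 = 0: its likelihood term
  # is the exact Gaussian observation density
  lp0 <- dnorm(fx$obs$y[1], 5000, sqrt(1.2^2 * 5000), log = TRUE)
  expect_equal(kalman_update(fr$predicted[[1]], fx$obs$y[1], 1.2)$log_predictive,
               lp0)

  # only time differences matter: relabelling calendar years changes nothing
  obs_shift <- observation_series(fx$obs$year + 57, fx$obs$r_cumulative,
                                  n_population = 5e3, y = fx$obs$y)
  expect_equal(lna_log_likelihood(th, cfg, obs_shift), fr$log_likelihood)

  # dropping the time-0 term removes exactly lp0 here (V0 = 0 means the
  # update cannot move the state)
  ll_no0 <- lna_log_likelihood(th, cfg, fx$obs,
                               lna_control(include_first_obs = FALSE))
  expect_equal(fr$log_likelihood - ll_no0, lp0, tolerance = 1e-8)
})

test_that("with uninformative observations the filter reproduces one long integration", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8, beta_log0_sd = 0.5)
  th <- static_params(1, 0.4, 1)
  fx <- generate_fixture("custom", seed = 52, config = cfg, params = th)

  # sigma_e so large that updates carry no information
  frq <- lna_filter(static_params(1, 0.4, 1e6), cfg, fx$obs)
  st <- lna_state(c(4900, 100, -8), diag(c(0, 0, 0.25)))
  for (k in 2:8) st <- lna_integrate(st, th, 1)
  end_filtered <- frq$filtered[[8]]
  expect_equal(end_filtered$eta, st$eta, tolerance = 1e-6)
  expect_equal(end_filtered$V, st$V, tolerance = 1e-6)
})

test_that("LNA log-likelihood matches a bootstrap particle filter when the
           linearisation is comfortable", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8, beta_log0_sd = 0.3)
  th <- static_params(1, 0.1, 1)
  fx <- generate_fixture("custom", seed = 5, config = cfg, params = th)
  icfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8.5, beta_log0_sd = 0.5)
  ll <- lna_log_likelihood(th, icfg, fx$obs)
  pf <- vapply(1:3, function(r) pf_loglik(th, icfg, fx$obs, 2e4, seed = 60 + r),
               numeric(1))
  # small-sigma regime: Gaussian approximation error is O(1) nat here; a
  # larger discrepancy would indicate an implementation fault
  expect_lt(abs(ll - mean(pf)), 2)
})

test_that("likelihood penalises grossly misspecified observation noise", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8, beta_log0_sd = 0.3)
  gen <- static_params(1, 0.2, 1)
  lls <- vapply(1:5, function(s) {
    fx <- generate_fixture("custom", seed = 300 + s, config = cfg, params = gen)
    lna_log_likelihood(static_params(1, 0.2, 25), cfg, fx$obs) -
      lna_log_likelihood(gen, cfg, fx$obs)
  }, numeric(1))
  expect_true(all(lls < 0))
})

test_that("latent path sampler is aligned, self-consistent, and concentrates
           when observations are exact", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8, beta_log0_sd = 0.3)
  th <- static_params(1, 0.2, 1)
  fx <- generate_fixture("custom", seed = 53, config = cfg, params = th)

  draws <- sample_latent_path(th, cfg, fx$obs, seed = 54, n_draws = 300)
  # grid alignment: a value at every observation time
  expect_true(all(vapply(draws, function(d)
    identical(d$times, as.numeric(0:7)), logical(1))))

  # ensemble mean matches the Rauch-Tung-Striebel smoother recursion
  fr <- lna_filter(th, cfg, fx$obs, keep_intervals = TRUE)
  n <- 8
  sm <- vector("list", n)
  sm[[n]] <- fr$filtered[[n]]$eta
  for (k in (n - 1):1) {
    G <- fr$intervals[[k]]$G
    J <- fr$filtered[[k]]$V %*% t(G) %*% solve(fr$predicted[[k + 1]]$V)
    sm[[k]] <- fr$filtered[[k]]$eta +
      as.numeric(J %*% (sm[[k + 1]] - fr$predicted[[k + 1]]$eta))
  }
  X <- simplify2array(lapply(draws, function(d) d$states))  # 8 x 3 x 300
  for (k in c(1, 4, 8)) {
    for (j in 1:3) {
      mc <- mean(X[k, j, ])
      se <- sd(X[k, j, ]) / sqrt(dim(X)[3])
      expect_lt(abs(mc - sm[[k]][j]), 3 * se + 1e-6)
    }
  }

  # near-exact observations: sampled S + I pins to y at observation times
  obs0 <- observe(fx$truth, 0:7, sigma_e = 0)
  d0 <- sample_latent_path(static_params(1, 0.2, 1e-3), cfg, obs0,
                           seed = 55, n_draws = 100)
  tot <- sapply(d0, function(d) d$states[, "s"] + d$states[, "i"])
  spread <- apply(tot, 1, sd)
  expect_true(all(spread < 1))
  expect_true(all(abs(rowMeans(tot) - obs0$y) < 1))
})

test_that("fine-grid bridge draws interpolate the yearly states", {
  cfg <- model_config(5e3, 4900, 100, beta_log0_mean = -8, beta_log0_sd = 0.3)
  th <- static_params(1, 0.2, 1)
  fx <- generate_fixture("custom", seed = 56, config = cfg, params = th)
  d <- sample_latent_path(th, cfg, fx$obs, seed = 57, n_draws = 20,
                          fine_steps = 9)[[1]]
  expect_equal(length(d$times), 8 + 7 * 9)
  expect_true(all(diff(d$times) > 0))
  # bridge values stay on the scale of the endpoints (no wild excursions)
  expect_true(all(d$states[, "s"] > -50 & d$states[, "s"] < 5100))
})
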