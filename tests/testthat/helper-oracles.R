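# Independent oracles used across the test suite. These deliberately avoid
# the package's LNA code paths so they can stand as cross-checks.

# Bootstrap particle filter estimate of the observed-data log-likelihood
# under the Euler-Maruyama SDE model.
pf_loglik <- function(params, config, obs, n_particles = 1e4, dt = 1 / 50,
                      seed = NULL) {
  gamma <- params[["gamma"]]; sigma <- params[["sigma"]]
  sigma_e <- params[["sigma_e"]]
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(obs)
  s <- rep(config$s0, n_particles)
  i <- rep(config$i0, n_particles)
  bl <- rnorm(n_particles, config$beta_log0_mean, config$beta_log0_sd)
  ll <- 0
  for (k in 1:n) {
    if (k > 1) {
      steps <- round((obs$t[k] - obs$t[k - 1]) / dt)
      for (st in 1:steps) {
        h_inf <- exp(bl) * s * i
        h_rem <- gamma * i
        d_inf <- pmax(0, rnorm(n_particles, h_inf * dt, sqrt(h_inf * dt)))
        d_rem <- pmax(0, rnorm(n_particles, h_rem * dt, sqrt(h_rem * dt)))
        s_new <- pmax(0, s - d_inf)
        i <- pmax(0, i + (s - s_new) - d_rem)
        s <- s_new
        bl <- bl + rnorm(n_particles, 0, sigma * sqrt(dt))
      }
    }
    mu <- s + i
    lw <- dnorm(obs$y[k], mu, sqrt(sigma_e^2 * pmax(mu, 1)), log = TRUE)
    m <- max(lw)
    w <- exp(lw - m)
    ll <- ll + m + log(mean(w))
    u <- (runif(1) + 0:(n_particles - 1)) / n_particles
    idx <- findInterval(u, cumsum(w / sum(w))) + 1L
    s <- s[idx]; i <- i[idx]; bl <- bl[idx]
  }
  ll
}

# Central finite differences of the drift, for checking the Jacobian.
fd_jacobian <- function(state, params, h = 1e-4) {
  x <- c(state[["s"]], state[["i"]], state[["beta_log"]])
  J <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (sir_drift(xp, params) - sir_drift(xm, params)) / (2 * h)
  }
  J
}

# Deterministic SIR ODE solution (Runge-Kutta via deSolve), the sigma = 0
# zero-noise limit of the model.
sir_ode <- function(s0, i0, beta, gamma, times) {
  deSolve::ode(c(s = s0, i = i0), times,
               function(t, y, p) list(c(-beta * y[1] * y[2],
                                        beta * y[1] * y[2] - gamma * y[2])),
               NULL, method = "ode45", rtol = 1e-10, atol = 1e-10)
}

random_valid_state <- function(n_population = 5e3) {
  s <- runif(1, 0, n_population)
  i <- runif(1, 0, n_population - s)
  epidemic_state(s, i, runif(1, -12, -5))
}

expect_psd <- function(V, tol = 1e-8) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(1, abs(max(ev))))
}
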