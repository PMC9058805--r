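#' Gaussian state of the linear noise approximation
#'
#' The LNA summarises the latent epidemic at time `t` by a Gaussian
#' \eqn{X_t \sim N(\eta_t, V_t)}: `eta` is the 3-vector mean
#' `(s, i, beta_log)` and `V` the 3x3 covariance. `V` is re-symmetrised on
#' construction and must be positive semi-definite to within a small
#' tolerance.
#'
#' @param eta Mean 3-vector.
#' @param V Covariance 3x3 matrix.
#' @param t Time (years).
#' @return An object of class `lna_state`.
#' @export
lna_state <- function(eta, V, t = 0) {
  stopifnot(length(eta) == 3, is.matrix(V), all(dim(V) == c(3, 3)))
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    stop("lna_state: covariance is not positive semi-definite")
  }
  structure(list(eta = stats::setNames(as.numeric(eta), c("s", "i", "beta_log")),
                 V = V, t = as.numeric(t)),
            class = "lna_state")
}

#' @export
print.lna_state <- function(x, ...) {
  cat(sprintf("<lna_state t=%.4g> eta = (%.4g, %.4g, %.4g)\n",
              x$t, x$eta[1], x$eta[2], x$eta[3]))
  print(signif(x$V, 4))
  invisible(x)
}

#' Solver and filter settings
#'
#' @param rtol,atol Relative and absolute tolerance of the adaptive ODE
#'   solver used for the LNA moment equations.
#' @param method `deSolve` integration method (default `"ode45"`, the
#'   adaptive Dormand-Prince Runge-Kutta 4(5) pair).
#' @param var_floor Observation-variance floor, in trees: the observation
#'   variance is `sigma_e^2 * max(P'eta, var_floor)`, preventing a vanishing
#'   variance when nearly all trees have been removed.
#' @param neg_tol Rejection tolerance: a parameter draw whose filtered or
#'   integrated mean takes `s` or `i` below `-neg_tol * N` yields a
#'   log-likelihood of `-Inf` rather than being silently clamped. The
#'   default (10% of `N`) only vetoes gross breakdown of the Gaussian
#'   approximation: modest negative excursions of the mean near the state
#'   boundary are part of the approximation's slack and carry valid
#'   likelihood information (confirmed against particle-filter runs), so
#'   rejecting them biases the sampler away from perfectly plausible
#'   parameter values.
#' @param restart If `TRUE` (default) each inter-observation integration is
#'   initialised at the filtered mean and covariance, keeping the
#'   linearisation local; if `FALSE` the mean path is integrated once without
#'   interruption and filtered moments are propagated along it through the
#'   fundamental matrix.
#' @param include_first_obs Should the observation at time 0 contribute a
#'   likelihood term (default `TRUE`)?
#' @return A list of settings for [lna_filter] and friends.
#' @export
lna_control <- function(rtol = 1e-8, atol = 1e-10, method = "ode45",
                        var_floor = 1, neg_tol = 0.1, restart = TRUE,
                        include_first_obs = TRUE) {
  list(rtol = rtol, atol = atol, method = method, var_floor = var_floor,
       neg_tol = neg_tol, restart = restart,
       include_first_obs = include_first_obs)
}

# indices of the unique (upper-triangle) covariance entries in the ODE state
.vix <- cbind(c(1, 1, 1, 2, 2, 3), c(1, 2, 3, 2, 3, 3))

vech3 <- function(V) V[.vix]

unvech3 <- function(v) {
  V <- matrix(0, 3, 3)
  V[.vix] <- v
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  V
}

# Joint RHS of the LNA moment ODEs: mean (3), unique covariance entries (6)
# and, optionally, the fundamental matrix G with dG/dt = H G (9).
lna_rhs <- function(t, y, parms) {
  gamma <- parms$gamma; sigma2 <- parms$sigma2
  s <- y[1]; i <- y[2]; b <- exp(y[3])
  bsi <- b * s * i
  a <- c(-bsi, bsi - gamma * i, 0)
  H <- matrix(c(-b * i, -b * s, -bsi,
                b * i, b * s - gamma, bsi,
                0, 0, 0), 3, 3, byrow = TRUE)
  V <- unvech3(y[4:9])
  HV <- H %*% V
  dV <- HV + t(HV)
  dV[1, 1] <- dV[1, 1] + bsi
  dV[1, 2] <- dV[1, 2] - bsi
  dV[2, 1] <- dV[2, 1] - bsi
  dV[2, 2] <- dV[2, 2] + bsi + gamma * i
  dV[3, 3] <- dV[3, 3] + sigma2
  dy <- c(a, vech3(dV))
  if (parms$fundamental) {
    G <- matrix(y[10:18], 3, 3)
    dy <- c(dy, as.numeric(H %*% G))
  }
  list(dy)
}

# Integrate the moment ODEs from (eta0, V0) over [t0, t0 + dt]; optionally
# track the fundamental matrix and return dense output at interior times.
# Uses the compiled RHS (src/lna_rhs.c); `lna_rhs` above is its plain-R
# reference implementation, kept for cross-checking.
lna_integrate_raw <- function(eta0, V0, params, dt, control,
                              fundamental = FALSE, dense_times = NULL) {
  y0 <- c(as.numeric(eta0), vech3(V0))
  if (fundamental) y0 <- c(y0, as.numeric(diag(3)))
  times <- unique(sort(c(0, dense_times, dt)))
  sol <- deSolve::ode(y = y0, times = times, func = "lna_derivs",
                      parms = c(params[["gamma"]], params[["sigma"]]^2),
                      dllname = "opmsir", initfunc = "lna_initmod",
                      method = control$method, rtol = control$rtol,
                      atol = control$atol)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1]))) {
    stop(sprintf("lna_integrate: solver failure near t = %.4g (state s=%.3g, i=%.3g)",
                 sol[nrow(sol), 1], sol[nrow(sol), 2], sol[nrow(sol), 3]))
  }
  sol
}

row_to_moments <- function(row, fundamental = FALSE) {
  eta <- row[2:4]
  V <- unvech3(row[5:10])
  out <- list(eta = eta, V = (V + t(V)) / 2)
  if (fundamental) out$G <- matrix(row[11:19], 3, 3)
  out
}

#' Integrate the LNA moment equations
#'
#' Advances an [lna_state] by `dt` years: the mean follows the deterministic
#' SIR ODE and the covariance the linear matrix ODE
#' \eqn{dV/dt = H V + V H' + b(\eta)}, with `H` the drift Jacobian and `b`
#' the diffusion matrix, both evaluated along the mean path. The six unique
#' covariance entries are integrated jointly with the mean by an adaptive
#' solver and the result is re-symmetrised.
#'
#' @param state An [lna_state].
#' @param params A [static_params].
#' @param dt Time step in years, `>= 0`; `dt = 0` returns the input.
#' @param control Settings from [lna_control].
#' @return The advanced [lna_state].
#' @examples
#' st <- lna_state(c(4900, 100, -8), diag(c(0, 0, 0.25)))
#' lna_integrate(st, static_params(1, 0.75, 1), dt = 1)
#' @export
lna_integrate <- function(state, params, dt, control = lna_control()) {
  stopifnot(inherits(state, "lna_state"), dt >= 0)
  if (dt == 0) return(state)
  sol <- lna_integrate_raw(state$eta, state$V, params, dt, control)
  m <- row_to_moments(sol[nrow(sol), ])
  lna_state(m$eta, m$V, t = state$t + dt)
}

#' Gaussian observation update
#'
#' Conjugate (Kalman) update of a predicted [lna_state] by one observation of
#' `y = S + I` under the model \eqn{Y_t \sim N(P'x_t, \sigma_e^2 P' x_t)}
#' with `P = (1, 1, 0)'`. The observation variance uses the predicted mean,
#' floored at `var_floor` trees.
#'
#' @param predicted The prior [lna_state] at the observation time.
#' @param y Scalar observation (on the `S + I` scale).
#' @param sigma_e Observation-noise scale.
#' @param var_floor Variance floor in trees (see [lna_control]).
#' @return A list with `posterior` (the updated [lna_state]) and
#'   `log_predictive`, the Gaussian log-density of `y` under the one-step
#'   predictive \eqn{N(P'\eta, P'VP + \sigma_e^2 P'\eta)}.
#' @export
kalman_update <- function(predicted, y, sigma_e, var_floor = 1) {
  P <- c(1, 1, 0)
  eta <- predicted$eta; V <- predicted$V
  mu <- sum(P * eta)
  r_var <- sigma_e^2 * max(mu, var_floor)
  s_var <- as.numeric(t(P) %*% V %*% P) + r_var
  if (!is.finite(s_var) || s_var <= 0) {
    stop("kalman_update: nonpositive predictive variance")
  }
  K <- as.numeric(V %*% P) / s_var
  eta_post <- eta + K * (y - mu)
  V_post <- V - outer(K, as.numeric(t(P) %*% V))
  list(posterior = lna_state(eta_post, V_post, t = predicted$t),
       log_predictive = stats::dnorm(y, mu, sqrt(s_var), log = TRUE))
}

#' Forward filter for the LNA state-space model
#'
#' Runs the Gaussian forward filter over a yearly observation series: starting
#' from \eqn{\eta_0 = (s_0, i_0, \bar\beta_0)} with
#' \eqn{V_0 = diag(0, 0, sd(\beta_0)^2)} (the Gaussian prior on the initial
#' log rate is marginalised analytically), it alternates observation updates
#' with integration of the LNA moment ODEs across each unit interval,
#' accumulating the observed-data log-likelihood \eqn{\log \pi(y | \theta)}.
#'
#' A parameter value whose mean path drives `s` or `i` negative (beyond
#' `control$neg_tol * N`) is flagged by a `-Inf` log-likelihood so samplers
#' cannot exploit unphysical regions; solver failures are likewise reported
#' as `-Inf` with a warning rather than an error.
#'
#' @param params A [static_params].
#' @param config A [model_config].
#' @param obs An [observation_series]; its `y = N - R` column is derived from
#'   `config$n_population` if absent.
#' @param control Settings from [lna_control].
#' @param keep_intervals Store per-interval fundamental matrices and dense
#'   moment output (needed by [sample_latent_path]).
#' @param dense_steps When `keep_intervals = TRUE`, number of interior
#'   grid points per interval at which dense moments are stored.
#' @return An object of class `lna_filter_result`: `log_likelihood`,
#'   lists `predicted` and `filtered` of [lna_state]s (one per observation),
#'   and (optionally) the interval records.
#' @export
lna_filter <- function(params, config, obs, control = lna_control(),
                       keep_intervals = FALSE, dense_steps = 0) {
  obs <- obs_with_population(obs, config$n_population)
  n <- nrow(obs)
  if (n < 2) stop("lna_filter: need at least 2 observations")
  neg_lim <- -control$neg_tol * config$n_population
  bad <- function(eta) any(eta[1:2] < neg_lim)

  eta <- c(config$s0, config$i0, config$beta_log0_mean)
  V <- diag(c(0, 0, config$beta_log0_sd^2))
  predicted <- vector("list", n)
  filtered <- vector("list", n)
  intervals <- if (keep_intervals) vector("list", n - 1) else NULL
  ll <- 0
  # non-restarting mode: reference mean path and filtered deviation moments
  m_f <- eta
  V_f <- V

  for (k in seq_len(n)) {
    t_k <- obs$t[k]
    if (k > 1) {
      dt <- obs$t[k] - obs$t[k - 1]
      start_eta <- if (control$restart) m_f else eta
      start_V <- V_f
      dense_times <- if (keep_intervals && dense_steps > 0) {
        seq(0, dt, length.out = dense_steps + 2)[-c(1, dense_steps + 2)]
      } else NULL
      sol <- tryCatch(
        lna_integrate_raw(start_eta, start_V, params, dt, control,
                          fundamental = keep_intervals || !control$restart,
                          dense_times = dense_times),
        error = function(e) e)
      if (inherits(sol, "error")) {
        warning(sprintf("lna_filter: %s; rejecting parameter value",
                        conditionMessage(sol)))
        return(structure(list(log_likelihood = -Inf), class = "lna_filter_result"))
      }
      fund <- keep_intervals || !control$restart
      m <- row_to_moments(sol[nrow(sol), ], fundamental = fund)
      if (control$restart) {
        eta_pred <- m$eta
      } else {
        eta <- m$eta  # unbroken reference path
        eta_pred <- m$eta + as.numeric(m$G %*% (m_f - start_eta))
      }
      V_pred <- m$V
      if (bad(eta_pred)) {
        return(structure(list(log_likelihood = -Inf), class = "lna_filter_result"))
      }
      if (keep_intervals) {
        intervals[[k - 1]] <- list(
          G = m$G, t0 = obs$t[k - 1], t1 = t_k,
          start_eta = start_eta, start_V = start_V,
          dense = if (dense_steps > 0) sol else NULL)
      }
      pred_state <- lna_state(eta_pred, V_pred, t = t_k)
    } else {
      pred_state <- lna_state(eta, V, t = t_k)
    }
    predicted[[k]] <- pred_state
    if (k > 1 || control$include_first_obs) {
      up <- tryCatch(kalman_update(pred_state, obs$y[k], params[["sigma_e"]],
                                   var_floor = control$var_floor),
                     error = function(e) e)
      if (inherits(up, "error")) {
        warning(sprintf("lna_filter: %s; rejecting parameter value",
                        conditionMessage(up)))
        return(structure(list(log_likelihood = -Inf), class = "lna_filter_result"))
      }
      ll <- ll + up$log_predictive
      post <- up$posterior
    } else {
      post <- pred_state
    }
    if (bad(post$eta)) {
      return(structure(list(log_likelihood = -Inf), class = "lna_filter_result"))
    }
    filtered[[k]] <- post
    m_f <- post$eta
    V_f <- post$V
  }
  structure(list(log_likelihood = ll, predicted = predicted,
                 filtered = filtered, intervals = intervals,
                 control = control, obs = obs, config = config,
                 params = params),
            class = "lna_filter_result")
}

#' Observed-data log-likelihood under the LNA
#'
#' Convenience wrapper around [lna_filter] returning only the scalar
#' \eqn{\log \pi(y | \theta)}.
#'
#' @inheritParams lna_filter
#' @return The log-likelihood (possibly `-Inf` for rejected parameter
#'   values).
#' @export
lna_log_likelihood <- function(params, config, obs, control = lna_control()) {
  lna_filter(params, config, obs, control)$log_likelihood
}

# Conditional draw helpers ---------------------------------------------------

# Solve S X = B for symmetric PSD S with a scale-aware ridge; falls back to
# an eigenvalue pseudo-inverse if the system is still near-singular.
solve_psd <- function(S, B) {
  S <- (S + t(S)) / 2
  ridge <- 1e-9 * max(diag(S), 1)
  out <- tryCatch(solve(S + diag(ridge, nrow(S)), B), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ev <- eigen(S, symmetric = TRUE)
  lam <- ev$values
  inv <- ifelse(lam > 1e-12 * max(lam, 1), 1 / pmax(lam, 1e-300), 0)
  ev$vectors %*% (inv * crossprod(ev$vectors, B))
}

rmvnorm3 <- function(mean, V) {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  as.numeric(mean + ev$vectors %*% (sqrt(lam) * stats::rnorm(3)))
}

#' Sample latent epidemic paths given data and parameters
#'
#' Draws from the conditional posterior \eqn{\pi(x | y, \theta)} of the
#' latent path by forward-filter backward-sampling over the Gaussian LNA
#' states at the observation times, optionally followed by Gaussian bridge
#' interpolation on a fine grid inside each yearly interval. Repeated draws
#' are independent given `(params, obs)`.
#'
#' @inheritParams lna_filter
#' @param seed Optional integer seed.
#' @param n_draws Number of independent path draws.
#' @param fine_steps Number of interior bridge points per yearly interval
#'   (0 = observation times only).
#' @param filter_result Optionally a precomputed [lna_filter] result with
#'   `keep_intervals = TRUE` (and matching `dense_steps`), to avoid
#'   refiltering.
#' @return A list of draws; each draw is a list with `times` and a matrix
#'   `states` (columns `s`, `i`, `beta_log`).
#' @export
sample_latent_path <- function(params, config, obs, seed = NULL, n_draws = 1,
                               fine_steps = 0, control = lna_control(),
                               filter_result = NULL) {
  fr <- filter_result
  if (is.null(fr)) {
    fr <- lna_filter(params, config, obs, control, keep_intervals = TRUE,
                     dense_steps = fine_steps)
  }
  if (!is.finite(fr$log_likelihood)) {
    stop("sample_latent_path: log-likelihood is not finite at these parameters")
  }
  n <- length(fr$filtered)
  obs_t <- vapply(fr$filtered, function(s) s$t, numeric(1))
  with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      x <- matrix(NA_real_, n, 3)
      x[n, ] <- rmvnorm3(fr$filtered[[n]]$eta, fr$filtered[[n]]$V)
      for (k in (n - 1):1) {
        iv <- fr$intervals[[k]]
        Vf <- fr$filtered[[k]]$V
        mf <- fr$filtered[[k]]$eta
        S <- fr$predicted[[k + 1]]$V
        Cc <- Vf %*% t(iv$G)
        gain <- t(solve_psd(S, t(Cc)))
        mean_k <- mf + as.numeric(gain %*% (x[k + 1, ] - fr$predicted[[k + 1]]$eta))
        var_k <- Vf - gain %*% t(Cc)
        x[k, ] <- rmvnorm3(mean_k, var_k)
      }
      if (fine_steps == 0) {
        return(list(times = obs_t, states = {
          colnames(x) <- c("s", "i", "beta_log"); x
        }))
      }
      # Gaussian bridge inside each interval, conditional on both endpoints
      all_t <- obs_t[1]
      all_x <- x[1, , drop = FALSE]
      for (k in seq_len(n - 1)) {
        iv <- fr$intervals[[k]]
        sol <- iv$dense
        fine <- bridge_interval(sol, iv, fr$filtered[[k]], x[k, ], x[k + 1, ])
        all_t <- c(all_t, iv$t0 + fine$tau, iv$t1)
        all_x <- rbind(all_x, fine$states, x[k + 1, , drop = FALSE])
      }
      colnames(all_x) <- c("s", "i", "beta_log")
      list(times = all_t, states = all_x)
    })
  })
}

# Draw interior bridge points of one interval sequentially, conditioning each
# fine-grid state on the previous one and on the interval's right endpoint.
bridge_interval <- function(sol, iv, filtered_left, x_left, x_right) {
  nr <- nrow(sol)
  tau <- sol[, 1]
  Vf <- filtered_left$V
  mf <- filtered_left$eta
  moms <- lapply(seq_len(nr), function(r) row_to_moments(sol[r, ], fundamental = TRUE))
  # moments conditional on the exact left endpoint X_t = x_left
  delta <- x_left - mf
  cond <- lapply(moms, function(m) {
    list(mean = m$eta + as.numeric(m$G %*% delta),
         Q = (m$V - m$G %*% Vf %*% t(m$G)), G = m$G)
  })
  ridge <- diag(1e-10, 3)
  x_prev <- x_left
  k_prev <- 1L
  out <- matrix(NA_real_, nr - 2, 3)
  G_end <- cond[[nr]]$G
  for (j in 2:(nr - 1)) {
    A <- cond[[j]]$G %*% solve(cond[[k_prev]]$G)
    B <- cond[[j]]$Q - A %*% cond[[k_prev]]$Q %*% t(A)
    B <- (B + t(B)) / 2
    a_mean <- cond[[j]]$mean + as.numeric(A %*% (x_prev - cond[[k_prev]]$mean))
    FF <- G_end %*% solve(cond[[j]]$G)
    R <- cond[[nr]]$Q - FF %*% cond[[j]]$Q %*% t(FF)
    R <- (R + t(R)) / 2
    S <- FF %*% B %*% t(FF) + R + ridge
    gain <- t(solve_psd(S, FF %*% t(B)))
    resid <- x_right - cond[[nr]]$mean - as.numeric(FF %*% (a_mean - cond[[j]]$mean))
    mean_j <- a_mean + as.numeric(gain %*% resid)
    var_j <- B - gain %*% FF %*% B
    x_prev <- rmvnorm3(mean_j, var_j)
    out[j - 1, ] <- x_prev
    k_prev <- j
  }
  list(tau = tau[2:(nr - 1)], states = out)
}
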