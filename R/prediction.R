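new_predictive_summary <- function(year, draws_by_time, mode, n_draws) {
  qs <- t(apply(draws_by_time, 2, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE))
  out <- data.frame(year = year, q2.5 = qs[, 1], q25 = qs[, 2],
                    median = qs[, 3], q75 = qs[, 4], q97.5 = qs[, 5],
                    check.names = FALSE)
  structure(out, mode = mode, n_draws = n_draws,
            class = c("predictive_summary", "data.frame"))
}

chain_paths_or_stop <- function(chain) {
  if (is.null(chain$latent_paths) || length(chain$latent_paths) == 0) {
    stop("this summary needs latent paths: re-run fit_mcmc with sample_paths = TRUE")
  }
  chain$latent_paths
}

# Observation draw on the cumulative-removed scale given latent y = s + i.
observe_draws <- function(y_latent, sigma_e, n_population, var_floor = 1) {
  v <- sigma_e^2 * pmax(y_latent, var_floor)
  ytil <- stats::rnorm(length(y_latent), y_latent, sqrt(v))
  pmin(pmax(n_population - ytil, 0), n_population)
}

#' Within-sample posterior predictive summary
#'
#' For each stored posterior draw `(theta, x)`, simulates a replicate
#' observation \eqn{\tilde y_t \sim N(P'x_t, \sigma_e^2 P'x_t)} at every
#' observation time, converts it to the cumulative-removed scale
#' `R = N - y` (clipped to `[0, N]`), and summarises medians, quartiles and
#' 95% bands per year. This integrates over both parameter and latent-path
#' uncertainty.
#'
#' @param chain An `opm_chain` from [fit_mcmc] with latent paths.
#' @param obs,config Default to those stored in the chain.
#' @param seed Optional integer seed for the observation-noise draws.
#' @param reps Observation-noise replicates per stored latent path.
#' @return A `predictive_summary` data frame (one row per observation year).
#' @export
within_sample_predictive <- function(chain, obs = chain$obs,
                                     config = chain$config, seed = NULL,
                                     reps = 10) {
  paths <- chain_paths_or_stop(chain)
  obs <- obs_with_population(obs, config$n_population)
  obs_t <- obs$t
  with_seed(seed, {
    sims <- do.call(rbind, lapply(paths, function(p) {
      idx <- match(round(p$times, 9), round(obs_t, 9))
      keep <- !is.na(idx)
      x <- p$states[keep, , drop = FALSE]
      y_lat <- x[, "s"] + x[, "i"]
      se <- chain$draws[p$draw, "sigma_e"]
      t(replicate(reps, observe_draws(y_lat, se, config$n_population)))
    }))
    new_predictive_summary(obs$year, sims, mode = "within_sample",
                           n_draws = nrow(sims))
  })
}

# Vectorised Euler-Maruyama push-forward of many draws at once; returns the
# latent state of every simulation at each whole-year horizon. Reaction
# increments are truncated at zero, so the latent cumulative removed count
# N - s - i is nondecreasing along every draw.
propagate_sde_ensemble <- function(s, i, bl, gamma, sigma, horizon_years,
                                   dt = 1 / 100) {
  n <- length(s)
  # FFBS draws are Gaussian and may dip slightly below the state boundary
  s <- pmax(s, 0)
  i <- pmax(i, 0)
  steps_per_year <- round(1 / dt)
  out <- array(NA_real_, c(n, horizon_years, 3),
               dimnames = list(NULL, NULL, c("s", "i", "beta_log")))
  for (yr in seq_len(horizon_years)) {
    for (k in seq_len(steps_per_year)) {
      h_inf <- exp(bl) * s * i
      h_rem <- gamma * i
      d_inf <- pmax(0, stats::rnorm(n, h_inf * dt, sqrt(h_inf * dt)))
      d_rem <- pmax(0, stats::rnorm(n, h_rem * dt, sqrt(h_rem * dt)))
      s_new <- pmax(0, s - d_inf)
      i <- pmax(0, i + (s - s_new) - d_rem)
      s <- s_new
      bl <- bl + stats::rnorm(n, 0, sigma * sqrt(dt))
    }
    out[, yr, 1] <- s; out[, yr, 2] <- i; out[, yr, 3] <- bl
  }
  out
}

# Terminal latent states and matching parameter rows for forward simulation.
terminal_states <- function(chain, n_sims) {
  paths <- chain_paths_or_stop(chain)
  term <- t(vapply(paths, function(p) p$states[nrow(p$states), ], numeric(3)))
  rows <- vapply(paths, function(p) p$draw, numeric(1))
  pick <- rep_len(seq_along(paths), n_sims)
  list(x = term[pick, , drop = FALSE], rows = rows[pick])
}

#' One-step-ahead out-of-sample prediction
#'
#' Predicts the observation one year beyond the end of the fitted series:
#' for each posterior draw the terminal filtered latent state is pushed
#' through the stochastic differential equation for one year
#' (Euler-Maruyama) and the observation model is applied, giving draws of
#' next year's cumulative removed count. The chain should have been fitted
#' to the series with its final point held out.
#'
#' @param chain An `opm_chain` fitted to the truncated series.
#' @param obs,config Default to those stored in the chain.
#' @param seed Optional integer seed.
#' @param n_sims Number of forward simulations; defaults to the number of
#'   retained MCMC draws.
#' @param dt Euler step in years.
#' @param observation_noise Apply the observation model to the propagated
#'   latent state (default `TRUE`, matching the out-of-sample predictive
#'   density).
#' @return A list with `draws` (predicted cumulative removed counts),
#'   `summary` (a one-row `predictive_summary`), and `year`.
#' @export
one_step_ahead <- function(chain, obs = chain$obs, config = chain$config,
                           seed = NULL, n_sims = nrow(chain$draws),
                           dt = 1 / 100, observation_noise = TRUE) {
  obs <- obs_with_population(obs, config$n_population)
  with_seed(seed, {
    ts <- terminal_states(chain, n_sims)
    th <- chain$draws[ts$rows, , drop = FALSE]
    fin <- propagate_sde_ensemble(ts$x[, "s"], ts$x[, "i"], ts$x[, "beta_log"],
                                  th[, "gamma"], th[, "sigma"], 1, dt)
    y_lat <- fin[, 1, "s"] + fin[, 1, "i"]
    draws <- if (observation_noise) {
      observe_draws(y_lat, th[, "sigma_e"], config$n_population)
    } else {
      pmin(pmax(config$n_population - y_lat, 0), config$n_population)
    }
    year <- max(obs$year) + 1
    list(draws = draws,
         summary = new_predictive_summary(year, matrix(draws, ncol = 1),
                                          mode = "one_step", n_draws = n_sims),
         year = year)
  })
}

#' Multi-year forward simulation
#'
#' Pushes each posterior draw's terminal latent state forward through the
#' stochastic differential equation for `horizon_years` years and summarises
#' the cumulative removed count per year. By default the latent
#' `R(t) = N - S - I` is reported (no observation noise), which saturates at
#' `N` as the susceptible pool is depleted.
#'
#' @inheritParams one_step_ahead
#' @param horizon_years Number of years to simulate beyond the data, >= 1.
#' @param observation_noise Add observation noise to each yearly value
#'   (default `FALSE`: report the latent removed count).
#' @param return_draws Also attach the per-draw year-by-year matrix as the
#'   `"draws"` attribute of the result.
#' @return A `predictive_summary` with one row per predicted year.
#' @export
forward_simulate <- function(chain, obs = chain$obs, config = chain$config,
                             horizon_years, seed = NULL,
                             n_sims = nrow(chain$draws), dt = 1 / 100,
                             observation_noise = FALSE, return_draws = FALSE) {
  if (horizon_years < 1) stop("forward_simulate: horizon_years must be >= 1")
  obs <- obs_with_population(obs, config$n_population)
  with_seed(seed, {
    ts <- terminal_states(chain, n_sims)
    th <- chain$draws[ts$rows, , drop = FALSE]
    fin <- propagate_sde_ensemble(ts$x[, "s"], ts$x[, "i"], ts$x[, "beta_log"],
                                  th[, "gamma"], th[, "sigma"],
                                  horizon_years, dt)
    r_draws <- sapply(seq_len(horizon_years), function(yr) {
      y_lat <- fin[, yr, "s"] + fin[, yr, "i"]
      if (observation_noise) {
        observe_draws(y_lat, th[, "sigma_e"], config$n_population)
      } else {
        pmin(pmax(config$n_population - y_lat, 0), config$n_population)
      }
    })
    r_draws <- matrix(r_draws, nrow = n_sims)
    out <- new_predictive_summary(max(obs$year) + seq_len(horizon_years),
                                  r_draws, mode = "forward", n_draws = n_sims)
    if (return_draws) attr(out, "draws") <- r_draws
    out
  })
}

#' Yearly posterior distributions of the basic reproduction number
#'
#' Transforms the stored joint draws of the latent log infestation rate and
#' the removal rate into yearly reproduction numbers
#' \eqn{R_0(t) = e^{\tilde\beta_t} N / \gamma}. Each stored latent path is
#' paired with its own parameter draw, so no independence between
#' \eqn{\tilde\beta_t} and \eqn{\gamma} is assumed.
#'
#' @param chain An `opm_chain` with latent paths.
#' @param config Defaults to the chain's configuration.
#' @return An object of class `r0_summary`: a list with `draws` (data frame
#'   `year`, `draw_id`, `r0`) and `summary` (per-year median and quartiles).
#' @export
r0_posterior <- function(chain, config = chain$config) {
  paths <- chain_paths_or_stop(chain)
  obs_t <- chain$obs$t
  years <- chain$obs$year
  draws <- do.call(rbind, lapply(seq_along(paths), function(j) {
    p <- paths[[j]]
    idx <- match(round(obs_t, 9), round(p$times, 9))
    bl <- p$states[idx, "beta_log"]
    gamma <- chain$draws[p$draw, "gamma"]
    data.frame(year = years, draw_id = j,
               r0 = basic_reproduction_number(bl, gamma, config$n_population))
  }))
  summ <- do.call(rbind, lapply(split(draws, draws$year), function(dd) {
    q <- stats::quantile(dd$r0, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(year = dd$year[1], q25 = q[1], median = q[2], q75 = q[3])
  }))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ), class = "r0_summary")
}

#' @export
print.r0_summary <- function(x, ...) {
  cat("<r0_summary> yearly posterior of R0(t) = exp(beta_log_t) * N / gamma\n")
  print(transform(x$summary, q25 = signif(q25, 3), median = signif(median, 3),
                  q75 = signif(q75, 3)))
  invisible(x)
}
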