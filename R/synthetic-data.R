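# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Yearly observation series of cumulative removals
#'
#' Container for the observed data: the cumulative number of unique trees that
#' have had nests removed, recorded once per year. Given the closed population
#' size `N`, observing the removed count `R(t)` is equivalent to observing
#' `y_t = N - R(t) = S_t + I_t`, which is the quantity the filter consumes.
#'
#' @param years Integer-valued year labels, strictly increasing with unit
#'   spacing (calendar years are fine; they are rebased internally).
#' @param r_cumulative Cumulative removed-tree counts, in `[0, N]` where `N`
#'   is known.
#' @param n_population Optional population size `N`; required before the
#'   filter observations `y` can be formed.
#' @param y Optional raw (unrounded) filter observations `N - R(t)`; when
#'   omitted they are derived from `r_cumulative` once `n_population` is set.
#' @return An object of class `observation_series`: a data frame with columns
#'   `year`, `t` (years rebased to 0..n), `r_cumulative` and, when `N` is
#'   known, `y`, plus an `n_population` attribute.
#' @examples
#' observation_series(2013:2020, c(5, 30, 80, 200, 380, 600, 850, 1100),
#'                    n_population = 5e3)
#' @export
observation_series <- function(years, r_cumulative, n_population = NULL,
                               y = NULL) {
  if (length(years) != length(r_cumulative)) {
    stop("observation_series: years and r_cumulative lengths differ")
  }
  if (length(years) < 2) stop("observation_series: need at least 2 points")
  d <- diff(years)
  if (any(d <= 0)) {
    stop(sprintf("observation_series: years must be strictly increasing (row %d)",
                 which(d <= 0)[1] + 1L))
  }
  if (any(d != 1)) {
    stop(sprintf("observation_series: years must have unit spacing (row %d)",
                 which(d != 1)[1] + 1L))
  }
  if (any(r_cumulative < 0)) {
    stop(sprintf("observation_series: negative count at row %d",
                 which(r_cumulative < 0)[1]))
  }
  out <- data.frame(year = as.numeric(years),
                    t = as.numeric(years) - years[1],
                    r_cumulative = as.numeric(r_cumulative))
  if (!is.null(n_population)) {
    if (any(r_cumulative > n_population)) {
      stop(sprintf("observation_series: count exceeds N at row %d",
                   which(r_cumulative > n_population)[1]))
    }
    out$y <- if (!is.null(y)) as.numeric(y) else n_population - out$r_cumulative
  }
  structure(out, n_population = n_population,
            class = c("observation_series", "data.frame"))
}

# Attach/derive filter observations y = N - R for a given population size.
obs_with_population <- function(obs, n_population) {
  if (!is.null(obs$y) && !is.null(attr(obs, "n_population")) &&
      attr(obs, "n_population") == n_population) {
    return(obs)
  }
  observation_series(obs$year, obs$r_cumulative, n_population = n_population)
}

new_simulated_epidemic <- function(times, states, params, config, seed,
                                   method, events = NULL) {
  structure(list(times = times, states = states, true_params = params,
                 config = config, seed = seed, method = method,
                 events = events),
            class = "simulated_epidemic")
}

#' @export
print.simulated_epidemic <- function(x, ...) {
  cat(sprintf("<simulated_epidemic: %s, N=%g, %d time points, t in [%g, %g]>\n",
              x$method, x$config$n_population, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Exact stochastic simulation of the Markov jump process SIR model
#'
#' Gillespie simulation of the integer-valued SIR model with reactions
#' `S + I -> 2I` at hazard \eqn{e^{\tilde\beta} S I} and `I -> R` at hazard
#' \eqn{\gamma I}. The log infestation rate is frozen between the nodes of a
#' fine grid of spacing `beta_step` and receives independent
#' `N(0, sigma^2 * beta_step)` increments at each node, so hazards are locally
#' constant as Gillespie's algorithm requires.
#'
#' @param config A [model_config].
#' @param params A [static_params]; `params["sigma"]` controls the log-rate
#'   random walk.
#' @param t_end Simulation horizon in years, > 0.
#' @param beta_step Grid spacing (years) on which the log rate is updated.
#' @param seed Optional integer seed (restores the caller's RNG stream).
#' @param beta_log0 Initial log rate; defaults to `config$beta_log0_mean`.
#' @return A `simulated_epidemic` with integer-valued `s`, `i` columns, the
#'   event log (`time`, `type` in `{"infestation", "removal"}`), and states
#'   recorded at every event and grid node.
#' @examples
#' cfg <- model_config(50, s0 = 45, i0 = 5, beta_log0_mean = log(0.02))
#' sim <- simulate_mjp(cfg, static_params(1, 0.5, 1), t_end = 2, seed = 1)
#' @export
simulate_mjp <- function(config, params, t_end, beta_step = 1 / 100,
                         seed = NULL, beta_log0 = config$beta_log0_mean) {
  if (t_end <= 0) stop("simulate_mjp: t_end must be > 0")
  if (beta_step <= 0) stop("simulate_mjp: beta_step must be > 0")
  with_seed(seed, {
    gamma <- params[["gamma"]]; sigma <- params[["sigma"]]
    s <- config$s0; i <- config$i0; t <- 0
    bl <- beta_log0
    n_grid <- ceiling(t_end / beta_step)
    # preallocate generously: at most 2N events plus grid nodes
    cap <- 2L * as.integer(config$n_population) + n_grid + 2L
    times <- numeric(cap); ss <- numeric(cap); ii <- numeric(cap)
    bb <- numeric(cap); ev_time <- numeric(cap); ev_type <- integer(cap)
    k <- 1L; ne <- 0L
    times[1] <- 0; ss[1] <- s; ii[1] <- i; bb[1] <- bl
    next_node <- beta_step
    while (t < t_end) {
      h1 <- exp(bl) * s * i
      h2 <- gamma * i
      h0 <- h1 + h2
      dt <- if (h0 > 0) stats::rexp(1, h0) else Inf
      if (t + dt >= min(next_node, t_end)) {
        # no event before the next grid node (or the horizon)
        t <- min(next_node, t_end)
        if (t >= next_node) {
          bl <- bl + stats::rnorm(1, 0, sigma * sqrt(beta_step))
          next_node <- next_node + beta_step
        }
      } else {
        t <- t + dt
        if (stats::runif(1) * h0 < h1) {
          s <- s - 1; i <- i + 1
          ne <- ne + 1L; ev_time[ne] <- t; ev_type[ne] <- 1L
        } else {
          i <- i - 1
          ne <- ne + 1L; ev_time[ne] <- t; ev_type[ne] <- 2L
        }
      }
      k <- k + 1L
      times[k] <- t; ss[k] <- s; ii[k] <- i; bb[k] <- bl
      if (i == 0 && sigma == 0) break  # absorbed; nothing more can happen
    }
    if (times[k] < t_end) {
      k <- k + 1L; times[k] <- t_end; ss[k] <- s; ii[k] <- i; bb[k] <- bl
    }
    states <- cbind(s = ss[1:k], i = ii[1:k], beta_log = bb[1:k])
    events <- data.frame(time = ev_time[seq_len(ne)],
                         type = c("infestation", "removal")[ev_type[seq_len(ne)]])
    new_simulated_epidemic(times[1:k], states, params, config, seed,
                           method = "mjp", events = events)
  })
}

#' Ensemble of Markov jump process simulations with a fixed rate
#'
#' Simulates many independent Gillespie realisations simultaneously, for
#' Monte-Carlo validation of the linear noise approximation. Restricted to
#' `sigma = 0` (constant log rate), which keeps every replicate's hazards
#' constant between events and allows the ensemble to be advanced in
#' lock-step.
#'
#' @inheritParams simulate_mjp
#' @param n_rep Number of replicates.
#' @param out_times Times (years) at which to record each replicate's state.
#' @return A list with matrices `s` and `i` of dimension
#'   `n_rep x length(out_times)`.
#' @export
simulate_mjp_ensemble <- function(config, params, t_end, n_rep,
                                  out_times, seed = NULL,
                                  beta_log0 = config$beta_log0_mean) {
  if (params[["sigma"]] != 0) {
    stop("simulate_mjp_ensemble: requires sigma = 0 (constant log rate)")
  }
  if (any(out_times < 0) || any(out_times > t_end)) {
    stop("simulate_mjp_ensemble: out_times outside [0, t_end]")
  }
  with_seed(seed, {
    gamma <- params[["gamma"]]; beta <- exp(beta_log0)
    s <- rep(config$s0, n_rep); i <- rep(config$i0, n_rep)
    t <- numeric(n_rep)
    ot <- sort(out_times)
    s_out <- matrix(NA_real_, n_rep, length(ot))
    i_out <- matrix(NA_real_, n_rep, length(ot))
    rec <- rep(1L, n_rep)  # next output index per replicate
    active <- rep(TRUE, n_rep)
    while (any(active)) {
      idx <- which(active)
      h1 <- beta * s[idx] * i[idx]
      h0 <- h1 + gamma * i[idx]
      dt <- ifelse(h0 > 0, stats::rexp(length(idx), pmax(h0, .Machine$double.xmin)),
                   Inf)
      t_new <- t[idx] + dt
      # record outputs the replicate passes before its next event
      for (j in seq_along(ot)) {
        hit <- rec[idx] == j & t_new > ot[j]
        if (any(hit)) {
          s_out[idx[hit], j] <- s[idx][hit]
          i_out[idx[hit], j] <- i[idx][hit]
          rec[idx[hit]] <- j + 1L
        }
      }
      done <- t_new > t_end | !is.finite(t_new)
      infect <- stats::runif(length(idx)) * h0 < h1
      take <- !done
      who <- idx[take]
      s[who] <- s[who] - infect[take]
      i[who] <- i[who] + ifelse(infect[take], 1, -1)
      t[who] <- t_new[take]
      active[idx[done]] <- FALSE
    }
    # replicates that finished before recording late outputs hold their state
    for (j in seq_along(ot)) {
      miss <- is.na(s_out[, j])
      if (any(miss)) { s_out[miss, j] <- s[miss]; i_out[miss, j] <- i[miss] }
    }
    list(s = s_out, i = i_out, times = ot)
  })
}

#' Euler-Maruyama simulation of the SIR diffusion
#'
#' Simulates the chemical-Langevin form of the SIR diffusion: over each step
#' the infestation and removal reaction counts receive independent Gaussian
#' increments with mean and variance equal to `hazard * dt`, truncated at zero
#' so that reaction counts cannot run backwards. This reproduces the drift and
#' diffusion matrix of the SIR stochastic differential equation while keeping
#' the cumulative removed count monotone. The log rate receives exact Brownian
#' increments. `s` and `i` are clamped at zero.
#'
#' @inheritParams simulate_mjp
#' @param dt Euler step (years), default 1/365.
#' @param demographic_noise Include the reaction-count (demographic) noise?
#'   With `demographic_noise = FALSE` and `sigma = 0` the path solves the
#'   deterministic SIR ODE.
#' @return A `simulated_epidemic` with the dense path.
#' @export
simulate_sde <- function(config, params, t_end, dt = 1 / 365, seed = NULL,
                         beta_log0 = config$beta_log0_mean,
                         demographic_noise = TRUE) {
  if (t_end <= 0) stop("simulate_sde: t_end must be > 0")
  if (dt <= 0) stop("simulate_sde: dt must be > 0")
  noise <- as.numeric(demographic_noise)
  with_seed(seed, {
    n <- ceiling(t_end / dt)
    times <- seq(0, by = dt, length.out = n + 1)
    times[n + 1] <- t_end
    st <- matrix(NA_real_, n + 1, 3,
                 dimnames = list(NULL, c("s", "i", "beta_log")))
    st[1, ] <- c(config$s0, config$i0, beta_log0)
    gamma <- params[["gamma"]]; sigma <- params[["sigma"]]
    for (k in seq_len(n)) {
      h <- times[k + 1] - times[k]
      s <- st[k, 1]; i <- st[k, 2]; bl <- st[k, 3]
      h_inf <- exp(bl) * s * i
      h_rem <- gamma * i
      d_inf <- max(0, stats::rnorm(1, h_inf * h, noise * sqrt(h_inf * h)))
      d_rem <- max(0, stats::rnorm(1, h_rem * h, noise * sqrt(h_rem * h)))
      s_new <- max(0, s - d_inf)
      i_new <- max(0, i + (s - s_new) - d_rem)
      st[k + 1, ] <- c(s_new, i_new, bl + stats::rnorm(1, 0, sigma * sqrt(h)))
    }
    new_simulated_epidemic(times, st, params, config, seed, method = "sde")
  })
}

# State of a simulated epidemic at arbitrary times (piecewise-constant for
# the jump process, nearest grid point for the diffusion path).
state_at <- function(epidemic, at_times) {
  idx <- findInterval(at_times + 1e-12, epidemic$times)
  idx[idx < 1] <- 1L
  epidemic$states[idx, , drop = FALSE]
}

#' Observe a simulated epidemic
#'
#' Applies the observation model: at each observation time the raw
#' observation is \eqn{y_t \sim N(S_t + I_t,\; \sigma_e^2 (S_t + I_t))}
#' (variance floored at one tree), and the reported cumulative removal count
#' is `N - y_t` rounded to the nearest integer and clipped to `[0, N]`.
#'
#' @param epidemic A `simulated_epidemic`.
#' @param obs_years Observation times (years) within the simulated span.
#' @param sigma_e Observation-noise scale.
#' @param seed Optional integer seed.
#' @param year0 Calendar label for time 0 (cosmetic; default 2013).
#' @return An [observation_series] carrying both the rounded counts and the
#'   raw `y` values the filter consumes.
#' @export
observe <- function(epidemic, obs_years, sigma_e, seed = NULL, year0 = 2013) {
  if (any(obs_years < min(epidemic$times) - 1e-9) ||
      any(obs_years > max(epidemic$times) + 1e-9)) {
    stop("observe: obs_years outside the simulated span")
  }
  with_seed(seed, {
    N <- epidemic$config$n_population
    x <- state_at(epidemic, obs_years)
    mu <- x[, "s"] + x[, "i"]
    v <- sigma_e^2 * pmax(mu, 1)  # variance floor of one tree
    y <- stats::rnorm(length(mu), mu, sqrt(v))
    r <- pmin(pmax(round(N - y), 0), N)
    observation_series(year0 + obs_years, r, n_population = N, y = y)
  })
}

#' Generate a synthetic study fixture
#'
#' Simulates a ground-truth epidemic and its noisy yearly observation series
#' under conditions emulating the two London parks the model was built for:
#' an 8-point yearly grid, park-scale populations, a slowly varying log
#' infestation rate near -8 to -10, removal rate near one per year, and
#' mean-proportional Gaussian observation noise.
#'
#' Presets: `"bushy-like"` uses `N = 5e3`, `beta_log0 = -8`, `gamma = 1`,
#' `sigma = 0.75`, `sigma_e = 1`; `"richmond-like"` uses `N = 4e4`,
#' `beta_log0 = -10`, `gamma = 1`, `sigma = 0.5`, `sigma_e = 0.5`. `"custom"`
#' requires `config` and `params`.
#'
#' @param preset One of `"bushy-like"`, `"richmond-like"`, `"custom"`.
#' @param seed Integer seed; one seed fully determines the fixture.
#' @param config,params For `preset = "custom"`, a [model_config] and
#'   [static_params].
#' @param n_years Number of yearly observations (default 8, years 0..7).
#' @param dt Euler step for the ground-truth path.
#' @return A list with elements `obs` (an [observation_series]) and `truth`
#'   (the underlying `simulated_epidemic`).
#' @examples
#' fx <- generate_fixture("bushy-like", seed = 1)
#' fx$obs
#' @export
generate_fixture <- function(preset = c("bushy-like", "richmond-like", "custom"),
                             seed = 1, config = NULL, params = NULL,
                             n_years = 8, dt = 1 / 365) {
  preset <- match.arg(preset)
  if (preset == "bushy-like") {
    config <- model_config(5e3, s0 = 5e3 - 100, i0 = 100,
                           beta_log0_mean = -8, beta_log0_sd = 0.5)
    params <- static_params(gamma = 1, sigma = 0.75, sigma_e = 1)
  } else if (preset == "richmond-like") {
    config <- model_config(4e4, s0 = 4e4 - 1400, i0 = 1400,
                           beta_log0_mean = -10, beta_log0_sd = 0.5)
    params <- static_params(gamma = 1, sigma = 0.5, sigma_e = 0.5)
  } else if (is.null(config) || is.null(params)) {
    stop("generate_fixture: preset 'custom' needs config and params")
  }
  t_end <- n_years - 1
  with_seed(seed, {
    truth <- simulate_sde(config, params, t_end = max(t_end, dt), dt = dt)
    obs <- observe(truth, obs_years = 0:t_end, sigma_e = params[["sigma_e"]])
    list(obs = obs, truth = truth)
  })
}
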