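#' Prior specification
#'
#' Independent priors for the static parameters and the initial log
#' infestation rate: lognormal LN(0, 0.5^2) for the removal rate `gamma`
#' (median removal time of one year, 95% interval (0.38, 2.66) years),
#' lognormal LN(1, 1) for the log-rate volatility `sigma` and for the
#' observation-noise scale `sigma_e`, and Gaussian N(-8.5, 0.5^2) for
#' \eqn{\tilde\beta_0}. All hyperparameters are overridable.
#'
#' @param gamma_meanlog,gamma_sdlog Lognormal hyperparameters of `gamma`.
#' @param sigma_meanlog,sigma_sdlog Lognormal hyperparameters of `sigma`.
#' @param sigma_e_meanlog,sigma_e_sdlog Lognormal hyperparameters of
#'   `sigma_e`.
#' @param beta_log0_mean,beta_log0_sd Gaussian hyperparameters of the initial
#'   log infestation rate.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(gamma_meanlog = 0, gamma_sdlog = 0.5,
                       sigma_meanlog = 1, sigma_sdlog = 1,
                       sigma_e_meanlog = 1, sigma_e_sdlog = 1,
                       beta_log0_mean = -8.5, beta_log0_sd = 0.5) {
  if (any(c(gamma_sdlog, sigma_sdlog, sigma_e_sdlog, beta_log0_sd) < 0)) {
    stop("prior_spec: scale hyperparameters must be >= 0")
  }
  structure(list(gamma_meanlog = gamma_meanlog, gamma_sdlog = gamma_sdlog,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 sigma_e_meanlog = sigma_e_meanlog,
                 sigma_e_sdlog = sigma_e_sdlog,
                 beta_log0_mean = beta_log0_mean,
                 beta_log0_sd = beta_log0_sd),
            class = "prior_spec")
}

#' Log prior density of the static parameters
#'
#' Sum of the three lognormal log-densities \eqn{\pi(\theta) =
#' \pi(\gamma)\pi(\sigma)\pi(\sigma_e)}. Nonpositive parameters have zero
#' prior mass.
#'
#' @param params A [static_params] (or positive numeric 3-vector).
#' @param prior A [prior_spec].
#' @return The log prior density (`-Inf` for nonpositive parameters).
#' @export
log_prior <- function(params, prior = prior_spec()) {
  th <- as.numeric(params)[1:3]
  if (any(th <= 0)) return(-Inf)
  stats::dlnorm(th[1], prior$gamma_meanlog, prior$gamma_sdlog, log = TRUE) +
    stats::dlnorm(th[2], prior$sigma_meanlog, prior$sigma_sdlog, log = TRUE) +
    stats::dlnorm(th[3], prior$sigma_e_meanlog, prior$sigma_e_sdlog, log = TRUE)
}

#' Prior 95% interval of the initial basic reproduction number
#'
#' Closed-form equal-tail 95% interval of \eqn{R_0 = e^{\tilde\beta_0} N /
#' \gamma} under the priors: \eqn{\log R_0} is Gaussian with mean
#' `beta_log0_mean + log(N) - gamma_meanlog` and variance
#' `beta_log0_sd^2 + gamma_sdlog^2`.
#'
#' @param prior A [prior_spec].
#' @param n_population Population size `N` (> 0).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' prior_r0_interval(prior_spec(), n_population = 5e3)  # about (0.25, 4.1)
#' @export
prior_r0_interval <- function(prior = prior_spec(), n_population) {
  if (n_population <= 0) stop("prior_r0_interval: n_population must be > 0")
  m <- prior$beta_log0_mean + log(n_population) - prior$gamma_meanlog
  s <- sqrt(prior$beta_log0_sd^2 + prior$gamma_sdlog^2)
  z <- stats::qnorm(0.975)
  c(lower = exp(m - z * s), upper = exp(m + z * s))
}

#' MCMC settings
#'
#' @param iterations Total number of Metropolis-Hastings iterations
#'   (default 10000).
#' @param burn_in Iterations discarded as burn-in (default 2000).
#' @param thin Thinning interval for retained draws.
#' @param proposal_sd Initial standard deviation of the joint Gaussian
#'   random-walk proposal on the log-parameter scale.
#' @param adapt Adapt the global proposal scale toward `target_accept`
#'   during burn-in only (frozen afterwards).
#' @param target_accept Target acceptance rate for adaptation.
#' @param sample_paths Draw latent paths for a thinned subset of retained
#'   draws (needed for R0 and within-sample summaries).
#' @param path_thin Keep one latent path draw per `path_thin` retained draws.
#' @param path_fine_steps Interior bridge points per yearly interval in the
#'   stored latent paths.
#' @param likelihood If `FALSE`, run in prior-only mode (the likelihood is
#'   held constant), so the chain targets the prior — used for calibration.
#' @param sample_beta_log0 Treat the initial log rate as a fourth sampled
#'   parameter instead of marginalising it inside the filter (sensitivity
#'   analysis).
#' @return A list of settings for [fit_mcmc].
#' @export
mcmc_control <- function(iterations = 10000, burn_in = 2000, thin = 1,
                         proposal_sd = 0.1, adapt = TRUE,
                         target_accept = 0.3, sample_paths = TRUE,
                         path_thin = 10, path_fine_steps = 0,
                         likelihood = TRUE, sample_beta_log0 = FALSE) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1, proposal_sd > 0)
  list(iterations = iterations, burn_in = burn_in, thin = thin,
       proposal_sd = proposal_sd, adapt = adapt,
       target_accept = target_accept, sample_paths = sample_paths,
       path_thin = path_thin, path_fine_steps = path_fine_steps,
       likelihood = likelihood, sample_beta_log0 = sample_beta_log0)
}

#' Random-walk Metropolis sampler for the static parameters
#'
#' Samples the marginal parameter posterior \eqn{\pi(\theta | y) \propto
#' \pi(\theta)\pi(y|\theta)} by a joint Gaussian random walk on
#' \eqn{(\log\gamma, \log\sigma, \log\sigma_e)}. Working on the log scale
#' turns the lognormal priors into Gaussians (the change-of-variables
#' Jacobian is absorbed exactly), and positivity is automatic. The
#' likelihood is the LNA marginal likelihood from [lna_filter], with the
#' Gaussian prior on \eqn{\tilde\beta_0} marginalised analytically inside
#' the filter. After the parameter sweep, latent paths are drawn for a
#' thinned subset of retained draws by [sample_latent_path].
#'
#' @param obs An [observation_series].
#' @param prior A [prior_spec].
#' @param config A [model_config]; its `beta_log0_*` fields are synchronised
#'   with the prior.
#' @param control Settings from [mcmc_control].
#' @param lna Settings from [lna_control].
#' @param seed Integer seed; the same seed reproduces the chain exactly.
#' @param init Optional initial `(gamma, sigma, sigma_e)`; defaults to the
#'   prior medians.
#' @return An object of class `opm_chain`: matrix `draws` (retained samples),
#'   `log_post` trace, `accepted` flags, `acceptance_rate`, list
#'   `latent_paths` (each with `draw` index, `times`, `states`), and the
#'   inputs (`obs`, `config`, `prior`, `control`, `seed`).
#' @export
fit_mcmc <- function(obs, prior = prior_spec(), config,
                     control = mcmc_control(), lna = lna_control(),
                     seed = NULL, init = NULL) {
  config$beta_log0_mean <- prior$beta_log0_mean
  config$beta_log0_sd <- prior$beta_log0_sd
  obs <- obs_with_population(obs, config$n_population)
  sample_b0 <- isTRUE(control$sample_beta_log0)
  d <- if (sample_b0) 4L else 3L
  mu0 <- c(prior$gamma_meanlog, prior$sigma_meanlog, prior$sigma_e_meanlog)
  sd0 <- c(prior$gamma_sdlog, prior$sigma_sdlog, prior$sigma_e_sdlog)
  if (sample_b0) {
    mu0 <- c(mu0, prior$beta_log0_mean)
    sd0 <- c(sd0, prior$beta_log0_sd)
  }

  loglik <- function(phi) {
    if (!control$likelihood) return(0)
    th <- static_params(exp(phi[1]), exp(phi[2]), exp(phi[3]))
    cfg <- config
    if (sample_b0) {
      cfg$beta_log0_mean <- phi[4]
      cfg$beta_log0_sd <- 0
    }
    ll <- tryCatch(suppressWarnings(lna_log_likelihood(th, cfg, obs, lna)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
  logpost <- function(phi) {
    sum(stats::dnorm(phi, mu0, sd0, log = TRUE)) + loglik(phi)
  }

  with_seed(seed, {
    phi <- if (is.null(init)) mu0 else {
      stopifnot(length(init) %in% c(3, d))
      c(log(init[1:3]), if (sample_b0) {
        if (length(init) == 4) init[4] else prior$beta_log0_mean
      })
    }
    lp <- logpost(phi)
    if (!is.finite(lp) && is.null(init)) {
      # prior medians can sit in a rejected region for some data sets;
      # search the prior for a valid starting point
      for (try in seq_len(500)) {
        phi <- stats::rnorm(d, mu0, sd0)
        lp <- logpost(phi)
        if (is.finite(lp)) break
      }
    }
    if (!is.finite(lp)) stop("fit_mcmc: could not find a starting value with positive posterior density")
    scale <- 1
    n_keep <- floor((control$iterations - control$burn_in) / control$thin)
    draws <- matrix(NA_real_, n_keep, d)
    lp_trace <- numeric(n_keep)
    acc_trace <- logical(n_keep)
    kept <- 0L
    acc_batch <- 0L
    n_acc_post <- 0L
    for (it in seq_len(control$iterations)) {
      phi_prop <- phi + scale * control$proposal_sd * stats::rnorm(d)
      lp_prop <- logpost(phi_prop)
      accept <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
      if (accept) { phi <- phi_prop; lp <- lp_prop }
      if (it <= control$burn_in) {
        acc_batch <- acc_batch + accept
        if (control$adapt && it %% 50 == 0) {
          rate <- acc_batch / 50
          if (rate > control$target_accept * 1.25) scale <- scale * 1.25
          if (rate < control$target_accept * 0.8) scale <- scale / 1.25
          acc_batch <- 0L
        }
      } else {
        n_acc_post <- n_acc_post + accept
        j <- it - control$burn_in
        if (j %% control$thin == 0) {
          kept <- kept + 1L
          draws[kept, ] <- phi
          lp_trace[kept] <- lp
          acc_trace[kept] <- accept
        }
      }
    }
    acceptance_rate <- n_acc_post / (control$iterations - control$burn_in)
    if (acceptance_rate < 0.001) {
      warning("fit_mcmc: acceptance rate below 0.1%; chain has not moved")
    }
    out <- draws
    out[, 1:3] <- exp(out[, 1:3])
    colnames(out) <- c("gamma", "sigma", "sigma_e",
                       if (sample_b0) "beta_log0")
    chain <- structure(
      list(draws = out, log_post = lp_trace, accepted = acc_trace,
           acceptance_rate = acceptance_rate, proposal_scale = scale,
           latent_paths = NULL, obs = obs, config = config, prior = prior,
           control = control, lna = lna, seed = seed),
      class = "opm_chain")
    if (control$sample_paths && control$likelihood) {
      chain$latent_paths <- draw_chain_paths(chain,
                                             path_thin = control$path_thin,
                                             fine_steps = control$path_fine_steps)
    }
    chain
  })
}

# Draw one latent path per `path_thin`-th retained draw, tagged with its row.
draw_chain_paths <- function(chain, path_thin = 10, fine_steps = 0) {
  idx <- seq(1, nrow(chain$draws), by = path_thin)
  lapply(idx, function(k) {
    th <- static_params(chain$draws[k, "gamma"], chain$draws[k, "sigma"],
                        chain$draws[k, "sigma_e"])
    cfg <- chain$config
    if ("beta_log0" %in% colnames(chain$draws)) {
      cfg$beta_log0_mean <- chain$draws[k, "beta_log0"]
      cfg$beta_log0_sd <- 0
    }
    p <- sample_latent_path(th, cfg, chain$obs, n_draws = 1,
                            fine_steps = fine_steps, control = chain$lna)[[1]]
    c(p, list(draw = k))
  })
}

#' @export
print.opm_chain <- function(x, ...) {
  q <- apply(x$draws[, 1:3, drop = FALSE], 2, stats::quantile,
             probs = c(0.025, 0.5, 0.975))
  cat(sprintf("<opm_chain: %d retained draws, acceptance rate %.2f>\n",
              nrow(x$draws), x$acceptance_rate))
  print(signif(t(q), 3))
  invisible(x)
}

# Effective sample size by Geyer's initial positive sequence estimator.
ess_ipse <- function(x) {
  m <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(m - 1, 10 * ceiling(sqrt(m))),
                    plot = FALSE)$acf[, 1, 1]
  # pair sums Gamma_k = rho_{2k} + rho_{2k+1}; stop at first negative
  tau <- 1
  k <- 1
  while (k + 1 < length(rho)) {
    g <- rho[k + 1] + rho[k + 2]
    if (g < 0) break
    tau <- tau + 2 * g
    k <- k + 2
  }
  m / tau
}

#' Chain convergence diagnostics
#'
#' Effective sample size (Geyer initial-positive-sequence), split-\eqn{\hat R}
#' (each chain half treated as a separate chain), and the acceptance rate.
#'
#' @param chain An `opm_chain` with at least 100 retained draws.
#' @return A data frame with one row per parameter: `ess`, `split_rhat`,
#'   posterior `median`, and the overall `acceptance_rate`.
#' @export
chain_diagnostics <- function(chain) {
  draws <- if (inherits(chain, "opm_chain")) chain$draws else as.matrix(chain)
  m <- nrow(draws)
  if (m < 100) stop("chain_diagnostics: need at least 100 retained draws")
  half <- floor(m / 2)
  out <- do.call(rbind, lapply(colnames(draws), function(p) {
    x <- draws[, p]
    if (stats::sd(x) == 0) {
      warning(sprintf("chain_diagnostics: parameter '%s' is constant; ESS degenerate", p))
      return(data.frame(parameter = p, ess = NA_real_, split_rhat = NA_real_,
                        median = stats::median(x)))
    }
    xs <- list(x[1:half], x[(half + 1):(2 * half)])
    w <- mean(vapply(xs, stats::var, numeric(1)))
    b <- half * stats::var(vapply(xs, mean, numeric(1)))
    rhat <- sqrt(((half - 1) / half * w + b / half) / w)
    data.frame(parameter = p, ess = ess_ipse(x), split_rhat = rhat,
               median = stats::median(x))
  }))
  attr(out, "acceptance_rate") <-
    if (inherits(chain, "opm_chain")) chain$acceptance_rate else NA_real_
  out
}
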