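#' Latent epidemic state
#'
#' Constructs the latent state \eqn{X_t = (S_t, I_t, \tilde\beta_t)'} of the
#' stochastic SIR model with a time-varying infestation rate: the number of
#' susceptible trees, the number of currently infested trees, and the logarithm
#' of the per-pair infestation rate. The removed count is always derived as
#' \eqn{R_t = N - S_t - I_t} and never stored.
#'
#' @param s Susceptible count (continuous relaxation, trees), `s >= 0`.
#' @param i Infested count (trees), `i >= 0`.
#' @param beta_log Log infestation rate \eqn{\tilde\beta_t = \log\beta_t}
#'   (log 1/year per susceptible-infested pair). Unconstrained.
#' @param t Time in years since the first observation.
#' @return An object of class `epidemic_state`: a named numeric vector with a
#'   time attribute.
#' @examples
#' epidemic_state(s = 4000, i = 100, beta_log = -8)
#' @export
epidemic_state <- function(s, i, beta_log, t = 0) {
  stopifnot(is.numeric(s), is.numeric(i), is.numeric(beta_log), length(s) == 1,
            length(i) == 1, length(beta_log) == 1)
  if (s < 0 || i < 0) {
    stop("epidemic_state: 's' and 'i' must be nonnegative")
  }
  x <- c(s = as.numeric(s), i = as.numeric(i), beta_log = as.numeric(beta_log))
  structure(x, t = as.numeric(t), class = "epidemic_state")
}

#' @export
print.epidemic_state <- function(x, ...) {
  cat(sprintf("<epidemic_state t=%.4g> S=%.4g I=%.4g beta_log=%.4g\n",
              attr(x, "t"), x[["s"]], x[["i"]], x[["beta_log"]]))
  invisible(x)
}

#' Static model parameters
#'
#' The static parameter vector \eqn{\theta = (\gamma, \sigma, \sigma_e)'}:
#' removal rate, volatility of the log infestation rate, and observation-noise
#' scale. All must be strictly positive.
#'
#' @param gamma Removal rate (1/year), strictly positive; `1/gamma` is the
#'   mean infested lifetime.
#' @param sigma Volatility of the Brownian log infestation rate
#'   (1/sqrt(year)); zero gives a constant rate.
#' @param sigma_e Observation-noise scale (dimensionless); observation variance
#'   is `sigma_e^2` times the observation mean. Zero gives exact observations.
#' @return An object of class `static_params` (named numeric vector).
#' @examples
#' static_params(gamma = 1, sigma = 0.75, sigma_e = 1)
#' @export
static_params <- function(gamma, sigma, sigma_e) {
  th <- c(gamma = as.numeric(gamma), sigma = as.numeric(sigma),
          sigma_e = as.numeric(sigma_e))
  if (any(!is.finite(th)) || gamma <= 0 || sigma < 0 || sigma_e < 0) {
    stop("static_params: need finite gamma > 0, sigma >= 0, sigma_e >= 0")
  }
  structure(th, class = "static_params")
}

#' Model configuration
#'
#' Fixed quantities of a single epidemic: the closed population size `N`, the
#' initial susceptible and infested counts, and the Gaussian prior on the
#' initial log infestation rate \eqn{\tilde\beta_0}.
#'
#' @param n_population Total number of trees `N` in the closed population.
#' @param s0 Initial susceptible count.
#' @param i0 Initial infested count; `s0 + i0 <= n_population`.
#' @param beta_log0_mean,beta_log0_sd Mean and standard deviation of the
#'   Gaussian prior on \eqn{\tilde\beta_0}. Defaults N(-8.5, 0.5^2).
#' @return An object of class `model_config` (a list).
#' @examples
#' model_config(n_population = 5e3, s0 = 4900, i0 = 100)
#' @export
model_config <- function(n_population, s0, i0,
                         beta_log0_mean = -8.5, beta_log0_sd = 0.5) {
  if (n_population <= 0) stop("model_config: n_population must be > 0")
  if (s0 < 0 || i0 < 0) stop("model_config: s0 and i0 must be nonnegative")
  if (s0 + i0 > n_population) {
    stop("model_config: s0 + i0 must not exceed n_population")
  }
  if (beta_log0_sd < 0) stop("model_config: beta_log0_sd must be >= 0")
  structure(list(n_population = as.numeric(n_population),
                 s0 = as.numeric(s0), i0 = as.numeric(i0),
                 beta_log0_mean = as.numeric(beta_log0_mean),
                 beta_log0_sd = as.numeric(beta_log0_sd)),
            class = "model_config")
}

as_state_vector <- function(state) {
  if (inherits(state, "epidemic_state")) unclass(state)[1:3]
  else {
    stopifnot(is.numeric(state), length(state) == 3)
    stats::setNames(as.numeric(state), c("s", "i", "beta_log"))
  }
}

#' Drift of the SIR diffusion
#'
#' Drift function \eqn{a(x, \theta)} of the SIR stochastic differential
#' equation with log infestation rate \eqn{\tilde\beta}:
#' \deqn{a(x,\theta) = (-e^{\tilde\beta} s i,\; e^{\tilde\beta} s i - \gamma i,\; 0)'.}
#' The log-rate component has zero drift because \eqn{\tilde\beta_t} is a
#' driftless Brownian motion.
#'
#' @param state An [epidemic_state] (or numeric 3-vector `(s, i, beta_log)`).
#' @param params A [static_params] object.
#' @return Numeric 3-vector `(ds/dt, di/dt, dbeta_log/dt)`.
#' @examples
#' sir_drift(epidemic_state(4000, 100, -8), static_params(1, 0.5, 1))
#' @export
sir_drift <- function(state, params) {
  x <- as_state_vector(state)
  infest <- exp(x[["beta_log"]]) * x[["s"]] * x[["i"]]
  c(-infest, infest - params[["gamma"]] * x[["i"]], 0)
}

#' Diffusion matrix of the SIR diffusion
#'
#' Diffusion coefficient \eqn{b(x, \theta)} (an instantaneous covariance
#' matrix): infection events add variance \eqn{e^{\tilde\beta} s i} to S and I
#' with perfect negative correlation, removals add \eqn{\gamma i} to I, and
#' the log rate diffuses with variance \eqn{\sigma^2}.
#'
#' @inheritParams sir_drift
#' @return Symmetric positive semi-definite 3x3 matrix.
#' @export
sir_diffusion <- function(state, params) {
  x <- as_state_vector(state)
  infest <- exp(x[["beta_log"]]) * x[["s"]] * x[["i"]]
  rem <- params[["gamma"]] * x[["i"]]
  matrix(c(infest, -infest, 0,
           -infest, infest + rem, 0,
           0, 0, params[["sigma"]]^2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("s", "i", "beta_log"), c("s", "i", "beta_log")))
}

#' Jacobian of the drift
#'
#' The matrix \eqn{H_t} with entries \eqn{\partial a_i / \partial x_j},
#' evaluated at `state`. Drives the covariance ODE of the linear noise
#' approximation.
#'
#' @inheritParams sir_drift
#' @return 3x3 numeric matrix; the third row is identically zero.
#' @export
sir_jacobian <- function(state, params) {
  x <- as_state_vector(state)
  b <- exp(x[["beta_log"]])
  s <- x[["s"]]; i <- x[["i"]]
  matrix(c(-b * i, -b * s, -b * s * i,
           b * i, b * s - params[["gamma"]], b * s * i,
           0, 0, 0),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("s", "i", "beta_log"), c("s", "i", "beta_log")))
}

#' Basic reproduction number
#'
#' Converts a log infestation rate to the basic reproduction number
#' \eqn{R_0 = \beta N / \gamma = e^{\tilde\beta} N / \gamma}: the expected
#' number of secondary infestations caused by one infested tree over its
#' infested lifetime when the population is wholly susceptible. With the
#' time-varying rate this yields a yearly reproduction number
#' \eqn{R_0(t) = \beta(t) N / \gamma}.
#'
#' @param beta_log Log infestation rate(s) \eqn{\tilde\beta} (vectorised).
#' @param gamma Removal rate, strictly positive (vectorised, recycled).
#' @param n_population Population size `N`, strictly positive.
#' @return Numeric vector of reproduction numbers.
#' @examples
#' basic_reproduction_number(-8, gamma = 1, n_population = 5e3)  # about 1.7
#' @export
basic_reproduction_number <- function(beta_log, gamma, n_population) {
  if (any(gamma <= 0)) stop("basic_reproduction_number: gamma must be > 0")
  if (any(n_population <= 0)) {
    stop("basic_reproduction_number: n_population must be > 0")
  }
  exp(beta_log) * n_population / gamma
}
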