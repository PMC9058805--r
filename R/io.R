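#' Read a yearly cumulative removal series
#'
#' Reads a CSV with header `year,cumulative_removed` into an
#' [observation_series], validating monotone unit-spaced years and count
#' bounds (errors name the offending row).
#'
#' @param path Path to the CSV file.
#' @param n_population Optional population size `N`; when supplied the filter
#'   observations `y = N - R` are attached.
#' @return An [observation_series].
#' @export
read_timeseries <- function(path, n_population = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("year", "cumulative_removed")
  if (!all(need %in% names(d))) {
    stop("read_timeseries: expected columns 'year,cumulative_removed'")
  }
  observation_series(d$year, d$cumulative_removed, n_population = n_population)
}

#' Write a yearly cumulative removal series
#'
#' @param obs An [observation_series].
#' @param path Output CSV path (header `year,cumulative_removed`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(obs, path) {
  utils::write.csv(data.frame(year = obs$year,
                              cumulative_removed = obs$r_cumulative),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic fixture to disk
#'
#' Writes the observation CSV plus a JSON truth sidecar containing the
#' generating parameters and the latent log-rate path at observation times.
#'
#' @param fixture A list from [generate_fixture].
#' @param csv_path Output CSV path.
#' @param truth_path Output JSON path (default: `csv_path` with a
#'   `.truth.json` suffix).
#' @return `csv_path`, invisibly.
#' @export
write_fixture <- function(fixture, csv_path,
                          truth_path = sub("\\.csv$", ".truth.json", csv_path)) {
  write_timeseries(fixture$obs, csv_path)
  tr <- fixture$truth
  bl <- state_at(tr, fixture$obs$t)[, "beta_log"]
  meta <- list(gamma = tr$true_params[["gamma"]],
               sigma = tr$true_params[["sigma"]],
               sigma_e = tr$true_params[["sigma_e"]],
               beta_log_path = as.numeric(bl),
               N = tr$config$n_population,
               s0 = tr$config$s0, i0 = tr$config$i0,
               seed = tr$seed)
  jsonlite::write_json(meta, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Write and read an MCMC chain
#'
#' The chain file is a CSV with columns
#' `iter,gamma,sigma,sigma_e,log_post,accepted`; a JSON sidecar records the
#' seed, configuration and priors so a run can be identified later.
#'
#' @param chain An `opm_chain`.
#' @param path Output CSV path.
#' @param meta_path JSON sidecar path (default `path` with `.meta.json`).
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path,
                        meta_path = sub("\\.csv$", ".meta.json", path)) {
  d <- data.frame(iter = seq_len(nrow(chain$draws)),
                  gamma = chain$draws[, "gamma"],
                  sigma = chain$draws[, "sigma"],
                  sigma_e = chain$draws[, "sigma_e"],
                  log_post = chain$log_post,
                  accepted = as.integer(chain$accepted))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = chain$seed,
               acceptance_rate = chain$acceptance_rate,
               config = unclass(chain$config),
               prior = unclass(chain$prior),
               control = chain$control[c("iterations", "burn_in", "thin")],
               package_version = as.character(utils::packageVersion("opmsir")))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  d <- utils::read.csv(path)
  need <- c("iter", "gamma", "sigma", "sigma_e", "log_post", "accepted")
  if (!all(need %in% names(d))) {
    stop("read_chain: unexpected chain file format")
  }
  d
}

#' Read a run configuration
#'
#' Reads a JSON run configuration with keys `data` (CSV path),
#' `n_population`, `s0`, `i0`, optional prior overrides under `prior`,
#' optional MCMC settings under `mcmc`, an optional `seed` and `output_dir`.
#' Unknown top-level keys are rejected.
#'
#' @param path Path to the JSON config.
#' @return A list with elements `data`, `config` (a [model_config]),
#'   `prior` (a [prior_spec]), `mcmc` (an [mcmc_control]), `seed`,
#'   `output_dir`.
#' @export
read_run_config <- function(path) {
  rc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("data", "n_population", "s0", "i0", "prior", "mcmc", "seed",
             "output_dir")
  extra <- setdiff(names(rc), known)
  if (length(extra)) {
    stop(sprintf("read_run_config: unknown key(s): %s",
                 paste(extra, collapse = ", ")))
  }
  for (k in c("data", "n_population", "s0", "i0")) {
    if (is.null(rc[[k]])) stop(sprintf("read_run_config: missing key '%s'", k))
  }
  prior <- do.call(prior_spec, as.list(rc$prior))
  cfg <- model_config(rc$n_population, rc$s0, rc$i0,
                      beta_log0_mean = prior$beta_log0_mean,
                      beta_log0_sd = prior$beta_log0_sd)
  mcmc <- do.call(mcmc_control, as.list(rc$mcmc))
  list(data = rc$data, config = cfg, prior = prior, mcmc = mcmc,
       seed = if (is.null(rc$seed)) NULL else as.integer(rc$seed),
       output_dir = if (is.null(rc$output_dir)) "." else rc$output_dir)
}

#' Write a predictive summary
#'
#' @param summary A `predictive_summary`.
#' @param path Output CSV path (`year,q2.5,q25,median,q75,q97.5`).
#' @return `path`, invisibly.
#' @export
write_predictive <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write yearly reproduction-number output
#'
#' @param r0 An `r0_summary`.
#' @param draws_path CSV of per-draw values (`year,draw_id,r0`).
#' @param summary_path CSV of per-year median and quartiles.
#' @return `draws_path`, invisibly.
#' @export
write_r0 <- function(r0, draws_path,
                     summary_path = sub("\\.csv$", ".summary.csv", draws_path)) {
  utils::write.csv(r0$draws, draws_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(r0$summary, summary_path, row.names = FALSE, quote = FALSE)
  invisible(draws_path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `fit`, `predict`, `r0` and
#' `report`, sharing one root seed across all stages. Intended to be called
#' from a thin `Rscript` wrapper (see `inst/scripts/opmsir-cli.R`); returns
#' the exit status instead of calling `quit()` so it can be tested in-process.
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`simulate <preset> <out.csv> [seed]` — write a fixture
#'     CSV plus truth JSON.}
#'   \item{fit}{`fit <config.json> <chain.csv>` — run the MCMC and write the
#'     chain CSV, metadata JSON and a diagnostics CSV.}
#'   \item{predict}{`predict <config.json> <chain.csv> <out_prefix>` — write
#'     within-sample, one-step and 5-year forward predictive CSVs.}
#'   \item{r0}{`r0 <config.json> <chain.csv> <out.csv>` — write per-draw and
#'     summary reproduction-number CSVs.}
#'   \item{report}{`report <chain.csv> <out.md>` — short markdown summary of
#'     posterior medians and intervals.}
#' }
#'
#' `predict` and `r0` re-run the latent-path draws from the stored chain
#' parameters, so they only need the chain CSV and the config.
#'
#' @param args Character vector of arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
opm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: opmsir-cli.R <simulate|fit|predict|r0|report> ...",
    "  simulate <bushy-like|richmond-like> <out.csv> [seed]",
    "  fit <config.json> <chain.csv>",
    "  predict <config.json> <chain.csv> <out_prefix>",
    "  r0 <config.json> <chain.csv> <out.csv>",
    "  report <chain.csv> <out.md>", sep = "\n")
  fail <- function(msg) {
    message(msg)
    invisible(1L)
  }
  if (length(args) < 1) return(fail(usage))
  cmd <- args[1]
  res <- tryCatch({
    switch(cmd,
      simulate = {
        if (length(args) < 3) stop(usage)
        seed <- if (length(args) >= 4) as.integer(args[4]) else 1L
        fx <- generate_fixture(args[2], seed = seed)
        write_fixture(fx, args[3])
        message(sprintf("wrote %s (seed %d)", args[3], seed))
      },
      fit = {
        if (length(args) < 3) stop(usage)
        rc <- read_run_config(args[2])
        obs <- read_timeseries(rc$data, n_population = rc$config$n_population)
        chain <- fit_mcmc(obs, rc$prior, rc$config, rc$mcmc, seed = rc$seed)
        write_chain(chain, args[3])
        diag <- chain_diagnostics(chain)
        utils::write.csv(diag, sub("\\.csv$", ".diagnostics.csv", args[3]),
                         row.names = FALSE, quote = FALSE)
        message(sprintf("wrote %s (acceptance rate %.2f)", args[3],
                        chain$acceptance_rate))
      },
      predict = {
        if (length(args) < 4) stop(usage)
        ch <- rebuild_chain(args[2], args[3])
        write_predictive(within_sample_predictive(ch, seed = ch$seed),
                         paste0(args[4], "_within.csv"))
        os <- one_step_ahead(ch, seed = ch$seed)
        write_predictive(os$summary, paste0(args[4], "_onestep.csv"))
        write_predictive(forward_simulate(ch, horizon_years = 5,
                                          seed = ch$seed),
                         paste0(args[4], "_forward.csv"))
        message(sprintf("wrote %s_{within,onestep,forward}.csv", args[4]))
      },
      r0 = {
        if (length(args) < 4) stop(usage)
        ch <- rebuild_chain(args[2], args[3])
        write_r0(r0_posterior(ch), args[4])
        message(sprintf("wrote %s", args[4]))
      },
      report = {
        if (length(args) < 3) stop(usage)
        d <- read_chain(args[2])
        qs <- sapply(c("gamma", "sigma", "sigma_e"), function(p)
          stats::quantile(d[[p]], c(0.025, 0.5, 0.975)))
        lines <- c("# Posterior summary", "",
                   sprintf("- retained draws: %d", nrow(d)),
                   sprintf("- acceptance rate: %.2f", mean(d$accepted)),
                   "",
                   "| parameter | 2.5% | median | 97.5% |",
                   "|---|---|---|---|",
                   sprintf("| %s | %.3g | %.3g | %.3g |",
                           c("gamma", "sigma", "sigma_e"),
                           qs[1, ], qs[2, ], qs[3, ]))
        writeLines(lines, args[3])
        message(sprintf("wrote %s", args[3]))
      },
      stop(usage))
    0L
  }, error = function(e) {
    message(sprintf("opmsir: error in '%s': %s", cmd, conditionMessage(e)))
    1L
  })
  invisible(res)
}

# Reconstruct enough of an opm_chain from a config + chain CSV to drive the
# prediction and R0 machinery: latent paths are redrawn from the stored
# parameter draws.
rebuild_chain <- function(config_path, chain_path, path_thin = 10) {
  rc <- read_run_config(config_path)
  obs <- read_timeseries(rc$data, n_population = rc$config$n_population)
  d <- read_chain(chain_path)
  chain <- structure(
    list(draws = as.matrix(d[, c("gamma", "sigma", "sigma_e")]),
         log_post = d$log_post, accepted = as.logical(d$accepted),
         acceptance_rate = mean(d$accepted), latent_paths = NULL,
         obs = obs, config = rc$config, prior = rc$prior,
         control = rc$mcmc, lna = lna_control(), seed = rc$seed),
    class = "opm_chain")
  with_seed(rc$seed, {
    chain$latent_paths <- draw_chain_paths(chain, path_thin = path_thin)
  })
  chain
}
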