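#' Parameter-recovery study
#'
#' Simulation-based check of the whole inference stack: repeatedly generate
#' a synthetic cohort from known population truths (likelihood tier), fit
#' the hierarchical model, and record whether each population-level
#' parameter's 94% HDI covers the truth. With well-calibrated inference,
#' coverage should be close to the nominal 94%.
#'
#' @param measure `"success"`, `"angular"` or `"distance"`.
#' @param n_reps number of seeded replications (default 20).
#' @param n_fish,n_sessions,trials_per_session cohort size (defaults 8, 15, 6).
#' @param truth population truth, as [default_population_truth()].
#' @param chains,tune,draws sampler configuration for the replications.
#'   Defaults are measure-specific: the success (Poisson) model is cheap but
#'   mixes slowly along its amplitude/time-constant ridge, so it gets long
#'   chains (4 x 5000 after 5000 warm-up); the trial-level models are
#'   costlier and mix well at 2 x 1000 after 1500 (angular) and 2 x 500
#'   after 800 (distance).
#' @param seed integer seed; replication r uses `seed + r`.
#' @param prob HDI mass (default 0.94).
#' @return data.frame, one row per replication x parameter: truth, HDI and
#'   coverage flag, with per-parameter coverage rates as attribute
#'   `"coverage"`.
#' @export
recovery_study <- function(measure, n_reps = 20, n_fish = 8, n_sessions = 15,
                           trials_per_session = 6,
                           truth = default_population_truth(),
                           chains = NULL, tune = NULL, draws = NULL, seed = 1,
                           prob = 0.94) {
  defaults <- switch(measure,
    success = c(chains = 4, tune = 5000, draws = 5000),
    angular = c(chains = 2, tune = 1500, draws = 1000),
    distance = c(chains = 2, tune = 800, draws = 500))
  chains <- chains %||% defaults[["chains"]]
  tune <- tune %||% defaults[["tune"]]
  draws <- draws %||% defaults[["draws"]]
  pop <- truth[[measure]]$pop
  truths <- c(A_mu = pop$A_mu, tau_mu = pop$tau_mu, mu_inf = pop$mu_inf)
  nodes <- c(A_mu = "A_pop", tau_mu = "tau_pop", mu_inf = "minf_pop")
  rows <- list()
  for (r in seq_len(n_reps)) {
    fp <- cohort_params(n_fish, truth, seed = seed + r)
    fp <- fp[fp$measure == measure, ]
    md <- draw_measures(fp, n_sessions, trials_per_session, seed = seed + 1000L + r)
    model <- build_model(md[c("fish_id", "session", "value")], measure)
    fit <- sample_posterior(model, chains = chains, tune = tune, draws = draws,
                            seed = seed + 2000L + r)
    for (p in names(truths)) {
      dr <- fit$draws[, nodes[[p]]]
      h <- hdi(dr, prob)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, measure = measure, parameter = p, truth = truths[[p]],
        median = median(dr), hdi_low = h[1], hdi_high = h[2],
        covered = truths[[p]] >= h[1] && truths[[p]] <= h[2],
        rhat_ok = fit$diagnostics$ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "coverage") <- tapply(out$covered, out$parameter, mean)
  out
}

#' Recover the learner time constant from simulated session medians
#'
#' Runs the trajectory simulator for a rotation stage, pushes the
#' trajectories through the metrics pipeline, and fits
#' `a * exp(-ses / tau) + c` to the across-fish session medians of the
#' angular error by nonlinear least squares. On a noiseless cohort the
#' medians decay from the rotation angle toward 0 with the configured time
#' constant, so the fitted `tau` recovers the truth.
#'
#' @param config [simulation_config()]; for a pure decay check use
#'   `kappa = Inf` (no aim noise) and `tau_spread = 0`.
#' @param seed integer seed.
#' @return list with `tau` (fitted), `fit` (the `nls` object), and
#'   `medians` (per-session across-fish median angular error).
#' @export
fit_session_median_decay <- function(config, seed = 1) {
  cohort <- generate_cohort(config, seed = seed, tier = "trajectory")
  keep <- cohort$samples$stage == "rotation"
  tm <- compute_trial_metrics(cohort$samples[keep, ],
                              target_radius = config$target_radius)
  sm <- summarize_sessions(tm)
  med <- tapply(sm$median_angular_error_deg, sm$session, median, na.rm = TRUE)
  ses <- as.numeric(names(med))
  df <- data.frame(ses = ses, y = as.numeric(med))
  a0 <- df$y[df$ses == 0] - min(df$y)
  # Levenberg-Marquardt: robust on (near-)zero-residual exponential decays
  fit <- minpack.lm::nlsLM(y ~ a * exp(-ses / tau) + c0, data = df,
                           start = list(a = max(a0, 1),
                                        tau = max(length(ses) / 4, 1),
                                        c0 = min(df$y)))
  list(tau = coef(fit)[["tau"]], fit = fit, medians = df)
}

#' Fit the three learning-curve models to a deposited-format dataset
#'
#' Reproduction harness for archival trial data: reads a directory of CSVs
#' in the trial dialect (raw samples or precomputed per-trial metrics; see
#' [read_trial_metrics()]), fits the hierarchical model for every requested
#' measure and stage, and returns the population-level summaries alongside
#' the fits. Point it at a local copy of a deposited dataset with
#' `options(fovadapt.deposited_data_dir = ...)`.
#'
#' @param path a CSV file or a directory containing exactly one CSV.
#' @param measures measures to fit (default all three).
#' @param stages stage labels to fit (default `"rotation"`).
#' @param chains,tune,draws,seed sampler configuration.
#' @return list with `summaries` (combined [fit_summary()] rows) and `fits`
#'   (named list of `fov_fit`).
#' @export
reproduce_deposited <- function(path, measures = c("success", "angular", "distance"),
                                stages = "rotation", chains = 4, tune = 1000,
                                draws = 1000, seed = 1) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) stop("no CSV files found in ", path)
    path <- files[1]
  }
  tm <- read_trial_metrics(path)
  fits <- list()
  summaries <- list()
  for (stage in stages) {
    for (measure in measures) {
      model <- build_model(tm, measure, stage = stage)
      fit <- sample_posterior(model, chains = chains, tune = tune,
                              draws = draws, seed = seed)
      key <- paste(measure, stage, sep = ":")
      fits[[key]] <- fit
      summaries[[key]] <- fit_summary(fit)
    }
  }
  list(summaries = do.call(rbind, summaries), fits = fits)
}
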