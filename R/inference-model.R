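# Extract one measure's modelling data from per-trial metrics (or accept a
# pre-extracted long table with columns fish_id, session, value).
extract_measure_data <- function(data, measure) {
  fam <- measure_family(measure)
  if ("value" %in% names(data)) {
    out <- data.frame(fish_id = data$fish_id, session = data$session,
                      value = data$value)
  } else if (measure == "success" && "success" %in% names(data)) {
    agg <- stats::aggregate(success ~ fish_id + session, data = data, FUN = sum)
    out <- data.frame(fish_id = agg$fish_id, session = agg$session,
                      value = agg$success)
  } else if (measure == "angular" && "angular_error_deg" %in% names(data)) {
    out <- data.frame(fish_id = data$fish_id, session = data$session,
                      value = data$angular_error_deg)
    out <- out[!is.na(out$value), ]
  } else if (measure == "distance" && "d_m" %in% names(data)) {
    out <- data.frame(fish_id = data$fish_id, session = data$session,
                      value = data$d_m)
  } else {
    stop("cannot extract measure '", measure,
         "' from the supplied data (expected trial metrics or a value column)")
  }
  if (nrow(out) == 0) stop("no data for measure '", measure, "'")
  if (measure == "success" && any(out$value < 0 | out$value != round(out$value))) {
    stop("success counts must be non-negative integers")
  }
  if (measure == "distance" && any(out$value <= 0)) {
    stop("distances must be positive")
  }
  out
}

#' Build a hierarchical learning-curve model
#'
#' Assembles the JAGS model for one measure within one stage: fish-level
#' exponential learning curves (non-centred around population-level location
#' and spread hyperparameters) feeding the measure's likelihood at the trial
#' level (success counts at the session level). Positive parameters are
#' hierarchical on the log scale; the angular measure's amplitude and
#' asymptote are Normal-hierarchical. With a single fish, or with
#' `hierarchical = FALSE`, the population priors are placed directly on the
#' fish-level parameters (a single-fish fit).
#'
#' @param data per-trial metrics from [compute_trial_metrics()] (or a long
#'   table with columns `fish_id`, `session`, `value`; success counts are
#'   aggregated per session automatically). If a `stage` column is present,
#'   rows are filtered to `stage`.
#' @param measure `"success"`, `"angular"` or `"distance"`.
#' @param stage stage label to fit (default: use all rows). Session indices
#'   are re-origined so the stage's first session is `ses = 0`.
#' @param hierarchy a [hierarchy_spec()]; default: empirical-Bayes centres
#'   from the data via [empirical_bayes_prior_centers()].
#' @param hierarchical set `FALSE` for a single-fish, non-hierarchical fit
#'   (required when the prior is meant to be exactly the population prior,
#'   e.g. conjugate checks).
#' @param flat_curve if `TRUE`, pins the amplitude to 0 so the model reduces
#'   to a constant mean (useful for degenerate checks); single-fish only.
#' @return object of class `fov_model`.
#' @export
build_model <- function(data, measure = c("success", "angular", "distance"),
                        stage = NULL, hierarchy = NULL, hierarchical = TRUE,
                        flat_curve = FALSE) {
  measure <- match.arg(measure)
  fam <- measure_family(measure)
  if (!is.null(stage) && "stage" %in% names(data)) {
    data <- data[data$stage == stage, ]
    if (nrow(data) == 0) stop("no rows for stage '", stage, "'")
  }
  md <- extract_measure_data(data, measure)
  md$session <- md$session - min(md$session)  # ses = 0 at the stage's first session
  fish_ids <- sort(unique(md$fish_id))
  n_fish <- length(fish_ids)
  if (flat_curve && (hierarchical && n_fish > 1)) {
    stop("flat_curve is supported for single-fish fits only")
  }
  if (n_fish == 1) hierarchical <- FALSE
  if (is.null(hierarchy)) {
    sm <- stats::aggregate(value ~ fish_id + session, data = md,
                           FUN = median)
    sm_in <- data.frame(fish_id = sm$fish_id, session = sm$session,
                        success_count = sm$value,
                        median_angular_error_deg = sm$value,
                        median_d_m = sm$value)
    hierarchy <- suppressWarnings(empirical_bayes_prior_centers(sm_in, measure))
    if (fam$per_trial) {
      # session medians hide trial-level dispersion; centre the spread-curve
      # priors on the within-session residual MADs instead
      med <- sm$value[match(paste(md$fish_id, md$session),
                            paste(sm$fish_id, sm$session))]
      resid <- md$value - med
      third <- quantile(md$session, c(1 / 3, 2 / 3))
      early <- mad(resid[md$session <= third[1]])
      late <- mad(resid[md$session >= third[2]])
      floor_ <- 0.1 * max(late, early, 0.25)
      hierarchy$entries$sigma_inf$center <- max(late, floor_)
      hierarchy$entries$A_sigma$center <- max(early - late, floor_)
    }
  }
  fish <- match(md$fish_id, fish_ids)
  cells <- unique(data.frame(fish = fish, ses = md$session))
  cells <- cells[order(cells$fish, cells$ses), ]
  cell <- match(paste(fish, md$session), paste(cells$fish, cells$ses))
  jdata <- list(y = md$value, cell = cell, cfish = cells$fish,
                cses = cells$ses, N = nrow(md), C = nrow(cells), F = n_fish)
  if (measure == "success") {
    # counts are already one observation per cell; index directly
    jdata$cell <- NULL
    jdata$N <- NULL
  }
  if (n_fish == 1) jdata$F <- NULL  # single-fish models have no fish loop
  structure(list(
    measure = measure, stage = stage %||% "all", family = fam,
    string = jags_model_string(measure, hierarchy, hierarchical, flat_curve),
    data = jdata, values = md, fish_ids = fish_ids, hierarchy = hierarchy,
    hierarchical = hierarchical, flat_curve = flat_curve
  ), class = "fov_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fov_model <- function(x, ...) {
  cat(sprintf("fov_model: measure=%s stage=%s fish=%d obs=%d %s\n",
              x$measure, x$stage, length(x$fish_ids),
              length(x$data$y),
              if (x$hierarchical) "hierarchical" else "single-fish"))
  invisible(x)
}

# Build the JAGS model text for a measure.
jags_model_string <- function(measure, hierarchy, hierarchical, flat_curve) {
  fam <- measure_family(measure)
  e <- hierarchy$entries
  dir_sign <- if (fam$direction > 0) "-" else ""  # A_mu = -amp when measure improves upward
  lines <- c("model {")
  # --- likelihood over fish x session cells ---
  if (measure == "success") {
    lines <- c(lines,
      "  for (c in 1:C) {",
      "    mu0[c] <- A[cfish[c]] * exp(-cses[c] / tau[cfish[c]]) + minf[cfish[c]]",
      "    mu[c] <- max(mu0[c], 0.001)",
      "    y[c] ~ dpois(mu[c])",
      "  }")
  } else if (measure == "angular") {
    lines <- c(lines,
      "  for (c in 1:C) {",
      "    ex[c] <- exp(-cses[c] / tau[cfish[c]])",
      "    mu[c] <- A[cfish[c]] * ex[c] + minf[cfish[c]]",
      "    prec[c] <- 1 / pow(Asig[cfish[c]] * ex[c] + sinf[cfish[c]], 2)",
      "  }",
      "  for (i in 1:N) { y[i] ~ dt(mu[cell[i]], prec[cell[i]], nu) }")
  } else {
    lines <- c(lines,
      "  for (c in 1:C) {",
      "    ex[c] <- exp(-cses[c] / tau[cfish[c]])",
      "    mu[c] <- A[cfish[c]] * ex[c] + minf[cfish[c]]",
      "    sg[c] <- Asig[cfish[c]] * ex[c] + sinf[cfish[c]]",
      "    rate[c] <- (mu[c] + sqrt(pow(mu[c], 2) + 4 * pow(sg[c], 2))) / (2 * pow(sg[c], 2))",
      "    shape[c] <- 1 + mu[c] * rate[c]",
      "  }",
      "  for (i in 1:N) { y[i] ~ dgamma(shape[cell[i]], rate[cell[i]]) }")
  }
  has_sigma <- fam$per_trial  # angular and distance carry a spread curve
  # --- fish-level parameters ---
  if (hierarchical) {
    # Parameterisation follows identification strength. Trial-level data
    # (angular, distance) pin every fish-level parameter, where centring
    # mixes far better under a Gibbs/slice sampler than non-centred offsets.
    # The session-level Poisson model identifies its amplitude and time
    # constant only weakly; centring them invites a sticky spurious mode at
    # amplitude ~ 0, so those two go non-centred while the well-identified
    # asymptote stays centred.
    weak_amp <- !fam$per_trial
    fish_block <- c(
      "  for (f in 1:F) {",
      if (fam$positive_mean) c(
        sprintf("    A[f] <- %samp[f]", dir_sign),
        if (weak_amp)
          "    amp[f] <- exp(log(amp_pop) + sd_amp * z_amp[f]); z_amp[f] ~ dnorm(0, 1)"
        else
          "    amp[f] ~ dlnorm(log(amp_pop), 1 / pow(sd_amp, 2))",
        "    minf[f] ~ dlnorm(log(minf_pop), 1 / pow(sd_minf, 2))"
      ) else c(
        "    A[f] ~ dnorm(A_pop, 1 / pow(sd_amp, 2))",
        "    minf[f] ~ dnorm(minf_pop, 1 / pow(sd_minf, 2))"
      ),
      if (weak_amp)
        "    tau[f] <- exp(log(tau_pop) + sd_tau * z_tau[f]); z_tau[f] ~ dnorm(0, 1)"
      else
        "    tau[f] ~ dlnorm(log(tau_pop), 1 / pow(sd_tau, 2))",
      if (has_sigma) c(
        "    Asig[f] ~ dlnorm(log(Asig_pop), 1 / pow(sd_Asig, 2))",
        "    sinf[f] ~ dlnorm(log(sinf_pop), 1 / pow(sd_sinf, 2))"
      ),
      "  }")
    pop_block <- c(
      if (fam$positive_mean) c(
        jags_prior(e$A_mu, "  amp_pop"),
        sprintf("  A_pop <- %samp_pop", dir_sign),
        jags_prior(e$mu_inf, "  minf_pop")
      ) else c(
        jags_prior(e$A_mu, "  A_pop"),
        jags_prior(e$mu_inf, "  minf_pop")
      ),
      jags_prior(e$tau_mu, "  tau_pop"),
      jags_sd_prior(e$A_mu, "  sd_amp"),
      jags_sd_prior(e$mu_inf, "  sd_minf"),
      jags_sd_prior(e$tau_mu, "  sd_tau"),
      if (has_sigma) c(
        jags_prior(e$A_sigma, "  Asig_pop"),
        jags_prior(e$sigma_inf, "  sinf_pop"),
        jags_sd_prior(e$A_sigma, "  sd_Asig"),
        jags_sd_prior(e$sigma_inf, "  sd_sinf")
      ),
      if (measure == "angular") jags_prior(e$nu, "  nu"))
    lines <- c(lines, fish_block, pop_block)
  } else {
    # single-fish: population priors directly on the fish's parameters
    fish_block <- c(
      if (flat_curve) "  A[1] <- 0"
      else if (fam$positive_mean) c(
        sprintf("  A[1] <- %samp[1]", dir_sign),
        jags_prior(e$A_mu, "  amp[1]")
      ) else jags_prior(e$A_mu, "  A[1]"),
      if (fam$positive_mean) jags_prior(e$mu_inf, "  minf[1]")
      else jags_prior(e$mu_inf, "  minf[1]"),
      if (flat_curve) "  tau[1] <- 1" else jags_prior(e$tau_mu, "  tau[1]"),
      if (has_sigma) c(
        if (flat_curve) "  Asig[1] <- 0" else jags_prior(e$A_sigma, "  Asig[1]"),
        jags_prior(e$sigma_inf, "  sinf[1]")
      ),
      if (measure == "angular") jags_prior(e$nu, "  nu"))
    lines <- c(lines, fish_block)
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Joint log density of a single-fish model at a parameter point
#'
#' For single-fish (non-hierarchical) models the joint density factorises
#' into the prior log densities of the fish's parameters plus the summed
#' measure log-likelihood of the trials; this function evaluates it in R,
#' independently of the sampler, so it can be checked term by term.
#'
#' @param model single-fish `fov_model` from
#'   `build_model(..., hierarchical = FALSE)`.
#' @param params a [learning_curve_params()] point.
#' @return scalar log density (up to no additive constant; all normalising
#'   terms are included).
#' @export
model_log_density <- function(model, params) {
  if (model$hierarchical) {
    stop("model_log_density supports single-fish (non-hierarchical) models")
  }
  fam <- model$family
  e <- model$hierarchy$entries
  lp <- 0
  if (!model$flat_curve) {
    amp <- if (fam$positive_mean) -fam$direction * params$A_mu else params$A_mu
    lp <- lp + prior_logdens(e$A_mu, amp) + prior_logdens(e$tau_mu, params$tau_mu)
  }
  lp <- lp + prior_logdens(e$mu_inf, params$mu_inf)
  if (fam$per_trial) {
    if (!model$flat_curve) lp <- lp + prior_logdens(e$A_sigma, params$A_sigma)
    lp <- lp + prior_logdens(e$sigma_inf, params$sigma_inf)
  }
  if (model$measure == "angular") lp <- lp + prior_logdens(e$nu, params$nu)
  ses <- if (model$measure == "success") model$data$cses else
    model$data$cses[model$data$cell]
  lp + sum(measure_loglik(model$measure, model$data$y, params, ses))
}
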