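# parameter names monitored for a model
model_monitors <- function(model) {
  fam <- model$family
  base <- c("A", "tau", "minf")
  if (fam$per_trial) base <- c(base, "Asig", "sinf")
  if (model$measure == "angular") base <- c(base, "nu")
  if (model$hierarchical) {
    pop <- c("A_pop", "tau_pop", "minf_pop", "sd_amp", "sd_tau", "sd_minf")
    if (fam$per_trial) pop <- c(pop, "Asig_pop", "sinf_pop", "sd_Asig", "sd_sinf")
    base <- c(base, pop)
  }
  base
}

#' Draw posterior samples for a learning-curve model
#'
#' Runs JAGS on a model built by [build_model()]: `tune` warm-up iterations
#' (split between sampler adaptation and burn-in) followed by `draws`
#' retained iterations on each of `chains` chains. The default configuration
#' (4 chains, 1000 tune, 1000 draws: 8000 retained samples) matches the
#' study's sampling scheme. Chains are seeded deterministically from `seed`,
#' so the same call reproduces the same draws.
#'
#' Diagnostics attached to the fit: split-R-hat and effective sample size for
#' every monitored parameter. The fit is flagged (`diagnostics$ok = FALSE`)
#' when any split-R-hat exceeds `rhat_threshold`. Divergence counts are an
#' HMC concept and are reported as `NA` under the Gibbs/slice backend.
#'
#' @param model `fov_model`.
#' @param chains,tune,draws sampler configuration (defaults 4 / 1000 / 1000).
#' @param seed integer seed; all chain RNGs derive from it.
#' @param rhat_threshold split-R-hat flag level (default 1.01).
#' @param quiet suppress JAGS progress output (default TRUE).
#' @return object of class `fov_fit`: posterior draws (`$samples` as a coda
#'   `mcmc.list`, `$draws` as a flat matrix), per-draw derived parameters
#'   (`$derived$pop` and `$derived$fish`), diagnostics, and the sampler
#'   configuration.
#' @export
sample_posterior <- function(model, chains = 4, tune = 1000, draws = 1000,
                             seed = 1, rhat_threshold = 1.01, quiet = TRUE) {
  stopifnot(inherits(model, "fov_model"), chains >= 1, tune >= 2, draws >= 1)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  n_adapt <- ceiling(tune / 2)
  jm <- rjags::jags.model(textConnection(model$string), data = model$data,
                          inits = inits, n.chains = chains, n.adapt = n_adapt,
                          quiet = quiet)
  update(jm, tune - n_adapt, progress.bar = "none")
  samples <- rjags::coda.samples(jm, model_monitors(model), n.iter = draws,
                                 progress.bar = "none")
  mat <- as.matrix(samples)
  n_fish <- length(model$fish_ids)
  col <- function(nm) if (nm %in% colnames(mat)) mat[, nm] else NULL
  fish_par <- function(nm) {
    # JAGS names length-1 monitored arrays without the [1] suffix
    if (n_fish == 1 && nm %in% colnames(mat)) return(mat[, nm])
    sapply(seq_len(n_fish), function(f) mat[, sprintf("%s[%d]", nm, f)])
  }
  A <- fish_par("A"); tau <- fish_par("tau"); minf <- fish_par("minf")
  if (is.null(dim(A))) { A <- cbind(A); tau <- cbind(tau); minf <- cbind(minf) }
  has_sigma <- model$family$per_trial
  Asig <- if (has_sigma) fish_par("Asig") else NULL
  sinf <- if (has_sigma) fish_par("sinf") else NULL
  if (has_sigma && is.null(dim(Asig))) { Asig <- cbind(Asig); sinf <- cbind(sinf) }
  fish_derived <- list(
    initial_value = A + minf,
    asymptotic_performance = minf,
    initial_learning_rate = -A / tau)
  if (model$hierarchical) {
    A_pop <- col("A_pop"); tau_pop <- col("tau_pop"); minf_pop <- col("minf_pop")
  } else {
    A_pop <- A[, 1]; tau_pop <- tau[, 1]; minf_pop <- minf[, 1]
  }
  pop_derived <- data.frame(
    initial_value = A_pop + minf_pop,
    asymptotic_performance = minf_pop,
    initial_learning_rate = -A_pop / tau_pop)
  rhat <- split_rhat(samples)
  ess <- coda::effectiveSize(samples)
  diagnostics <- list(rhat = rhat, ess = ess, divergences = NA_integer_,
                      rhat_threshold = rhat_threshold,
                      ok = all(rhat < rhat_threshold, na.rm = TRUE))
  structure(list(
    measure = model$measure, stage = model$stage, fish_ids = model$fish_ids,
    samples = samples, draws = mat,
    pop = data.frame(A_mu = A_pop, tau_mu = tau_pop, mu_inf = minf_pop),
    fish = list(A_mu = A, tau_mu = tau, mu_inf = minf,
                A_sigma = Asig, sigma_inf = sinf),
    derived = list(pop = pop_derived, fish = fish_derived),
    diagnostics = diagnostics,
    config = list(chains = chains, tune = tune, draws = draws, seed = seed),
    id = paste(model$measure, model$stage, seed, n_fish, sep = ":")
  ), class = "fov_fit")
}

#' @export
print.fov_fit <- function(x, ...) {
  cat(sprintf("fov_fit: %s / %s, %d fish, %d draws (%d chains)\n",
              x$measure, x$stage, length(x$fish_ids), nrow(x$draws),
              x$config$chains))
  s <- fit_summary(x)
  print(s[s$level == "population", c("parameter", "median", "hdi_low", "hdi_high")],
        row.names = FALSE)
  if (!x$diagnostics$ok) {
    cat(sprintf("WARNING: max split-R-hat %.3f exceeds %.2f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                x$diagnostics$rhat_threshold))
  }
  invisible(x)
}

#' Summarise a fit's derived parameters
#'
#' Medians and 94% HDIs of the initial value, asymptotic performance and
#' initial learning rate, for the population and for each fish.
#'
#' @param fit `fov_fit`.
#' @param prob HDI probability mass (default 0.94).
#' @return data.frame with columns `measure, stage, level, fish_id,
#'   parameter, median, hdi_low, hdi_high`.
#' @export
fit_summary <- function(fit, prob = 0.94) {
  pars <- c("initial_value", "asymptotic_performance", "initial_learning_rate")
  rows <- list()
  for (p in pars) {
    d <- fit$derived$pop[[p]]
    h <- hdi(d, prob)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = fit$measure, stage = fit$stage, level = "population",
      fish_id = NA_character_, parameter = p, median = median(d),
      hdi_low = h[1], hdi_high = h[2], stringsAsFactors = FALSE)
    for (f in seq_along(fit$fish_ids)) {
      df <- fit$derived$fish[[p]][, f]
      hf <- hdi(df, prob)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = fit$measure, stage = fit$stage, level = "fish",
        fish_id = as.character(fit$fish_ids[f]), parameter = p,
        median = median(df), hdi_low = hf[1], hdi_high = hf[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split-R-hat convergence diagnostic
#'
#' Rank-free split-R-hat: each chain is split in half and the classical
#' Gelman-Rubin potential scale reduction factor is computed over the split
#' chains, for every monitored parameter.
#'
#' @param samples a coda `mcmc.list`.
#' @return named numeric vector of R-hat values.
#' @export
split_rhat <- function(samples) {
  chains <- lapply(samples, as.matrix)
  half <- floor(nrow(chains[[1]]) / 2)
  splits <- list()
  for (ch in chains) {
    splits[[length(splits) + 1L]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1L]] <- ch[half + seq_len(half), , drop = FALSE]
  }
  m <- length(splits)
  n <- half
  out <- sapply(colnames(chains[[1]]), function(p) {
    x <- sapply(splits, function(s) s[, p])
    means <- colMeans(x)
    vars <- apply(x, 2, stats::var)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  names(out) <- colnames(chains[[1]])
  out
}

# random draws from a measure's likelihood at given curve mean/sd
rmeasure <- function(measure, n, mu, sg = NULL, nu = NULL) {
  switch(measure,
    success = rpois(n, pmax(mu, 1e-3)),
    angular = mu + sg * rt(n, df = nu),
    distance = {
      sr <- gamma_mode_sd_to_shape_rate(pmax(mu, 1e-6), sg)
      rgamma(n, shape = sr$shape, rate = sr$rate)
    })
}

# draw one cohort's parameter set from the hierarchy's priors (R-side mirror
# of the JAGS prior structure)
draw_params_from_prior <- function(model) {
  e <- model$hierarchy$entries
  fam <- model$family
  n_fish <- length(model$fish_ids)
  pos <- function(entry, pop, sd_f) exp(log(pop) + sd_f * rnorm(n_fish))
  if (model$hierarchical) {
    amp_pop <- prior_draw(e$A_mu); minf_pop <- prior_draw(e$mu_inf)
    tau_pop <- prior_draw(e$tau_mu)
    sd_amp <- rgamma_sd_prior(e$A_mu)
    sd_minf <- rgamma_sd_prior(e$mu_inf)
    sd_tau <- rgamma_sd_prior(e$tau_mu)
    if (fam$positive_mean) {
      amp <- pos(e$A_mu, amp_pop, sd_amp)
      minf <- pos(e$mu_inf, minf_pop, sd_minf)
      A <- -fam$direction * amp
    } else {
      A <- amp_pop + sd_amp * rnorm(n_fish)
      minf <- minf_pop + sd_minf * rnorm(n_fish)
    }
    tau <- pos(e$tau_mu, tau_pop, sd_tau)
    if (fam$per_trial) {
      Asig_pop <- prior_draw(e$A_sigma); sinf_pop <- prior_draw(e$sigma_inf)
      Asig <- pos(e$A_sigma, Asig_pop, rgamma_sd_prior(e$A_sigma))
      sinf <- pos(e$sigma_inf, sinf_pop, rgamma_sd_prior(e$sigma_inf))
    } else {
      Asig <- rep(0, n_fish); sinf <- rep(1, n_fish)
    }
  } else {
    amp <- if (model$flat_curve) 0 else prior_draw(e$A_mu)
    A <- if (fam$positive_mean) -fam$direction * amp else amp
    tau <- if (model$flat_curve) 1 else prior_draw(e$tau_mu)
    minf <- prior_draw(e$mu_inf)
    Asig <- if (fam$per_trial && !model$flat_curve) prior_draw(e$A_sigma) else 0
    sinf <- if (fam$per_trial) prior_draw(e$sigma_inf) else 1
  }
  nu <- if (model$measure == "angular") prior_draw(e$nu) else 30
  list(A = A, tau = tau, minf = minf, Asig = Asig, sinf = sinf, nu = nu)
}

#' Prior predictive simulation
#'
#' Draws parameter sets from the model's priors and simulates full datasets
#' at the observed fish-session layout, to check that the priors generate all
#' plausible data and exclude pathological data before any fitting.
#'
#' @param model `fov_model`.
#' @param n_draws number of prior datasets (default 200).
#' @param seed integer seed.
#' @param bounds optional length-2 numeric: plausibility bounds on the data;
#'   the summary reports the fraction of simulated values inside them.
#' @return list with `datasets` (list of data.frames `fish, ses, value`) and
#'   `summary` (quantiles of simulated values, fraction inside `bounds`).
#' @export
prior_predictive <- function(model, n_draws = 200, seed = 1, bounds = NULL) {
  set.seed(seed)
  ses_of <- if (model$measure == "success") model$data$cses else
    model$data$cses[model$data$cell]
  fish_of <- if (model$measure == "success") model$data$cfish else
    model$data$cfish[model$data$cell]
  datasets <- lapply(seq_len(n_draws), function(i) {
    p <- draw_params_from_prior(model)
    mu <- p$A[fish_of] * exp(-ses_of / p$tau[fish_of]) + p$minf[fish_of]
    sg <- p$Asig[fish_of] * exp(-ses_of / p$tau[fish_of]) + p$sinf[fish_of]
    value <- rmeasure(model$measure, length(ses_of), mu, sg, p$nu)
    data.frame(fish = fish_of, ses = ses_of, value = value)
  })
  all_values <- unlist(lapply(datasets, `[[`, "value"))
  summary <- list(quantiles = quantile(all_values, c(0, .01, .25, .5, .75, .99, 1)))
  if (!is.null(bounds)) {
    summary$fraction_in_bounds <- mean(all_values >= bounds[1] & all_values <= bounds[2])
  }
  list(datasets = datasets, summary = summary)
}

#' Posterior predictive check
#'
#' Replicates the dataset under draws from the fitted posterior and compares
#' observed session medians with the replicated predictive distribution: for
#' each fish-session cell, the observed median is checked against the
#' central `prob` interval of the replicated medians.
#'
#' @param fit `fov_fit`.
#' @param model the `fov_model` the fit came from.
#' @param seed integer seed.
#' @param n_rep number of replicated datasets (default 200).
#' @param prob predictive interval mass (default 0.94).
#' @return list with `coverage` (fraction of cells whose observed median is
#'   inside its predictive interval), `cells` (per-cell data.frame), and
#'   `n_rep`.
#' @export
posterior_predictive <- function(fit, model, seed = 1, n_rep = 200, prob = 0.94) {
  set.seed(seed)
  idx <- round(seq(1, nrow(fit$draws), length.out = n_rep))
  C <- model$data$C
  cfish <- model$data$cfish; cses <- model$data$cses
  obs <- numeric(C)
  n_per_cell <- integer(C)
  if (model$measure == "success") {
    obs <- model$data$y
    n_per_cell[] <- 1L
  } else {
    for (c_ in seq_len(C)) {
      yc <- model$data$y[model$data$cell == c_]
      obs[c_] <- median(yc)
      n_per_cell[c_] <- length(yc)
    }
  }
  nu_draws <- if ("nu" %in% colnames(fit$draws)) fit$draws[, "nu"] else rep(30, nrow(fit$draws))
  rep_med <- matrix(NA_real_, n_rep, C)
  for (r in seq_along(idx)) {
    i <- idx[r]
    A <- fit$fish$A_mu[i, ]; tau <- fit$fish$tau_mu[i, ]; minf <- fit$fish$mu_inf[i, ]
    Asig <- if (is.null(fit$fish$A_sigma)) rep(0, length(fit$fish_ids)) else
      fit$fish$A_sigma[i, ]
    sinf <- if (is.null(fit$fish$sigma_inf)) rep(1, length(fit$fish_ids)) else
      fit$fish$sigma_inf[i, ]
    ex <- exp(-cses / tau[cfish])
    mu <- A[cfish] * ex + minf[cfish]
    sg <- Asig[cfish] * ex + sinf[cfish]
    for (c_ in seq_len(C)) {
      vals <- rmeasure(model$measure, n_per_cell[c_], mu[c_], sg[c_], nu_draws[i])
      rep_med[r, c_] <- median(vals)
    }
  }
  lo <- apply(rep_med, 2, quantile, probs = (1 - prob) / 2)
  hi <- apply(rep_med, 2, quantile, probs = 1 - (1 - prob) / 2)
  inside <- obs >= lo & obs <= hi
  list(coverage = mean(inside),
       cells = data.frame(fish = cfish, ses = cses, observed = obs,
                          pred_low = lo, pred_high = hi, inside = inside),
       n_rep = n_rep)
}
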