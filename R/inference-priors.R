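#' Empirical-Bayes prior centres from session summaries
#'
#' Prior centres are set to the most reasonable values that can be read off
#' coarse data summaries, then given deliberately broad widths: the asymptote
#' centre is the median of the last third of sessions, the amplitude centre
#' is the first-third median minus the asymptote centre, and the time
#' constant centre is one third of the stage length. Spread-curve centres use
#' the median absolute deviation of the early and late session values. With
#' fewer than 3 sessions, fixed per-measure defaults are used with a warning.
#'
#' @param session_metrics output of [summarize_sessions()] for one stage
#'   (all fish pooled).
#' @param measure `"success"`, `"angular"` or `"distance"`.
#' @return a `hierarchy_spec` object; see [hierarchy_spec()].
#' @export
empirical_bayes_prior_centers <- function(session_metrics,
                                          measure = c("success", "angular", "distance")) {
  measure <- match.arg(measure)
  fam <- measure_family(measure)
  values <- switch(measure,
    success = session_metrics$success_count,
    angular = session_metrics$median_angular_error_deg,
    distance = session_metrics$median_d_m)
  ses <- session_metrics$session
  ok <- !is.na(values)
  values <- values[ok]; ses <- ses[ok]
  n_ses <- length(unique(ses))
  if (n_ses < 3) {
    warning("fewer than 3 sessions; using fixed default prior centres")
    return(default_hierarchy_spec(measure))
  }
  s_len <- diff(range(ses)) + 1
  lo <- ses <= quantile(ses, 1 / 3)
  hi <- ses >= quantile(ses, 2 / 3)
  scale <- max(mad(values), sd(values) / 2, 0.25)
  mu_inf_c <- median(values[hi])
  # anchor the amplitude on the stage's first session: with short time
  # constants the curve has already decayed within the first third
  A_c <- median(values[ses == min(ses)]) - mu_inf_c
  tau_c <- max(s_len / 3, 1)
  sinf_c <- max(mad(values[hi]), 0.25 * scale)
  Asig_c <- max(mad(values[lo]) - sinf_c, 0.25 * scale)
  if (fam$positive_mean) {
    # Amplitude magnitude with a fixed improvement direction. The centre is
    # floored at the data scale: the first-vs-last contrast is a noisy guess,
    # and a Gamma prior whose rate is tied to a near-zero contrast would
    # actively exclude real amplitudes (the width must stay broad even when
    # the guess collapses).
    A_c <- max(abs(A_c), scale)
    mu_inf_c <- max(mu_inf_c, 0.25 * scale)
  }
  hierarchy_spec(measure,
                 A_mu = A_c, tau_mu = tau_c, mu_inf = mu_inf_c,
                 A_sigma = Asig_c, sigma_inf = sinf_c,
                 width_scale = scale)
}

default_hierarchy_spec <- function(measure) {
  switch(measure,
    success = hierarchy_spec("success", A_mu = 1.5, tau_mu = 5, mu_inf = 3,
                             A_sigma = 1, sigma_inf = 1, width_scale = 1),
    angular = hierarchy_spec("angular", A_mu = 10, tau_mu = 5, mu_inf = 0,
                             A_sigma = 10, sigma_inf = 8, width_scale = 10),
    distance = hierarchy_spec("distance", A_mu = 2, tau_mu = 5, mu_inf = 3.5,
                              A_sigma = 1.5, sigma_inf = 1, width_scale = 1))
}

#' Hierarchical prior specification for one measure
#'
#' Encodes one prior entry per learning-curve parameter, following the
#' family rules: positive parameters (`tau_mu`, `A_sigma`, `sigma_inf`, and
#' the amplitude magnitude and asymptote of the positive-mean measures) get
#' Gamma priors with shape 2 and the stated mean; continuous parameters (the
#' angular measure's `A_mu` and `mu_inf`) get Normal priors; the Student-t
#' degrees of freedom get an Exponential prior with mean 30. Fish-level
#' spreads get Gamma(2, ...) priors centred on `fish_sd` (log-scale spread
#' 0.3 for positive parameters).
#'
#' @param measure measure name.
#' @param A_mu,tau_mu,mu_inf,A_sigma,sigma_inf prior centres. For
#'   positive-mean measures `A_mu` is the centre of the amplitude
#'   *magnitude*; the improvement direction of the measure fixes its sign.
#' @param width_scale data scale used to set Normal prior widths
#'   (`2 * max(|centre|, width_scale)`) and fish-level spread centres.
#' @param nu_mean mean of the Exponential prior on `nu` (default 30).
#' @return object of class `hierarchy_spec`: a named list of prior entries
#'   `list(family, center, width, fish_sd)`.
#' @export
hierarchy_spec <- function(measure, A_mu, tau_mu, mu_inf, A_sigma = 1,
                           sigma_inf = 1, width_scale = 1, nu_mean = 30) {
  fam <- measure_family(measure)
  stopifnot(tau_mu > 0, A_sigma > 0, sigma_inf > 0, width_scale > 0)
  norm_entry <- function(center) {
    list(family = "normal", center = center,
         width = 2 * max(abs(center), width_scale), fish_sd = width_scale)
  }
  gamma_entry <- function(center, shape = 2) {
    stopifnot(center > 0)
    list(family = "gamma", center = center, width = NA_real_, fish_sd = 0.3,
         shape = shape)
  }
  # curve parameters get deliberately flatter Gamma priors (shape 1.2-1.5)
  # than the dispersion parameters: their EB centres are the crudest guesses,
  # and the amplitude/time-constant pair is weakly identified, so prior pull
  # translates directly into attenuation
  entries <- list(tau_mu = gamma_entry(tau_mu, 1.2),
                  A_sigma = gamma_entry(A_sigma),
                  sigma_inf = gamma_entry(sigma_inf),
                  nu = list(family = "exponential", center = nu_mean,
                            width = NA_real_, fish_sd = NA_real_))
  if (fam$positive_mean) {
    entries$A_mu <- gamma_entry(A_mu, 1.2)
    entries$mu_inf <- gamma_entry(mu_inf, 1.5)
  } else {
    entries$A_mu <- norm_entry(A_mu)
    entries$mu_inf <- norm_entry(mu_inf)
  }
  structure(list(measure = measure, entries = entries), class = "hierarchy_spec")
}

# log prior density of one population-level parameter value under its entry
prior_logdens <- function(entry, x) {
  switch(entry$family,
    gamma = {
      k <- entry$shape %||% 2
      dgamma(x, shape = k, rate = k / entry$center, log = TRUE)
    },
    normal = dnorm(x, entry$center, entry$width, log = TRUE),
    exponential = dexp(x, rate = 1 / entry$center, log = TRUE))
}

# one random draw from a population-level prior entry
prior_draw <- function(entry, n = 1) {
  switch(entry$family,
    gamma = {
      k <- entry$shape %||% 2
      rgamma(n, shape = k, rate = k / entry$center)
    },
    normal = rnorm(n, entry$center, entry$width),
    exponential = rexp(n, rate = 1 / entry$center))
}

# JAGS prior snippet for a population node
jags_prior <- function(entry, node) {
  switch(entry$family,
    gamma = sprintf("%s ~ dgamma(%.10g, %.10g)", node,
                    entry$shape %||% 2, (entry$shape %||% 2) / entry$center),
    normal = sprintf("%s ~ dnorm(%.10g, %.10g)", node, entry$center,
                     1 / entry$width^2),
    exponential = sprintf("%s ~ dexp(%.10g)", node, 1 / entry$center))
}

# Fish-level spread hyperprior: Gamma(3, 3/centre). With cohorts of only a
# handful of animals, a spread prior with substantial mass near zero lets the
# population interval collapse onto the realised cohort; shape 3 keeps the
# spread bounded away from zero while staying broad on the right.
jags_sd_prior <- function(entry, node) {
  sprintf("%s ~ dgamma(3, %.10g)", node, 3 / entry$fish_sd)
}

rgamma_sd_prior <- function(entry, n = 1) rgamma(n, 3, 3 / entry$fish_sd)
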