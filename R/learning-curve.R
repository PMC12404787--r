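#' Measure families
#'
#' The three performance measures are modelled with likelihoods matched to
#' their data type: session success counts with a Poisson, trial-level signed
#' angular errors with a Student-t (location `mu`, scale `sigma`, shared
#' degrees of freedom `nu`), and trial-level adjusted distances with a Gamma
#' parameterised by its mode and standard deviation. Each measure also
#' carries an improvement direction: success grows with learning
#' (`direction = +1` means the curve amplitude is negative), while angular
#' error magnitude and distance shrink (`direction = -1`).
#'
#' @param measure one of `"success"`, `"angular"`, `"distance"`.
#' @return list with `measure`, `family`, `positive_mean` (must the mean
#'   curve stay positive?), `per_trial` (trial-level data, vs one count per
#'   session), and `direction` (+1 if learning increases the measure).
#' @export
measure_family <- function(measure = c("success", "angular", "distance")) {
  measure <- match.arg(measure)
  switch(measure,
    success = list(measure = "success", family = "poisson",
                   positive_mean = TRUE, per_trial = FALSE, direction = +1),
    angular = list(measure = "angular", family = "student_t",
                   positive_mean = FALSE, per_trial = TRUE, direction = -1),
    distance = list(measure = "distance", family = "gamma",
                    positive_mean = TRUE, per_trial = TRUE, direction = -1)
  )
}

#' Exponential learning-curve parameters
#'
#' Bundle of the parameters describing one fish's learning curve for one
#' measure within one stage. The expected session-`ses` performance is
#' `A_mu * exp(-ses / tau_mu) + mu_inf`, and the spread of the data around it
#' is `A_sigma * exp(-ses / tau_mu) + sigma_inf` (the two curves share the
#' time constant). `ses = 0` is the first session of the stage.
#'
#' @param A_mu curve amplitude, in measure units. Negative for measures that
#'   improve upward (success).
#' @param tau_mu time constant in sessions (> 0).
#' @param mu_inf asymptote, measure units.
#' @param A_sigma spread-curve amplitude (>= 0), measure units.
#' @param sigma_inf asymptotic spread (> 0), measure units.
#' @param nu Student-t degrees of freedom (> 0); only used by the angular
#'   measure, shared across all fish.
#' @param tau_sigma optional separate time constant for the spread curve;
#'   `NULL` (the default, and the form the model is usually written in)
#'   shares `tau_mu`.
#' @return object of class `learning_curve_params`.
#' @export
learning_curve_params <- function(A_mu, tau_mu, mu_inf, A_sigma = 0,
                                  sigma_inf = 1, nu = 30, tau_sigma = NULL) {
  stopifnot(tau_mu > 0, A_sigma >= 0, sigma_inf > 0, nu > 0,
            is.null(tau_sigma) || tau_sigma > 0)
  structure(list(A_mu = A_mu, tau_mu = tau_mu, mu_inf = mu_inf,
                 A_sigma = A_sigma, sigma_inf = sigma_inf, nu = nu,
                 tau_sigma = tau_sigma),
            class = "learning_curve_params")
}

#' @export
print.learning_curve_params <- function(x, ...) {
  cat(sprintf(
    "learning curve: mu(ses) = %.3g exp(-ses/%.3g) + %.3g; sigma(ses) = %.3g exp(-ses/%.3g) + %.3g; nu = %.3g\n",
    x$A_mu, x$tau_mu, x$mu_inf, x$A_sigma, x$tau_mu, x$sigma_inf, x$nu))
  invisible(x)
}

#' Mean learning curve
#'
#' @param params [learning_curve_params()].
#' @param ses session index (>= 0; 0 is the stage's first session). Vectorised.
#' @return `A_mu * exp(-ses / tau_mu) + mu_inf`.
#' @export
curve_mean <- function(params, ses) {
  stopifnot(params$tau_mu > 0, all(ses >= 0))
  params$A_mu * exp(-ses / params$tau_mu) + params$mu_inf
}

#' Spread learning curve
#'
#' The session-dependent dispersion; shares `tau_mu` with the mean curve
#' unless a separate `tau_sigma` was supplied.
#'
#' @inheritParams curve_mean
#' @return `A_sigma * exp(-ses / tau_mu) + sigma_inf`; an error if any value
#'   is non-positive.
#' @export
curve_sd <- function(params, ses) {
  stopifnot(params$tau_mu > 0, all(ses >= 0))
  tau_s <- if (is.null(params$tau_sigma)) params$tau_mu else params$tau_sigma
  out <- params$A_sigma * exp(-ses / tau_s) + params$sigma_inf
  if (any(out <= 0)) stop("spread curve must stay positive")
  out
}

#' Convert a (mode, sd) Gamma parameterisation to (shape, rate)
#'
#' The distance likelihood is a Gamma distribution specified by its mode and
#' standard deviation. Solving `mode = (shape - 1) / rate` and
#' `sd^2 = shape / rate^2` gives
#' `rate = (mode + sqrt(mode^2 + 4 sd^2)) / (2 sd^2)` and
#' `shape = 1 + mode * rate`, so `shape > 1` always (the density is
#' unimodal with an interior mode).
#'
#' @param mode distribution mode (> 0). Vectorised.
#' @param sd standard deviation (> 0). Vectorised.
#' @return list with numeric `shape` and `rate`.
#' @export
gamma_mode_sd_to_shape_rate <- function(mode, sd) {
  stopifnot(all(mode > 0), all(sd > 0))
  rate <- (mode + sqrt(mode^2 + 4 * sd^2)) / (2 * sd^2)
  list(shape = 1 + mode * rate, rate = rate)
}

#' Log-likelihood of one datum under a measure's likelihood
#'
#' Evaluates the measure-specific log density at session `ses` of the
#' learning curve: Poisson(`curve_mean`) for success counts, Student-t
#' (location `curve_mean`, scale `curve_sd`, df `nu`) for angular errors,
#' Gamma(mode `curve_mean`, sd `curve_sd`) for distances. The Student-t
#' "std" is interpreted as the scale parameter, not the standard deviation.
#'
#' @param measure `"success"`, `"angular"` or `"distance"`.
#' @param y observed value(s): non-negative integer counts, real degrees, or
#'   positive meters.
#' @param params [learning_curve_params()].
#' @param ses session index (vectorised with `y`).
#' @return log-density; `-Inf` with a warning for data outside the support.
#' @export
measure_loglik <- function(measure, y, params, ses) {
  fam <- measure_family(measure)
  mu <- curve_mean(params, ses)
  out <- switch(fam$family,
    poisson = {
      bad <- y < 0 | y != round(y)
      if (any(bad)) warning("counts must be non-negative integers; returning -Inf")
      if (any(mu <= 0)) stop("Poisson mean curve must stay positive over the fitted sessions")
      ll <- dpois(ifelse(bad, 0, y), mu, log = TRUE)
      ll[bad] <- -Inf
      ll
    },
    student_t = {
      sg <- curve_sd(params, ses)
      dt((y - mu) / sg, df = params$nu, log = TRUE) - log(sg)
    },
    gamma = {
      if (any(mu <= 0)) stop("Gamma mode curve must stay positive over the fitted sessions")
      sg <- curve_sd(params, ses)
      sr <- gamma_mode_sd_to_shape_rate(mu, sg)
      bad <- y <= 0
      if (any(bad)) warning("distances must be positive; returning -Inf")
      ll <- dgamma(ifelse(bad, 1, y), shape = sr$shape, rate = sr$rate, log = TRUE)
      ll[bad] <- -Inf
      ll
    })
  out
}

#' Derived learning parameters
#'
#' Three scalars characterise a fitted curve: the initial value
#' `A_mu + mu_inf` (the curve at `ses = 0`), the asymptotic performance
#' `mu_inf`, and the initial learning rate `-A_mu / tau_mu` (the derivative
#' of the mean curve at `ses = 0`). Positive learning rates indicate
#' improvement for success; negative rates indicate improvement for angular
#' error and distance.
#'
#' @param A_mu,tau_mu,mu_inf curve parameters, or a
#'   [learning_curve_params()] object as the first argument. Vectorised, so
#'   posterior draws can be transformed per draw.
#' @return list with `initial_value`, `asymptotic_performance`,
#'   `initial_learning_rate`.
#' @export
derived_parameters <- function(A_mu, tau_mu = NULL, mu_inf = NULL) {
  if (inherits(A_mu, "learning_curve_params")) {
    p <- A_mu
    A_mu <- p$A_mu; tau_mu <- p$tau_mu; mu_inf <- p$mu_inf
  }
  stopifnot(all(tau_mu > 0))
  list(initial_value = A_mu + mu_inf,
       asymptotic_performance = mu_inf,
       initial_learning_rate = -A_mu / tau_mu)
}
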