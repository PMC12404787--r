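#' Highest density interval
#'
#' Shortest contiguous interval containing at least `prob` of the draws: the
#' draws are sorted and every window of `ceiling(prob * n)` consecutive
#' values is considered; the leftmost shortest window wins ties. A warning
#' flags possible multimodality when the empirical histogram inside the
#' interval has a pronounced interior trough.
#'
#' @param draws numeric vector of posterior draws (>= 100 recommended).
#' @param prob probability mass (default 0.94).
#' @return numeric length-2 vector `c(low, high)`.
#' @examples
#' hdi(rnorm(1e4))  # close to c(-1.88, 1.88)
#' @export
hdi <- function(draws, prob = 0.94) {
  stopifnot(is.numeric(draws), length(draws) >= 2, prob > 0, prob <= 1)
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)  # which.min takes the leftmost minimum
  out <- c(s[i], s[i + m - 1])
  # multimodality heuristic: deep interior dip in the histogram of the draws
  if (n >= 500 && out[2] > out[1]) {
    h <- graphics::hist(draws[draws >= out[1] & draws <= out[2]],
                        breaks = 20, plot = FALSE)$counts
    k <- length(h)
    if (k >= 9) {
      edge <- min(mean(h[1:3]), mean(h[(k - 2):k]))
      interior <- min(h[4:(k - 3)])
      if (edge > 0 && interior < 0.25 * edge) {
        warning("draws look multimodal; a contiguous HDI may be misleading")
      }
    }
  }
  out
}

#' Region of practical equivalence for a measure
#'
#' Stage differences smaller than these half-widths are treated as
#' practically zero: 1 success/session, 5 degrees of angular error, 2 m of
#' distance.
#'
#' @param measure `"success"`, `"angular"` or `"distance"`, or a numeric
#'   half-width to override.
#' @return numeric length-2 interval `c(-hw, +hw)`.
#' @export
rope_spec <- function(measure) {
  hw <- if (is.numeric(measure)) measure else
    switch(match.arg(measure, c("success", "angular", "distance")),
           success = 1, angular = 5, distance = 2)
  c(-hw, hw)
}

#' Fraction of draws inside a ROPE
#'
#' @param difference_draws numeric vector of paired posterior differences.
#' @param rope length-2 interval (closed), e.g. from [rope_spec()].
#' @return fraction in `[0, 1]`.
#' @export
rope_overlap <- function(difference_draws, rope) {
  stopifnot(length(rope) == 2, rope[1] <= rope[2])
  mean(difference_draws >= rope[1] & difference_draws <= rope[2])
}

# deterministic permutation derived from a seed and a fit identity, so that
# pairing of independent posteriors is reproducible and symmetric in the
# arguments (swapping fits exactly negates the differences)
fit_permutation <- function(n, seed, id) {
  key <- sum(utf8ToInt(id)) %% 10000L
  rs <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()),
          add = TRUE)
  set.seed((abs(seed) %% 100000L) * 10000L + key)
  sample.int(n)
}

#' Compare a derived parameter between two stage fits
#'
#' Forms per-draw differences `fit_b - fit_a` of a derived population
#' parameter, after a seed-stable permutation of each fit's draws (the two
#' posteriors are independent, so the pairing is arbitrary; a deterministic
#' permutation avoids spurious draw-order correlation while keeping the
#' comparison reproducible and antisymmetric). Reports the median, the 94%
#' HDI and the overlap with the measure's ROPE.
#'
#' @param fit_a,fit_b `fov_fit` objects for the same measure.
#' @param parameter `"initial_value"`, `"asymptotic_performance"` or
#'   `"initial_learning_rate"`.
#' @param rope ROPE interval; default [rope_spec()] of the fits' measure.
#'   Note the printed ROPEs are calibrated for stage differences of the
#'   measures themselves (initial/asymptotic values), not for rates.
#' @param seed integer seed for the pairing permutation.
#' @param prob HDI mass (default 0.94).
#' @return object of class `stage_comparison`: list with `parameter`,
#'   `differences` (draws), `median`, `hdi`, `rope`, `rope_overlap`.
#' @export
compare_stages <- function(fit_a, fit_b,
                           parameter = c("initial_value",
                                         "asymptotic_performance",
                                         "initial_learning_rate"),
                           rope = NULL, seed = 1, prob = 0.94) {
  parameter <- match.arg(parameter)
  if (!identical(fit_a$measure, fit_b$measure)) {
    stop("fits are for different measures: ", fit_a$measure, " vs ", fit_b$measure)
  }
  if (is.null(rope)) rope <- rope_spec(fit_a$measure)
  a <- fit_a$derived$pop[[parameter]]
  b <- fit_b$derived$pop[[parameter]]
  n <- min(length(a), length(b))
  a <- a[fit_permutation(length(a), seed, fit_a$id)][seq_len(n)]
  b <- b[fit_permutation(length(b), seed, fit_b$id)][seq_len(n)]
  d <- b - a
  structure(list(parameter = parameter, measure = fit_a$measure,
                 stage_a = fit_a$stage, stage_b = fit_b$stage,
                 differences = d, median = median(d), hdi = hdi(d, prob),
                 rope = rope, rope_overlap = rope_overlap(d, rope)),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf(
    "%s / %s: %s minus %s = %.3g (%.0f%% HDI %.3g to %.3g), ROPE overlap %.3f\n",
    x$measure, x$parameter, x$stage_b, x$stage_a, x$median, 94,
    x$hdi[1], x$hdi[2], x$rope_overlap))
  invisible(x)
}

#' Relationship between learning rates across perturbation stages
#'
#' Bayesian simple linear regression of each fish's initial learning rate in
#' the second exposure (savings) on its rate in the first exposure
#' (rotation), across fish. By default each fish contributes its posterior
#' median rate; with `measurement_error = TRUE` the per-fish posterior
#' spread enters as known observation noise on both axes.
#'
#' @param fit_a,fit_b `fov_fit` objects of the same measure for the two
#'   stages (a = first exposure, b = second); at least 3 fish must appear in
#'   both.
#' @param seed integer seed.
#' @param chains,tune,draws sampler configuration for the regression
#'   (defaults 2 / 1000 / 1000).
#' @param measurement_error include per-fish posterior SDs as known noise.
#' @return list with `slope_draws`, `median`, `hdi`, `n_fish`.
#'
#' @details The residual variance carries a small noise floor (0.5% of the
#'   response scale) so that degenerate inputs with exactly collinear points
#'   keep a proper posterior.
#' @export
learning_rate_slope <- function(fit_a, fit_b, seed = 1, chains = 2,
                                tune = 1000, draws = 1000,
                                measurement_error = FALSE) {
  shared <- intersect(fit_a$fish_ids, fit_b$fish_ids)
  if (length(shared) < 3) stop("need at least 3 fish present in both stages")
  ia <- match(shared, fit_a$fish_ids)
  ib <- match(shared, fit_b$fish_ids)
  x <- apply(fit_a$derived$fish$initial_learning_rate[, ia, drop = FALSE], 2, median)
  y <- apply(fit_b$derived$fish$initial_learning_rate[, ib, drop = FALSE], 2, median)
  sx <- apply(fit_a$derived$fish$initial_learning_rate[, ia, drop = FALSE], 2, sd)
  sy <- apply(fit_b$derived$fish$initial_learning_rate[, ib, drop = FALSE], 2, sd)
  scale_y <- max(sd(y), 1e-3)
  scale_x <- max(sd(x), 1e-3)
  if (measurement_error) {
    mstr <- "model {
      for (i in 1:n) {
        xt[i] ~ dnorm(x[i], 1 / (sx[i] * sx[i]))
        y[i] ~ dnorm(alpha + beta * xt[i],
                     1 / (sigma * sigma + sy[i] * sy[i] + floor2))
      }
      alpha ~ dnorm(mu_y, 1 / (100 * s_y * s_y))
      beta ~ dnorm(0, 1 / (100 * pow(s_y / s_x, 2)))
      sigma ~ dgamma(2, 2 / s_y)
    }"
    jdata <- list(x = x, y = y, sx = pmax(sx, 1e-6), sy = pmax(sy, 1e-6),
                  n = length(x), mu_y = mean(y), s_y = scale_y, s_x = scale_x,
                  floor2 = (0.005 * scale_y)^2)
  } else {
    mstr <- "model {
      for (i in 1:n) {
        y[i] ~ dnorm(alpha + beta * x[i], 1 / (sigma * sigma + floor2))
      }
      alpha ~ dnorm(mu_y, 1 / (100 * s_y * s_y))
      beta ~ dnorm(0, 1 / (100 * pow(s_y / s_x, 2)))
      sigma ~ dgamma(2, 2 / s_y)
    }"
    jdata <- list(x = x, y = y, n = length(x), mu_y = mean(y),
                  s_y = scale_y, s_x = scale_x, floor2 = (0.005 * scale_y)^2)
  }
  set.seed(seed)
  inits <- lapply(sample.int(.Machine$integer.max - 1L, chains), function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  jm <- rjags::jags.model(textConnection(mstr), data = jdata, inits = inits,
                          n.chains = chains, n.adapt = ceiling(tune / 2),
                          quiet = TRUE)
  update(jm, tune - ceiling(tune / 2), progress.bar = "none")
  sm <- rjags::coda.samples(jm, "beta", n.iter = draws, progress.bar = "none")
  beta <- as.vector(as.matrix(sm))
  list(slope_draws = beta, median = median(beta), hdi = hdi(beta),
       n_fish = length(shared), points = data.frame(fish_id = shared, x = x, y = y))
}
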