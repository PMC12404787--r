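#' Configuration of a synthetic FOV cohort
#'
#' Describes the experimental schedule and the simulated vehicle/learner.
#' Defaults mirror the study conditions: five stages (baseline, rotation 15
#' sessions, washout 10, savings 15, final 10) of 6 trials each, a +45
#' degree rightward rotation during the perturbation stages, a 2.5 m
#' start-to-target distance, a 3-minute trial timeout, and a 12 Hz control
#' loop. Baseline defaults to 12 sessions, the study's observed minimum to
#' criterion.
#'
#' @param n_fish number of fish (default 8, the study's 45-degree cohort).
#' @param stages named integer vector of session counts per stage, in
#'   chronological order.
#' @param rotation named numeric vector of rotation angles (degrees,
#'   clockwise-positive) per stage.
#' @param trials_per_session trials per session (default 6).
#' @param speed vehicle speed in m/s (default 0.15; makes a straight drive
#'   to the target last about 17 s).
#' @param dt control timestep in seconds (default 1/12).
#' @param timeout trial time limit in seconds (default 180).
#' @param start,target arena coordinates (m), 2.5 m apart by default.
#' @param target_radius target disc radius (m, default 0.25).
#' @param arena arena bounds `c(xmin, xmax, ymin, ymax)` in meters.
#' @param kappa von Mises concentration of the per-trial aim noise
#'   (default 20; ~13 degrees circular SD). `Inf` disables noise.
#' @param kappa_step concentration of optional within-trial heading wobble;
#'   `Inf` (default) disables it.
#' @param dwell stationary-dwell probability per step (default 0): fraction
#'   of control steps in which the fish faces inward and the vehicle idles.
#' @param tau_policy learner time constant in sessions (default 4): the
#'   heading bias relaxes toward full compensation of the rotation with this
#'   time constant, and carries over between stages (producing aftereffects
#'   in washout).
#' @param tau_spread log-scale SD of between-fish variation in `tau_policy`
#'   (default 0.2).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_fish = 8,
                              stages = c(baseline = 12, rotation = 15,
                                         washout = 10, savings = 15, final = 10),
                              rotation = c(baseline = 0, rotation = 45,
                                           washout = 0, savings = 45, final = 0),
                              trials_per_session = 6,
                              speed = 0.15, dt = 1 / 12, timeout = 180,
                              start = c(0, 0), target = c(0, 2.5),
                              target_radius = 0.25,
                              arena = c(-3, 3, -1.5, 4.5),
                              kappa = 20, kappa_step = Inf, dwell = 0,
                              tau_policy = 4, tau_spread = 0.2) {
  stages <- unlist(stages)        # tolerate YAML-style lists
  rotation <- unlist(rotation)
  stopifnot(n_fish >= 1, all(stages >= 1), trials_per_session >= 1,
            speed > 0, dt > 0, timeout > 0, target_radius >= 0,
            length(arena) == 4, kappa >= 0, dwell >= 0, dwell < 1,
            tau_policy > 0, tau_spread >= 0,
            identical(names(stages), names(rotation)))
  structure(list(n_fish = n_fish, stages = stages, rotation = rotation,
                 trials_per_session = trials_per_session, speed = speed,
                 dt = dt, timeout = timeout, start = start, target = target,
                 target_radius = target_radius, arena = arena, kappa = kappa,
                 kappa_step = kappa_step, dwell = dwell,
                 tau_policy = tau_policy, tau_spread = tau_spread),
            class = "simulation_config")
}

#' Map a fish heading to a vehicle motion direction
#'
#' The FOV control system moves the vehicle in the direction the fish is
#' facing, optionally rotated by a fixed perturbation angle (positive =
#' clockwise/rightward).
#'
#' @param heading fish heading, degrees (clockwise-positive frame).
#' @param rotation_angle perturbation, degrees.
#' @return vehicle direction in degrees, wrapped to (-180, 180].
#' @examples
#' pose_to_motion(0, 45)    # 45
#' pose_to_motion(170, 90)  # -100 (wrapped)
#' @export
pose_to_motion <- function(heading, rotation_angle) {
  wrap_angle(heading + rotation_angle)
}

#' Simulate one FOV trial
#'
#' Discrete-time kinematics of an open-loop aiming policy: at trial start
#' the agent commits to a heading equal to the bearing to the target plus
#' its current bias plus von Mises aim noise; at every control step the
#' vehicle moves `speed * dt` along [pose_to_motion()] of that heading
#' (plus optional step wobble). The trial ends when the vehicle enters the
#' target disc, leaves the arena, or times out.
#'
#' @param policy list with `bias` (degrees; the learner's current heading
#'   offset) and optionally `kappa`, `kappa_step`, `dwell` overriding the
#'   config.
#' @param config [simulation_config()].
#' @param rotation_angle perturbation for this trial, degrees.
#' @return list with `samples` (data.frame `t, x, y`), `end_reason`
#'   (`"target_reached"`, `"boundary"` or `"timeout"`), `heading` (the
#'   committed aim, degrees) and `n_steps`.
#' @export
simulate_trial <- function(policy, config, rotation_angle = 0) {
  kappa <- policy$kappa %||% config$kappa
  kappa_step <- policy$kappa_step %||% config$kappa_step
  dwell <- policy$dwell %||% config$dwell
  dxy <- config$target - config$start
  bearing <- -rad2deg(atan2(dxy[2], dxy[1]))  # clockwise-positive frame
  aim_noise <- if (is.finite(kappa)) rvonmises(1, 0, kappa) else 0
  heading <- bearing + policy$bias + aim_noise
  max_steps <- ceiling(config$timeout / config$dt)
  xs <- numeric(max_steps + 1); ys <- numeric(max_steps + 1)
  pos <- config$start
  xs[1] <- pos[1]; ys[1] <- pos[2]
  end_reason <- "timeout"
  n <- 1L
  for (step in seq_len(max_steps)) {
    if (dwell > 0 && runif(1) < dwell) {
      n <- n + 1L; xs[n] <- pos[1]; ys[n] <- pos[2]
      next
    }
    wob <- if (is.finite(kappa_step)) rvonmises(1, 0, kappa_step) else 0
    dir_cw <- pose_to_motion(heading + wob, rotation_angle)
    a <- deg2rad(-dir_cw)
    pos <- pos + config$speed * config$dt * c(cos(a), sin(a))
    n <- n + 1L; xs[n] <- pos[1]; ys[n] <- pos[2]
    if (sum((pos - config$target)^2) <= config$target_radius^2) {
      end_reason <- "target_reached"; break
    }
    if (pos[1] < config$arena[1] || pos[1] > config$arena[2] ||
        pos[2] < config$arena[3] || pos[2] > config$arena[4]) {
      end_reason <- "boundary"; break
    }
  }
  list(samples = data.frame(t = (seq_len(n) - 1) * config$dt,
                            x = xs[seq_len(n)], y = ys[seq_len(n)]),
       end_reason = end_reason, heading = heading, n_steps = n - 1L)
}

#' Population-level ground truth for the measure-tier generator
#'
#' Default learning-curve truths for the rotation stage, anchored to the
#' across-fish estimates of the 45-degree study: success improves from 1.9
#' to 3.4 successes/session, angular error decays from about 11 degrees to
#' 0, distance from 6 m toward 3.8 m; time constants are implied by the
#' reported initial learning rates. Spreads describe between-fish variation
#' (log-scale SDs for positive parameters).
#'
#' @return nested list: per measure, `pop` (curve parameters) and `spread`.
#' @export
default_population_truth <- function() {
  list(
    success = list(
      pop = list(A_mu = -1.5, tau_mu = 2.6, mu_inf = 3.4,
                 A_sigma = 0, sigma_inf = 1, nu = NA),
      spread = list(log_amp = 0.2, log_tau = 0.2, log_mu_inf = 0.15)),
    angular = list(
      pop = list(A_mu = 11.3, tau_mu = 1.7, mu_inf = 0.1,
                 A_sigma = 12, sigma_inf = 8, nu = 20),
      spread = list(A_mu = 3, log_tau = 0.2, mu_inf = 2,
                    log_A_sigma = 0.2, log_sigma_inf = 0.2)),
    distance = list(
      pop = list(A_mu = 2.2, tau_mu = 2.4, mu_inf = 3.8,
                 A_sigma = 1.5, sigma_inf = 0.8, nu = NA),
      spread = list(log_amp = 0.2, log_tau = 0.2, log_mu_inf = 0.15)))
}

#' Draw per-fish true learning-curve parameters
#'
#' Fish-level truths are drawn around the population truth following the
#' model's own hierarchy: log-normal variation for positive parameters
#' (amplitude magnitudes, time constants, positive asymptotes, spread
#' parameters) and normal variation for the angular measure's amplitude and
#' asymptote.
#'
#' @param n_fish number of fish.
#' @param truth population truth, as [default_population_truth()].
#' @param seed integer seed.
#' @return data.frame: `fish_id, measure, A_mu, tau_mu, mu_inf, A_sigma,
#'   sigma_inf, nu`, with the population truth attached as attribute
#'   `"population"`.
#' @export
cohort_params <- function(n_fish = 8, truth = default_population_truth(),
                          seed = 1) {
  set.seed(seed)
  rows <- list()
  for (measure in names(truth)) {
    tr <- truth[[measure]]
    p <- tr$pop; s <- tr$spread
    fam <- measure_family(measure)
    lnorm_around <- function(center, lsd) {
      exp(log(center) + rnorm(n_fish, 0, lsd))
    }
    if (fam$positive_mean) {
      amp <- lnorm_around(abs(p$A_mu), s$log_amp)
      A <- sign(p$A_mu) * amp
      minf <- lnorm_around(p$mu_inf, s$log_mu_inf)
    } else {
      A <- rnorm(n_fish, p$A_mu, s$A_mu)
      minf <- rnorm(n_fish, p$mu_inf, s$mu_inf)
    }
    tau <- lnorm_around(p$tau_mu, s$log_tau)
    Asig <- if (p$A_sigma > 0) lnorm_around(p$A_sigma, s$log_A_sigma %||% 0.2)
            else rep(0, n_fish)
    sinf <- if (fam$per_trial) lnorm_around(p$sigma_inf, s$log_sigma_inf %||% 0.2)
            else rep(1, n_fish)
    rows[[measure]] <- data.frame(
      fish_id = sprintf("fish%02d", seq_len(n_fish)), measure = measure,
      A_mu = A, tau_mu = tau, mu_inf = minf, A_sigma = Asig,
      sigma_inf = sinf, nu = p$nu, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "population") <- truth
  out
}

#' Draw trial-level measure samples from the likelihoods
#'
#' Likelihood-tier generator: for every fish and session, success counts are
#' drawn from a Poisson with the curve mean (clipped at the physical
#' maximum of 6; clips are counted in attribute `"clipped"`), angular errors
#' per trial from the Student-t, and distances per trial from the
#' mode/sd-parameterised Gamma.
#'
#' @param fish_params data.frame from [cohort_params()].
#' @param n_sessions sessions per fish (default 15, the rotation stage).
#' @param trials_per_session trials per session (default 6).
#' @param seed integer seed.
#' @return data.frame `measure, fish_id, session, trial, value` (success
#'   rows have `trial = NA`: one count per session), with attribute
#'   `"clipped"` (number of Poisson draws clipped at 6).
#' @export
draw_measures <- function(fish_params, n_sessions = 15,
                          trials_per_session = 6, seed = 1) {
  set.seed(seed)
  clipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(fish_params))) {
    fp <- fish_params[i, ]
    params <- learning_curve_params(fp$A_mu, fp$tau_mu, fp$mu_inf,
                                    fp$A_sigma, fp$sigma_inf,
                                    if (is.na(fp$nu)) 30 else fp$nu)
    ses <- 0:(n_sessions - 1)
    mu <- curve_mean(params, ses)
    if (fp$measure == "success") {
      if (any(mu <= 0)) stop("success mean curve must stay positive; check truths")
      y <- rpois(n_sessions, mu)
      clipped <- clipped + sum(y > 6)
      y <- pmin(y, 6)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = fp$measure, fish_id = fp$fish_id, session = ses,
        trial = NA_integer_, value = y, stringsAsFactors = FALSE)
    } else {
      sg <- curve_sd(params, ses)
      for (s in seq_along(ses)) {
        y <- rmeasure(fp$measure, trials_per_session, mu[s], sg[s], params$nu)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = fp$measure, fish_id = fp$fish_id, session = ses[s],
          trial = seq_len(trials_per_session) - 1L, value = y,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "clipped") <- clipped
  out
}

#' Generate a full synthetic cohort
#'
#' Two tiers. The `"trajectory"` tier simulates raw vehicle trajectories
#' for every fish, stage, session and trial with [simulate_trial()]: each
#' fish's heading bias relaxes exponentially toward compensation of the
#' current stage's rotation with the fish's true time constant, and carries
#' over between stages (so washout shows an aftereffect). The `"measures"`
#' tier draws trial-level measure values directly from the likelihoods via
#' [draw_measures()] (one stage). Regeneration from the same config and
#' seed is bit-identical.
#'
#' @param config [simulation_config()].
#' @param seed integer seed.
#' @param tier `"trajectory"` or `"measures"`.
#' @param truth population truth for the measures tier
#'   (default [default_population_truth()]).
#' @return list of class `synthetic_cohort`: `samples` (trajectory tier; the
#'   tidy trial CSV dialect: `fish_id, stage, session, trial, t_s, x_m, y_m,
#'   x0, y0, xT, yT, end_reason`) or `measures`, plus `truth` (per-fish
#'   ground-truth table), `config` and `seed`.
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1,
                            tier = c("trajectory", "measures"),
                            truth = default_population_truth()) {
  tier <- match.arg(tier)
  if (tier == "measures") {
    fp <- cohort_params(config$n_fish, truth, seed = seed)
    meas <- draw_measures(fp, n_sessions = unname(config$stages["rotation"]),
                          trials_per_session = config$trials_per_session,
                          seed = seed + 1L)
    return(structure(list(measures = meas, truth = fp, config = config,
                          seed = seed), class = "synthetic_cohort"))
  }
  set.seed(seed)
  taus <- exp(log(config$tau_policy) + rnorm(config$n_fish, 0, config$tau_spread))
  fish_ids <- sprintf("fish%02d", seq_len(config$n_fish))
  chunks <- list()
  for (f in seq_len(config$n_fish)) {
    bias_prev <- 0
    for (stage in names(config$stages)) {
      rot <- config$rotation[[stage]]
      bias_target <- -rot
      for (s in seq_len(config$stages[[stage]]) - 1L) {
        bias <- bias_target + (bias_prev - bias_target) * exp(-s / taus[f])
        for (tr in seq_len(config$trials_per_session) - 1L) {
          sim <- simulate_trial(list(bias = bias), config, rotation_angle = rot)
          ns <- nrow(sim$samples)
          chunks[[length(chunks) + 1L]] <- data.frame(
            fish_id = fish_ids[f], stage = stage, session = s, trial = tr,
            t_s = sim$samples$t, x_m = sim$samples$x, y_m = sim$samples$y,
            x0 = config$start[1], y0 = config$start[2],
            xT = config$target[1], yT = config$target[2],
            end_reason = sim$end_reason, stringsAsFactors = FALSE)
        }
      }
      # bias state at the end of the stage seeds the next stage (aftereffect)
      n_s <- config$stages[[stage]]
      bias_prev <- bias_target + (bias_prev - bias_target) * exp(-(n_s - 1) / taus[f])
    }
  }
  samples <- do.call(rbind, chunks)
  rownames(samples) <- NULL
  truth_df <- data.frame(fish_id = fish_ids, tau_policy = taus,
                         stringsAsFactors = FALSE)
  structure(list(samples = samples, truth = truth_df, config = config,
                 seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  if (!is.null(x$samples)) {
    cat(sprintf("synthetic cohort (trajectory tier): %d fish, %d sample rows\n",
                length(unique(x$samples$fish_id)), nrow(x$samples)))
  } else {
    cat(sprintf("synthetic cohort (measures tier): %d fish, %d rows\n",
                length(unique(x$measures$fish_id)), nrow(x$measures)))
  }
  invisible(x)
}
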