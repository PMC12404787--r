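# Independent brute-force oracles and fixture generators used across tests.
# These re-derive every quantity from first principles, without calling the
# package's own implementations.

# polyline length by explicit pairwise loop
oracle_path_length <- function(x, y) {
  tot <- 0
  for (i in 2:length(x)) {
    tot <- tot + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  }
  tot
}

# signed clockwise angle via complex arguments (independent of atan2(cross, dot))
oracle_angular_error <- function(start, end, target) {
  u <- complex(real = target[1] - start[1], imaginary = target[2] - start[2])
  v <- complex(real = end[1] - start[1], imaginary = end[2] - start[2])
  ang <- -Arg(v / u) * 180 / pi  # clockwise positive
  if (ang <= -180) ang <- ang + 360
  ang
}

# one random trial trajectory as a samples-dialect data.frame chunk
random_trial_samples <- function(fish, session, trial, n_pts = 12,
                                 target = c(0, 2.5)) {
  x <- cumsum(c(runif(1, -1, 1), rnorm(n_pts - 1, 0, 0.3)))
  y <- cumsum(c(runif(1, -1, 1), rnorm(n_pts - 1, 0.25, 0.3)))
  data.frame(fish_id = fish, stage = "rotation", session = session,
             trial = trial, t_s = seq(0, by = 0.5, length.out = n_pts),
             x_m = x, y_m = y, x0 = x[1], y0 = y[1],
             xT = target[1], yT = target[2],
             stringsAsFactors = FALSE)
}

# a cohort of random polyline trials, `n_sessions` sessions of 6 trials
random_trial_cohort <- function(n_sessions, fish = "f1", seed = 1) {
  set.seed(seed)
  chunks <- list()
  for (s in seq_len(n_sessions) - 1L) {
    for (tr in 0:5) {
      chunks[[length(chunks) + 1L]] <- random_trial_samples(fish, s, tr)
    }
  }
  do.call(rbind, chunks)
}

# hand-built minimal fov_fit carrying given derived population/fish draws;
# used to unit-test the comparison machinery without running a sampler
fake_fit <- function(measure, stage, pop_derived, fish_ilr = NULL,
                     fish_ids = NULL) {
  fish <- list()
  if (!is.null(fish_ilr)) {
    fish$initial_learning_rate <- fish_ilr
    if (is.null(fish_ids)) fish_ids <- sprintf("f%02d", seq_len(ncol(fish_ilr)))
  }
  structure(list(measure = measure, stage = stage,
                 fish_ids = fish_ids %||% "f01",
                 derived = list(pop = pop_derived, fish = fish),
                 id = paste(measure, stage, "test", sep = ":")),
            class = "fov_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small single-fish Poisson dataset + fit, reused by several tests
tiny_success_fit <- function(seed = 7, flat = TRUE, tune = 600, draws = 800,
                             chains = 2) {
  set.seed(seed)
  dat <- data.frame(fish_id = "f1", session = 0:14, value = rpois(15, 3))
  hs <- hierarchy_spec("success", A_mu = 1, tau_mu = 5, mu_inf = 3)
  m <- build_model(dat, "success", hierarchy = hs, hierarchical = FALSE,
                   flat_curve = flat)
  list(model = m,
       fit = sample_posterior(m, chains = chains, tune = tune, draws = draws,
                              seed = seed))
}
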