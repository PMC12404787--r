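test_that("clean_trajectory interpolates short gaps and preserves timestamps", {
  # one untracked frame between (0,0) and (0,0.2): midpoint inserted
  s <- data.frame(t = c(0, 0.25, 0.5), x = c(0, NA, 0), y = c(0, NA, 0.2))
  out <- clean_trajectory(s, smooth_window = 1)
  expect_equal(nrow(out), 3)
  expect_equal(out$t, s$t)
  expect_equal(out[2, c("x", "y")], data.frame(x = 0, y = 0.1, row.names = 2L))

  # no gaps: identity (window-1 smoother)
  s2 <- data.frame(t = 0:5, x = rnorm(6), y = rnorm(6))
  expect_equal(clean_trajectory(s2, smooth_window = 1), s2)

  # constant runs survive the default window-3 median smoother
  s3 <- data.frame(t = 0:9, x = rep(1, 10), y = rep(2, 10))
  expect_equal(clean_trajectory(s3), s3)
})

test_that("clean_trajectory matches an independent interpolation oracle on a noisy walk", {
  set.seed(42)
  n <- 200
  t <- seq(0, by = 0.1, length.out = n)
  x <- cumsum(rnorm(n, 0, 0.05)); y <- cumsum(rnorm(n, 0, 0.05))
  drop <- sort(sample(2:(n - 1), n %/% 10))
  xs <- x; ys <- y
  xs[drop] <- NA; ys[drop] <- NA
  out <- clean_trajectory(data.frame(t = t, x = xs, y = ys), smooth_window = 1)
  expect_equal(nrow(out), n)  # all dropped frames bridged (gaps < 1 s)
  # oracle: point-wise linear interpolation against the valid neighbours
  keep <- setdiff(seq_len(n), drop)
  expect_equal(out$x, approx(t[keep], x[keep], xout = t)$y, tolerance = 1e-12)
  expect_equal(out$y, approx(t[keep], y[keep], xout = t)$y, tolerance = 1e-12)
})

test_that("clean_trajectory drops frames in long gaps and rejects empty trials", {
  s <- data.frame(t = c(0, 0.5, 2, 3.5, 4), x = c(0, NA, NA, NA, 1),
                  y = c(0, NA, NA, NA, 1))
  out <- clean_trajectory(s, max_gap = 1, smooth_window = 1)
  expect_equal(out$t, c(0, 4))  # 4-second gap: all interior frames dropped
  expect_error(clean_trajectory(data.frame(t = 0:2, x = c(1, NA, NA),
                                           y = c(1, NA, NA))),
               "empty trial")
  expect_error(clean_trajectory(data.frame(t = c(0, 0), x = c(1, 2), y = c(1, 2))),
               "strictly increasing")
})

test_that("path_length sums segment lengths", {
  expect_equal(path_length(c(0, 0, 1), c(0, 1, 1)), 2)
  # straight line sampled at 10 points is still 2.5 m
  expect_equal(path_length(rep(0, 10), seq(0, 2.5, length.out = 10)), 2.5)
  expect_warning(l1 <- path_length(1, 1), "single sample")
  expect_equal(l1, 0)
  set.seed(1)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(path_length(x, y), oracle_path_length(x, y), tolerance = 1e-12)
})

test_that("path_length is invariant under rigid motions", {
  set.seed(2)
  x <- cumsum(rnorm(30)); y <- cumsum(rnorm(30))
  l0 <- path_length(x, y)
  for (th in c(0.3, 1.7, -2.2)) {
    xr <- cos(th) * x - sin(th) * y + 5
    yr <- sin(th) * x + cos(th) * y - 3
    expect_equal(path_length(xr, yr), l0, tolerance = 1e-10)
  }
})

test_that("angular_error follows the clockwise-positive sign convention", {
  expect_equal(angular_error(c(0, 0), c(0, 2.5), c(0, 2.5)), 0)
  # end = target direction rotated 45 degrees clockwise -> +45
  expect_equal(angular_error(c(0, 0), c(sin(pi / 4), cos(pi / 4)), c(0, 1)), 45)
  # a fish pushed rightward (clockwise) of the target is positive
  expect_gt(angular_error(c(0, 0), c(1, 2.5), c(0, 2.5)), 0)
  expect_warning(e <- angular_error(c(0, 0), c(0, 0), c(0, 1)), "zero displacement")
  expect_true(is.na(e))
})

test_that("angular_error matches the independent complex-argument oracle", {
  set.seed(3)
  for (i in 1:500) {
    s <- runif(2, -5, 5); e <- runif(2, -5, 5); g <- runif(2, -5, 5)
    if (all(e == s) || all(g == s)) next
    expect_equal(angular_error(s, e, g), oracle_angular_error(s, e, g),
                 tolerance = 1e-9)
  }
})

test_that("angular_error(start, target, target) = 0 and reflections flip the sign", {
  set.seed(4)
  for (i in 1:50) {
    s <- runif(2); g <- s + runif(2, 0.1, 2)
    expect_equal(angular_error(s, g, g), 0, tolerance = 1e-12)
    # reflect the end point about the start->target axis: error negates
    e <- s + runif(2, -2, 2)
    u <- (g - s) / sqrt(sum((g - s)^2))
    v <- e - s
    e_ref <- s + 2 * sum(v * u) * u - v
    a <- angular_error(s, e, g)
    expect_equal(angular_error(s, e_ref, g), -a, tolerance = 1e-9)
  }
})

test_that("is_success uses a closed target disc", {
  expect_true(is_success(c(0, 2.5), c(0, 2.5)))
  expect_false(is_success(c(10, 0), c(0, 2.5)))
  expect_true(is_success(c(0.25, 2.5), c(0, 2.5), radius = 0.25))  # boundary
})

test_that("session_efficiency is total path over total displacement", {
  expect_equal(session_efficiency(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(session_efficiency(c(4, 6), c(2, 3)), 2)
  set.seed(5)
  len <- runif(6, 2, 8); se <- runif(6, 1, 4)
  expect_equal(session_efficiency(len, se), sum(len) / sum(se))
  expect_error(session_efficiency(c(1, 1), c(0, 0)), "degenerate")
  expect_warning(e1 <- session_efficiency(c(1, 1), c(0, 0), allow_degenerate = TRUE))
  expect_equal(e1, 1)
})

test_that("adjusted_distance adds the EAL penalty only on failures", {
  expect_equal(adjusted_distance(3, 2, TRUE, 1.5), 3)
  expect_equal(adjusted_distance(4, 1, FALSE, 1.5), 5.5)
  set.seed(6)
  len <- runif(20, 2, 8); et <- runif(20, 0, 3); eff <- runif(1, 1, 2)
  d <- adjusted_distance(len, et, rep(FALSE, 20), eff)
  expect_equal(d, len + eff * et)
  expect_true(all(d >= len))
})

test_that("compute_trial_metrics satisfies the per-trial invariants", {
  samples <- random_trial_cohort(4, seed = 11)
  tm <- compute_trial_metrics(samples)
  expect_equal(nrow(tm), 24)
  expect_true(all(tm$len_m >= tm$SE_m - 1e-12))        # polyline >= chord
  expect_true(all(tm$d_m >= tm$len_m - 1e-12))
  eq <- abs(tm$d_m - tm$len_m) < 1e-12
  expect_true(all(eq == (tm$success | tm$ET_m == 0)))
  expect_true(all(tm$angular_error_deg > -180 & tm$angular_error_deg <= 180,
                  na.rm = TRUE))
  expect_true(all(tm$EAL_m >= 0))
})

test_that("a recorded end_reason overrides the geometric success test", {
  samples <- random_trial_cohort(1, seed = 12)
  samples$end_reason <- "target_reached"
  tm <- compute_trial_metrics(samples)
  expect_true(all(tm$success))
  samples$end_reason <- "timeout"
  expect_false(any(compute_trial_metrics(samples)$success))
})

test_that("summarize_sessions counts successes and takes medians", {
  samples <- random_trial_cohort(2, seed = 13)
  tm <- compute_trial_metrics(samples)
  tm$success <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2)
  tm$d_m <- ifelse(tm$success, tm$len_m, tm$len_m + tm$eff * tm$ET_m)
  sm <- summarize_sessions(tm)
  expect_equal(sm$success_count, c(4, 4))
  expect_true(all(sm$success_count <= sm$n_trials))
  # median conventions
  tm1 <- tm[tm$session == 0, ][1:3, ]
  tm1$angular_error_deg <- c(-10, 0, 10)
  expect_equal(summarize_sessions(tm1)$median_angular_error_deg, 0)
  tm2 <- tm[tm$session == 0, ][1:4, ]
  tm2$angular_error_deg <- c(1, 2, 3, 4)
  expect_equal(summarize_sessions(tm2)$median_angular_error_deg, 2.5)
  # order invariance
  sm_perm <- summarize_sessions(tm[sample(nrow(tm)), ])
  expect_equal(sm_perm, sm)
})

test_that("baseline_criterion applies the three-session window rules", {
  mk <- function(successes, ang, d, sessions) {
    do.call(rbind, lapply(seq_along(sessions), function(i) {
      data.frame(fish_id = "f1", stage = "baseline", session = sessions[i],
                 trial = 0:5, success = c(rep(TRUE, successes[i]),
                                          rep(FALSE, 6 - successes[i])),
                 angular_error_deg = rep(ang[i], 6), len_m = rep(d[i], 6),
                 SE_m = 2, ET_m = 0.5, EAL_m = 0.5, d_m = rep(d[i], 6),
                 eff = 1, degenerate = FALSE)
    }))
  }
  good <- mk(c(5, 5, 5), c(0, 1, -1), c(3, 3, 3), 0:2)
  r <- baseline_criterion(good)
  expect_true(r$passed)
  expect_equal(r$session, 2)

  # the success rule works on the window median of the session counts:
  # alternating 3 and 0 never reaches a median of 4 in any window
  alt <- mk(rep(c(3, 0), 5), rep(0, 10), rep(3, 10), 0:9)
  expect_false(baseline_criterion(alt)$passed)
  # alternating 0 and 6 first passes on the (6, 0, 6) window ending at 3
  alt2 <- mk(rep(c(0, 6), 5), rep(0, 10), rep(3, 10), 0:9)
  r2 <- baseline_criterion(alt2)
  expect_true(r2$passed)
  expect_equal(r2$session, 3)

  # angle and distance thresholds
  expect_false(baseline_criterion(mk(c(5, 5, 5), c(20, 20, 20), c(3, 3, 3), 0:2))$passed)
  expect_false(baseline_criterion(mk(c(5, 5, 5), c(0, 0, 0), c(5, 5, 5), 0:2))$passed)

  # insufficient history and the 25-session cap
  expect_false(baseline_criterion(good[good$session < 2, ])$passed)
  late <- mk(c(5, 5, 5), c(0, 0, 0), c(3, 3, 3), 24:26)
  expect_false(baseline_criterion(late)$passed)
})

test_that("baseline_criterion index matches an exhaustive window-scan oracle", {
  # an improving fish: success rises, angle and distance shrink, with noise
  set.seed(14)
  n_ses <- 20
  tm <- do.call(rbind, lapply(0:(n_ses - 1), function(s) {
    p <- min(0.2 + 0.05 * s, 0.95)
    data.frame(fish_id = "f1", stage = "baseline", session = s, trial = 0:5,
               success = runif(6) < p,
               angular_error_deg = rnorm(6, 40 * exp(-s / 4), 8),
               len_m = 3, SE_m = 2.5, ET_m = 0.3, EAL_m = 0.3,
               d_m = rnorm(6, 3 + 4 * exp(-s / 4), 0.5), eff = 1.1,
               degenerate = FALSE)
  }))
  got <- baseline_criterion(tm)
  # oracle: scan every window explicitly
  oracle <- NA_integer_
  for (s in 0:(n_ses - 3)) {
    win <- tm[tm$session %in% c(s, s + 1, s + 2), ]
    counts <- sapply(c(s, s + 1, s + 2),
                     function(w) sum(win$success[win$session == w]))
    if (median(counts) >= 4 && abs(median(win$angular_error_deg)) < 15 &&
        median(win$d_m) < 4.5) { oracle <- s + 2L; break }
  }
  expect_equal(got$session, oracle)
  expect_equal(got$passed, !is.na(oracle))
})
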