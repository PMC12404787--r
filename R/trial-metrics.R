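#' Clean a raw vehicle trajectory
#'
#' Raw FOV trajectories contain frames in which the tracker lost the fish;
#' those frames carry `NA` coordinates. Cleaning (i) drops untracked frames,
#' (ii) linearly interpolates the positions of frames inside tracking gaps
#' shorter than `max_gap` seconds, and (iii) applies a running-median smoother
#' to the coordinates. Timestamps are never altered, and the smoother keeps
#' the first and last samples fixed (`endrule = "keep"`) because the trial
#' metrics are anchored on the trajectory endpoints.
#'
#' @param samples data.frame with numeric columns `t` (seconds, strictly
#'   increasing), `x`, `y` (meters; `NA` marks an untracked frame).
#' @param max_gap longest tracking gap, in seconds, that is bridged by linear
#'   interpolation; frames inside longer gaps are dropped. Default 1 s.
#' @param smooth_window odd integer width of the running-median smoother
#'   applied to `x` and `y`; `1` disables smoothing. Default 3.
#' @return data.frame with columns `t`, `x`, `y` and no missing values.
#' @seealso [compute_trial_metrics()]
#' @export
clean_trajectory <- function(samples, max_gap = 1, smooth_window = 3) {
  stopifnot(is.data.frame(samples), all(c("t", "x", "y") %in% names(samples)),
            max_gap >= 0, smooth_window >= 1, smooth_window %% 2 == 1)
  t <- samples$t
  x <- samples$x
  y <- samples$y
  if (anyNA(t)) stop("trajectory timestamps must not be missing")
  if (is.unsorted(t, strictly = TRUE)) {
    stop("trajectory timestamps must be strictly increasing")
  }
  valid <- !is.na(x) & !is.na(y)
  if (sum(valid) < 2) {
    stop("empty trial: fewer than 2 valid samples after removing untracked frames")
  }
  tv <- t[valid]
  # interpolate gap frames whose surrounding valid samples are < max_gap apart
  keep <- valid
  if (any(!valid)) {
    prev_valid <- findInterval(t, tv)                 # index of last valid t <= t
    for (i in which(!valid)) {
      p <- prev_valid[i]
      if (p >= 1 && p < length(tv) && (tv[p + 1] - tv[p]) < max_gap) {
        keep[i] <- TRUE
      }
    }
    xi <- approx(tv, x[valid], xout = t[keep])$y
    yi <- approx(tv, y[valid], xout = t[keep])$y
  } else {
    xi <- x
    yi <- y
  }
  out <- data.frame(t = t[keep], x = xi, y = yi)
  if (smooth_window > 1 && nrow(out) > smooth_window) {
    out$x <- as.numeric(runmed(out$x, smooth_window, endrule = "keep"))
    out$y <- as.numeric(runmed(out$y, smooth_window, endrule = "keep"))
  }
  out
}

#' Trajectory path length
#'
#' Sum of consecutive Euclidean segment lengths of a sampled 2-D polyline.
#'
#' @param x,y numeric coordinate vectors (meters), or `x` a two-column
#'   matrix/data.frame with `y` missing.
#' @return total length in meters; a single sample yields 0 with a warning.
#' @examples
#' path_length(c(0, 0, 1), c(0, 1, 1))  # 2
#' @export
path_length <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    y <- x[, 2]
    x <- x[, 1]
  }
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  if (length(x) < 2) {
    warning("path_length of a single sample is 0")
    return(0)
  }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Signed angular error of a trial
#'
#' Angle from the start-to-target direction to the start-to-end direction,
#' computed with the full-quadrant arctangent of the cross and dot products
#' of the two vectors. Positive angles are clockwise in the arena frame (the
#' direction of a rightward rotation of vehicle motion), so an unadapted fish
#' under a +45 degree perturbation produces an angular error of +45 degrees.
#'
#' @param start,end,target two-column matrices (or length-2 vectors) of
#'   arena coordinates in meters, row-wise paired.
#' @return signed degrees in (-180, 180]; `NA` where `end == start` (zero
#'   displacement) or `target == start`, with a warning.
#' @examples
#' angular_error(c(0, 0), c(2.5, 0), c(0, 2.5))  # +90 (due "right" of target)
#' @export
angular_error <- function(start, end, target) {
  as_mat <- function(p) {
    if (is.null(dim(p))) matrix(p, ncol = 2, byrow = TRUE) else as.matrix(p)
  }
  s <- as_mat(start); e <- as_mat(end); g <- as_mat(target)
  n <- max(nrow(s), nrow(e), nrow(g))
  if (nrow(s) == 1) s <- s[rep(1, n), , drop = FALSE]
  if (nrow(e) == 1) e <- e[rep(1, n), , drop = FALSE]
  if (nrow(g) == 1) g <- g[rep(1, n), , drop = FALSE]
  u <- g - s   # start -> target
  v <- e - s   # start -> end
  bad <- (rowSums(u^2) == 0) | (rowSums(v^2) == 0)
  cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  dot <- u[, 1] * v[, 1] + u[, 2] * v[, 2]
  # counter-clockwise angle from u to v is atan2(cross, dot); clockwise-positive
  out <- wrap_angle(-rad2deg(atan2(cross, dot)))
  if (any(bad)) {
    warning("angular error undefined for trials with zero displacement; returning NA")
    out[bad] <- NA_real_
  }
  out
}

#' Did the trial end inside the target area?
#'
#' The target is modelled as a closed disc (a point exactly on the boundary
#' counts as inside). When the input data record an explicit trial outcome
#' (`end_reason`), [compute_trial_metrics()] prefers that record over this
#' geometric test.
#'
#' @param end two-column matrix or length-2 vector of final positions (m).
#' @param target target centre(s), same shape as `end`.
#' @param radius target disc radius in meters (default 0.25).
#' @return logical vector.
#' @export
is_success <- function(end, target, radius = 0.25) {
  if (is.null(dim(end))) end <- matrix(end, ncol = 2, byrow = TRUE)
  if (is.null(dim(target))) target <- matrix(target, ncol = 2, byrow = TRUE)
  stopifnot(radius >= 0)
  d2 <- (end[, 1] - target[, 1])^2 + (end[, 2] - target[, 2])^2
  d2 <= radius^2
}

#' Session efficiency
#'
#' Ratio of the summed path lengths to the summed start-to-end straight-line
#' distances over the trials of one session. Efficiency 1 means every trial
#' was driven in a straight line; larger values mean more meandering.
#'
#' @param len numeric vector of trial path lengths (m).
#' @param se numeric vector of trial start-to-end distances (m).
#' @param allow_degenerate if `TRUE`, a session whose start-to-end distances
#'   all vanish yields efficiency 1 with a warning instead of an error.
#' @return scalar efficiency (>= 1 whenever all `se > 0`).
#' @export
session_efficiency <- function(len, se, allow_degenerate = FALSE) {
  stopifnot(length(len) == length(se), length(len) >= 1)
  tot_se <- sum(se)
  if (tot_se == 0) {
    if (allow_degenerate) {
      warning("degenerate session (all start-to-end distances 0); using efficiency 1")
      return(1)
    }
    stop("degenerate session: all start-to-end distances are 0, efficiency undefined")
  }
  sum(len) / tot_se
}

#' Efficiency-adjusted trial distance
#'
#' Successful trials are scored by their raw path length. Failed trials are
#' penalised by the estimated additional length (EAL): the end-to-target
#' distance scaled by the session's efficiency, i.e. the extra path the fish
#' would plausibly have needed to reach the target at its demonstrated
#' efficiency.
#'
#' @param len trial path length (m).
#' @param et end-to-target distance (m).
#' @param success logical.
#' @param eff session efficiency from [session_efficiency()].
#' @return adjusted distance `d` in meters: `len` if successful, otherwise
#'   `len + eff * et`.
#' @export
adjusted_distance <- function(len, et, success, eff) {
  stopifnot(length(eff) == 1 || length(eff) == length(len))
  ifelse(success, len, len + eff * et)
}

#' Compute per-trial performance metrics for a cohort
#'
#' Takes tidy trajectory samples (one row per tracked frame) and returns one
#' row per trial with the three performance measures and their ingredients:
#' success, signed angular error, path length `len`, start-to-end distance
#' `SE`, end-to-target distance `ET`, estimated additional length `EAL`, and
#' the efficiency-adjusted distance `d`. Session efficiency is computed per
#' (fish, stage, session) from the cleaned trials.
#'
#' @param samples data.frame with columns `fish_id`, `stage`, `session`,
#'   `trial`, `t_s`, `x_m`, `y_m`, `xT`, `yT` and optionally `end_reason`
#'   (one of `"target_reached"`, `"timeout"`, `"boundary"`; repeated per
#'   sample row). When `end_reason` is present it determines success;
#'   otherwise the geometric disc test is used.
#' @param target_radius target disc radius in meters for the geometric
#'   success test (default 0.25).
#' @param max_gap,smooth_window passed to [clean_trajectory()].
#' @param allow_degenerate_efficiency passed to [session_efficiency()].
#' @return data.frame, one row per trial: `fish_id, stage, session, trial,
#'   success, angular_error_deg, len_m, SE_m, ET_m, EAL_m, d_m, eff,
#'   degenerate`.
#' @export
compute_trial_metrics <- function(samples, target_radius = 0.25, max_gap = 1,
                                  smooth_window = 3,
                                  allow_degenerate_efficiency = FALSE) {
  req <- c("fish_id", "stage", "session", "trial", "t_s", "x_m", "y_m", "xT", "yT")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("samples are missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  has_reason <- "end_reason" %in% names(samples)
  key <- interaction(samples$fish_id, samples$stage, samples$session,
                     samples$trial, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(samples)), key), function(idx) {
    tr <- samples[idx, ]
    cleaned <- tryCatch(
      clean_trajectory(data.frame(t = tr$t_s, x = tr$x_m, y = tr$y_m),
                       max_gap = max_gap, smooth_window = smooth_window),
      error = function(e) NULL
    )
    if (is.null(cleaned)) {
      warning(sprintf("dropping empty trial %s/%s/s%s/t%s",
                      tr$fish_id[1], tr$stage[1], tr$session[1], tr$trial[1]))
      return(NULL)
    }
    n <- nrow(cleaned)
    start <- c(cleaned$x[1], cleaned$y[1])
    end <- c(cleaned$x[n], cleaned$y[n])
    target <- c(tr$xT[1], tr$yT[1])
    len <- path_length(cleaned$x, cleaned$y)
    se <- sqrt(sum((end - start)^2))
    et <- sqrt(sum((target - end)^2))
    ang <- suppressWarnings(angular_error(start, end, target))
    success <- if (has_reason) {
      identical(as.character(tr$end_reason[1]), "target_reached")
    } else {
      is_success(end, target, target_radius)
    }
    degenerate <- se == 0
    if (degenerate) success <- FALSE  # zero-displacement trials count as failures
    data.frame(fish_id = tr$fish_id[1], stage = tr$stage[1],
               session = tr$session[1], trial = tr$trial[1],
               success = success, angular_error_deg = ang,
               len_m = len, SE_m = se, ET_m = et,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no usable trials in input")
  rownames(out) <- NULL
  # session efficiency, then EAL and adjusted distance
  skey <- interaction(out$fish_id, out$stage, out$session, drop = TRUE)
  out$eff <- NA_real_
  for (k in levels(skey)) {
    i <- which(skey == k)
    out$eff[i] <- session_efficiency(out$len_m[i], out$SE_m[i],
                                     allow_degenerate = allow_degenerate_efficiency)
  }
  out$EAL_m <- out$eff * out$ET_m
  out$d_m <- adjusted_distance(out$len_m, out$ET_m, out$success, out$eff)
  out[c("fish_id", "stage", "session", "trial", "success", "angular_error_deg",
        "len_m", "SE_m", "ET_m", "EAL_m", "d_m", "eff", "degenerate")]
}

#' Summarise trials into session-level metrics
#'
#' Sessions are represented by the median across their trials: the success
#' count, the median signed angular error (over trials with a defined error),
#' and the median efficiency-adjusted distance. Even-length medians use the
#' mean of the two middle values.
#'
#' @param trial_metrics output of [compute_trial_metrics()].
#' @return data.frame, one row per (fish, stage, session): `fish_id, stage,
#'   session, n_trials, success_count, median_angular_error_deg, median_d_m,
#'   eff, all_errors_missing`.
#' @export
summarize_sessions <- function(trial_metrics) {
  skey <- interaction(trial_metrics$fish_id, trial_metrics$stage,
                      trial_metrics$session, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(trial_metrics, skey), function(tm) {
    ang <- tm$angular_error_deg[!is.na(tm$angular_error_deg)]
    all_missing <- length(ang) == 0
    if (all_missing) {
      warning(sprintf("session %s/%s/%s has no defined angular errors",
                      tm$fish_id[1], tm$stage[1], tm$session[1]))
    }
    data.frame(fish_id = tm$fish_id[1], stage = tm$stage[1],
               session = tm$session[1], n_trials = nrow(tm),
               success_count = sum(tm$success),
               median_angular_error_deg = if (all_missing) NA_real_ else median(ang),
               median_d_m = median(tm$d_m),
               eff = tm$eff[1],
               all_errors_missing = all_missing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$fish_id, out$stage, out$session), ]
}

#' Baseline advancement criterion
#'
#' A fish advances from baseline training once, over three consecutive
#' sessions, (i) the median session success count is at least
#' `min_successes`, (ii) the absolute median angular error over the window's
#' trials is below `max_abs_angle` degrees, and (iii) the median adjusted
#' distance over the window's trials is below `max_distance` meters. Fish
#' that have not met the criterion within `max_sessions` baseline sessions
#' are reported as failing.
#'
#' @param trial_metrics per-trial metrics for one fish's baseline stage
#'   (output of [compute_trial_metrics()], possibly pre-filtered; rows with
#'   `stage == "baseline"` are used when several stages are present).
#' @param min_successes,max_abs_angle,max_distance criterion thresholds
#'   (defaults 4 successes, 15 degrees, 4.5 m).
#' @param max_sessions baseline session cap (default 25; 0-based session
#'   indices `0 .. max_sessions - 1` are eligible).
#' @return list with `passed` (logical), `session` (0-based index of the
#'   last session of the first qualifying window, or `NA`), and `window`
#'   (the three session indices, or `NULL`).
#' @export
baseline_criterion <- function(trial_metrics, min_successes = 4,
                               max_abs_angle = 15, max_distance = 4.5,
                               max_sessions = 25) {
  tm <- trial_metrics
  if ("stage" %in% names(tm) && any(tm$stage == "baseline")) {
    tm <- tm[tm$stage == "baseline", ]
  }
  if (length(unique(tm$fish_id)) > 1) {
    stop("baseline_criterion expects a single fish; split the data first")
  }
  sessions <- sort(unique(tm$session))
  fail <- list(passed = FALSE, session = NA_integer_, window = NULL)
  if (length(sessions) < 3) return(fail)
  sm <- summarize_sessions(tm)
  for (s in sessions) {
    win <- c(s, s + 1, s + 2)
    if (!all(win %in% sessions)) next
    if (win[3] > max_sessions - 1) break  # past the baseline cap
    counts <- sm$success_count[match(win, sm$session)]
    wtrials <- tm[tm$session %in% win, ]
    ang <- wtrials$angular_error_deg[!is.na(wtrials$angular_error_deg)]
    ok <- median(counts) >= min_successes &&
      length(ang) > 0 && abs(median(ang)) < max_abs_angle &&
      median(wtrials$d_m) < max_distance
    if (ok) return(list(passed = TRUE, session = win[3], window = win))
  }
  fail
}
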