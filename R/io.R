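#' Read tidy trial samples from CSV
#'
#' The trial CSV dialect has one row per tracked frame: `fish_id, stage,
#' session, trial, t_s, x_m, y_m` plus per-trial geometry columns
#' `x0, y0, xT, yT` and optionally `end_reason`. A separate per-trial
#' sidecar CSV with those geometry columns (keyed by `fish_id, stage,
#' session, trial`) may be supplied instead.
#'
#' @param path samples CSV path.
#' @param sidecar optional per-trial geometry CSV path.
#' @return data.frame in the samples dialect.
#' @export
read_trial_samples <- function(path, sidecar = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("fish_id", "stage", "session", "trial", "t_s", "x_m", "y_m")
  problems <- setdiff(req, names(x))
  if (!is.null(sidecar)) {
    sc <- read.csv(sidecar, stringsAsFactors = FALSE)
    key <- c("fish_id", "stage", "session", "trial")
    problems <- c(problems, setdiff(key, names(sc)))
    if (length(problems)) {
      stop("input is missing required columns: ", paste(unique(problems), collapse = ", "))
    }
    x <- merge(x, sc, by = key, sort = FALSE)
  }
  geo <- setdiff(c("xT", "yT"), names(x))
  problems <- c(problems, geo)
  if (length(problems)) {
    stop("input is missing required columns: ", paste(unique(problems), collapse = ", "))
  }
  x
}

#' Read per-trial metrics from CSV
#'
#' Accepts either a precomputed metrics table (`fish_id, stage, session,
#' trial, success, angular_error_deg, len_m, SE_m, ET_m, EAL_m, d_m`) or a
#' raw samples table, which is then passed through
#' [compute_trial_metrics()].
#'
#' @param path CSV path.
#' @param ... passed to [compute_trial_metrics()] for raw input.
#' @return per-trial metrics data.frame.
#' @export
read_trial_metrics <- function(path, ...) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("angular_error_deg", "d_m") %in% names(x))) {
    if (is.character(x$success)) x$success <- x$success %in% c("TRUE", "True", "true", "1")
    return(x)
  }
  if (all(c("t_s", "x_m", "y_m") %in% names(x))) {
    return(compute_trial_metrics(x, ...))
  }
  stop("unrecognised input: expected raw trial samples or precomputed trial metrics")
}

#' Write a synthetic cohort to a directory
#'
#' Writes `samples.csv` (or `measures.csv` for the likelihood tier),
#' `truth.csv` and a `config.yaml` echo of the generating configuration and
#' seed, so a run can be regenerated exactly.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$samples)) {
    write.csv(cohort$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  } else {
    write.csv(cohort$measures, file.path(dir, "measures.csv"), row.names = FALSE)
  }
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  cfg$stages <- as.list(cfg$stages)
  cfg$rotation <- as.list(cfg$rotation)
  yaml::write_yaml(list(config = cfg, seed = cohort$seed,
                        package_version = as.character(packageVersion("fovadapt"))),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write per-trial and per-session metrics CSVs
#'
#' @param trial_metrics output of [compute_trial_metrics()].
#' @param dir output directory.
#' @return `dir`, invisibly; writes `trial_metrics.csv` and
#'   `session_metrics.csv`.
#' @export
write_metrics <- function(trial_metrics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(trial_metrics, file.path(dir, "trial_metrics.csv"), row.names = FALSE)
  write.csv(summarize_sessions(trial_metrics),
            file.path(dir, "session_metrics.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a fit's parameter summary CSV
#'
#' @param fit `fov_fit`.
#' @param path output CSV path.
#' @return the summary data.frame, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  s <- fit_summary(fit)
  s$rhat_max <- max(fit$diagnostics$rhat, na.rm = TRUE)
  s$converged <- fit$diagnostics$ok
  write.csv(s, path, row.names = FALSE)
  invisible(s)
}

#' Write a comparison report CSV
#'
#' One row per stage comparison:
#' `measure, parameter, stage_a, stage_b, median_diff, hdi_low, hdi_high,
#' rope_overlap`.
#'
#' @param comparisons a list of `stage_comparison` objects.
#' @param path output CSV path.
#' @return the report data.frame, invisibly.
#' @export
write_comparison_report <- function(comparisons, path) {
  rows <- lapply(comparisons, function(cmp) {
    data.frame(measure = cmp$measure, parameter = cmp$parameter,
               stage_a = cmp$stage_a, stage_b = cmp$stage_b,
               median_diff = cmp$median, hdi_low = cmp$hdi[1],
               hdi_high = cmp$hdi[2], rope_overlap = cmp$rope_overlap,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a run manifest
#'
#' Records inputs, seed and package version so deterministic outputs can be
#' reproduced byte-identically.
#'
#' @param dir output directory.
#' @param inputs named list of input paths/settings.
#' @param seed integer seed used for the run.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, inputs, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(inputs = inputs, seed = seed,
                        package_version = as.character(packageVersion("fovadapt"))),
                   p)
  invisible(p)
}
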