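#' Canonical double-gamma hemodynamic response function
#'
#' The conventional difference-of-gammas HRF: a positive gamma peaking near
#' 5 s minus a scaled gamma producing the post-peak undershoot, normalized to
#' peak amplitude 1. Negative times return 0 (causality).
#'
#' @param t Time in seconds (vectorized).
#' @param peak_delay,undershoot_delay Gamma delays (seconds); defaults 6, 16.
#' @param peak_disp,undershoot_disp Gamma dispersions; defaults 1, 1.
#' @param undershoot_ratio Peak/undershoot amplitude ratio; default 6.
#' @return Amplitude at `t`, peak-normalized.
#' @examples
#' hrf_double_gamma(c(0, 5, 15))
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 6) {
  raw <- function(tt) {
    stats::dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
      stats::dgamma(tt, shape = undershoot_delay / undershoot_disp,
                    scale = undershoot_disp) / undershoot_ratio
  }
  pk <- stats::optimize(raw, c(0.1, undershoot_delay), maximum = TRUE)$objective
  out <- ifelse(t < 0, 0, raw(pmax(t, 0)) / pk)
  out
}

#' Discrete-cosine drift basis
#'
#' Orthonormal DCT basis spanning the constant term and the slow cosine
#' components up to order `floor(2 * n * tr / cutoff + 1)` (the conventional
#' drift order for a high-pass cutoff period of `cutoff` seconds), used both
#' as the design matrix's drift block and as the subspace removed by
#' [highpass()].
#'
#' @param n_volumes Number of volumes.
#' @param tr Repetition time, seconds.
#' @param cutoff High-pass cutoff period, seconds; must exceed `2 * tr`.
#' @return An `n_volumes` x (K + 1) orthonormal matrix (constant column
#'   first).
#' @export
dct_basis <- function(n_volumes, tr, cutoff = 120) {
  if (cutoff <= 2 * tr)
    stop("high-pass cutoff must exceed 2 * tr (period, in seconds)",
         call. = FALSE)
  n <- n_volumes
  K <- floor(2 * n * tr / cutoff + 1)
  t_idx <- seq_len(n) - 1
  B <- vapply(0:K, function(k) cos(pi * (2 * t_idx + 1) * k / (2 * n)),
              numeric(n))
  B <- sweep(B, 2, sqrt(colSums(B^2)), `/`)
  colnames(B) <- paste0("drift_", 0:K)
  B
}

#' High-pass filter by discrete-cosine projection
#'
#' Removes all DCT components (including the mean) with period longer than
#' `cutoff` seconds from a series or a volumes x series matrix. Applying the
#' same filter to data and design keeps the GLM estimates identical to
#' including the drift columns as regressors.
#'
#' @param x Numeric vector or matrix with volumes in rows.
#' @param tr Repetition time, seconds.
#' @param cutoff Cutoff period in seconds (default 120).
#' @return Filtered object of the same shape.
#' @export
highpass <- function(x, tr, cutoff = 120) {
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, ncol = 1) else as.matrix(x)
  B <- dct_basis(nrow(xm), tr, cutoff)
  out <- xm - B %*% crossprod(B, xm)
  if (v) drop(out) else out
}

#' Build an event-related design matrix
#'
#' One task column per condition -- per-event boxcars convolved with the
#' double-gamma HRF on a grid oversampled `oversample`-fold relative to the
#' TR (onsets are not TR-locked), decimated to volume acquisition times --
#' plus the DCT drift block with periods above `cutoff` seconds.
#'
#' @param events Event table for a single run (columns `onset`, `duration`,
#'   and the grouping column named by `by`).
#' @param n_volumes Volumes in the run.
#' @param tr Repetition time, seconds.
#' @param by Events column defining the regressor grouping: `"trial_type"`
#'   (condition-resolved, default) or `"room_type"` (room-resolved).
#' @param conditions Regressor levels; defaults to the sorted unique values
#'   of `events[[by]]`.
#' @param oversample Oversampling factor of the convolution grid.
#' @param cutoff Drift-block cutoff period, seconds; `NULL` for no drift
#'   block.
#' @param hrf Function of time giving the HRF (default
#'   [hrf_double_gamma()]).
#' @return A volumes x regressors matrix with attributes `task_cols`,
#'   `conditions`, `tr`.
#' @export
build_design_matrix <- function(events, n_volumes, tr,
                                by = "trial_type", conditions = NULL,
                                oversample = 10, cutoff = 120,
                                hrf = hrf_double_gamma) {
  stopifnot(all(c("onset", "duration", by) %in% names(events)) ||
              nrow(events) == 0)
  run_len <- n_volumes * tr
  if (nrow(events) > 0) {
    bad <- which(events$onset + events$duration > run_len)
    if (length(bad)) {
      r <- if ("run" %in% names(events)) events$run[bad[1]] else NA
      stop(sprintf(
        "event at onset %.1f s (run %s) extends beyond scan end (%.0f s)",
        events$onset[bad[1]], r, run_len), call. = FALSE)
    }
    if (is.null(conditions)) conditions <- sort(unique(events[[by]]))
  } else if (is.null(conditions)) {
    conditions <- condition_table()$condition_id
  }
  dt <- tr / oversample
  tail_s <- 32
  n_grid <- ceiling((run_len + tail_s) / dt)
  h <- hrf(seq(0, tail_s, by = dt))
  task <- vapply(conditions, function(k) {
    u <- numeric(n_grid)
    ev <- events[!is.na(events[[by]]) & events[[by]] == k, , drop = FALSE]
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        j0 <- floor(ev$onset[i] / dt) + 1
        j1 <- ceiling((ev$onset[i] + ev$duration[i]) / dt)
        u[j0:min(j1, n_grid)] <- 1
      }
    }
    conv <- stats::convolve(u, rev(h), type = "open")[seq_len(n_grid)] * dt
    conv[(seq_len(n_volumes) - 1) * oversample + 1]
  }, numeric(n_volumes))
  colnames(task) <- paste0("cond_", conditions)
  X <- if (is.null(cutoff)) task else cbind(task, dct_basis(n_volumes, tr, cutoff))
  structure(X, task_cols = seq_along(conditions), conditions = conditions,
            tr = tr)
}

#' Fit a run-level GLM by ordinary least squares
#'
#' Estimates per-voxel condition amplitudes from a voxel time-series matrix
#' and a design built by [build_design_matrix()]. Drift columns in the
#' design absorb slow trends; only the task amplitudes are returned.
#'
#' @param bold Volumes x voxels matrix.
#' @param design Design matrix from [build_design_matrix()].
#' @return A voxels x conditions beta matrix (columns named by condition).
#' @export
fit_run_glm <- function(bold, design) {
  bold <- as.matrix(bold)
  if (nrow(bold) != nrow(design))
    stop("bold and design disagree on the number of volumes", call. = FALSE)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    dropped <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, bold)
  task <- attr(design, "task_cols")
  B <- t(coef[task, , drop = FALSE])
  colnames(B) <- as.character(attr(design, "conditions"))
  rownames(B) <- colnames(bold) %||% as.character(seq_len(ncol(bold)))
  B
}

#' Average run betas over a subset of runs
#'
#' Element-wise mean of the voxels x conditions beta matrices of a run
#' subset, as used to form each half of a split-half fold.
#'
#' @param betas A beta table ([simulate_betas()] or [fit_experiment_glm()])
#'   restricted to a single subject, ROI and hemisphere.
#' @param runs Run ids to average (must all be present).
#' @return A voxels x conditions matrix.
#' @export
average_halves <- function(betas, runs) {
  key <- unique(betas[, intersect(c("subject", "roi", "hemisphere"),
                                  names(betas))])
  if (nrow(key) != 1)
    stop("average_halves() expects betas from a single subject/ROI/hemisphere",
         call. = FALSE)
  if (!all(runs %in% betas$run))
    stop("run subset contains runs absent from the beta table", call. = FALSE)
  mats <- betas$betas[match(runs, betas$run)]
  average_matrices(mats)
}

average_matrices <- function(mats) {
  d1 <- dimnames(mats[[1]])
  dm <- dim(mats[[1]])
  ok <- vapply(mats, function(m) identical(dim(m), dm) &&
                 identical(rownames(m), d1[[1]]), logical(1))
  if (!all(ok))
    stop("voxel sets differ across runs; cannot average", call. = FALSE)
  Reduce(`+`, mats) / length(mats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate voxel BOLD time series
#'
#' Generates per-run voxel x volume time series as the event-related design
#' matrix (task block of [build_design_matrix()]) times the run's condition
#' amplitudes from [simulate_betas()], plus white Gaussian noise (no temporal
#' autocorrelation, matching the OLS estimator's assumption).
#'
#' @param config A [sim_config()] with `level = "bold"`.
#' @param schedule Event table for all runs (one subject), as from
#'   [generate_event_schedule()]; generated per subject from the config seed
#'   when `NULL`.
#' @param rois ROIs to simulate.
#' @param noise_sd_bold Volume-wise noise SD; defaults to the config's
#'   `noise_sd_run`.
#' @return A tibble with columns `subject`, `roi`, `hemisphere`, `run`, and
#'   `bold` (list of volumes x voxels matrices); attributes carry the config,
#'   per-subject schedules (`schedules`), and the amplitude table used
#'   (`amplitudes`, also retrievable noise-free via [ground_truth()]).
#' @export
simulate_bold <- function(config, schedule = NULL, rois = config$rois,
                          noise_sd_bold = config$noise_sd_run) {
  stopifnot(inherits(config, "navaff_config"))
  if (config$level != "bold")
    stop("simulate_bold() requires a config with level = \"bold\"",
         call. = FALSE)
  beta_cfg <- config
  beta_cfg$level <- "beta"
  amps <- simulate_betas(beta_cfg, rois = rois)
  run_len <- config$n_volumes * config$tr
  scheds <- purrr::map(seq_len(config$n_subjects), function(s) {
    sc <- if (is.null(schedule)) generate_event_schedule(config, s) else schedule
    if (nrow(sc) && max(sc$onset + sc$duration) > run_len)
      stop(sprintf("run length %.0f s is shorter than the schedule span %.1f s",
                   run_len, max(sc$onset + sc$duration)), call. = FALSE)
    sc
  })
  designs <- purrr::map(scheds, function(sc) {
    purrr::map(seq_len(config$n_runs), function(r) {
      build_design_matrix(sc[sc$run == r, , drop = FALSE],
                          config$n_volumes, config$tr,
                          conditions = condition_table()$condition_id)
    })
  })
  bold <- purrr::pmap(amps[, c("subject", "run", "betas")],
                      function(subject, run, betas) {
    X <- designs[[subject]][[run]]
    task <- X[, attr(X, "task_cols"), drop = FALSE]
    Y <- task %*% t(betas[, as.character(attr(X, "conditions")), drop = FALSE])
    if (noise_sd_bold > 0) {
      ns <- with_seed_(derive_seed(config$seed, 31L, subject, run),
                       function() stats::rnorm(length(Y), 0, noise_sd_bold))
      Y <- Y + ns
    }
    colnames(Y) <- rownames(betas)
    Y
  })
  out <- dplyr::mutate(amps[, c("subject", "roi", "hemisphere", "run")],
                       bold = bold)
  structure(out, config = config, schedules = scheds,
            amplitudes = amps, ground_truth = ground_truth(amps),
            provenance = "experimental")
}

#' Estimate run betas for a whole simulated experiment
#'
#' Applies [fit_run_glm()] to every row of a [simulate_bold()] table using
#' each subject's schedule, returning a beta table of the same shape as
#' [simulate_betas()] so that downstream stages are agnostic to the
#' simulation level.
#'
#' @param bold_tbl Output of [simulate_bold()].
#' @param cutoff High-pass cutoff period (seconds) for the drift block.
#' @param by Regressor grouping (`"trial_type"` or `"room_type"`).
#' @return A beta table (`subject`, `roi`, `hemisphere`, `run`, `betas`).
#' @export
fit_experiment_glm <- function(bold_tbl, cutoff = 120, by = "trial_type") {
  config <- attr(bold_tbl, "config")
  scheds <- attr(bold_tbl, "schedules")
  betas <- purrr::pmap(bold_tbl[, c("subject", "run", "bold")],
                       function(subject, run, bold) {
    sc <- scheds[[subject]]
    X <- build_design_matrix(sc[sc$run == run, , drop = FALSE],
                             nrow(bold), config$tr, by = by,
                             conditions = if (by == "trial_type")
                               condition_table()$condition_id else 1:8,
                             cutoff = cutoff)
    fit_run_glm(bold, X)
  })
  out <- dplyr::mutate(bold_tbl[, c("subject", "roi", "hemisphere", "run")],
                       betas = betas)
  structure(out, config = config, ground_truth = attr(bold_tbl, "ground_truth"),
            provenance = "experimental",
            class = c("navaff_betas", class(out)))
}
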