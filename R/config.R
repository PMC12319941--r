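#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-experiment generator.
#' Defaults reproduce the target experiment's scale: 16 subjects, 8
#' event-related runs of 228 volumes at TR 2 s, 4 repetitions of each of the
#' 10 conditions per run (32 per condition overall), and 50 voxels per
#' ROI-hemisphere.
#'
#' Effect magnitudes are expressed in units of the within-run noise standard
#' deviation (`noise_sd_run`):
#' \describe{
#'   \item{affordance_contra}{mean boost for an open doorway in a hemisphere's
#'     contralateral visual hemifield, applied to the translation conditions
#'     1-6 (both-door conditions are boosted in both hemispheres).}
#'   \item{ego_motion_code}{scale of the per-hemisphere voxel pattern that
#'     separates the four ego-motion directions.}
#'   \item{forward_bias}{mean boost for forward relative to backward motion.}
#'   \item{turn_contra_bias}{mean boost for turns toward a hemisphere's
#'     contralateral hemifield (right hemisphere: left turns).}
#'   \item{consistency_gain}{extra mean response for consistent contralateral
#'     turns (turn toward the doorway), an interaction term on conditions
#'     7 (right hemisphere) and 10 (left hemisphere) only.}
#'   \item{room_texture_code}{scale of the voxel pattern separating the 8
#'     room textures (used by room-resolved simulation and decoding).}
#' }
#'
#' @param n_subjects Number of subjects.
#' @param n_runs Number of experimental runs per subject.
#' @param n_voxels Voxels per ROI-hemisphere entering analysis.
#' @param reps_per_run Stimulus repetitions per condition per run.
#' @param tr Repetition time in seconds.
#' @param n_volumes Volumes acquired per experimental run.
#' @param stim_duration Stimulus duration in seconds.
#' @param isi_range Minimum and maximum inter-stimulus interval in seconds.
#' @param level `"beta"` to simulate run-level response amplitudes directly,
#'   `"bold"` to simulate voxel time series for the GLM stage.
#' @param rois Character vector of ROI labels to simulate.
#' @param affordance_contra,ego_motion_code,forward_bias,turn_contra_bias,consistency_gain,room_texture_code
#'   Non-negative effect magnitudes (see Details).
#' @param noise_sd_run Within-run noise SD (per voxel, per condition estimate).
#' @param noise_sd_subject SD of the stable per-voxel subject offset.
#' @param baseline Baseline response amplitude, arbitrary units.
#' @param roi_gain Optional named numeric of per-ROI multipliers applied to
#'   every effect magnitude (default 1 for each ROI).
#' @param mask_size Voxels in each localizer mask from which ROIs are selected.
#' @param seed Integer seed; together with the other fields it fully
#'   determines all simulated output.
#' @return A list of class `navaff_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 4, seed = 1)
#' cfg$n_runs
#' @export
sim_config <- function(n_subjects = 16,
                       n_runs = 8,
                       n_voxels = 50,
                       reps_per_run = 4,
                       tr = 2,
                       n_volumes = 228,
                       stim_duration = 2.5,
                       isi_range = c(3.5, 9.5),
                       level = c("beta", "bold"),
                       rois = rois_default(),
                       affordance_contra = 1,
                       ego_motion_code = 1,
                       forward_bias = 0.5,
                       turn_contra_bias = 1,
                       consistency_gain = 1,
                       room_texture_code = 0.5,
                       noise_sd_run = 1,
                       noise_sd_subject = 0.5,
                       baseline = 100,
                       roi_gain = NULL,
                       mask_size = 150,
                       seed = 1L) {
  level <- match.arg(level)
  stopifnot(
    n_subjects >= 1, n_runs >= 1, n_voxels >= 1, reps_per_run >= 0,
    tr > 0, n_volumes >= 1, stim_duration > 0,
    length(isi_range) == 2, isi_range[1] <= isi_range[2], isi_range[1] >= 0,
    noise_sd_run >= 0, noise_sd_subject >= 0, mask_size >= n_voxels,
    is.numeric(seed), length(seed) == 1, is.finite(seed)
  )
  eff <- c(affordance_contra = affordance_contra,
           ego_motion_code = ego_motion_code,
           forward_bias = forward_bias,
           turn_contra_bias = turn_contra_bias,
           consistency_gain = consistency_gain,
           room_texture_code = room_texture_code)
  if (any(eff < 0)) {
    stop("effect magnitudes must be non-negative: ",
         paste(names(eff)[eff < 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(roi_gain)) {
    roi_gain <- stats::setNames(rep(1, length(rois)), rois)
  } else {
    if (!all(rois %in% names(roi_gain)))
      stop("roi_gain must name every ROI in `rois`", call. = FALSE)
    roi_gain <- roi_gain[rois]
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
         n_voxels = as.integer(n_voxels), reps_per_run = as.integer(reps_per_run),
         tr = tr, n_volumes = as.integer(n_volumes),
         stim_duration = stim_duration, isi_range = as.numeric(isi_range),
         level = level, rois = rois, effects = as.list(eff),
         noise_sd_run = noise_sd_run, noise_sd_subject = noise_sd_subject,
         baseline = baseline, roi_gain = roi_gain,
         mask_size = as.integer(mask_size), seed = as.integer(seed)),
    class = "navaff_config"
  )
}

#' @export
print.navaff_config <- function(x, ...) {
  cat("<navaff_config>\n")
  cat(sprintf("  %d subjects x %d runs, %d voxels/ROI-hemisphere, level = %s\n",
              x$n_subjects, x$n_runs, x$n_voxels, x$level))
  cat(sprintf("  TR %g s, %d volumes/run, %d reps/condition/run\n",
              x$tr, x$n_volumes, x$reps_per_run))
  cat("  effects (units of run noise SD):\n")
  for (nm in names(x$effects))
    cat(sprintf("    %-18s %g\n", nm, x$effects[[nm]]))
  cat(sprintf("  noise_sd_run %g, noise_sd_subject %g, seed %d\n",
              x$noise_sd_run, x$noise_sd_subject, x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' A flat, declarative JSON serialization of [sim_config()] so that runs can
#' be reproduced from a single file; the seed is mandatory on read.
#'
#' @param config A `navaff_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `navaff_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "navaff_config"))
  x <- config
  x$effects <- NULL
  x$roi_gain <- as.list(config$roi_gain)  # keep names in JSON
  x <- c(unclass(x), config$effects)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seed)) stop("config file must contain a seed", call. = FALSE)
  if (!is.null(x$roi_gain)) x$roi_gain <- unlist(x$roi_gain)
  do.call(sim_config, x[intersect(names(x), names(formals(sim_config)))])
}
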