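#' Simulate run-level condition response amplitudes (betas)
#'
#' Generates, for every subject x ROI x hemisphere x run, a voxels x
#' conditions matrix of response amplitudes with the lateralized effect
#' structure of the affordance/ego-motion design and known ground truth:
#'
#' * a contralateral-doorway boost (`affordance_contra`) on translation
#'   conditions whose doorway falls in the hemisphere's contralateral
#'   hemifield (right hemisphere: left-side doorways; both-door conditions
#'   boosted in both hemispheres),
#' * a forward-motion boost (`forward_bias`) on conditions 1-3,
#' * a contralateral-turn boost (`turn_contra_bias`; right hemisphere: left
#'   turns),
#' * a consistency interaction (`consistency_gain`) on consistent
#'   contralateral turns only (condition 7 in the right hemisphere, 10 in the
#'   left),
#' * a per-hemisphere voxel pattern separating ego-motion directions
#'   (`ego_motion_code`),
#' * a stable per-voxel subject offset (`noise_sd_subject`), and
#' * independent Gaussian run noise (`noise_sd_run`).
#'
#' With `by = "room"` the generator instead emits room-resolved patterns
#' (voxels x 8 room types) carrying the `room_texture_code` pattern, for the
#' room-texture decoding scheme.
#'
#' @param config A [sim_config()] with `level = "beta"`.
#' @param rois ROIs to simulate (default from the config).
#' @param by `"condition"` (default) or `"room"` for room-resolved patterns.
#' @return A tibble with columns `subject`, `roi`, `hemisphere`, `run`, and
#'   `betas` (list of voxels x conditions matrices), carrying the config and
#'   a `ground_truth` attribute (the expected, noise-free amplitude matrix
#'   per subject x ROI x hemisphere); retrieve it with [ground_truth()].
#' @examples
#' b <- simulate_betas(sim_config(n_subjects = 2, n_voxels = 8, seed = 1))
#' dim(b$betas[[1]])
#' @export
simulate_betas <- function(config, rois = config$rois,
                           by = c("condition", "room")) {
  stopifnot(inherits(config, "navaff_config"))
  by <- match.arg(by)
  if (config$level != "beta")
    stop("simulate_betas() requires a config with level = \"beta\"",
         call. = FALSE)
  grid <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    roi = rois,
    hemisphere = c("left", "right")
  )
  cells <- purrr::pmap(grid, function(subject, roi, hemisphere) {
    simulate_cell(config, subject, roi, hemisphere, by)
  })
  out <- tidyr::unnest(
    dplyr::mutate(grid,
                  run = list(seq_len(config$n_runs)),
                  betas = purrr::map(cells, "runs")),
    c("run", "betas")
  )
  gt <- dplyr::mutate(grid, expected = purrr::map(cells, "expected"))
  structure(out, config = config, ground_truth = gt,
            provenance = "experimental",
            class = c("navaff_betas", class(out)))
}

# Expected (noise-free) amplitude matrix for one subject/ROI/hemisphere cell,
# plus its n_runs noisy realizations.
simulate_cell <- function(config, subject, roi, hemisphere, by = "condition") {
  V <- config$n_voxels
  g <- cond_groups()
  roi_i <- match(roi, config$rois)
  hemi_i <- match(hemisphere, c("left", "right"))
  gain <- unname(config$roi_gain[roi])
  if (is.na(gain)) gain <- 1
  eff <- config$effects

  with_seed_(derive_seed(config$seed, 19L, subject, roi_i, hemi_i,
                         if (by == "room") 1L else 0L), function() {
    subj_off <- stats::rnorm(V, 0, config$noise_sd_subject)
    if (by == "room") {
      n_room <- 8L
      W <- matrix(stats::rnorm(V * n_room), V, n_room)
      M <- config$baseline + subj_off +
        gain * eff$room_texture_code * W
      colnames(M) <- as.character(seq_len(n_room))
    } else {
      contra <- if (hemisphere == "right") "left" else "right"
      ct <- condition_table()
      door_contra <- ct$affordance %in% c(contra, "both") &
        ct$condition_id %in% c(g$forward, g$backward)
      turn_contra <- ct$condition_id %in%
        (if (hemisphere == "right") g$left_turn else g$right_turn)
      cons_contra <- ct$condition_id ==
        (if (hemisphere == "right") 7L else 10L)
      bias <- gain * (eff$affordance_contra * door_contra +
                        eff$forward_bias * (ct$ego_motion == "forward") +
                        eff$turn_contra_bias * turn_contra +
                        eff$consistency_gain * cons_contra)
      ego_lab <- c("forward", "backward", "left_turn", "right_turn")
      U <- matrix(stats::rnorm(V * 4), V, 4)
      M <- config$baseline + subj_off +
        matrix(bias, V, 10, byrow = TRUE) +
        gain * eff$ego_motion_code * U[, match(ct$ego_motion, ego_lab)]
      colnames(M) <- as.character(ct$condition_id)
    }
    rownames(M) <- as.character(seq_len(V))
    C <- ncol(M)
    noise <- stats::rnorm(V * C * config$n_runs, 0, config$noise_sd_run)
    dim(noise) <- c(V, C, config$n_runs)
    runs <- lapply(seq_len(config$n_runs), function(r) {
      B <- M + noise[, , r]
      dimnames(B) <- dimnames(M)
      B
    })
    list(expected = M, runs = runs)
  })
}

#' Ground truth of a simulated dataset
#'
#' @param x An object produced by [simulate_betas()] or [simulate_bold()].
#' @return A tibble with one row per subject x ROI x hemisphere and an
#'   `expected` list-column holding the injected noise-free amplitude matrix.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Usable-run scenarios
#'
#' Assigns each subject a number of usable experimental runs, mimicking
#' run-level data exclusion. The default proportions reproduce the target
#' study's exclusion outcome -- 12 of 16 subjects with all 8 runs, 1 with 6,
#' and 3 with 5 -- and are rescaled (largest remainder) for other sample
#' sizes. Subjects are assigned to scenarios in a seeded random order.
#'
#' @param n_subjects Number of subjects.
#' @param proportions Named numeric: names are usable-run counts, values
#'   their relative frequencies.
#' @param seed Seed for the assignment order.
#' @return A tibble with columns `subject`, `usable_runs`.
#' @export
usable_run_scenarios <- function(n_subjects = 16,
                                 proportions = c(`8` = 12, `6` = 1, `5` = 3),
                                 seed = 1L) {
  counts <- as.integer(names(proportions))
  if (any(counts < 2))
    stop("usable run counts below 2 leave the split-half analysis undefined",
         call. = FALSE)
  quota <- proportions / sum(proportions) * n_subjects
  n_each <- floor(quota)
  rem <- n_subjects - sum(n_each)
  if (rem > 0) {
    extra <- order(quota - n_each, decreasing = TRUE)[seq_len(rem)]
    n_each[extra] <- n_each[extra] + 1
  }
  assign <- rep(counts, n_each)
  assign <- with_seed_(derive_seed(seed, 23L), function() sample(assign))
  tibble::tibble(subject = seq_len(n_subjects), usable_runs = assign)
}

#' Restrict simulated betas to usable runs
#'
#' @param betas A [simulate_betas()] table.
#' @param scenarios A [usable_run_scenarios()] table.
#' @return The filtered beta table (runs beyond each subject's usable count
#'   dropped), attributes preserved.
#' @export
apply_usable_runs <- function(betas, scenarios) {
  keep <- dplyr::left_join(
    betas[, c("subject", "run")], scenarios, by = "subject")
  if (anyNA(keep$usable_runs))
    stop("scenarios table must cover every subject", call. = FALSE)
  out <- betas[keep$run <= keep$usable_runs, ]
  for (a in c("config", "ground_truth", "provenance"))
    attr(out, a) <- attr(betas, a)
  out
}

#' Simulate localizer category responses
#'
#' Produces per-voxel localizer response amplitudes over the candidate mask
#' of each ROI-hemisphere, for ROI selection. Scene-selective ROIs (OPA,
#' PPA, MPA) carry a positive scenes-over-objects selectivity gradient across
#' mask voxels; EVC carries a general visual drive for all categories over
#' fixation. The output is tagged with localizer provenance so that ROI
#' selection can assert its independence from the experimental runs.
#'
#' @param config A [sim_config()]; `mask_size` sets the candidate voxels per
#'   ROI-hemisphere.
#' @return A tibble with columns `subject`, `roi`, `hemisphere`, `voxel`, and
#'   response amplitudes `scenes`, `objects`, `faces`, `scrambled`,
#'   `fixation`.
#' @export
simulate_localizer <- function(config) {
  stopifnot(inherits(config, "navaff_config"))
  grid <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    roi = config$rois,
    hemisphere = c("left", "right")
  )
  cells <- purrr::pmap(grid, function(subject, roi, hemisphere) {
    V <- config$mask_size
    with_seed_(derive_seed(config$seed, 29L, subject,
                           match(roi, config$rois),
                           match(hemisphere, c("left", "right"))), function() {
      drive <- stats::rnorm(V, 1, 0.3)
      sel <- if (roi == "EVC") rep(0, V) else stats::rnorm(V, 1.5, 0.5)
      noise <- function() stats::rnorm(V, 0, 0.3)
      tibble::tibble(
        voxel = seq_len(V),
        scenes = drive + sel + noise(),
        objects = drive + noise(),
        faces = drive + noise(),
        scrambled = drive + noise(),
        fixation = noise()
      )
    })
  })
  out <- tidyr::unnest(dplyr::mutate(grid, data = cells), "data")
  structure(out, config = config, provenance = "localizer")
}
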