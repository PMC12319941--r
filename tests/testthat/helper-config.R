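# Small configurations used across tests: one ROI and few voxels keep the
# Monte-Carlo loops fast while exercising the same code paths as the
# full-scale design.

tiny_config <- function(seed = 1L, ...) {
  args <- list(n_subjects = 1, n_voxels = 6, n_runs = 4, rois = "OPA",
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Zero out every injected effect (null world).
null_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, affordance_contra = 0, ego_motion_code = 0,
              forward_bias = 0, turn_contra_bias = 0, consistency_gain = 0,
              room_texture_code = 0, ...)
}

# Noise-free configuration: deterministic expectations become exact.
exact_config <- function(seed = 1L, ...) {
  null_config(seed = seed, noise_sd_run = 0, noise_sd_subject = 0, ...)
}

# Mean +/- 3 Monte-Carlo standard errors covers zero?
within_3se <- function(x, target = 0) {
  se <- stats::sd(x) / sqrt(length(x))
  abs(mean(x) - target) <= 3 * se
}

random_means_table <- function(seed = 99, n_subjects = 4, roi = "OPA") {
  set.seed(seed)
  tidyr::expand_grid(subject = seq_len(n_subjects), roi = roi,
                     hemisphere = c("left", "right"), condition_id = 1:10) |>
    dplyr::mutate(response = stats::rnorm(dplyr::n()))
}
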