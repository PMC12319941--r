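#' ROI-mean condition responses
#'
#' Averages all voxels of each ROI-hemisphere within each run, then averages
#' across runs (run-then-grand order), yielding each subject's mean response
#' to each condition per ROI and hemisphere.
#'
#' @param betas A beta table ([simulate_betas()] / [fit_experiment_glm()]).
#' @param scenarios Optional [usable_run_scenarios()] table applied first.
#' @return A tibble: `subject`, `roi`, `hemisphere`, `condition_id`,
#'   `response`.
#' @export
condition_means <- function(betas, scenarios = NULL) {
  if (!is.null(scenarios)) betas <- apply_usable_runs(betas, scenarios)
  if (any(vapply(betas$betas, nrow, integer(1)) == 0))
    stop("empty ROI: beta matrix with zero voxels", call. = FALSE)
  C <- ncol(betas$betas[[1]])
  cm <- t(vapply(betas$betas, colMeans, numeric(C)))  # per-run voxel means
  key <- paste(betas$subject, betas$roi, betas$hemisphere, sep = "\r")
  fkey <- factor(key, levels = unique(key))
  avg <- rowsum(cm, fkey, reorder = FALSE) / as.vector(table(fkey))
  first <- !duplicated(key)
  tibble::tibble(
    subject = rep(betas$subject[first], each = C),
    roi = rep(betas$roi[first], each = C),
    hemisphere = rep(betas$hemisphere[first], each = C),
    condition_id = rep(as.integer(colnames(betas$betas[[1]])),
                       times = sum(first)),
    response = as.vector(t(avg))
  )
}

# Shared core for lateralized contrasts. `sets` gives, per hemisphere, the
# condition ids whose mean forms the "contra" and "ipsi" values; each
# hemisphere's contra/ipsi means are computed first and then averaged
# (unweighted) across hemispheres.
lateralized_contrast <- function(means, name, sets) {
  lab <- dplyr::bind_rows(purrr::imap(sets, function(s, h) {
    tibble::tibble(hemisphere = h,
                   condition_id = c(s$contra, s$ipsi),
                   role = rep(c("contra", "ipsi"),
                              c(length(s$contra), length(s$ipsi))))
  }))
  d <- dplyr::inner_join(means, lab, by = c("hemisphere", "condition_id"))
  got <- d |>
    dplyr::count(.data$subject, .data$roi)
  if (any(got$n != nrow(lab)))
    stop("contrast ", name, " requires both hemispheres and conditions ",
         paste(sort(unique(lab$condition_id)), collapse = ", "),
         call. = FALSE)
  d |>
    dplyr::group_by(.data$subject, .data$roi, .data$hemisphere, .data$role) |>
    dplyr::summarise(v = mean(.data$response), .groups = "drop") |>
    dplyr::group_by(.data$subject, .data$roi, .data$role) |>
    dplyr::summarise(v = mean(.data$v), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "v") |>
    dplyr::mutate(contrast = name, diff = .data$contra - .data$ipsi) |>
    dplyr::relocate("contrast", .after = "roi")
}

#' Contralateral doorway vs painting contrast
#'
#' Among the single-door translation conditions (2, 3, 5, 6), each
#' hemisphere's "contra" value is the mean response to conditions whose open
#' doorway falls in its contralateral hemifield (right hemisphere:
#' left-door conditions 2 and 5) and "ipsi" the mean for doorways in the
#' ipsilateral hemifield; values are averaged across hemispheres and
#' `diff = contra - ipsi`.
#'
#' @param means A [condition_means()] table.
#' @return A tibble: `subject`, `roi`, `contrast`, `contra`, `ipsi`, `diff`.
#' @export
contra_door_contrast <- function(means) {
  g <- cond_groups()
  ld <- intersect(g$door_left, c(g$forward, g$backward))   # 2, 5
  rd <- intersect(g$door_right, c(g$forward, g$backward))  # 3, 6
  lateralized_contrast(means, "contra_door",
                       list(right = list(contra = ld, ipsi = rd),
                            left = list(contra = rd, ipsi = ld)))
}

#' Forward vs backward motion contrast
#'
#' Whole-field contrast: mean response over the forward conditions (1-3)
#' minus the backward conditions (4-6), hemisphere-averaged.
#'
#' @param means A [condition_means()] table.
#' @return A tibble: `subject`, `roi`, `contrast`, `forward`, `backward`,
#'   `diff`.
#' @export
forward_backward_contrast <- function(means) {
  g <- cond_groups()
  d <- means[means$condition_id %in% c(g$forward, g$backward), ]
  got <- dplyr::count(d, .data$subject, .data$roi)
  if (any(got$n != 12))
    stop("forward/backward contrast requires conditions 1-6 in both hemispheres",
         call. = FALSE)
  d |>
    dplyr::group_by(.data$subject, .data$roi, .data$hemisphere) |>
    dplyr::summarise(
      fwd = mean(.data$response[.data$condition_id %in% g$forward]),
      bwd = mean(.data$response[.data$condition_id %in% g$backward]),
      .groups = "drop") |>
    dplyr::group_by(.data$subject, .data$roi) |>
    dplyr::summarise(forward = mean(.data$fwd), backward = mean(.data$bwd),
                     .groups = "drop") |>
    dplyr::mutate(contrast = "forward_backward",
                  diff = .data$forward - .data$backward) |>
    dplyr::relocate("contrast", .after = "roi")
}

#' Contralateral vs ipsilateral turn contrast
#'
#' Each hemisphere's "contra" value is the mean response to turns toward its
#' contralateral hemifield (right hemisphere: left turns, conditions 7-8)
#' and "ipsi" to turns toward the ipsilateral hemifield; hemisphere-averaged,
#' `diff = contra - ipsi`.
#'
#' @param means A [condition_means()] table.
#' @return A tibble: `subject`, `roi`, `contrast`, `contra`, `ipsi`, `diff`.
#' @export
turn_direction_contrast <- function(means) {
  g <- cond_groups()
  lateralized_contrast(means, "turn_direction",
                       list(right = list(contra = g$left_turn,
                                         ipsi = g$right_turn),
                            left = list(contra = g$right_turn,
                                        ipsi = g$left_turn)))
}

#' Consistent vs inconsistent turns by visual field
#'
#' Within each hemisphere's contralateral-field turns, the difference
#' between the consistent turn (toward the doorway; condition 7 for the
#' right hemisphere, 10 for the left) and the inconsistent turn (toward the
#' painting; 8 right-hemisphere, 9 left), and the analogous construction
#' within ipsilateral-field turns; both hemisphere-averaged. A region that
#' integrates affordance and ego-motion responds more to consistent
#' contralateral turns, with no such difference for ipsilateral turns.
#'
#' @param means A [condition_means()] table.
#' @return A tibble with two rows per subject x ROI (`contrast` =
#'   `"consistency_contra"`, `"consistency_ipsi"`): `consistent`,
#'   `inconsistent`, `diff`.
#' @export
consistency_by_field_contrast <- function(means) {
  g <- cond_groups()
  lab <- dplyr::bind_rows(purrr::map(c("left", "right"), function(h) {
    contra_turns <- if (h == "right") g$left_turn else g$right_turn
    tibble::tibble(hemisphere = h, condition_id = g$turns) |>
      dplyr::mutate(
        field = ifelse(.data$condition_id %in% contra_turns,
                       "contra", "ipsi"),
        status = ifelse(.data$condition_id %in% g$consistent,
                        "consistent", "inconsistent"))
  }))
  d <- dplyr::inner_join(means, lab, by = c("hemisphere", "condition_id"))
  got <- dplyr::count(d, .data$subject, .data$roi)
  if (any(got$n != nrow(lab)) || nrow(got) == 0)
    stop("consistency contrast requires the turn conditions 7-10 in both hemispheres",
         call. = FALSE)
  d |>
    dplyr::group_by(.data$subject, .data$roi, .data$field, .data$status) |>
    dplyr::summarise(v = mean(.data$response), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "status", values_from = "v") |>
    dplyr::mutate(contrast = paste0("consistency_", .data$field),
                  diff = .data$consistent - .data$inconsistent) |>
    dplyr::select("subject", "roi", "contrast", "consistent",
                  "inconsistent", "diff") |>
    dplyr::arrange(.data$subject, .data$roi, .data$contrast)
}

#' All lateralized and whole-field contrasts
#'
#' Convenience wrapper computing every univariate contrast as one long
#' table.
#'
#' @param means A [condition_means()] table.
#' @return A tibble: `subject`, `roi`, `contrast`, `diff` (plus the
#'   contrast-specific component columns where shared).
#' @export
roi_contrasts <- function(means) {
  dplyr::bind_rows(
    contra_door_contrast(means)[, c("subject", "roi", "contrast", "diff")],
    forward_backward_contrast(means)[, c("subject", "roi", "contrast", "diff")],
    turn_direction_contrast(means)[, c("subject", "roi", "contrast", "diff")],
    consistency_by_field_contrast(means)[, c("subject", "roi", "contrast",
                                             "diff")]
  )
}

#' Group-level contrast test
#'
#' Paired/one-sample t-test of each contrast's difference against zero, per
#' ROI.
#'
#' @param contrasts Long contrast table from [roi_contrasts()] (or one of
#'   the individual contrast functions).
#' @param tails 1 (directional, diff > 0) or 2.
#' @return A tidy tibble: `roi`, `contrast`, `n`, `mean_diff`, `t`, `df`,
#'   `p`.
#' @export
group_contrast_test <- function(contrasts, tails = 1) {
  key <- paste(contrasts$roi, contrasts$contrast, sep = "\r")
  idx <- split(seq_len(nrow(contrasts)),
               factor(key, levels = sort(unique(key))))
  rows <- lapply(idx, function(ix) {
    tt <- paired_t(contrasts$diff[ix], rep(0, length(ix)), tails = tails,
                   direction = "greater")
    tibble::tibble(roi = contrasts$roi[ix[1]],
                   contrast = contrasts$contrast[ix[1]],
                   n = length(ix), mean_diff = mean(contrasts$diff[ix]),
                   t = tt$t, df = tt$df, p = tt$p)
  })
  dplyr::bind_rows(rows)
}
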