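#' Localizer selection statistic
#'
#' Per-voxel contrast value used to rank voxels for ROI selection:
#' `"scenes_gt_objects"` (scene-selective ROIs) is the scenes-minus-objects
#' response; `"all_gt_fixation"` (early visual cortex) is the mean response
#' over all stimulus categories minus fixation. Inputs must carry localizer
#' provenance -- selection never sees experimental-run estimates.
#'
#' @param localizer A localizer response table ([simulate_localizer()] or a
#'   user table with the same category columns), grouped by any of
#'   `subject`, `roi`, `hemisphere`.
#' @param scheme `"scenes_gt_objects"` or `"all_gt_fixation"`.
#' @return The input table's grouping columns plus `voxel` and `statistic`.
#' @export
selection_statistic <- function(localizer,
                                scheme = c("scenes_gt_objects",
                                           "all_gt_fixation")) {
  scheme <- match.arg(scheme)
  prov <- attr(localizer, "provenance")
  if (!is.null(prov) && !identical(prov, "localizer"))
    stop("ROI selection must use localizer data; got provenance \"", prov,
         "\"", call. = FALSE)
  need <- if (scheme == "scenes_gt_objects") c("scenes", "objects")
          else c("scenes", "objects", "faces", "scrambled", "fixation")
  missing <- setdiff(need, names(localizer))
  if (length(missing))
    stop("localizer table lacks condition columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  stat <- if (scheme == "scenes_gt_objects") {
    localizer$scenes - localizer$objects
  } else {
    (localizer$scenes + localizer$objects + localizer$faces +
       localizer$scrambled) / 4 - localizer$fixation
  }
  keep <- intersect(c("subject", "roi", "hemisphere", "voxel"),
                    names(localizer))
  out <- dplyr::mutate(localizer[, keep], statistic = stat)
  structure(out, provenance = "localizer")
}

#' Select the top-N voxels of a functional ROI
#'
#' Ranks mask voxels by the selection statistic (descending) within each
#' subject x ROI x hemisphere group and keeps the top `n`; selected voxels
#' need not be contiguous. Ties at the cut are broken toward the lowest
#' voxel id (deterministic). A mask smaller than `n` selects all its voxels
#' with a warning; an optional `threshold` first drops voxels whose
#' statistic falls below it (mirroring a significance-thresholded mask).
#'
#' @param stats A statistic table from [selection_statistic()] (columns
#'   `voxel`, `statistic`, plus grouping columns).
#' @param n Voxels to select per group (default 50).
#' @param mask Optional voxel-id vector restricting the candidate set.
#' @param threshold Optional minimum statistic for a voxel to be eligible.
#' @return A tibble of the selected voxels: grouping columns, `voxel`,
#'   `statistic`, and `rank` (1 = largest statistic), ordered by rank within
#'   group.
#' @export
select_top_voxels <- function(stats, n = 50, mask = NULL, threshold = NULL) {
  prov <- attr(stats, "provenance")
  if (!is.null(prov) && !identical(prov, "localizer"))
    stop("ROI selection must use localizer data; got provenance \"", prov,
         "\"", call. = FALSE)
  if (!is.null(mask)) stats <- stats[stats$voxel %in% mask, , drop = FALSE]
  if (!is.null(threshold))
    stats <- stats[stats$statistic >= threshold, , drop = FALSE]
  if (nrow(stats) == 0)
    stop("empty mask: no candidate voxels to select from", call. = FALSE)
  grp <- intersect(c("subject", "roi", "hemisphere"), names(stats))
  if (anyNA(stats$statistic))
    stop("selection statistic undefined (NA) for some mask voxels",
         call. = FALSE)
  out <- stats |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(dplyr::desc(.data$statistic), .data$voxel,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= n) |>
    dplyr::ungroup()
  short <- out |>
    dplyr::count(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::filter(.data$n < !!n)
  if (nrow(short))
    warning(sprintf("%d group(s) have masks smaller than n = %d; all mask voxels selected",
                    nrow(short), n), call. = FALSE)
  out
}
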