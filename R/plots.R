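#' Plot decoding difference scores
#'
#' Bar plot of the group-mean within-minus-between difference score per ROI
#' and scheme, with individual-subject points; positive values indicate
#' smaller cross-split distances for same-information pairs, i.e. decoding.
#'
#' @param scores Output of [decode_patterns()].
#' @return A ggplot object.
#' @export
plot_decoding_scores <- function(scores) {
  summ <- scores |>
    dplyr::group_by(.data$roi, .data$scheme) |>
    dplyr::summarise(mean_diff = mean(.data$diff),
                     se = stats::sd(.data$diff) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$roi, y = .data$mean_diff)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_diff - .data$se,
                                        ymax = .data$mean_diff + .data$se),
                           width = 0.2) +
    ggplot2::geom_jitter(data = scores,
                         ggplot2::aes(y = .data$diff), width = 0.12,
                         alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scheme)) +
    ggplot2::labs(x = NULL, y = "between - within distance (AU)") +
    ggplot2::theme_classic()
}

#' Plot univariate contrast differences
#'
#' @param contrasts Long contrast table from [roi_contrasts()].
#' @return A ggplot object.
#' @export
plot_contrasts <- function(contrasts) {
  summ <- contrasts |>
    dplyr::group_by(.data$roi, .data$contrast) |>
    dplyr::summarise(mean_diff = mean(.data$diff),
                     se = stats::sd(.data$diff) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$roi, y = .data$mean_diff)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_diff - .data$se,
                                        ymax = .data$mean_diff + .data$se),
                           width = 0.2) +
    ggplot2::geom_jitter(data = contrasts,
                         ggplot2::aes(y = .data$diff), width = 0.12,
                         alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "contrast difference (AU)") +
    ggplot2::theme_classic()
}

#' Plot a condition distance matrix
#'
#' @param distances A conditions x conditions matrix (e.g. one entry of
#'   [subject_distances()]`$distances`).
#' @return A ggplot object.
#' @export
plot_distance_matrix <- function(distances) {
  df <- tidyr::expand_grid(cond_a = rownames(distances),
                           cond_b = colnames(distances)) |>
    dplyr::mutate(distance = as.vector(t(distances)))
  ggplot2::ggplot(df, ggplot2::aes(.data$cond_b, .data$cond_a,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(rownames(distances))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "condition (half B)", y = "condition (half A)",
                  fill = "distance (AU)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Draw a hypothesis matrix
#'
#' @param object A [build_hypothesis_matrix()] object.
#' @param ... Unused.
#' @return A ggplot object showing within / between / excluded cells.
#' @export
autoplot.hypothesis_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cond_b), factor(.data$cond_a),
                                   fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(factor(df$cond_a)))) +
    ggplot2::scale_fill_manual(values = c(within = "#f4c542",
                                          between = "#2f6f9e",
                                          excluded = "grey85")) +
    ggplot2::labs(title = attr(object, "scheme"),
                  x = "condition", y = "condition", fill = NULL) +
    ggplot2::theme_minimal()
}
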