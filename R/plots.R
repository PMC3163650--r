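#' MA-plot of one array with its fitted correction curve
#'
#' @param ma An MA tibble from any normalization stage.
#' @param array Array id to plot (default: first).
#' @param sample_n Spots are down-sampled to at most this many points.
#' @return A ggplot object.
#' @export
plot_ma <- function(ma, array = NULL, sample_n = 5000L) {
  assert_cols(ma, c("array_id", "M", "A"))
  array <- array %||% ma$array_id[1]
  d <- dplyr::filter(ma, .data$array_id == array, !is.na(.data$M))
  if (nrow(d) > sample_n) d <- dplyr::slice_sample(d, n = sample_n)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(title = paste("MA-plot:", array),
                  subtitle = paste("state:", unique(d$state)),
                  x = "A = log2 sqrt(R*G)", y = "M = log2(R/G)") +
    ggplot2::theme_minimal()
  curve <- attr(ma, "curve")
  if (!is.null(curve)) {
    cv <- dplyr::filter(curve, .data$array_id == array)
    p <- p + ggplot2::geom_line(data = cv,
                                ggplot2::aes(x = .data$A, y = .data$c_hat),
                                colour = "red")
  }
  p
}

#' Volcano-style plot of a permutation DE result
#'
#' @param object A `de_result`.
#' @param p_threshold Adjusted p-value drawn as a horizontal guide.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, p_threshold = 0.05, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_M,
                                  y = -log10(pmax(.data$p_adj, 1e-6)),
                                  colour = .data$p_adj < p_threshold)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 name = paste("p_adj <", p_threshold)) +
    ggplot2::labs(x = "mean M = log2(HAB/LAB)", y = "-log10 adjusted p",
                  title = if (!is.na(object$region))
                    paste("Region", object$region) else NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of qPCR fold-regulation values with SEM
#'
#' @param object A `fold_table` from [fold_regulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fold_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$fold,
                                       fill = .data$reference)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold - .data$sem,
                                        ymax = .data$fold + .data$sem),
                           width = 0.2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "grey60"),
                               name = "reference") +
    ggplot2::labs(y = "fold regulation (vs lowest-expressing group)") +
    ggplot2::theme_minimal()
}

#' Variant map of a locus
#'
#' Positions of annotated variants along the TSS-relative axis, coloured
#' by type and shaped by region class.
#'
#' @param variants Annotated variant tibble.
#' @return A ggplot object.
#' @export
plot_variant_map <- function(variants) {
  assert_cols(variants, c("type", "rel_position", "location"))
  d <- dplyr::mutate(variants, class = region_class(.data$location))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_position, y = .data$class,
                                  colour = .data$type)) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "position relative to transcription start (bp)",
                  y = NULL, colour = "type") +
    ggplot2::theme_minimal()
}
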