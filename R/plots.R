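# ggplot2 displays for the main result types.

#' Gene-structure diagram
#'
#' Exons as boxes, introns as lines, with the splicing modes available at
#' each intron annotated above it.
#'
#' @param object A `gene_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_model
#' @export
autoplot.gene_model <- function(object, ...) {
  exons <- model_exons(object)
  ints <- object$introns
  labels <- if (!is.null(object$states)) {
    vapply(ints$intron, function(id) {
      paste(setdiff(object$states[[id]], "canonical"), collapse = "\n")
    }, character(1))
  } else {
    rep("", nrow(ints))
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ints,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
      linewidth = 0.4
    ) +
    ggplot2::geom_rect(
      data = exons,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.25, ymax = 0.25),
      fill = "grey35"
    ) +
    ggplot2::geom_text(
      data = dplyr::mutate(ints, label = labels,
                           mid = (.data$start + .data$end) / 2),
      ggplot2::aes(x = .data$mid, y = 0.45, label = .data$label),
      size = 2.8, vjust = 0
    ) +
    ggplot2::scale_y_continuous(limits = c(-0.6, 1), breaks = NULL) +
    ggplot2::labs(x = paste0(object$gene_id, " (bp)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Relative-expression bar chart
#'
#' 2^-ddCt fold changes with delta-method standard errors, faceted by gene.
#'
#' @param object An `expression_result`.
#' @param letters Optional tibble with `gene`, `condition`, `letter` to
#'   print over the bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot expression_result
#' @export
autoplot.expression_result <- function(object, letters = NULL, ...) {
  df <- object$summary
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$fold)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fold - .data$se, ymax = .data$fold + .data$se),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
  if (!is.null(letters)) {
    df2 <- dplyr::left_join(df, letters, by = c("gene", "condition"))
    p <- p + ggplot2::geom_text(
      data = df2,
      ggplot2::aes(y = .data$fold + 2 * .data$se, label = .data$letter),
      vjust = 0
    )
  }
  p
}

#' Coverage profile plot
#'
#' @param profile Result of [coverage_profile()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(profile) {
  ggplot2::ggplot(profile$depth, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey60") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "reference position (bp)", y = "depth") +
    ggplot2::theme_minimal()
}
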