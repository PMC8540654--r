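#' Ordination scatter plot
#'
#' First two ordination axes, optionally coloured by a grouping vector (e.g.
#' BC-load category).
#'
#' @param object An `ordination` from [pcoa()] or [nmds()].
#' @param groups Optional label per sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ordination <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  axes <- setdiff(names(df), "sample_id")[1:2]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                        y = .data[[axes[2]]]))
  if (!is.null(groups)) {
    df$group <- as.character(groups)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                          y = .data[[axes[2]]],
                                          colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = paste(object$method, "ordination"),
                  subtitle = if (!is.null(object$stress))
                    sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Rarefaction curve plot
#'
#' @param curves Output of [rarefaction_curves()].
#' @param colour_by Optional named vector mapping sample ids to a grouping.
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curves, colour_by = NULL) {
  df <- curves
  if (!is.null(colour_by)) df$group <- colour_by[df$sample_id]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$mean_observed,
                                   group = .data$sample_id,
                                   colour = if (is.null(colour_by)) NULL
                                            else .data$group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "reads subsampled", y = "mean observed taxa",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Indicator-taxon effect bar chart
#'
#' Horizontal bars of LDA log10 scores per reported taxon, faceted by the
#' enriched group, mirroring the usual effect-size panel.
#'
#' @param indicators Output of [indicator_taxa()].
#' @return A ggplot object.
#' @export
plot_indicators <- function(indicators) {
  if (nrow(indicators) == 0L)
    abort("no indicators to plot.")
  df <- indicators
  df$label <- paste0(df$taxon, " (", df$rank_letter, ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lda_score,
                                   y = stats::reorder(.data$label, .data$lda_score),
                                   fill = .data$enriched_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(log[10] ~ "LDA score"), y = NULL,
                  fill = "enriched in") +
    ggplot2::theme_minimal()
}
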