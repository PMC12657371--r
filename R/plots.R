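# ggplot2 views of the result types: correlation heatmap, group box plots,
# mediation path diagram.

#' Correlation heatmap
#'
#' Tile plot of partial correlations from [partial_correlation_matrix()],
#' annotated with the coefficient and starred where the FDR-adjusted q-value
#' falls below `q_cutoff`.
#'
#' @param pc Tibble from [partial_correlation_matrix()].
#' @param q_cutoff Significance cut-off on the q-value.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(pc, q_cutoff = 0.05) {
  pc$label <- sprintf("%.2f%s", pc$r, ifelse(pc$q_value < q_cutoff, "*", ""))
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Group comparison box plot
#'
#' @param data Cohort tibble.
#' @param value Column to plot.
#' @param group Grouping column (default `"group"`).
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(data, value, group = "group") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]], y = .data[[value]],
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Mediation path diagram
#'
#' Draws the X -> M -> Y triangle with the fitted path coefficients, the
#' direct effect, and the bootstrap interval of the indirect effect.
#'
#' @param object A `glymph_mediation` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glymph_mediation
#' @export
autoplot.glymph_mediation <- function(object, ...) {
  p <- object$paths
  est <- function(path) p$estimate[p$path == path]
  pval <- function(path) p$p_value[p$path == path]
  star <- function(pv) if (pv < 0.001) "***" else if (pv < 0.01) "**"
    else if (pv < 0.05) "*" else ""
  lab <- function(path) sprintf("%s = %.3f%s", path, est(path), star(pval(path)))
  nodes <- data.frame(
    x = c(0, 1, 2), y = c(0, 1, 0),
    label = c(object$x, object$m, object$y)
  )
  edges <- data.frame(
    x = c(0.12, 1.12, 0.15), y = c(0.12, 0.88, 0),
    xend = c(0.88, 1.88, 1.85), yend = c(0.88, 0.12, 0),
    label = c(lab("a"), lab("b"),
              sprintf("%s  (c = %.3f)", lab("c_prime"), est("c")))
  )
  sub <- sprintf("indirect a*b = %.3f, %d%% CI [%.3f, %.3f]%s",
                 object$indirect, round(100 * object$conf_level),
                 object$ci_low, object$ci_high,
                 if (is.finite(object$mediation_percent %||% NA_real_))
                   sprintf(", mediated %.1f%%", object$mediation_percent) else "")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"))) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$label)) +
    ggplot2::geom_text(data = edges,
                       ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                    y = (.data$y + .data$yend) / 2 + 0.08,
                                    label = .data$label), size = 3.2) +
    ggplot2::labs(subtitle = sub) +
    ggplot2::xlim(-0.3, 2.3) + ggplot2::ylim(-0.3, 1.3) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
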