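# ggplot2 views of the main result types.

#' @export
autoplot.bn_arc_strength <- function(object, threshold = 0.30, ...) {
  tbl <- tibble::as_tibble(object)
  tbl <- tbl[!is.na(tbl$direction) & tbl$from < tbl$to, , drop = FALSE]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$support)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "bootstrap support (either direction)", y = "node pairs",
      title = "Arc-strength distribution",
      subtitle = sprintf("consensus threshold %.2f", threshold)
    )
}

#' @export
autoplot.bn_metrics <- function(object, ...) {
  tbl <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar(fill = "grey35") +
    ggplot2::labs(
      x = "node degree (in + out)", y = "nodes",
      title = "Degree distribution of the consensus network"
    )
}

#' @export
autoplot.bn_ordination <- function(object, colour = NULL, ...) {
  tbl <- tibble::as_tibble(object)
  if (!is.null(colour)) tbl$colour <- colour
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::labs(
      title = "NMDS ordination",
      subtitle = sprintf("stress = %.3f", attr(object, "stress"))
    )
  if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), alpha = 0.7) +
      ggplot2::labs(colour = NULL)
  }
}

#' Heat map of a parent-configuration sweep
#'
#' Plots `P(target = level | parent configuration)` from [parent_sweep()]
#' as a tile map over parent states.
#'
#' @param sweep Output of [parent_sweep()].
#' @param level Target level to display (default: last level).
#' @return A ggplot object.
#' @export
plot_parent_sweep <- function(sweep, level = NULL) {
  level <- level %||% utils::tail(unique(sweep$level), 1)
  tbl <- sweep[sweep$level == level, , drop = FALSE]
  pa <- setdiff(names(tbl), c("level", "prob"))
  tbl$config <- apply(tbl[, pa, drop = FALSE], 1, paste, collapse = "/")
  tbl$config <- factor(tbl$config, levels = tbl$config[order(tbl$prob)])
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$config, y = 1, fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey90", high = "grey10", limits = c(0, 1)) +
    ggplot2::labs(
      x = paste(pa, collapse = " / "), y = NULL, fill = sprintf("P(%s)", level),
      title = "Conditional probability over parent configurations"
    ) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1),
      axis.text.y = ggplot2::element_blank(),
      axis.ticks.y = ggplot2::element_blank()
    )
}
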