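#' Plot a Ward.D2 dendrogram
#'
#' Classic rectangular dendrogram with merge heights on the distance scale.
#'
#' @param object A [ward_d2_linkage()] result.
#' @param labels Show leaf labels (default on for <= 60 leaves).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ward_dendrogram <- function(object, labels = object$n <= 60, ...) {
  ord <- leaf_order(object)
  xpos <- numeric(object$n)          # leaf x positions in plotting order
  xpos[ord] <- seq_len(object$n)
  node_x <- numeric(length(object$height))
  node_y <- object$height
  seg <- vector("list", length(object$height))
  child_xy <- function(id, s) {
    if (id < 0) c(xpos[-id], 0) else c(node_x[id], node_y[id])
  }
  for (s in seq_along(object$height)) {
    a <- child_xy(object$merge[s, 1], s)
    b <- child_xy(object$merge[s, 2], s)
    node_x[s] <- (a[1] + b[1]) / 2
    seg[[s]] <- tibble(
      x = c(a[1], b[1], a[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_y[s]),
      yend = c(node_y[s], node_y[s], node_y[s])
    )
  }
  segs <- dplyr::bind_rows(seg)
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::labs(x = NULL, y = "merge height (Ward.D2)") +
    ggplot2::theme_minimal()
  if (labels) {
    p <- p + ggplot2::scale_x_continuous(
      breaks = seq_len(object$n), labels = object$labels[ord]
    ) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         hjust = 1,
                                                         vjust = 0.5))
  } else {
    p <- p + ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
  p
}

#' Heatmap of a heterosis table
#'
#' Cross x trait tile map of mid-parent (or better-parent) heterosis.
#'
#' @param object A [heterosis_table()] result.
#' @param metric `"mph"` or `"bph"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.heterosis_tbl <- function(object, metric = c("mph", "bph"), ...) {
  metric <- match.arg(metric)
  lab <- c(mph = "mid-parent heterosis (%)",
           bph = "better-parent heterosis (%)")[metric]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$trait, y = .data$cross,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  name = lab) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of combining-ability effects
#'
#' GCA effects per parent, faceted by role, with error bars of one standard
#' error when the trial supplies an error variance.
#'
#' @param object An [combining_ability()] `lxt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lxt_fit <- function(object, ...) {
  g <- object$gca
  p <- ggplot2::ggplot(g, ggplot2::aes(x = stats::reorder(.data$parent,
                                                          .data$gca),
                                       y = .data$gca)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$role, scales = "free_x") +
    ggplot2::labs(x = NULL,
                  y = paste0("GCA effect",
                             if (!is.null(object$trait))
                               paste0(" (", object$trait, ")"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!all(is.na(g$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gca - .data$se,
                   ymax = .data$gca + .data$se), width = 0.2)
  }
  p
}
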