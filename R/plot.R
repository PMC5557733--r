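# ggplot2 views of the per-node maps: orthographic projections of the
# averaged surface nodes coloured by significance band or displacement.

.project_axes <- function(view) {
  switch(view,
         lateral = c("z", "y"),
         medial = c("z", "y"),
         superior = c("z", "x"),
         inferior = c("z", "x"),
         posterior = c("x", "y"),
         stopf("unknown view '%s'", view))
}

#' Plot a significance probability map
#'
#' Orthographic projection of the averaged model nodes coloured with the
#' four-band palette (blue p <= 0.05, pale pink p <= 0.01, dark pink
#' p <= 0.001, purple p <= 0.0001).
#'
#' @param sig a \code{significance_map}.
#' @param model an \code{averaged_model} (node positions to draw).
#' @param axis which coordinate's test to show ("x", "y" or "z").
#' @param view projection ("lateral", "medial", "superior", "inferior",
#'   "posterior").
#' @return a ggplot object.
#' @export
plot_significance_map <- function(sig, model, axis = "y",
                                  view = "lateral") {
  ax <- match.arg(axis, AXIS_NAMES)
  pa <- .project_axes(view)
  nodes <- as.data.frame(model$mean)
  names(nodes) <- AXIS_NAMES
  nodes$band <- factor(ifelse(is.na(sig$category[, ax]), "ns",
                              sig$category[, ax]),
                       levels = names(.sig_palette))
  ggplot2::ggplot(nodes,
                  ggplot2::aes(.data[[pa[1]]], .data[[pa[2]]],
                               colour = .data$band)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = .sig_palette, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Significance map, %s-axis (%s view)",
                                  ax, view),
                  x = paste(pa[1], "(mm)"), y = paste(pa[2], "(mm)"),
                  colour = "p band") +
    ggplot2::theme_minimal()
}

#' Plot a displacement difference map
#'
#' Orthographic projection coloured by the signed per-node displacement on
#' one axis (red = group A greater, blue = group B greater).
#'
#' @param diff a \code{difference_map}.
#' @param model an \code{averaged_model} for node positions.
#' @param axis displacement axis ("x", "y", "z").
#' @param view projection (see \code{plot_significance_map}).
#' @return a ggplot object.
#' @export
plot_difference_map <- function(diff, model, axis = "y", view = "lateral") {
  ax <- match.arg(axis, AXIS_NAMES)
  pa <- .project_axes(view)
  nodes <- as.data.frame(model$mean)
  names(nodes) <- AXIS_NAMES
  nodes$delta <- diff$delta[, ax]
  lim <- max(abs(nodes$delta), 1e-12)
  ggplot2::ggplot(nodes,
                  ggplot2::aes(.data[[pa[1]]], .data[[pa[2]]],
                               colour = .data$delta)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_gradient2(low = "#2055FF", mid = "white",
                                    high = "#FF2020", limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Displacement %s - %s, %s-axis (%s view)",
                                  diff$labels[1], diff$labels[2], ax, view),
                  x = paste(pa[1], "(mm)"), y = paste(pa[2], "(mm)"),
                  colour = "mm") +
    ggplot2::theme_minimal()
}
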