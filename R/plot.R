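# Cluster visualization: quality property over cluster index, coloured by
# similarity to the cluster seed.

#' Red-to-green similarity colour ramp
#'
#' Maps similarity 0 to red and 1 to green; values outside `[0, 1]` are
#' clamped.  This is the colour scale used by [plot_clusters()], exposed so
#' the mapping can be inspected directly.
#'
#' @param x Numeric vector of similarities.
#' @return Character vector of hex colours.
#' @examples
#' similarity_colours(c(0, 0.3, 1))
#' @export
similarity_colours <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  m <- grDevices::colorRamp(c("red", "green"))(x)
  grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

#' Scatterplot of a quality property over cluster index
#'
#' One point per record at its cluster index, coloured by the member's
#' similarity to its cluster seed on a red (low) to green (high) ramp;
#' seeds have similarity 1 and render full green.  Because seeds are
#' selected in decreasing order of the sort property, their points form a
#' monotonically decreasing green curve.  The input is never modified.
#'
#' @param x A `dise_result` from [dise_cluster()], or an assignments data
#'   frame with columns `cluster_index`, `similarity_to_seed` and the `y`
#'   column.
#' @param y Name of the numeric column to plot on the y axis (default
#'   `"sort_value"`, i.e. the clustering sort property).
#' @param y_label Axis label (defaults to the sort field name when `x` is
#'   a `dise_result`, else `y`).
#' @return A ggplot object.
#' @export
plot_clusters <- function(x, y = "sort_value", y_label = NULL) {
  df <- if (inherits(x, "dise_result")) x$assignments else x
  if (!NROW(df)) stop("no cluster assignments to plot")
  if (is.null(df[[y]])) stop(sprintf("column '%s' not present", y))
  if (anyNA(df[[y]])) {
    stop(sprintf("missing '%s' value on record(s): %s", y,
                 paste(df$record_id[is.na(df[[y]])], collapse = ", ")))
  }
  if (is.null(y_label)) {
    y_label <- if (inherits(x, "dise_result") && y == "sort_value")
      x$config$sort_field else y
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cluster_index, y = .data[[y]],
    colour = pmin(pmax(.data$similarity_to_seed, 0), 1))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient(low = "red", high = "green",
                                   limits = c(0, 1),
                                   name = "similarity\nto seed") +
    ggplot2::labs(x = "cluster index", y = y_label) +
    ggplot2::theme_bw()
}

#' Write a cluster plot to an image file
#'
#' @param plot A ggplot object from [plot_clusters()].
#' @param file Output path; format from the extension (`.png`, `.pdf`, or
#'   `.svg` where the platform supports it).
#' @param width,height Plot size in inches.
#' @param dpi Raster resolution.
#' @return Invisibly, `file`.
#' @export
save_cluster_plot <- function(plot, file, width = 7, height = 5, dpi = 150) {
  ggplot2::ggsave(file, plot = plot, width = width, height = height,
                  dpi = dpi)
  invisible(file)
}
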