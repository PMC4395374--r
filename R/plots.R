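# ggplot2 displays for sweep reports and images.

utils::globalVariables(c("n_te", "source", "col", "row", "value"))

#' Plot a contrast/SDNR sweep
#'
#' Lines of contrast or SDNR against the number of TE averages, one line
#' per source reconstruction.
#'
#' @param report a `swi_sweep` tibble from [sweep_report()].
#' @param metric `"contrast"` or `"sdnr"`.
#' @return a ggplot object.
#' @export
plot_sweep <- function(report, metric = c("contrast", "sdnr")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(report,
                  ggplot2::aes(x = n_te, y = .data[[metric]], colour = source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(report$n_te)) +
    ggplot2::labs(x = "TE averages (nTE)",
                  y = if (metric == "contrast") "lesion contrast (S1-S2)/S1"
                      else "SDNR (S1-S2)/noise STD",
                  colour = "source") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
autoplot.swi_sweep <- function(object, metric = c("contrast", "sdnr"), ...) {
  plot_sweep(object, metric)
}

#' Display an image plane
#'
#' Raster display of a matrix or `te_image`, grayscale, image orientation
#' (row 1 on top).
#'
#' @param img numeric matrix or `te_image`.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  pl <- as_image_plane(img)
  df <- expand.grid(row = seq_len(nrow(pl$data)), col = seq_len(ncol(pl$data)))
  df$value <- as.vector(pl$data)
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
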