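#' Plot an en-face image
#'
#' @param image An [enface] image or matrix (0--255).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_enface <- function(image, title = NULL) {
  px <- as_pixel_matrix(image)
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- px[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(
      low = "black", high = "white", limits = c(0, 255)
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "grey") +
    ggplot2::theme_void()
}

#' Plot gain and loss maps of a difference analysis
#'
#' Shows the binarized gain (averaged-only signal) and loss (single-only
#' signal) masks side by side, with the box grid overlaid.
#'
#' @param x A `diff_result` from [diff_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diff_result <- function(x, ...) {
  to_df <- function(mask, which) {
    idx <- which(mask, arr.ind = TRUE)
    tibble::tibble(
      row = idx[, 1], col = idx[, 2], change = which
    )
  }
  df <- dplyr::bind_rows(
    to_df(x$gain_mask, "gain (averaged only)"),
    to_df(x$loss_mask, "loss (single only)")
  )
  g <- x$scores$grid
  lines <- tibble::tibble(
    pos = g$origin[2] + seq(0, g$n_cols) * g$box_side - 0.5
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(fill = "red") +
    ggplot2::geom_vline(data = lines, ggplot2::aes(xintercept = .data$pos),
      linewidth = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = .data$pos),
      linewidth = 0.2, colour = "grey40"
    ) +
    ggplot2::facet_wrap(~change) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Pixel change at threshold %d (%s)", x$threshold, x$slab)
    )
}

#' Plot per-box gain/loss scores
#'
#' @param x A `box_scores` object from [score_boxes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.box_scores <- function(x, ...) {
  df <- x$boxes |>
    tidyr::pivot_longer(
      c("gain_pixels", "loss_pixels"),
      names_to = "change", values_to = "pixels"
    ) |>
    dplyr::mutate(change = sub("_pixels", "", .data$change))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$pixels), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$pixels), size = 3) +
    ggplot2::facet_wrap(~change) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "pixels/box")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
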