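#' Automatic grey-level threshold of an image
#'
#' Computes a global binarization threshold from the 256-bin intensity
#' histogram. `"otsu"` (default) maximises the between-class variance;
#' `"isodata"` iterates the midpoint between the mean intensities below and
#' above the threshold until it stabilises (the classic intermeans
#' auto-threshold).
#'
#' @param image An [enface] image or matrix (0--255).
#' @param method `"otsu"` or `"isodata"`.
#' @return An integer threshold in \[0, 255\]; foreground is
#'   `>= threshold` by the package's convention.
#' @export
auto_threshold <- function(image, method = c("otsu", "isodata")) {
  method <- match.arg(method)
  px <- round_half_away(as_pixel_matrix(image))
  if (length(unique(as.vector(px))) < 2L) {
    stop("cannot auto-threshold a constant image", call. = FALSE)
  }
  h <- as.numeric(tabulate(as.vector(px) + 1L, nbins = 256L))
  lev <- 0:255
  if (method == "otsu") {
    w <- cumsum(h)
    mu <- cumsum(h * lev)
    n <- w[256]
    mu_t <- mu[256]
    # split after level t: class 0 = {0..t}, class 1 = {t+1..255}
    w0 <- w[1:255]
    w1 <- n - w0
    m0 <- mu[1:255] / w0
    m1 <- (mu_t - mu[1:255]) / w1
    bcv <- w0 * w1 * (m0 - m1)^2
    bcv[!is.finite(bcv)] <- -Inf
    t_star <- which.max(bcv) # split between t_star-1 and t_star
    as.integer(t_star) # foreground >= t_star
  } else {
    t_cur <- mean(px)
    for (i in 1:100) {
      lo <- px < t_cur
      if (!any(lo) || all(lo)) break
      t_new <- (mean(px[lo]) + mean(px[!lo])) / 2
      if (abs(t_new - t_cur) < 0.5) {
        t_cur <- t_new
        break
      }
      t_cur <- t_new
    }
    as.integer(ceiling(t_cur))
  }
}

#' Vessel density of an en-face image
#'
#' Vessel density (VD) is the fraction of image area occupied by binarized
#' vessel signal: the image is binarized at an automatic threshold
#' (foreground `>= threshold`) and foreground pixels are counted, whole-image
#' and per grid box (VD in pixels/box is the unit used for 172x172 boxes).
#'
#' @param image An [enface] image or matrix.
#' @param grid Optional [box_grid()] for per-box counts.
#' @param method Thresholding method ([auto_threshold()]), or `"fixed"`.
#' @param threshold Threshold value when `method = "fixed"`.
#' @param validity_mask Optional logical matrix restricting the counted area.
#' @return A one-row tibble: `method`, `threshold`, `vessel_pixels`,
#'   `total_pixels`, `vd_fraction`, and (when `grid` is given) a `per_box`
#'   list-column with the per-box pixel counts.
#' @export
vessel_density <- function(image, grid = NULL,
                           method = c("otsu", "isodata", "fixed"),
                           threshold = NULL, validity_mask = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(!is.null(threshold))
  } else {
    threshold <- auto_threshold(image, method)
  }
  mask <- as_pixel_matrix(image) >= threshold
  total <- length(mask)
  if (!is.null(validity_mask)) {
    mask <- mask & validity_mask
    total <- sum(validity_mask)
  }
  out <- tibble::tibble(
    method = method, threshold = as.numeric(threshold),
    vessel_pixels = sum(mask), total_pixels = total,
    vd_fraction = sum(mask) / total
  )
  if (!is.null(grid)) {
    ext <- box_extents(grid, nrow(mask), ncol(mask))
    out$per_box <- list(tibble::tibble(
      box_id = ext$box_id, row = ext$row, col = ext$col,
      vessel_pixels = count_in_boxes(mask, grid)
    ))
  }
  out
}
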