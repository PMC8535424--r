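#' Positive-part pixel subtraction
#'
#' `subtract_positive(a, b)` is the per-pixel `max(a - b, 0)`. Applied in both
#' directions it yields the gain map (averaged minus single, where averaging
#' added signal) and the loss map (single minus averaged).
#'
#' @param a,b Co-dimensional images or matrices.
#' @return A numeric matrix.
#' @export
subtract_positive <- function(a, b) {
  pa <- as_pixel_matrix(a)
  pb <- as_pixel_matrix(b)
  if (!all(dim(pa) == dim(pb))) stop("images differ in size", call. = FALSE)
  pmax(pa - pb, 0)
}

#' Default difference-map threshold for a slab
#'
#' The grey-level separating vessel signal from background in difference
#' images: about 40 for the superficial plexus and the full-retina slab; 60
#' for the deep complex, whose stronger background noise needs a higher cut to
#' keep the flagged area comparable.
#'
#' @param slab `"SVP"`, `"DVC"` or `"FULL"`.
#' @return An integer threshold.
#' @export
slab_threshold <- function(slab) {
  switch(match.arg(slab, c("SVP", "DVC", "FULL")),
    SVP = 40L, DVC = 60L, FULL = 40L
  )
}

#' Binarize a difference map
#'
#' Foreground is `map >= threshold` (the boundary value counts as
#' foreground). If `threshold` is `NULL` the slab default is used
#' ([slab_threshold()]).
#'
#' @param map Numeric matrix (difference map).
#' @param threshold Grey-level threshold in \[0, 255\], or `NULL`.
#' @param slab Slab used for the default threshold.
#' @return A logical matrix.
#' @export
binarize <- function(map, threshold = NULL, slab = "SVP") {
  if (is.null(threshold)) threshold <- slab_threshold(slab)
  stopifnot(threshold >= 0, threshold <= 255)
  as_pixel_matrix(map) >= threshold
}

#' Red overlay of a binary mask on a grayscale image
#'
#' Replicates the base image into RGB and paints mask pixels pure red, the
#' standard visualisation of gained or lost pixels on top of the averaged
#' image.
#'
#' @param base Grayscale image (0--255).
#' @param mask Logical matrix.
#' @return A `height x width x 3` numeric array (0--255).
#' @export
make_overlay <- function(base, mask) {
  px <- as_pixel_matrix(base)
  if (!all(dim(px) == dim(mask))) stop("mask size mismatch", call. = FALSE)
  rgb <- array(px, dim = c(dim(px), 3))
  r <- rgb[, , 1]
  g <- rgb[, , 2]
  b <- rgb[, , 3]
  r[mask] <- 255
  g[mask] <- 0
  b[mask] <- 0
  rgb[, , 1] <- r
  rgb[, , 2] <- g
  rgb[, , 3] <- b
  rgb
}

#' Define a box grid for semi-quantitative grading
#'
#' The default grid divides a 516x516 raster into nine identical 172x172
#' boxes (3 rows x 3 columns, about 29,500 pixels each).
#'
#' @param box_side Box side in pixels.
#' @param n_rows,n_cols Grid dimensions.
#' @param origin `(row, col)` of the grid's top-left corner (1-based).
#' @return A `box_grid` object.
#' @export
box_grid <- function(box_side = 172L, n_rows = 3L, n_cols = 3L,
                     origin = c(1L, 1L)) {
  structure(
    list(
      box_side = as.integer(box_side), n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols), origin = as.integer(origin)
    ),
    class = "box_grid"
  )
}

# Tibble of box extents; errors if the grid overflows the image.
box_extents <- function(grid, height, width) {
  g <- grid
  if (g$origin[1] + g$n_rows * g$box_side - 1L > height ||
    g$origin[2] + g$n_cols * g$box_side - 1L > width) {
    stop("box grid does not fit inside the image", call. = FALSE)
  }
  tidyr::expand_grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols)) |>
    dplyr::mutate(
      box_id = (.data$row - 1L) * g$n_cols + .data$col,
      row0 = g$origin[1] + (.data$row - 1L) * g$box_side,
      col0 = g$origin[2] + (.data$col - 1L) * g$box_side
    ) |>
    dplyr::relocate("box_id")
}

count_in_boxes <- function(mask, grid) {
  ext <- box_extents(grid, nrow(mask), ncol(mask))
  purrr::pmap_int(
    list(ext$row0, ext$col0),
    function(r0, c0) {
      sum(mask[r0:(r0 + grid$box_side - 1L), c0:(c0 + grid$box_side - 1L)])
    }
  )
}

#' Per-box gain/loss counts and presence flags
#'
#' Counts mask pixels in each grid box and flags a box when its count reaches
#' `min_pixels` (an automated surrogate for expert presence/absence grading;
#' the small floor keeps isolated noise pixels from flipping flags). The gain
#' score (and loss score) of the image is the number of flagged boxes.
#'
#' @param gain_mask,loss_mask Logical matrices (binarized difference maps).
#' @param grid A [box_grid()].
#' @param min_pixels Minimum pixels in a box for its flag to be 1.
#' @param validity_mask Optional logical matrix; counts are restricted to it
#'   (so border fill from registration is not scored).
#' @return A `box_scores` object: `boxes` tibble (`box_id`, `row`, `col`,
#'   `gain_pixels`, `loss_pixels`, `gain_flag`, `loss_flag`) plus
#'   `gain_score` and `loss_score`.
#' @export
score_boxes <- function(gain_mask, loss_mask, grid = box_grid(),
                        min_pixels = 50L, validity_mask = NULL) {
  if (!is.null(validity_mask)) {
    gain_mask <- gain_mask & validity_mask
    loss_mask <- loss_mask & validity_mask
  }
  ext <- box_extents(grid, nrow(gain_mask), ncol(gain_mask))
  boxes <- dplyr::mutate(ext,
    gain_pixels = count_in_boxes(gain_mask, grid),
    loss_pixels = count_in_boxes(loss_mask, grid),
    gain_flag = as.integer(.data$gain_pixels >= min_pixels),
    loss_flag = as.integer(.data$loss_pixels >= min_pixels)
  ) |>
    dplyr::select(
      "box_id", "row", "col", "gain_pixels", "loss_pixels",
      "gain_flag", "loss_flag"
    )
  structure(
    list(
      boxes = boxes, gain_score = sum(boxes$gain_flag),
      loss_score = sum(boxes$loss_flag), min_pixels = as.integer(min_pixels),
      grid = grid
    ),
    class = "box_scores"
  )
}

#' @export
print.box_scores <- function(x, ...) {
  cat(sprintf(
    "<box_scores> gain score %d / %d, loss score %d / %d\n",
    x$gain_score, nrow(x$boxes), x$loss_score, nrow(x$boxes)
  ))
  print(x$boxes)
  invisible(x)
}

erode1 <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-H, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -W, drop = FALSE])
  mask & up & dn & lf & rt
}

#' Ground-truth-based surrogate grading of detection gain
#'
#' Stands in for expert grading on synthetic data: a box is flagged as a true
#' gain in capillary detection only if at least `min_pixels` gained pixels lie
#' on the ground-truth vessel support — gain on background is noise, not
#' vessel detection.
#'
#' @param gain_mask Binarized gain map.
#' @param gt_vessel_mask Ground-truth vessel support.
#' @param grid A [box_grid()].
#' @param min_pixels Flag floor, as in [score_boxes()].
#' @param validity_mask Optional logical matrix; grading is restricted to it
#'   (pass the averaging validity mask so zero-filled border regions are not
#'   graded).
#' @return Integer vector of per-box flags (row-major box order).
#' @export
surrogate_grade_gain <- function(gain_mask, gt_vessel_mask,
                                 grid = box_grid(), min_pixels = 50L,
                                 validity_mask = NULL) {
  if (is.null(gt_vessel_mask)) stop("ground truth required", call. = FALSE)
  if (!is.null(validity_mask)) gain_mask <- gain_mask & validity_mask
  as.integer(count_in_boxes(gain_mask & gt_vessel_mask, grid) >= min_pixels)
}

#' Ground-truth-based surrogate grading of vessel loss
#'
#' Flags a box as a true loss of vessel detection only if enough lost pixels
#' fall on vessel support that was perfused in every acquisition (eroded by
#' 1 px to discount interpolation effects at vessel edges): losing an
#' intermittently perfused capillary, background noise, or a motion stripe is
#' not an erased vessel.
#'
#' @param loss_mask Binarized loss map.
#' @param gt Ground truth from [generate_stack()] (or a logical matrix giving
#'   the consistently perfused support directly).
#' @inheritParams surrogate_grade_gain
#' @return Integer vector of per-box flags.
#' @export
surrogate_grade_loss <- function(loss_mask, gt, grid = box_grid(),
                                 min_pixels = 50L, validity_mask = NULL) {
  support <- if (is.matrix(gt)) gt else consistent_vessel_mask(gt)
  if (!is.null(validity_mask)) loss_mask <- loss_mask & validity_mask
  as.integer(
    count_in_boxes(loss_mask & erode1(support), grid) >= min_pixels
  )
}

#' Gain/loss difference analysis of an averaged image
#'
#' The full change analysis between an averaged image and the first
#' non-averaged acquisition (both in the registered reference frame):
#' positive-part subtraction in both directions, binarization at the slab
#' threshold, red overlays, and 9-box scoring.
#'
#' @param averaged The averaged image ([average_stack()]).
#' @param single The first non-averaged acquisition (reference frame).
#' @param slab Slab for the default threshold; defaults to the averaged
#'   image's slab attribute.
#' @param grid A [box_grid()].
#' @param threshold Optional explicit threshold (overrides the slab default).
#' @param min_pixels Box flag floor.
#' @param validity_mask Optional restriction mask; defaults to the averaged
#'   image's validity mask when present.
#' @return A `diff_result`: list with `gain_map`, `loss_map`, `gain_mask`,
#'   `loss_mask`, `threshold`, `scores` ([score_boxes()] result),
#'   `overlay_gain`, `overlay_loss`, and a one-row `summary` tibble with mean
#'   pixels gained/lost per box.
#' @export
diff_pipeline <- function(averaged, single, slab = NULL, grid = box_grid(),
                          threshold = NULL, min_pixels = 50L,
                          validity_mask = NULL) {
  if (is.null(slab)) {
    slab <- attr(averaged, "slab")
    if (is.null(slab) || is.na(slab)) slab <- "SVP"
  }
  if (is.null(threshold)) threshold <- slab_threshold(slab)
  if (is.null(validity_mask)) validity_mask <- attr(averaged, "validity_mask")
  gain_map <- subtract_positive(averaged, single)
  loss_map <- subtract_positive(single, averaged)
  gain_mask <- binarize(gain_map, threshold)
  loss_mask <- binarize(loss_map, threshold)
  scores <- score_boxes(gain_mask, loss_mask, grid,
    min_pixels = min_pixels,
    validity_mask = validity_mask
  )
  structure(
    list(
      gain_map = gain_map, loss_map = loss_map,
      gain_mask = gain_mask, loss_mask = loss_mask,
      threshold = threshold, slab = slab, scores = scores,
      overlay_gain = make_overlay(averaged, gain_mask),
      overlay_loss = make_overlay(single, loss_mask),
      summary = tibble::tibble(
        slab = slab, threshold = threshold,
        mean_gain_pixels_per_box = mean(scores$boxes$gain_pixels),
        mean_loss_pixels_per_box = mean(scores$boxes$loss_pixels),
        gain_score = scores$gain_score, loss_score = scores$loss_score
      )
    ),
    class = "diff_result"
  )
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf(
    "<diff_result> slab=%s threshold=%d; mean gain %.1f px/box, mean loss %.1f px/box\n",
    x$slab, x$threshold, x$summary$mean_gain_pixels_per_box,
    x$summary$mean_loss_pixels_per_box
  ))
  invisible(x)
}
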