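#' Average-intensity projection of a registered stack
#'
#' Collapses a registered stack to a single image by the per-pixel arithmetic
#' mean over frames, the average-intensity Z-projection. Accumulation is done
#' in real arithmetic with a single rounding (half away from zero) to 8-bit at
#' the end. By default all frames contribute everywhere, including the zeros
#' filled in outside a frame's validity region (mirroring what a plain stack
#' projection does); with `valid_only = TRUE` each pixel averages only the
#' frames valid there. The stack's joint validity mask is carried alongside so
#' downstream counts can be restricted to it.
#'
#' @param stack A `registered_stack`, `octa_stack`, or list of co-dimensional
#'   images.
#' @param valid_only Average only valid frames per pixel.
#' @param round_8bit Round the result to 8-bit integers (default `TRUE`).
#' @return An `averaged_image`: an [enface] image with attributes `n_frames`
#'   and `validity_mask`.
#' @export
average_stack <- function(stack, valid_only = FALSE, round_8bit = TRUE) {
  images <- stack_images(stack)
  n <- length(images)
  if (n < 2L) stop("need at least 2 frames to average", call. = FALSE)
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1])) stop("frames must share dimensions")
  acc <- Reduce(`+`, lapply(images, as_pixel_matrix))
  if (valid_only && inherits(stack, "registered_stack")) {
    counts <- Reduce(`+`, lapply(stack$valid, function(v) v * 1))
    avg <- acc / pmax(counts, 1)
  } else {
    avg <- acc / n
  }
  if (round_8bit) avg <- round_half_away(avg)
  vmask <- if (inherits(stack, "registered_stack")) {
    stack$validity_mask
  } else {
    matrix(TRUE, nrow(avg), ncol(avg))
  }
  out <- if (inherits(images[[1]], "enface")) {
    enface_like(avg, images[[1]])
  } else {
    enface(avg)
  }
  attr(out, "acquisition_index") <- NA_integer_
  attr(out, "n_frames") <- n
  attr(out, "validity_mask") <- vmask
  class(out) <- c("averaged_image", class(out))
  out
}
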