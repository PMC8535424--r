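#' En-face angiogram images
#'
#' An `enface` object is a numeric matrix of 8-bit intensities (0--255),
#' row-major with the origin at the top-left (row 1 = top of the image),
#' carrying acquisition metadata as attributes: `slab` (`"SVP"`, `"DVC"` or
#' `"FULL"`), `scan_area` (`"A3x3"` or `"A6x6"`), `eye_id`,
#' `acquisition_index` (1-based) and `quality_index`, a 0--100 acquisition
#' quality score in the spirit of the device-reported Signal Strength Index
#' (`NA` when unknown).
#'
#' @param pixels Numeric matrix of intensities; values are clamped to
#'   \[0, 255\].
#' @param slab,scan_area,eye_id,acquisition_index,quality_index Acquisition
#'   metadata; all optional.
#' @return An `enface` object (a matrix with metadata attributes).
#' @examples
#' img <- enface(matrix(runif(64, 0, 255), 8, 8), slab = "SVP")
#' dim(img)
#' @export
enface <- function(pixels, slab = NA_character_, scan_area = NA_character_,
                   eye_id = NA_character_, acquisition_index = NA_integer_,
                   quality_index = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (length(pixels) == 0L) stop("zero-sized raster", call. = FALSE)
  pixels <- pmin(pmax(pixels, 0), 255)
  if (!is.na(slab)) slab <- match.arg(slab, c("SVP", "DVC", "FULL"))
  if (!is.na(scan_area)) scan_area <- match.arg(scan_area, c("A3x3", "A6x6"))
  structure(pixels,
    class = c("enface", "matrix", "array"),
    slab = slab, scan_area = scan_area, eye_id = eye_id,
    acquisition_index = as.integer(acquisition_index),
    quality_index = as.numeric(quality_index)
  )
}

#' @export
print.enface <- function(x, ...) {
  cat(sprintf(
    "<enface> %d x %d  slab=%s area=%s eye=%s acq=%s quality=%s\n",
    nrow(x), ncol(x), attr(x, "slab"), attr(x, "scan_area"),
    attr(x, "eye_id"), attr(x, "acquisition_index"),
    ifelse(is.na(attr(x, "quality_index")), "NA",
      sprintf("%.1f", attr(x, "quality_index"))
    )
  ))
  invisible(x)
}

# Rebuild an enface around new pixels, keeping metadata from a template.
enface_like <- function(pixels, template) {
  enface(pixels,
    slab = attr(template, "slab"), scan_area = attr(template, "scan_area"),
    eye_id = attr(template, "eye_id"),
    acquisition_index = attr(template, "acquisition_index"),
    quality_index = attr(template, "quality_index")
  )
}

as_pixel_matrix <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

# Round half away from zero to the 8-bit range.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read an en-face image from PNG, TIFF or JPEG
#'
#' Images are decoded with EBImage; RGB rasters are converted to luminance,
#' and intensities are rescaled to the 0--255 range (a 16-bit TIFF whose
#' maximum value is 65535 maps to 255). Metadata fields are attached
#' unchanged.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @inheritParams enface
#' @return An [enface] image.
#' @seealso [save_enface()]
#' @export
load_enface <- function(path, slab = NA_character_, scan_area = NA_character_,
                        eye_id = NA_character_,
                        acquisition_index = NA_integer_,
                        quality_index = NA_real_) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color) {
    img <- EBImage::channel(img, "luminance")
  }
  px <- EBImage::imageData(img)
  if (length(dim(px)) > 2L) px <- px[, , 1L]
  if (length(px) == 0L) stop("zero-sized raster: ", path, call. = FALSE)
  # EBImage stores (x, y) in [0, 1]; transpose to row = y, scale to 8-bit.
  px <- t(px) * 255
  enface(px,
    slab = slab, scan_area = scan_area, eye_id = eye_id,
    acquisition_index = acquisition_index, quality_index = quality_index
  )
}

#' Write an en-face image as PNG
#'
#' All pipeline outputs are written as PNG; intensities are rounded to 8-bit
#' so that an 8-bit write/read round trip is lossless.
#'
#' @param image An [enface] image or plain matrix (0--255).
#' @param path Output path (`.png`, or `.tif`/`.tiff` for TIFF).
#' @return `path`, invisibly.
#' @export
save_enface <- function(image, path) {
  px <- round_half_away(as_pixel_matrix(image)) / 255
  EBImage::writeImage(EBImage::Image(t(px)), path)
  invisible(path)
}

#' Crop the device logo band from an image
#'
#' Exported device images carry a square logo in the bottom-left corner. To
#' keep the raster rectangular, the full bottom band of rows of the logo's
#' height is removed; surviving pixel intensities are untouched. `side_px = 0`
#' is a no-op (synthetic images carry no logo).
#'
#' @param image An [enface] image.
#' @param side_px Height of the logo square, in pixels.
#' @return The cropped [enface] image.
#' @export
crop_logo <- function(image, side_px = 0L) {
  side_px <- as.integer(side_px)
  stopifnot(side_px >= 0L)
  if (side_px >= nrow(image) || side_px >= ncol(image)) {
    stop("crop region larger than image", call. = FALSE)
  }
  if (side_px == 0L) return(image)
  enface_like(as_pixel_matrix(image)[seq_len(nrow(image) - side_px), ,
    drop = FALSE
  ], image)
}
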