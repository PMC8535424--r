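#' Centred similarity transforms
#'
#' A similarity transform maps image coordinates `p = (x, y)` (column, row;
#' 1-based; y increasing downwards) about the image centre `c`:
#' `T(p) = s R(theta) (p - c) + c + (tx, ty)`, with `theta` in degrees and a
#' uniform scale `s` (no shear), the motion model of scale-rotation stack
#' alignment. Resampling with `T` is an inverse warp: the output at `p` is the
#' source image sampled at `T(p)`.
#'
#' @param tx,ty Translation in pixels.
#' @param theta Rotation in degrees (positive = towards increasing row for
#'   increasing column, i.e. clockwise on screen).
#' @param s Uniform scale; must be positive.
#' @return A `similarity_transform` object.
#' @examples
#' t1 <- similarity_transform(5, 3, 2, 1.01)
#' invert_similarity(t1)
#' @export
similarity_transform <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(theta), is.finite(s), s > 0)
  structure(list(tx = tx, ty = ty, theta = theta, s = s),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity> tx=%.3f ty=%.3f theta=%.3f deg s=%.4f\n",
    x$tx, x$ty, x$theta, x$s
  ))
  invisible(x)
}

is_identity_transform <- function(t, tol = 1e-12) {
  abs(t$tx) < tol && abs(t$ty) < tol && abs(t$theta) < tol && abs(t$s - 1) < tol
}

#' @rdname similarity_transform
#' @param transform A `similarity_transform`.
#' @export
invert_similarity <- function(transform) {
  t <- transform
  th <- -t$theta * pi / 180
  s2 <- 1 / t$s
  # inverse of p -> sR(p-c)+c+t about the same centre
  tx2 <- -s2 * (cos(th) * t$tx - sin(th) * t$ty)
  ty2 <- -s2 * (sin(th) * t$tx + cos(th) * t$ty)
  similarity_transform(tx2, ty2, -t$theta, s2)
}

# Apply the centred similarity to coordinate vectors (x, y), centre from dims.
apply_similarity <- function(transform, x, y, height, width) {
  t <- transform
  th <- t$theta * pi / 180
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  dx <- x - cx
  dy <- y - cy
  list(
    x = t$s * (cos(th) * dx - sin(th) * dy) + cx + t$tx,
    y = t$s * (sin(th) * dx + cos(th) * dy) + cy + t$ty
  )
}

#' Resample an image under a similarity transform and deformation field
#'
#' Inverse-warp resampling with bilinear interpolation: the output at pixel
#' `p` is the source sampled at `T(p + u(p))`, where `u` is an optional
#' per-pixel displacement field. Pixels whose source coordinate falls outside
#' the raster are set to 0 and flagged invalid.
#'
#' @param image An [enface] image or numeric matrix.
#' @param transform A [similarity_transform()] (default identity).
#' @param field Optional deformation field: a list with per-pixel displacement
#'   matrices `ux`, `uy` matching the image dimensions.
#' @return A list with `image` (same class as input) and `valid` (logical
#'   matrix).
#' @export
resample <- function(image, transform = similarity_transform(), field = NULL) {
  px <- as_pixel_matrix(image)
  empty <- matrix(numeric(0), 0, 0)
  ux <- if (is.null(field)) empty else field$ux
  uy <- if (is.null(field)) empty else field$uy
  if (is_identity_transform(transform) && is.null(field)) {
    return(list(image = image, valid = matrix(TRUE, nrow(px), ncol(px))))
  }
  r <- warp_image_cpp(
    px, transform$tx, transform$ty, transform$theta,
    transform$s, ux, uy
  )
  out <- if (inherits(image, "enface")) enface_like(r$image, image) else r$image
  list(image = out, valid = r$valid)
}

# --- cubic B-spline machinery for deformation fields ------------------------

# Basis matrix (n_pixels x n_control) for a uniform cubic B-spline with
# control-point spacing h px; control points cover [1, n] with a margin so
# every pixel has 4 supporting controls.
bspline_basis <- function(n, spacing) {
  t <- (seq_len(n) - 1) / spacing
  i <- floor(t)
  u <- t - i
  n_ctrl <- max(i) + 4L
  B <- matrix(0, n, n_ctrl)
  w <- cbind(
    (1 - u)^3 / 6,
    (3 * u^3 - 6 * u^2 + 4) / 6,
    (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
    u^3 / 6
  )
  for (k in 0:3) B[cbind(seq_len(n), i + k + 1L)] <- w[, k + 1L]
  B
}

# Dense displacement matrices from control coefficients.
field_from_coefficients <- function(cx, cy, basis_row, basis_col) {
  list(
    ux = basis_row %*% cx %*% t(basis_col),
    uy = basis_row %*% cy %*% t(basis_col),
    coef_x = cx, coef_y = cy
  )
}

#' Build a B-spline deformation field object
#'
#' @param height,width Image dimensions in pixels.
#' @param spacing Control-point spacing in pixels.
#' @param coef_x,coef_y Optional coefficient matrices (defaults: zero field).
#' @return A `deformation_field` list with dense `ux`, `uy` displacement
#'   matrices, the control coefficients and the grid spacing.
#' @export
deformation_field <- function(height, width, spacing = 32,
                              coef_x = NULL, coef_y = NULL) {
  Br <- bspline_basis(height, spacing)
  Bc <- bspline_basis(width, spacing)
  if (is.null(coef_x)) coef_x <- matrix(0, ncol(Br), ncol(Bc))
  if (is.null(coef_y)) coef_y <- matrix(0, ncol(Br), ncol(Bc))
  f <- field_from_coefficients(coef_x, coef_y, Br, Bc)
  structure(c(f, list(spacing = spacing, height = height, width = width)),
    class = "deformation_field"
  )
}

# Smooth random field as a sum of Gaussian bumps (ground-truth warps). The
# best-fit global similarity component (small-angle: translation + rotation +
# isotropic scale) is projected out, so the generator's decomposition into
# similarity jitter plus elastic residual is identifiable — without this, part
# of the "elastic" deformation is an unlabelled extra similarity.
gaussian_bump_field <- function(height, width, amplitude, length_scale,
                                n_bumps = 4L) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  make <- function() {
    u <- matrix(0, height, width)
    for (b in seq_len(n_bumps)) {
      cx <- runif(1, 1, width)
      cy <- runif(1, 1, height)
      a <- runif(1, -1, 1) * amplitude
      u <- u + a * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * length_scale^2))
    }
    u
  }
  ux <- make()
  uy <- make()
  # similarity displacement model: (t1 + a*x - b*y, t2 + b*x + a*y), centred
  xc <- xs - (width + 1) / 2
  yc <- ys - (height + 1) / 2
  X <- cbind(1, as.vector(xc), -as.vector(yc))
  Y <- cbind(1, as.vector(yc), as.vector(xc))
  # joint LS for (t1, t2, a, b)
  A <- rbind(
    cbind(X[, 1], 0, X[, 2], X[, 3]),
    cbind(0, Y[, 1], Y[, 2], Y[, 3])
  )
  rhs <- c(as.vector(ux), as.vector(uy))
  beta <- solve(crossprod(A), crossprod(A, rhs))
  ux <- ux - matrix(beta[1] + beta[3] * xc - beta[4] * yc, height, width)
  uy <- uy - matrix(beta[2] + beta[3] * yc + beta[4] * xc, height, width)
  list(ux = ux, uy = uy)
}
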