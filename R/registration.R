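#' @title Intensity-based stack registration
#' @description Aligns every acquisition of a stack to the first acquired
#'   image, the way en-face angiogram stacks are prepared for averaging:
#'   first a similarity (translation + rotation + uniform scale, no shear)
#'   registration, then a B-spline elastic refinement that absorbs the smooth
#'   residual deformation left by ocular curvature. Both stages minimise the
#'   mean squared intensity difference to the reference, evaluated on the
#'   pixels that land inside the source raster; both are deterministic
#'   (identity initialisation, fixed iteration caps), so registration needs no
#'   seed.
#' @name registration
NULL

mse_between <- function(a, b, mask = NULL) {
  d <- (as_pixel_matrix(a) - as_pixel_matrix(b))^2
  if (!is.null(mask)) d <- d[mask]
  mean(d)
}

grad_x <- function(m) {
  W <- ncol(m)
  (m[, c(2:W, W)] - m[, c(1, 1:(W - 1))]) / 2
}

grad_y <- function(m) {
  H <- nrow(m)
  (m[c(2:H, H), ] - m[c(1, 1:(H - 1)), ]) / 2
}

# Gaussian prefilter + x2 downsample (binomial 5-tap kernel).
pyramid_down <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad <- function(v, n) c(rep(v[1], 2), v, rep(v[length(v)], 2))
  m <- apply(m, 2, function(col) {
    stats::convolve(pad(col), rev(k), type = "filter")
  })
  m <- t(apply(m, 1, function(row) {
    stats::convolve(pad(row), rev(k), type = "filter")
  }))
  m[seq(1, nrow(m), 2), seq(1, ncol(m), 2), drop = FALSE]
}

build_pyramid <- function(m, levels = 3L) {
  out <- vector("list", levels)
  out[[levels]] <- m # finest last
  for (l in rev(seq_len(levels - 1L))) out[[l]] <- pyramid_down(out[[l + 1L]])
  out
}

# Similarity registration of one frame to the reference.
register_pair_linear <- function(moving, ref, levels = 3L,
                                 coarse_search_px = 8) {
  pm <- build_pyramid(moving, levels)
  pr <- build_pyramid(ref, levels)
  par <- c(0, 0, 0, 1)
  for (l in seq_len(levels)) {
    fn <- local({
      mv <- pm[[l]]
      rf <- pr[[l]]
      stride <- if (max(dim(mv)) > 200) 2L else 1L
      function(p) warp_mse_cpp(mv, rf, p[1], p[2], p[3], p[4], stride)[1]
    })
    if (l == 1L) {
      # translation/rotation grid search secures the capture range at the
      # top level
      steps <- seq(-coarse_search_px, coarse_search_px, by = 2) /
        2^(levels - 1L)
      grid <- expand.grid(tx = steps, ty = steps, th = seq(-6, 6, by = 2))
      vals <- apply(grid, 1, function(g) fn(c(g[1], g[2], g[3], 1)))
      best <- which.min(vals)
      par <- c(grid$tx[best], grid$ty[best], grid$th[best], 1)
    } else {
      par[1:2] <- par[1:2] * 2
    }
    maxit <- c(100, 60, 40)[min(l, 3L)]
    half <- max(dim(pm[[l]])) / 2
    fit <- stats::optim(par, fn,
      method = "L-BFGS-B",
      lower = c(-half, -half, -20, 0.8),
      upper = c(half, half, 20, 1.25),
      control = list(
        maxit = maxit, ndeps = c(1e-2, 1e-2, 1e-2, 1e-4), factr = 1e6
      )
    )
    par <- fit$par
  }
  similarity_transform(par[1], par[2], par[3], par[4])
}

#' Similarity (linear) registration of a stack to its first frame
#'
#' For each non-reference frame, finds the similarity transform minimising the
#' mean squared intensity difference to the reference under a 3-level Gaussian
#' pyramid search, and resamples the frame into the reference grid with
#' bilinear interpolation. The reference frame is returned untouched.
#'
#' @param stack An `octa_stack` from [generate_stack()], or a plain list of
#'   [enface] images / matrices sharing dimensions.
#' @param reference_index Index of the reference frame (default 1, the first
#'   acquired image).
#' @param max_scale_dev Sanity bound on `|s - 1|`; a fitted transform outside
#'   it raises a registration-failure error naming the frame.
#' @param levels Pyramid levels.
#' @return A `registered_stack`: list with `images` (resampled frames),
#'   `transforms`, `valid` (per-frame logical matrices), `validity_mask`
#'   (pixels valid in all frames), `reference_index` and an `mse` tibble with
#'   per-frame MSE before/after.
#' @export
register_linear <- function(stack, reference_index = 1L,
                            max_scale_dev = 0.2, levels = 3L) {
  images <- stack_images(stack)
  n <- length(images)
  stopifnot(n >= 2, reference_index >= 1, reference_index <= n)
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1])) stop("stack images must share dimensions")
  ref <- as_pixel_matrix(images[[reference_index]])
  transforms <- vector("list", n)
  out <- vector("list", n)
  valid <- vector("list", n)
  mse <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == reference_index) {
      transforms[[k]] <- similarity_transform()
      out[[k]] <- images[[k]]
      valid[[k]] <- matrix(TRUE, nrow(ref), ncol(ref))
      mse[[k]] <- tibble::tibble(
        frame = k, mse_unregistered = 0, mse_linear = 0
      )
      next
    }
    mv <- as_pixel_matrix(images[[k]])
    t_k <- register_pair_linear(mv, ref, levels = levels)
    if (abs(t_k$s - 1) > max_scale_dev || abs(t_k$theta) > 45) {
      stop(sprintf(
        "linear registration failed for frame %d (s=%.3f, theta=%.1f)",
        k, t_k$s, t_k$theta
      ), call. = FALSE)
    }
    mse0 <- mse_between(mv, ref)
    r <- resample(images[[k]], t_k)
    mse1 <- mse_between(r$image, ref, r$valid)
    if (mse1 > mse0) { # never worse than no registration
      t_k <- similarity_transform()
      r <- resample(images[[k]], t_k)
      mse1 <- mse0
    }
    transforms[[k]] <- t_k
    out[[k]] <- r$image
    valid[[k]] <- r$valid
    mse[[k]] <- tibble::tibble(
      frame = k, mse_unregistered = mse0, mse_linear = mse1
    )
  }
  structure(
    list(
      images = out, transforms = transforms, fields = NULL, valid = valid,
      validity_mask = Reduce(`&`, valid),
      reference_index = as.integer(reference_index),
      mse = dplyr::bind_rows(mse)
    ),
    class = "registered_stack"
  )
}

stack_images <- function(stack) {
  if (inherits(stack, "octa_stack")) stack$images
  else if (inherits(stack, "registered_stack")) stack$images
  else if (is.list(stack)) stack
  else stop("expected a stack (list of images)", call. = FALSE)
}

# Second-difference penalty (discrete bending energy on the control grid).
bending_penalty <- function(C) {
  d2r <- diff(C, differences = 2)
  d2c <- t(diff(t(C), differences = 2))
  dmix <- diff(t(diff(t(C))))
  (sum(d2r^2) + sum(d2c^2) + 2 * sum(dmix^2)) / length(C)
}

bending_gradient <- function(C) {
  g <- matrix(0, nrow(C), ncol(C))
  d2r <- diff(C, differences = 2)
  g[1:nrow(d2r), ] <- g[1:nrow(d2r), ] + d2r
  g[2:(nrow(d2r) + 1), ] <- g[2:(nrow(d2r) + 1), ] - 2 * d2r
  g[3:(nrow(d2r) + 2), ] <- g[3:(nrow(d2r) + 2), ] + d2r
  d2c <- t(diff(t(C), differences = 2))
  g[, 1:ncol(d2c)] <- g[, 1:ncol(d2c)] + d2c
  g[, 2:(ncol(d2c) + 1)] <- g[, 2:(ncol(d2c) + 1)] - 2 * d2c
  g[, 3:(ncol(d2c) + 2)] <- g[, 3:(ncol(d2c) + 2)] + d2c
  dm <- diff(t(diff(t(C)))) # (nr-1) x (nc-1)
  gm <- matrix(0, nrow(C), ncol(C))
  nr <- nrow(dm)
  nc <- ncol(dm)
  gm[1:nr, 1:nc] <- gm[1:nr, 1:nc] + dm
  gm[1:nr + 1, 1:nc] <- gm[1:nr + 1, 1:nc] - dm
  gm[1:nr, 1:nc + 1] <- gm[1:nr, 1:nc + 1] - dm
  gm[1:nr + 1, 1:nc + 1] <- gm[1:nr + 1, 1:nc + 1] + dm
  2 * (g + 2 * gm) / length(C)
}

register_pair_elastic <- function(moving, ref, ref_valid, spacing, lambda,
                                  max_iter, displacement_bound) {
  H <- nrow(moving)
  W <- ncol(moving)
  Br <- bspline_basis(H, spacing)
  Bc <- bspline_basis(W, spacing)
  nr <- ncol(Br)
  nc <- ncol(Bc)
  np <- nr * nc
  unpack <- function(p) {
    list(
      cx = matrix(p[1:np], nr, nc),
      cy = matrix(p[np + 1:np], nr, nc)
    )
  }
  warp_for <- function(p) {
    cf <- unpack(p)
    warp_image_cpp(
      moving, 0, 0, 0, 1,
      Br %*% cf$cx %*% t(Bc), Br %*% cf$cy %*% t(Bc)
    )
  }
  fn <- function(p) {
    cf <- unpack(p)
    w <- warp_for(p)
    m <- w$valid & ref_valid
    data <- mean((w$image[m] - ref[m])^2) / 2
    data + lambda * (bending_penalty(cf$cx) + bending_penalty(cf$cy))
  }
  gr <- function(p) {
    cf <- unpack(p)
    w <- warp_for(p)
    m <- w$valid & ref_valid
    res <- (w$image - ref) * m
    n_ok <- sum(m)
    gx <- grad_x(w$image)
    gy <- grad_y(w$image)
    gcx <- t(Br) %*% (res * gx) %*% Bc / n_ok +
      lambda * bending_gradient(cf$cx)
    gcy <- t(Br) %*% (res * gy) %*% Bc / n_ok +
      lambda * bending_gradient(cf$cy)
    c(as.numeric(gcx), as.numeric(gcy))
  }
  fit <- stats::optim(rep(0, 2 * np), fn, gr,
    method = "L-BFGS-B",
    control = list(maxit = max_iter)
  )
  cf <- unpack(fit$par)
  field <- deformation_field(H, W, spacing, cf$cx, cf$cy)
  if (max(abs(field$ux), abs(field$uy)) > displacement_bound) {
    stop(sprintf(
      "elastic registration exceeded the %g px displacement bound",
      displacement_bound
    ), call. = FALSE)
  }
  field
}

#' B-spline elastic refinement of a linearly registered stack
#'
#' For each non-reference frame of an already linearly aligned stack,
#' estimates a cubic B-spline deformation field (control-point spacing
#' `grid_spacing` px) minimising the mean squared difference to the reference
#' plus a bending-energy regulariser with weight `lambda`, by L-BFGS with an
#' analytic gradient. The residual MSE after the elastic stage never exceeds
#' the residual after the linear stage (the optimiser starts from the zero
#' field).
#'
#' @param linear_stack A `registered_stack` from [register_linear()].
#' @param grid_spacing B-spline control-point spacing in pixels.
#' @param lambda Bending-energy weight.
#' @param max_iter L-BFGS iteration cap per frame.
#' @param displacement_bound Maximum allowed |displacement| in pixels; a
#'   larger fitted field raises a registration-failure error.
#' @return The `registered_stack` with `fields`, re-resampled `images`,
#'   updated validity masks and an `mse_elastic` column.
#' @export
register_elastic <- function(linear_stack, grid_spacing = 32, lambda = 0.1,
                             max_iter = 50L, displacement_bound = 15) {
  st <- linear_stack
  stopifnot(inherits(st, "registered_stack"))
  n <- length(st$images)
  ref_i <- st$reference_index
  ref <- as_pixel_matrix(st$images[[ref_i]])
  fields <- vector("list", n)
  mse_el <- numeric(n)
  for (k in seq_len(n)) {
    if (k == ref_i) {
      fields[[k]] <- deformation_field(nrow(ref), ncol(ref), grid_spacing)
      mse_el[k] <- 0
      next
    }
    mv <- as_pixel_matrix(st$images[[k]])
    f <- register_pair_elastic(
      mv, ref, st$valid[[ref_i]], grid_spacing, lambda,
      max_iter, displacement_bound
    )
    w <- warp_image_cpp(mv, 0, 0, 0, 1, f$ux, f$uy)
    new_valid <- w$valid & st$valid[[k]]
    img <- if (inherits(st$images[[k]], "enface")) {
      enface_like(w$image, st$images[[k]])
    } else {
      w$image
    }
    st$images[[k]] <- img
    st$valid[[k]] <- new_valid
    fields[[k]] <- f
    mse_el[k] <- mse_between(w$image, ref, new_valid)
  }
  st$fields <- fields
  st$validity_mask <- Reduce(`&`, st$valid)
  st$mse$mse_elastic <- mse_el
  st
}

#' Full registration pipeline (linear then elastic)
#'
#' @inheritParams register_linear
#' @inheritParams register_elastic
#' @param elastic Set `FALSE` to stop after the linear stage.
#' @return A `registered_stack`.
#' @export
register_stack <- function(stack, reference_index = 1L, elastic = TRUE,
                           grid_spacing = 32, lambda = 0.1,
                           max_iter = 50L) {
  st <- register_linear(stack, reference_index)
  if (elastic) {
    st <- register_elastic(st,
      grid_spacing = grid_spacing, lambda = lambda,
      max_iter = max_iter
    )
  }
  st
}

#' @export
print.registered_stack <- function(x, ...) {
  cat(sprintf(
    "<registered_stack> %d frames, reference %d, elastic: %s\n",
    length(x$images), x$reference_index,
    ifelse(is.null(x$fields), "no", "yes")
  ))
  print(x$mse)
  invisible(x)
}

# Bilinear sample of matrix m at fractional (row, col) coordinate vectors;
# out-of-range coordinates clamp to the border.
bilinear_at <- function(m, rows, cols) {
  H <- nrow(m)
  W <- ncol(m)
  rows <- pmin(pmax(rows, 1), H)
  cols <- pmin(pmax(cols, 1), W)
  r0 <- pmin(floor(rows), H - 1)
  c0 <- pmin(floor(cols), W - 1)
  fr <- rows - r0
  fc <- cols - c0
  (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
    fr * (1 - fc) * m[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * m[cbind(r0, c0 + 1)] +
    fr * fc * m[cbind(r0 + 1, c0 + 1)]
}

#' Registration recovery errors against synthetic ground truth
#'
#' For each non-reference frame, compares the recovered geometry with the
#' generator's: the similarity parameter errors (recovered transform vs the
#' inverse of the applied jitter) and the mean residual displacement in
#' pixels, obtained by composing the recovered mapping with the true warp —
#' a perfectly registered pixel maps back onto itself.
#'
#' @param reg A `registered_stack` from [register_linear()] /
#'   [register_stack()].
#' @param gt Ground truth from [generate_stack()].
#' @param stride Pixel subsampling stride for the residual computation.
#' @return A tibble with one row per non-reference frame: `frame`,
#'   `err_tx`, `err_ty`, `err_theta`, `err_s`, `mean_residual_px`.
#' @export
recovery_errors <- function(reg, gt, stride = 2L) {
  ref_i <- reg$reference_index
  H <- nrow(reg$images[[1]])
  W <- ncol(reg$images[[1]])
  rows <- seq(1L, H, by = stride)
  cols <- seq(1L, W, by = stride)
  px <- as.vector(matrix(cols, length(rows), length(cols), byrow = TRUE))
  py <- as.vector(matrix(rows, length(rows), length(cols)))
  out <- lapply(setdiff(seq_along(reg$images), ref_i), function(k) {
    B <- reg$transforms[[k]]
    inv_true <- invert_similarity(gt$transforms[[k]])
    x <- px
    y <- py
    keep <- reg$validity_mask[cbind(py, px)]
    x <- x[keep]
    y <- y[keep]
    if (!is.null(reg$fields) && !is.null(reg$fields[[k]])) {
      x1 <- x + bilinear_at(reg$fields[[k]]$ux, y, x)
      y1 <- y + bilinear_at(reg$fields[[k]]$uy, y, x)
    } else {
      x1 <- x
      y1 <- y
    }
    q <- apply_similarity(B, x1, y1, H, W)
    if (!is.null(gt$fields[[k]])) {
      qx <- q$x + bilinear_at(gt$fields[[k]]$ux, q$y, q$x)
      qy <- q$y + bilinear_at(gt$fields[[k]]$uy, q$y, q$x)
    } else {
      qx <- q$x
      qy <- q$y
    }
    fin <- apply_similarity(gt$transforms[[k]], qx, qy, H, W)
    tibble::tibble(
      frame = k,
      err_tx = abs(B$tx - inv_true$tx), err_ty = abs(B$ty - inv_true$ty),
      err_theta = abs(B$theta - inv_true$theta),
      err_s = abs(B$s - inv_true$s),
      mean_residual_px = mean(sqrt((fin$x - x)^2 + (fin$y - y)^2))
    )
  })
  dplyr::bind_rows(out)
}
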