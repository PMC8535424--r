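#' Specify a synthetic OCTA acquisition series
#'
#' Builds the parameter set for the synthetic angiogram generator. The
#' generator emulates the appearance of en-face angiograms of the retinal
#' capillary plexuses: bright branching arteriolar/venular trunks (superficial
#' plexus only) over a random capillary mesh on a dark background, Gaussian
#' acquisition noise, full-width bright motion-stripe artifacts, per-acquisition
#' rigid jitter (eye motion between sequential scans) plus a smooth elastic
#' deformation (ocular curvature), intermittent capillary perfusion (a fraction
#' of capillary segments carries no flow signal in any given acquisition), and,
#' for oedema eyes, dark cystoid regions that locally attenuate signal.
#'
#' Defaults are chosen so that the two-level intensity model (background near
#' 20, vessels near 180 on the 8-bit scale) makes the standard difference-map
#' thresholds (40 for SVP, 60 for DVC) meaningful. The deep complex style uses
#' a denser, finer mesh without large trunks and carries more noise; oedema
#' eyes get extra noise, stronger jitter and cystoid attenuation.
#'
#' @param image_side Image side in pixels (square raster).
#' @param slab_style `"SVP"` or `"DVC"` appearance.
#' @param group `"healthy"` or `"oedema"`.
#' @param n_trunks Number of large vessel trunks (SVP default 6; DVC 0).
#' @param branching_depth Trunk branching depth.
#' @param capillary_density Target fraction of pixels covered by the capillary
#'   mesh (trunks excluded); must be at most 0.6.
#' @param vessel_intensity_mean,background_mean Mean 8-bit intensities of
#'   vessel and background pixels.
#' @param noise_sd Gaussian noise SD (intensity levels).
#' @param motion_stripe_rate Expected number of bright motion-artifact rows
#'   per acquisition (Poisson).
#' @param jitter_translation_sd,jitter_rotation_sd,jitter_scale_sd SDs of the
#'   per-acquisition similarity jitter (pixels, degrees, unitless).
#' @param elastic_amp,elastic_scale Amplitude (px) and length scale (px) of
#'   the smooth per-acquisition elastic deformation.
#' @param dropout_rate Fraction of capillary segments non-perfused in each
#'   acquisition.
#' @param n_cysts Number of cystoid regions (oedema only).
#' @param n_acquisitions Number of sequential acquisitions per stack.
#' @param seed Master seed; every generator output is a pure function of
#'   (spec, seed).
#' @return A `synthetic_spec` list.
#' @examples
#' sp <- synthetic_spec(image_side = 128, seed = 1)
#' st <- generate_stack(sp)
#' length(st$images)
#' @export
synthetic_spec <- function(image_side = 516L,
                           slab_style = c("SVP", "DVC"),
                           group = c("healthy", "oedema"),
                           n_trunks = NULL,
                           branching_depth = 3L,
                           capillary_density = NULL,
                           vessel_intensity_mean = 180,
                           background_mean = 20,
                           noise_sd = NULL,
                           motion_stripe_rate = 1,
                           jitter_translation_sd = 4,
                           jitter_rotation_sd = 2,
                           jitter_scale_sd = 0.01,
                           elastic_amp = 4,
                           elastic_scale = 48,
                           dropout_rate = 0.15,
                           n_cysts = NULL,
                           n_acquisitions = 5L,
                           seed = 1L) {
  slab_style <- match.arg(slab_style)
  group <- match.arg(group)
  if (is.null(n_trunks)) n_trunks <- if (slab_style == "SVP") 6L else 0L
  if (is.null(capillary_density)) {
    capillary_density <- if (slab_style == "SVP") 0.18 else 0.28
  }
  if (is.null(noise_sd)) {
    noise_sd <- (if (slab_style == "SVP") 15 else 20) +
      (if (group == "oedema") 6 else 0)
  }
  if (is.null(n_cysts)) n_cysts <- if (group == "oedema") 4L else 0L
  if (group == "oedema") {
    jitter_translation_sd <- jitter_translation_sd * 1.5
    jitter_rotation_sd <- jitter_rotation_sd * 1.5
  }
  if (capillary_density > 0.6) {
    stop("capillary_density > 0.6 is not a plausible angiogram", call. = FALSE)
  }
  stopifnot(
    image_side >= 3, vessel_intensity_mean > background_mean,
    noise_sd >= 0, motion_stripe_rate >= 0, dropout_rate >= 0,
    dropout_rate <= 1, jitter_translation_sd >= 0, jitter_rotation_sd >= 0,
    jitter_scale_sd >= 0, elastic_amp >= 0, elastic_scale > 0,
    n_acquisitions >= 2
  )
  structure(
    list(
      image_side = as.integer(image_side), slab_style = slab_style,
      group = group, n_trunks = as.integer(n_trunks),
      branching_depth = as.integer(branching_depth),
      capillary_density = capillary_density,
      vessel_intensity_mean = vessel_intensity_mean,
      background_mean = background_mean, noise_sd = noise_sd,
      motion_stripe_rate = motion_stripe_rate,
      jitter_translation_sd = jitter_translation_sd,
      jitter_rotation_sd = jitter_rotation_sd,
      jitter_scale_sd = jitter_scale_sd,
      elastic_amp = elastic_amp, elastic_scale = elastic_scale,
      dropout_rate = dropout_rate, n_cysts = as.integer(n_cysts),
      n_acquisitions = as.integer(n_acquisitions), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# --- drawing primitives -----------------------------------------------------

# Stamp disks of given radius at (x, y) sample points into a logical matrix.
stamp_points <- function(mask, xs, ys, radius) {
  side_r <- nrow(mask)
  side_c <- ncol(mask)
  r <- max(0.5, radius)
  off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  off <- off[off$dx^2 + off$dy^2 <= r^2, , drop = FALSE]
  xi <- rep(round(xs), each = nrow(off)) + off$dx
  yi <- rep(round(ys), each = nrow(off)) + off$dy
  keep <- xi >= 1 & xi <= side_c & yi >= 1 & yi <= side_r
  mask[cbind(yi[keep], xi[keep])] <- TRUE
  mask
}

# A jagged branch path from (x, y) along `angle` (radians), returned as dense
# sample points; heading wanders so vessels are not straight lines.
branch_path <- function(x, y, angle, len, wiggle = 0.12) {
  n_steps <- max(4L, round(len / 1.5))
  headings <- angle + cumsum(rnorm(n_steps, 0, wiggle))
  xs <- x + cumsum(1.5 * cos(headings))
  ys <- y + cumsum(1.5 * sin(headings))
  list(x = c(x, xs), y = c(y, ys))
}

draw_trunk_tree <- function(mask, x, y, angle, len, width, depth) {
  path <- branch_path(x, y, angle, len)
  mask <- stamp_points(mask, path$x, path$y, width / 2)
  if (depth > 0L) {
    xe <- path$x[length(path$x)]
    ye <- path$y[length(path$y)]
    end_angle <- atan2(
      ye - path$y[length(path$y) - 1L],
      xe - path$x[length(path$x) - 1L]
    )
    for (sgn in c(-1, 1)) {
      child <- end_angle + sgn * runif(1, 0.35, 0.9)
      mask <- draw_trunk_tree(
        mask, xe, ye, child, len * 0.72,
        max(width - 1, 1), depth - 1L
      )
    }
  }
  mask
}

# Random-walk capillary path; returns linear pixel indices (width 1).
capillary_path <- function(side, n_steps, step, wiggle) {
  x <- runif(1, 1, side)
  y <- runif(1, 1, side)
  headings <- runif(1, 0, 2 * pi) + cumsum(rnorm(n_steps, 0, wiggle))
  xs <- round(x + cumsum(step * cos(headings)))
  ys <- round(y + cumsum(step * sin(headings)))
  keep <- xs >= 1 & xs <= side & ys >= 1 & ys <= side
  unique(ys[keep] + (xs[keep] - 1L) * side)
}

#' Generate a ground-truth vessel network
#'
#' Draws `n_trunks` branching vessel trees (recursive jagged branches, width
#' tapering from about 4 px down to 1 px) and overlays a random-walk capillary
#' mesh until the mesh covers approximately `capillary_density` of the raster.
#' The deep-complex style uses a finer, denser mesh and no trunks.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `vessel_mask` (logical), `trunk_mask`, and
#'   `capillary_paths` (list of pixel-index vectors, one per capillary
#'   segment; the unit of intermittent-perfusion dropout).
#' @export
generate_vessel_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  side <- spec$image_side
  trunk <- matrix(FALSE, side, side)
  if (spec$n_trunks > 0L) {
    for (i in seq_len(spec$n_trunks)) {
      edge <- sample(4L, 1L)
      pos <- runif(1, side * 0.1, side * 0.9)
      start <- switch(edge,
        c(1, pos, 0), c(side, pos, pi),
        c(pos, 1, pi / 2), c(pos, side, -pi / 2)
      )
      angle <- start[3] + runif(1, -0.5, 0.5)
      trunk <- draw_trunk_tree(
        trunk, start[1], start[2], angle,
        len = side / 3.2, width = 4, depth = spec$branching_depth
      )
    }
  }
  caps <- matrix(FALSE, side, side)
  paths <- list()
  if (spec$capillary_density > 0) {
    n_steps <- if (spec$slab_style == "SVP") 70L else 35L
    step <- if (spec$slab_style == "SVP") 1.3 else 1.0
    wiggle <- if (spec$slab_style == "SVP") 0.25 else 0.5
    target <- spec$capillary_density * side * side
    n_fg <- 0L
    max_paths <- 60000L
    while (n_fg < target && length(paths) < max_paths) {
      idx <- capillary_path(side, n_steps, step, wiggle)
      if (length(idx) == 0L) next
      paths[[length(paths) + 1L]] <- idx
      new <- idx[!caps[idx]]
      caps[new] <- TRUE
      n_fg <- n_fg + length(new)
    }
  }
  list(
    vessel_mask = trunk | caps, trunk_mask = trunk,
    capillary_paths = paths
  )
}

# --- quality index ----------------------------------------------------------

#' Acquisition quality score (signal-strength surrogate)
#'
#' A 0--100 quality index standing in for the device-reported Signal Strength
#' Index: the Michelson contrast between the 99th and 25th intensity
#' percentiles, divided by a robust noise estimate, mapped monotonically to
#' \[0, 100\]. Noise is estimated from horizontal first differences between
#' adjacent background pixels (both below the image median), scaled by the MAD
#' — this keeps vessel edges out of the noise estimate. A constant image
#' scores 0; adding noise to an image lowers its score.
#'
#' @param image An [enface] image or numeric matrix (0--255).
#' @return A number in \[0, 100\].
#' @export
ssi_surrogate <- function(image) {
  px <- as_pixel_matrix(image)
  if (length(px) == 0L) stop("empty image", call. = FALSE)
  rng <- range(px)
  if (rng[1] == rng[2]) return(0)
  q <- quantile(px, c(0.25, 0.99), names = FALSE)
  contrast <- (q[2] - q[1]) / (q[2] + q[1] + 1e-6)
  med <- median(px)
  a <- px[, -ncol(px)]
  b <- px[, -1]
  flat <- a <= med & b <= med
  noise <- if (any(flat)) {
    1.4826 * median(abs((b - a)[flat])) / sqrt(2)
  } else {
    0
  }
  snr <- contrast / (noise / 255 + 0.01)
  min(100, max(0, 100 * snr / (snr + 5)))
}

# --- rendering --------------------------------------------------------------

cyst_attenuation_map <- function(side, n_cysts) {
  map <- matrix(1, side, side)
  mask <- matrix(FALSE, side, side)
  if (n_cysts == 0L) return(list(map = map, mask = mask))
  xs <- matrix(seq_len(side), side, side, byrow = TRUE)
  ys <- matrix(seq_len(side), side, side)
  for (i in seq_len(n_cysts)) {
    cx <- runif(1, side * 0.25, side * 0.75)
    cy <- runif(1, side * 0.25, side * 0.75)
    a <- runif(1, side / 12, side / 6)
    b <- runif(1, side / 12, side / 6)
    f <- runif(1, 0.2, 0.5)
    q <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
    map <- map * (1 - (1 - f) * exp(-q^2))
    mask <- mask | (q <= 1)
  }
  list(map = map, mask = mask)
}

render_seed <- function(spec, k) spec$seed + 7919L * k

#' Render one synthetic acquisition
#'
#' Renders acquisition `k` from a ground-truth object: capillary segments
#' dropped out in this acquisition are removed from the vessel support;
#' vessels and background are drawn at their mean intensities; cystoid regions
#' attenuate the local signal (oedema eyes); zero-mean Gaussian noise is added
#' and the result clamped once to \[0, 255\]; the acquisition's similarity
#' jitter and elastic warp are applied; finally bright motion-stripe rows are
#' overwritten (stripes are scan-line artifacts, so they stay axis-aligned in
#' the output frame). The quality index of the result is attached.
#' Reproducible in isolation: acquisition `k` depends only on (spec, k).
#'
#' @param gt Ground truth from [generate_stack()].
#' @param spec The [synthetic_spec()] used to build `gt`.
#' @param k Acquisition index (1-based).
#' @return An [enface] image.
#' @export
render_acquisition <- function(gt, spec, k) {
  stopifnot(k >= 1, k <= length(gt$transforms))
  set.seed(render_seed(spec, k))
  side <- spec$image_side
  perfused <- gt$vessel_mask & !gt$dropout_masks[[k]]
  base <- matrix(spec$background_mean, side, side)
  base[perfused] <- spec$vessel_intensity_mean
  base <- base * gt$cyst_map
  if (spec$noise_sd > 0) {
    base <- base + matrix(rnorm(side * side, 0, spec$noise_sd), side, side)
  }
  base <- pmin(pmax(base, 0), 255)
  warped <- resample(base, gt$transforms[[k]], gt$fields[[k]])$image
  rows <- gt$stripe_rows[[k]]
  if (length(rows) > 0L) {
    warped[rows, ] <- pmin(pmax(
      matrix(rnorm(length(rows) * side, 200, 25), length(rows), side),
      0
    ), 255)
  }
  img <- enface(warped,
    slab = spec$slab_style, scan_area = "A3x3",
    eye_id = sprintf("SYN%d", spec$seed), acquisition_index = k
  )
  attr(img, "quality_index") <- ssi_surrogate(img)
  img
}

#' Generate a synthetic acquisition stack with ground truth
#'
#' Generates one eye's stack of sequential acquisitions. The first acquisition
#' carries identity geometry (it is the registration reference, so recovery of
#' the other acquisitions' transforms can be judged against absolute ground
#' truth); later acquisitions get independent similarity jitter and smooth
#' elastic warps. Each acquisition draws its own intermittent-perfusion
#' dropout and motion-stripe rows.
#'
#' @param spec A [synthetic_spec()].
#' @return An `octa_stack`: list with `images` (list of [enface]) and
#'   `ground_truth` (vessel/trunk masks, capillary paths, per-acquisition
#'   transforms, elastic fields, dropout masks, stripe rows, cyst map/mask).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  net <- generate_vessel_network(spec) # seeds with spec$seed
  side <- spec$image_side
  n <- spec$n_acquisitions
  cysts <- cyst_attenuation_map(side, spec$n_cysts)
  transforms <- vector("list", n)
  fields <- vector("list", n)
  dropout <- vector("list", n)
  stripes <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == 1L) {
      transforms[[k]] <- similarity_transform()
      fields[k] <- list(NULL)
    } else {
      transforms[[k]] <- similarity_transform(
        tx = rnorm(1, 0, spec$jitter_translation_sd),
        ty = rnorm(1, 0, spec$jitter_translation_sd),
        theta = rnorm(1, 0, spec$jitter_rotation_sd),
        s = max(0.8, 1 + rnorm(1, 0, spec$jitter_scale_sd))
      )
      fields[k] <- list(if (spec$elastic_amp > 0) {
        gaussian_bump_field(side, side, spec$elastic_amp, spec$elastic_scale)
      } else {
        NULL
      })
    }
    drop_mask <- matrix(FALSE, side, side)
    if (spec$dropout_rate > 0 && length(net$capillary_paths) > 0L) {
      dropped <- runif(length(net$capillary_paths)) < spec$dropout_rate
      for (idx in net$capillary_paths[dropped]) drop_mask[idx] <- TRUE
      drop_mask <- drop_mask & !net$trunk_mask
    }
    dropout[[k]] <- drop_mask
    n_stripes <- stats::rpois(1, spec$motion_stripe_rate)
    stripes[[k]] <- if (n_stripes > 0L) sample(side, min(n_stripes, side)) else integer(0)
  }
  gt <- list(
    vessel_mask = net$vessel_mask, trunk_mask = net$trunk_mask,
    capillary_paths = net$capillary_paths,
    transforms = transforms, fields = fields, dropout_masks = dropout,
    stripe_rows = stripes, cyst_map = cysts$map, cyst_mask = cysts$mask
  )
  images <- lapply(seq_len(n), function(k) render_acquisition(gt, spec, k))
  structure(list(images = images, ground_truth = gt, spec = spec),
    class = "octa_stack"
  )
}

#' @export
print.octa_stack <- function(x, ...) {
  cat(sprintf(
    "<octa_stack> %d acquisitions, %d x %d, style=%s group=%s seed=%d\n",
    length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
    x$spec$slab_style, x$spec$group, x$spec$seed
  ))
  invisible(x)
}

#' Consistently perfused vessel support
#'
#' Vessel pixels perfused in every acquisition (the vessel mask minus the
#' union of per-acquisition dropout masks). This is the support on which
#' averaging must never erase signal.
#'
#' @param gt Ground truth from [generate_stack()].
#' @return Logical matrix.
#' @export
consistent_vessel_mask <- function(gt) {
  m <- gt$vessel_mask
  for (d in gt$dropout_masks) m <- m & !d
  m
}
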