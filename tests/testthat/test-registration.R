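test_that("similarity transforms invert exactly", {
  t1 <- similarity_transform(5.2, -3.1, 7.5, 1.04)
  inv <- invert_similarity(t1)
  # composing forward and inverse mappings must fix arbitrary points
  pts <- list(c(10, 20), c(100, 7), c(55.5, 80.2))
  for (p in pts) {
    q <- octava:::apply_similarity(t1, p[1], p[2], 128, 128)
    back <- octava:::apply_similarity(inv, q$x, q$y, 128, 128)
    expect_equal(c(back$x, back$y), p, tolerance = 1e-10)
  }
})

test_that("resample is exact for identity and invalidates off-raster moves", {
  cv <- clean_vessel_image(64, seed = 1)
  r <- resample(cv$image)
  expect_identical_pixels(r$image, cv$image)
  expect_true(all(r$valid))

  off <- resample(cv$image, similarity_transform(tx = 64))
  expect_false(any(off$valid))
  expect_true(all(unclass(off$image) == 0))
})

test_that("translation round trip returns the original within interpolation error", {
  cv <- clean_vessel_image(96, seed = 2)
  fwd <- resample(cv$image, similarity_transform(5, 3))
  back <- resample(fwd$image, similarity_transform(-5, -3))
  joint <- back$valid & resample(fwd$valid * 1, similarity_transform(-5, -3))$image > 0.5
  diff <- abs(unclass(back$image) - unclass(cv$image))[joint]
  expect_lte(max(diff), 2)
})

test_that("self-registration returns the identity", {
  cv <- clean_vessel_image(96, seed = 3)
  st <- list(cv$image, cv$image)
  reg <- register_linear(st)
  t2 <- reg$transforms[[2]]
  expect_lte(abs(t2$tx), 0.1)
  expect_lte(abs(t2$ty), 0.1)
  expect_lte(abs(t2$theta), 0.05)
  expect_identical_pixels(reg$images[[1]], cv$image)
})

test_that("known shifts and rotations are recovered accurately", {
  cv <- clean_vessel_image(128, seed = 4)
  base <- cv$image

  shifted <- resample(base, similarity_transform(5, 3))$image
  reg <- register_linear(list(base, shifted))
  t2 <- reg$transforms[[2]]
  # registration recovers the inverse mapping of the applied warp
  expect_equal(t2$tx, -5, tolerance = 0.5 / 5)
  expect_equal(t2$ty, -3, tolerance = 0.5 / 3)

  rotated <- resample(base, similarity_transform(theta = 2))$image
  reg2 <- register_linear(list(base, rotated))
  expect_equal(reg2$transforms[[2]]$theta, -2, tolerance = 0.2 / 2)
})

test_that("registration never increases the MSE to the reference", {
  for (seed in 1:3) {
    sp <- synthetic_spec(image_side = 128, seed = seed)
    st <- generate_stack(sp)
    reg <- register_stack(st)
    m <- reg$mse[-reg$reference_index, ]
    expect_true(all(m$mse_linear <= m$mse_unregistered + 1e-9))
    expect_true(all(m$mse_elastic <= m$mse_linear + 1e-9))
  }
})

test_that("elastic refinement of an already identical frame stays near zero", {
  cv <- clean_vessel_image(96, seed = 5)
  reg <- register_stack(list(cv$image, cv$image), elastic = TRUE)
  f <- reg$fields[[2]]
  expect_lte(max(abs(f$ux), abs(f$uy)), 0.1)
})

test_that("a strong bending penalty shrinks the deformation field", {
  sp <- quiet_spec(96, seed = 6, elastic_amp = 3, capillary_density = 0.2)
  st <- generate_stack(sp)
  lin <- register_linear(st$images[1:2])
  mean_disp <- function(lambda) {
    el <- register_elastic(lin, lambda = lambda, max_iter = 30)
    f <- el$fields[[2]]
    mean(sqrt(f$ux^2 + f$uy^2))
  }
  d_small <- mean_disp(0.1)
  d_big <- mean_disp(1e6)
  expect_lt(d_big, d_small)
  expect_lt(d_big, 0.05)
})

test_that("a known smooth warp is recovered to subpixel accuracy", {
  sp <- quiet_spec(128, seed = 7, elastic_amp = 4, capillary_density = 0.25,
    noise_sd = 5
  )
  st <- generate_stack(sp)
  reg <- register_stack(st$images[1:3])
  # fold in ground truth: only frames 2..3 carry warps
  gt <- st$ground_truth
  gt$transforms <- gt$transforms[1:3]
  gt$fields <- gt$fields[1:3]
  errs <- recovery_errors(reg, gt)
  expect_lte(mean(errs$mean_residual_px), 1)
})

test_that("transforms outside the sanity bounds raise a registration failure", {
  cv <- clean_vessel_image(96, seed = 8)
  scaled <- resample(cv$image, similarity_transform(s = 1.1))$image
  expect_error(
    register_linear(list(cv$image, scaled), max_scale_dev = 0.01),
    "registration failed for frame 2"
  )
})
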