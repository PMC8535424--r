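test_that("an empty spec draws nothing and generation is deterministic", {
  sp <- quiet_spec(64, seed = 5, n_trunks = 0, capillary_density = 0)
  net <- generate_vessel_network(sp)
  expect_false(any(net$vessel_mask))

  sp2 <- quiet_spec(96, seed = 9, capillary_density = 0.15)
  expect_identical(
    generate_vessel_network(sp2)$vessel_mask,
    generate_vessel_network(sp2)$vessel_mask
  )
  st_a <- generate_stack(sp2)
  st_b <- generate_stack(sp2)
  expect_identical(
    lapply(st_a$images, unclass),
    lapply(st_b$images, unclass)
  )
})

test_that("capillary mesh coverage approximates the requested density", {
  for (seed in 1:3) {
    sp <- quiet_spec(128, seed = seed, n_trunks = 0, capillary_density = 0.2)
    net <- generate_vessel_network(sp)
    expect_equal(mean(net$vessel_mask), 0.2, tolerance = 0.05 / 0.2)
  }
  expect_error(
    synthetic_spec(capillary_density = 0.7),
    "capillary_density"
  )
})

test_that("the noiseless limit renders the exact two-level image", {
  cv <- clean_vessel_image(96, seed = 3)
  px <- unclass(cv$image)
  expect_setequal(unique(as.vector(px)), c(20, 180))
  expect_identical(px == 180, unname(cv$mask))
})

test_that("vessel pixels keep their mean intensity under noise", {
  sp <- quiet_spec(128, seed = 4, noise_sd = 10, capillary_density = 0.2)
  st <- generate_stack(sp)
  vessel_vals <- unclass(st$images[[1]])[st$ground_truth$vessel_mask]
  expect_equal(mean(vessel_vals), 180, tolerance = 2 / 180)
})

test_that("complete dropout removes all capillary signal", {
  sp <- quiet_spec(96, seed = 6, n_trunks = 0, capillary_density = 0.2,
    dropout_rate = 1, noise_sd = 5
  )
  st <- generate_stack(sp)
  img <- unclass(st$images[[1]])
  cap_pixels <- img[st$ground_truth$vessel_mask]
  # former capillary sites are indistinguishable from background
  expect_lt(abs(mean(cap_pixels) - 20), 1)
  expect_true(all(cap_pixels <= 20 + 5 * 5))
})

test_that("dropout masks vary across acquisitions and stay inside vessels", {
  any_differ <- FALSE
  for (seed in 1:10) {
    sp <- quiet_spec(64, seed = seed, n_trunks = 0, capillary_density = 0.15,
      dropout_rate = 0.3
    )
    st <- generate_stack(sp)
    dm <- st$ground_truth$dropout_masks
    for (d in dm) expect_true(all(st$ground_truth$vessel_mask[d]))
    if (!identical(dm[[1]], dm[[2]])) any_differ <- TRUE
  }
  expect_true(any_differ)
})

test_that("the first acquisition always carries identity geometry", {
  sp <- synthetic_spec(image_side = 64, seed = 2)
  st <- generate_stack(sp)
  t1 <- st$ground_truth$transforms[[1]]
  expect_equal(c(t1$tx, t1$ty, t1$theta, t1$s), c(0, 0, 0, 1))
  expect_null(st$ground_truth$fields[[1]])

  frozen <- quiet_spec(64, seed = 2)
  stf <- generate_stack(frozen)
  for (t in stf$ground_truth$transforms) {
    expect_equal(c(t$tx, t$ty, t$theta, t$s), c(0, 0, 0, 1))
  }
})

test_that("stack images share the spec's dimensions", {
  sp <- synthetic_spec(image_side = 80, seed = 1)
  st <- generate_stack(sp)
  expect_length(st$images, 5)
  for (img in st$images) expect_equal(dim(img), c(80, 80))
})

test_that("quality surrogate is zero for flat images and decreases with noise", {
  expect_equal(ssi_surrogate(matrix(50, 32, 32)), 0)
  cv <- clean_vessel_image(96, seed = 8)
  clean_q <- ssi_surrogate(cv$image)
  set.seed(1)
  noisy <- unclass(cv$image) + matrix(rnorm(96^2, 0, 30), 96, 96)
  expect_gt(clean_q, ssi_surrogate(pmin(pmax(noisy, 0), 255)))
})

test_that("quality surrogate regression value is stable", {
  cv <- clean_vessel_image(64, seed = 123)
  set.seed(99)
  img <- pmin(pmax(unclass(cv$image) +
    matrix(rnorm(64^2, 0, 15), 64, 64), 0), 255)
  # frozen from the first computed value of this fixture
  expect_equal(ssi_surrogate(img), 73.761672, tolerance = 1e-6)
})

test_that("oedema eyes carry cysts and score lower quality than healthy", {
  q_h <- q_o <- numeric(0)
  for (seed in 1:20) {
    sp_h <- synthetic_spec(image_side = 96, seed = seed, group = "healthy")
    sp_o <- synthetic_spec(image_side = 96, seed = seed, group = "oedema")
    st_o <- generate_stack(sp_o)
    expect_true(any(st_o$ground_truth$cyst_mask))
    q_h <- c(q_h, attr(generate_stack(sp_h)$images[[1]], "quality_index"))
    q_o <- c(q_o, attr(st_o$images[[1]], "quality_index"))
  }
  expect_gt(mean(q_h), mean(q_o))
})

test_that("healthy eyes carry no cysts", {
  sp <- synthetic_spec(image_side = 64, seed = 3, group = "healthy")
  st <- generate_stack(sp)
  expect_false(any(st$ground_truth$cyst_mask))
})

test_that("VD variability ranks oedema above healthy and DVC above SVP", {
  cv_of <- function(slab, group) {
    cvs <- numeric(0)
    for (seed in 1:12) {
      sp <- synthetic_spec(
        image_side = 128, seed = seed, slab_style = slab, group = group,
        jitter_translation_sd = 0, jitter_rotation_sd = 0,
        jitter_scale_sd = 0, elastic_amp = 0, motion_stripe_rate = 0
      )
      st <- generate_stack(sp)
      vd <- vapply(
        st$images,
        function(im) vessel_density(im)$vd_fraction, numeric(1)
      )
      cvs <- c(cvs, sd(vd) / mean(vd))
    }
    mean(cvs)
  }
  expect_gt(cv_of("SVP", "oedema"), cv_of("SVP", "healthy"))
  expect_gt(cv_of("DVC", "healthy"), cv_of("SVP", "healthy"))
})
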