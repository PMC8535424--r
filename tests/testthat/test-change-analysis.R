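test_that("positive-part subtraction obeys its algebra", {
  a <- matrix(c(50, 10, 200, 0), 2, 2)
  b <- matrix(c(30, 40, 200, 5), 2, 2)
  expect_equal(subtract_positive(a, b), pmax(a - b, 0))
  expect_true(all(subtract_positive(a, a) == 0))
  expect_equal(subtract_positive(a, b)[1, 1], 20)
  expect_equal(subtract_positive(b, a)[1, 1], 0)

  set.seed(11)
  for (i in 1:20) {
    x <- matrix(sample(0:255, 100, TRUE), 10, 10)
    y <- matrix(sample(0:255, 100, TRUE), 10, 10)
    expect_equal(subtract_positive(x, y) - subtract_positive(y, x), x - y)
    # disjoint support, always
    expect_true(all(subtract_positive(x, y) * subtract_positive(y, x) == 0))
  }
  expect_error(subtract_positive(a, matrix(0, 3, 3)), "differ in size")
})

test_that("binarization uses >= and the slab defaults", {
  m <- matrix(c(39, 40, 41, 60), 2, 2)
  expect_equal(binarize(m, 40), m >= 40)
  expect_true(all(binarize(m, 0)))
  expect_false(any(binarize(matrix(254, 3, 3), 255)))
  expect_equal(slab_threshold("SVP"), 40)
  expect_equal(slab_threshold("DVC"), 60)
  expect_equal(slab_threshold("FULL"), 40)
  expect_equal(binarize(m, slab = "DVC"), m >= 60)
})

test_that("binarized foreground is non-increasing in the threshold", {
  set.seed(3)
  m <- matrix(sample(0:255, 64^2, TRUE), 64, 64)
  counts <- vapply(
    seq(0, 255, by = 15),
    function(t) sum(binarize(m, t)), numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("overlays paint exactly the mask in pure red", {
  base <- matrix(sample(0:255, 36, TRUE), 6, 6)
  none <- make_overlay(base, matrix(FALSE, 6, 6))
  expect_equal(none[, , 1], base)
  expect_equal(none[, , 2], base)
  expect_equal(none[, , 3], base)

  all_mask <- make_overlay(base, matrix(TRUE, 6, 6))
  expect_true(all(all_mask[, , 1] == 255 & all_mask[, , 2] == 0 &
    all_mask[, , 3] == 0))

  checker <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  ov <- make_overlay(base, checker)
  expect_true(all(ov[, , 1][checker] == 255))
  expect_equal(ov[, , 2][!checker], base[!checker])
})

test_that("box scores count, flag and conserve totals", {
  empty <- matrix(FALSE, 516, 516)
  zero <- score_boxes(empty, empty)
  expect_true(all(zero$boxes$gain_pixels == 0))
  expect_equal(zero$gain_score, 0)
  expect_equal(zero$loss_score, 0)

  full <- matrix(TRUE, 516, 516)
  s <- score_boxes(full, empty)
  expect_true(all(s$boxes$gain_pixels == 172^2))
  expect_equal(s$gain_score, 9)

  set.seed(21)
  rnd <- matrix(runif(516^2) < 0.07, 516, 516)
  sr <- score_boxes(rnd, empty)
  expect_equal(sum(sr$boxes$gain_pixels), sum(rnd)) # grid tiles the raster
  # brute-force recount of one box
  expect_equal(
    sr$boxes$gain_pixels[5],
    sum(rnd[173:344, 173:344])
  )
  expect_error(
    score_boxes(matrix(FALSE, 100, 100), matrix(FALSE, 100, 100)),
    "does not fit"
  )
})

test_that("surrogate gain grading ignores gain outside true vessels", {
  gt_mask <- matrix(FALSE, 516, 516)
  gt_mask[1:172, 1:172] <- TRUE # vessels only in box 1
  gain <- matrix(TRUE, 516, 516)
  flags <- surrogate_grade_gain(gain, gt_mask)
  expect_equal(flags, c(1, rep(0, 8)))
  # restriction is a no-op when ground truth covers everything
  expect_equal(
    surrogate_grade_gain(gain, matrix(TRUE, 516, 516)),
    score_boxes(gain, matrix(FALSE, 516, 516))$boxes$gain_flag
  )
})

test_that("a restored dropped-out capillary is graded as true gain", {
  sp <- quiet_spec(516, seed = 13, n_trunks = 0, capillary_density = 0.15,
    dropout_rate = 0.3, noise_sd = 5
  )
  st <- generate_stack(sp)
  reg <- register_linear(st) # identity geometry; instant
  avg <- average_stack(reg)
  d <- diff_pipeline(avg, reg$images[[1]], slab = "SVP")
  flags <- surrogate_grade_gain(d$gain_mask, st$ground_truth$vessel_mask)
  expect_true(any(flags == 1))
  # nothing consistently perfused was erased
  expect_true(all(surrogate_grade_loss(d$loss_mask, st$ground_truth) == 0))
})

test_that("the difference pipeline composes its parts consistently", {
  cv <- clean_vessel_image(516, seed = 14)
  same <- diff_pipeline(cv$image, cv$image, slab = "SVP")
  expect_true(all(same$gain_map == 0))
  expect_true(all(same$loss_map == 0))
  expect_equal(same$scores$gain_score, 0)

  up <- enface(pmin(unclass(cv$image) + 50, 255))
  shifted <- diff_pipeline(up, cv$image, slab = "SVP")
  expect_true(all(shifted$gain_mask[unclass(cv$image) <= 205]))
  expect_equal(sum(shifted$loss_mask), 0)

  sp <- synthetic_spec(image_side = 516, seed = 15,
    jitter_translation_sd = 0, jitter_rotation_sd = 0, jitter_scale_sd = 0,
    elastic_amp = 0
  )
  st <- generate_stack(sp)
  avg <- average_stack(st$images)
  d <- diff_pipeline(avg, st$images[[1]], slab = "SVP")
  # independent recount: box sums equal whole-image mask counts
  expect_equal(sum(d$scores$boxes$gain_pixels), sum(d$gain_mask))
  expect_equal(sum(d$scores$boxes$loss_pixels), sum(d$loss_mask))
  # disjoint gain/loss support
  expect_true(all(d$gain_map * d$loss_map == 0))
})
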