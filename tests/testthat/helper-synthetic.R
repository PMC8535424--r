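# Small specs keep unit tests fast; the acceptance suite uses full-size
# cohorts.

quiet_spec <- function(side = 96, seed = 1, ...) {
  args <- list(
    image_side = side, seed = seed,
    jitter_translation_sd = 0, jitter_rotation_sd = 0, jitter_scale_sd = 0,
    elastic_amp = 0, motion_stripe_rate = 0, dropout_rate = 0, noise_sd = 0
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# Two-level vessel image without any corruption.
clean_vessel_image <- function(side = 96, seed = 1, vessel = 180,
                               background = 20) {
  sp <- quiet_spec(side, seed,
    vessel_intensity_mean = vessel,
    background_mean = background
  )
  st <- generate_stack(sp)
  list(image = st$images[[1]], mask = st$ground_truth$vessel_mask, stack = st)
}

expect_identical_pixels <- function(a, b) {
  expect_equal(
    unname(as.vector(unclass(a))), unname(as.vector(unclass(b)))
  )
}
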