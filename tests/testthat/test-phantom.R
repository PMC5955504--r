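test_that("a smooth-margin phantom mask is an exact filled ellipse", {
  # generic (non-lattice-aligned) centre: integer-aligned centres bias the
  # pixel count low by boundary ties
  spec <- phantom_spec(image_height = 64, image_width = 64,
                       lesion_center = c(32.3, 31.6), lesion_radii = c(12, 9),
                       margin_irregularity = 0, rng_seed = 3)
  ph <- generate_phantom(spec)
  expect_equal(sum(ph$mask$pixels), pi * 12 * 9, tolerance = 0.02)
  expect_true(all(ph$mask$pixels %in% c(0L, 1L)))
})

test_that("identical seeds give bit-identical phantoms", {
  spec <- phantom_spec(margin_irregularity = 0.15, shadow_strength = 0.4,
                       halo_width = 2, rng_seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$pixels, b$mask$pixels)
})

test_that("lesion/background contrast is respected on the generated image", {
  spec <- phantom_spec(contrast = 0.4, speckle_scale = 0.15, rng_seed = 5)
  ph <- generate_phantom(spec)
  inside <- ph$mask$pixels == 1
  ratio <- mean(ph$image$pixels[inside]) / mean(ph$image$pixels[!inside])
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.5)
})

test_that("speckle is multiplicative with unit mean and the noise-free field recovers the mask", {
  spec <- phantom_spec(contrast = 0.4, rng_seed = 17)
  ph <- generate_phantom(spec)
  noise <- ph$image$pixels / ph$image$field
  se <- stats::sd(noise) / sqrt(length(noise))
  expect_lt(abs(mean(noise) - 1), 3 * se + 1e-9)
  # thresholding the noise-free field at the contrast midpoint recovers the mask
  midpoint <- 0.55 * (1 + spec$contrast) / 2
  recovered <- (ph$image$field < midpoint) * 1L
  expect_gte(dice_coef(recovered, ph$mask$pixels), 0.98)
})

test_that("posterior shadowing attenuates the column band beneath the lesion", {
  base <- phantom_spec(shadow_strength = 0, speckle_scale = 0.1,
                       lesion_center = c(24, 32), rng_seed = 8)
  shadowed <- phantom_spec(shadow_strength = 0.6, speckle_scale = 0.1,
                           lesion_center = c(24, 32), rng_seed = 8)
  a <- generate_phantom(base)
  b <- generate_phantom(shadowed)
  below <- a$image$field[50:64, 28:36]
  below_sh <- b$image$field[50:64, 28:36]
  expect_lt(mean(below_sh), 0.75 * mean(below))
})

test_that("out-of-frame lesions are rejected with the offending coordinate", {
  expect_error(phantom_spec(lesion_center = c(5, 32), lesion_radii = c(12, 12)),
               "row")
  expect_error(phantom_spec(lesion_center = c(32, 60), lesion_radii = c(8, 12)),
               "col")
})

test_that("generate_dataset groups images by patient with jittered geometry", {
  ds <- generate_dataset(10, 2, rng_seed = 21)
  expect_equal(nrow(ds), 20)
  expect_equal(dplyr::n_distinct(ds$patient_id), 10)
  ds2 <- generate_dataset(10, 2, rng_seed = 21)
  expect_identical(purrr::map(ds$image, "pixels"), purrr::map(ds2$image, "pixels"))
  # per-patient views share one geometry up to the stated jitter
  centers <- purrr::map(ds$spec, "lesion_center")
  by_pat <- split(centers, ds$patient_id)
  jitter <- phantom_ranges()$center_jitter
  for (views in by_pat) {
    expect_lte(max(abs(views[[1]] - views[[2]])), 2 * jitter)
  }
})

test_that("datasets round-trip through PNG + manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, 2, rng_seed = 31)
  manifest <- write_dataset(ds, dir)
  expect_equal(nrow(manifest), 2 * nrow(ds))
  back <- read_dataset(dir)
  expect_equal(nrow(back), nrow(ds))
  expect_identical(back$mask[[1]]$pixels, ds$mask[[1]]$pixels)
  # 8-bit quantisation: intensities agree to half a grey level
  expect_lt(max(abs(back$image[[1]]$pixels -
                      pmin(pmax(ds$image[[1]]$pixels, 0), 1))), 1 / 255)
})
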