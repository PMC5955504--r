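test_that("seed erosion follows the published size rule on square masks", {
  sq <- function(side, h = 60, w = 60) {
    m <- matrix(0L, h, w)
    m[seq_len(side) + 10, seq_len(side) + 10] <- 1L
    m
  }
  s400 <- make_seed(sq(20))          # area 400 < 500 -> erode by 4
  expect_equal(sum(s400$pixels), 12 * 12)
  s900 <- make_seed(sq(30))          # area 900 > 500 -> erode by 8
  expect_equal(sum(s900$pixels), 14 * 14)
  # exactly 500 px is treated as large
  m500 <- matrix(0L, 60, 60); m500[11:30, 11:35] <- 1L   # 20 x 25 = 500
  s500 <- make_seed(m500)
  expect_equal(sum(s500$pixels), 4 * 9)
  # erosion result is always inside the truth
  expect_true(all(s900$pixels <= sq(30)))
  expect_equal(s900$role, "seed")
  expect_error(make_seed(matrix(0L, 20, 20)), "empty")
})

test_that("a seed too small to survive erosion falls back to the centroid", {
  m <- matrix(0L, 32, 32); m[15:18, 15:18] <- 1L
  expect_message(s <- make_seed(m), "centroid")
  expect_equal(sum(s$pixels), 1)
  expect_equal(which(s$pixels == 1, arr.ind = TRUE)[1, ], c(row = 16, col = 16),
               ignore_attr = TRUE)
})

test_that("edge indicator is 1 on flat images and dips at edges; ramps match 1/(1+s^2)", {
  g <- edge_indicator(matrix(5, 40, 40), sigma_smooth = 0)
  expect_true(all(g == 1))
  step <- matrix(0, 40, 40); step[, 21:40] <- 10
  gs <- edge_indicator(step, sigma_smooth = 1)
  expect_lt(min(gs), min(gs[, 1:5]))
  # linear ramp of slope s: interior gradient is exactly s
  s <- 0.8
  ramp <- matrix(rep(s * (1:40), each = 40), 40, 40, byrow = FALSE)
  ramp <- t(ramp)
  gr <- edge_indicator(ramp, sigma_smooth = 0)
  expect_equal(gr[20, 20], 1 / (1 + s^2), tolerance = 1e-6)
})

test_that("stability bound and divergence detection are enforced", {
  expect_error(drls_config(mu_weight = 0.1, timestep = 5), "stability")
  f <- level_set_field(matrix(rnorm(16 * 16), 16, 16))
  expect_error(evolve(f, matrix(1, 8, 8)), "share a grid")
})

test_that("balloon force with no edges expands the contour strictly every iteration", {
  seed <- matrix(0L, 64, 64); seed[28:36, 28:36] <- 1L
  cfg <- drls_config(timestep = 1, mu_weight = 0.2, epsilon_width = 1.5)
  f <- init_level_set(seed, cfg, method = "signed_distance")
  g1 <- matrix(1, 64, 64)
  areas <- enclosed_area(f, 1.5)
  for (i in 1:60) {
    f <- evolve(f, g1, cfg, steps = 1)
    areas <- c(areas, enclosed_area(f, 1.5))
    expect_true(all(is.finite(f$phi)))
  }
  expect_true(all(diff(areas) > 0))
  expect_gt(sum(f$phi < 0), sum(seed))
})

test_that("pure regularization leaves a signed-distance contour near-stationary", {
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, `+`)) - 15
  cfg <- drls_config(lambda_weight = 0, alpha_weight = 0)
  f <- evolve(level_set_field(d), matrix(1, 64, 64), cfg, steps = 50)
  a0 <- sum(d < 0)
  expect_lt(abs(sum(f$phi < 0) - a0) / a0, 0.05)
})

test_that("the level-set benchmark segments a sharp disk phantom accurately", {
  spec <- phantom_spec(image_height = 128, image_width = 128,
                       lesion_center = c(64, 64), lesion_radii = c(30, 30),
                       margin_irregularity = 0, contrast = 0.3,
                       speckle_scale = 0.2, rng_seed = 7)
  ph <- generate_phantom(spec)
  res <- segment_drls(ph$image, ph$mask)
  expect_true(all(is.finite(res$field$phi)))
  expect_gte(dice_coef(res$mask, ph$mask), 0.95)
  # seed rule: lesion ~2800 px -> erosion by 8
  expect_lt(sum(res$seed$pixels), sum(ph$mask$pixels))
  expect_true(all(res$seed$pixels <= ph$mask$pixels))
})

test_that("keeping the truth as seed with no balloon force stays put", {
  spec <- phantom_spec(image_height = 96, image_width = 96,
                       lesion_center = c(48, 48), lesion_radii = c(20, 20),
                       contrast = 0.3, speckle_scale = 0.2, rng_seed = 19)
  ph <- generate_phantom(spec)
  cfg <- drls_config(alpha_weight = 0, n_iterations = 300)
  img <- ph$image$pixels
  img255 <- 255 * (img - min(img)) / diff(range(img))
  g <- edge_indicator(img255, cfg$sigma_smooth)
  f <- evolve(init_level_set(ph$mask$pixels, cfg), g, cfg, cfg$n_iterations)
  expect_gte(dice_coef((f$phi < 0) * 1L, ph$mask$pixels), 0.95)
})

test_that("a contrastless image is over-segmented: the failure mode is flagged by FPF", {
  blank <- matrix(0.5, 96, 96)
  truth <- matrix(0L, 96, 96); truth[36:60, 36:60] <- 1L
  res <- segment_drls(blank, truth, drls_config(n_iterations = 400))
  expect_gt(fpf(res$mask, truth), 0)
  expect_gt(sum(res$mask$pixels), sum(truth))
})
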