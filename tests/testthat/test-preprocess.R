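test_that("resize_pad scales the long side and centres the short side with zeros", {
  img <- matrix(runif(300 * 600), 300, 600)
  res <- resize_pad(img, config = preprocess_config(target_size = 208))
  expect_equal(dim(res$image), c(208, 208))
  p <- res$placement
  expect_equal(p$content_h, 104)
  expect_equal(p$content_w, 208)
  expect_equal(p$pad_top, 52)
  expect_true(all(res$image[1:52, ] == 0))
  expect_true(all(res$image[157:208, ] == 0))

  sq <- resize_pad(matrix(runif(600 * 600), 600, 600),
                   config = preprocess_config(208))
  expect_equal(sq$placement$pad_top, 0)
  expect_equal(sq$placement$pad_left, 0)
})

test_that("aspect ratio of the content region is preserved to rounding", {
  set.seed(4)
  for (i in 1:10) {
    h <- sample(50:400, 1); w <- sample(50:400, 1)
    res <- resize_pad(matrix(1, h, w), config = preprocess_config(208))
    p <- res$placement
    # the long side maps to 208 exactly; the short side is within half a
    # pixel of exact proportional scaling
    expect_equal(max(p$content_h, p$content_w), 208)
    expect_lte(abs(min(p$content_h, p$content_w) - 208 * min(h, w) / max(h, w)), 0.5)
  }
})

test_that("masks stay strictly binary through resize and map_back inverts placement", {
  set.seed(9)
  img <- matrix(runif(180 * 240), 180, 240)
  mask <- matrix(0L, 180, 240)
  mask[60:120, 90:170] <- 1L   # 61 x 81 lesion, well over 100 px
  res <- resize_pad(img, mask, preprocess_config(208))
  expect_true(all(res$mask %in% c(0L, 1L)))
  back <- map_back(res$mask, res$placement)
  expect_equal(dim(back), c(180, 240))
  expect_gte(dice_coef(back, mask), 0.95)
})

test_that("standardize yields mean 0, population sd 1, and handles constants", {
  x <- matrix(c(0, 2, 0, 2), 2, 2)
  out <- standardize(x)
  expect_equal(sort(unique(as.vector(out))), c(-1, 1))
  y <- standardize(matrix(runif(500), 20, 25))
  expect_lt(abs(mean(y)), 1e-6)
  expect_lt(abs(sqrt(mean(y^2)) - 1), 1e-6)
  expect_warning(z <- standardize(matrix(3, 8, 8)), "constant")
  expect_true(all(z == 0))
})

test_that("augmentation output is exactly a horizontal flip composed with an equal-axis zoom", {
  set.seed(12)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(0L, 64, 64); mask[20:40, 25:45] <- 1L
  cfg <- preprocess_config(target_size = 64)
  for (i in 1:20) {
    ag <- augment(img, mask, cfg)
    redo <- apply_flip_zoom(img, mask, ag$flipped, ag$zoom)
    expect_identical(ag$image, redo$image)
    expect_identical(ag$mask, redo$mask)
    expect_true(ag$zoom >= cfg$zoom_range[1] && ag$zoom <= cfg$zoom_range[2])
    expect_true(all(ag$mask %in% c(0L, 1L)))
  }
})

test_that("flip is an involution and unit zoom is the identity", {
  img <- matrix(runif(48 * 48), 48, 48)
  mask <- matrix(rbinom(48 * 48, 1, 0.2), 48, 48)
  once <- apply_flip_zoom(img, mask, flipped = TRUE, zoom = 1)
  twice <- apply_flip_zoom(once$image, once$mask, flipped = TRUE, zoom = 1)
  expect_equal(twice$image, img)
  expect_equal(matrix(twice$mask, 48, 48), matrix(as.integer(mask), 48, 48))
  none <- apply_flip_zoom(img, mask, flipped = FALSE, zoom = 1)
  expect_equal(none$image, img)
})

test_that("zoom scales mask area by the squared factor", {
  mask <- matrix(0L, 100, 100)
  ij <- which(outer((1:100 - 50)^2, (1:100 - 50)^2, `+`) <= 20^2)
  mask[ij] <- 1L
  a0 <- sum(mask)
  z <- apply_flip_zoom(matrix(0, 100, 100), mask, flipped = FALSE, zoom = 1.25)
  expect_equal(sum(z$mask) / a0, 1.25^2, tolerance = 0.05)
})

test_that("zoomed-out images are centre-padded with zeros", {
  img <- matrix(1, 60, 60)
  mask <- matrix(1L, 60, 60)
  z <- apply_flip_zoom(img, mask, flipped = FALSE, zoom = 0.5)
  expect_equal(dim(z$image), c(60, 60))
  expect_equal(z$image[1, 1], 0)
  expect_equal(sum(z$mask), 30 * 30)
})
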