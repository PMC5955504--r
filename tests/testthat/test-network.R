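test_that("filter counts follow 2^(base + layer) and shapes propagate as published", {
  mu <- build_network(network_config("multi_unet"))
  enc <- dplyr::filter(mu$shapes, .data$stage %in% c("encoder", "bottleneck"))
  expect_equal(enc$filters, c(64, 128, 256, 512, 1024))
  expect_equal(enc$height[enc$stage == "bottleneck"], 13)
  expect_equal(mu$output_size, 208)

  ou <- build_network(network_config("original_unet"))
  expect_equal(ou$output_size, 388)
  expect_equal(ou$crops, c(88, 40, 16, 4))
  dec <- dplyr::filter(ou$shapes, .data$stage == "decoder")
  expect_equal(dec$crop_per_edge[order(dec$level)], c(88, 40, 16, 4))
})

test_that("incompatible input sizes are rejected naming the offending layer", {
  expect_error(build_network(network_config("multi_unet", input_size = 100)),
               "layer 3")
  expect_error(network_config("multi_unet",
                              crop_per_edge_by_layer = c(1, 2, 3, 4)),
               "original_unet")
  expect_error(build_network(network_config("original_unet", input_size = 570)),
               "layer")
})

test_that("doubling the filter base doubles every layer's filter count", {
  a <- build_network(scale_profile(rng_seed = 1))
  b <- build_network(scale_profile(filter_exponent_base = 3, rng_seed = 1))
  expect_equal(b$shapes$filters, 2 * a$shapes$filters)
  # introspect actual weight shapes, not just the table
  for (l in 1:4) {
    expect_equal(ncol(b$params$enc[[l]]$conv1$w),
                 2 * ncol(a$params$enc[[l]]$conv1$w))
  }
})

test_that("soft dice loss matches its closed forms and a brute-force sum", {
  g <- matrix(rbinom(25, 1, 0.5), 5, 5)
  g[1, 1] <- 1
  # perfect prediction, smooth -> 0 limit
  expect_equal(soft_dice_loss(g, g, smooth = 1e-12), -1, tolerance = 1e-9)
  # all-zero prediction closed form
  expect_equal(soft_dice_loss(matrix(0, 5, 5), g, smooth = 1),
               -1 / (sum(g) + 1))
  # brute-force oracle on random probabilities
  set.seed(42)
  for (i in 1:10) {
    p <- matrix(runif(25), 5, 5)
    acc_num <- 0; acc_p <- 0; acc_g <- 0
    for (r in 1:5) for (c in 1:5) {
      acc_num <- acc_num + p[r, c] * g[r, c]
      acc_p <- acc_p + p[r, c]; acc_g <- acc_g + g[r, c]
    }
    expect_equal(soft_dice_loss(p, g, 1), -(2 * acc_num + 1) / (acc_p + acc_g + 1),
                 tolerance = 1e-12)
  }
  expect_error(soft_dice_loss(matrix(0, 4, 4), g), "shape")
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- network_config("multi_unet", depth = 3, filter_exponent_base = 1,
                        input_size = 16, dropout_rate = 0, rng_seed = 11)
  model <- build_network(cfg)
  set.seed(2)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
  g <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 2, 1))
  fw <- busseg:::unet_forward(model, x, training = TRUE)
  lb <- busseg:::negative_dice_batch(fw$y, g, 1)
  dz <- lb$dp * fw$y * (1 - fw$y)
  grads <- busseg:::unet_backward(model, fw$cache, dz)
  eps <- 1e-6
  spots <- list(list(c("enc", "conv1"), 1), list(c("dec", "conv2"), 1),
                list(c("out"), NA))
  for (s in spots) {
    m2 <- model
    if (s[[1]][1] == "out") {
      ana <- grads$out$w[1]
      m2$params$out$w[1] <- m2$params$out$w[1] + eps
    } else {
      lev <- s[[2]]
      ana <- grads[[s[[1]][1]]][[lev]][[s[[1]][2]]]$w[3]
      m2$params[[s[[1]][1]]][[lev]][[s[[1]][2]]]$w[3] <-
        m2$params[[s[[1]][1]]][[lev]][[s[[1]][2]]]$w[3] + eps
    }
    fw2 <- busseg:::unet_forward(m2, x, training = FALSE)
    num <- (busseg:::negative_dice_batch(fw2$y, g, 1)$loss - lb$loss) / eps
    expect_equal(ana, num, tolerance = 1e-3)
  }
})

test_that("compiled patch kernels agree exactly with the base-R reference", {
  set.seed(5)
  for (i in 1:12) {
    h <- sample(4:10, 1); w <- sample(4:10, 1)
    n <- sample(1:3, 1); ch <- sample(1:4, 1)
    k <- sample(c(1L, 3L), 1); pad <- if (k == 3L) sample(0:1, 1) else 0L
    x <- array(rnorm(h * w * n * ch), c(h, w, n, ch))
    expect_identical(busseg:::im2col(x, k, pad)$m, busseg:::im2col_ref(x, k, pad))
    dm <- matrix(rnorm((h + 2 * pad - k + 1) * (w + 2 * pad - k + 1) * n * k * k * ch),
                 ncol = k * k * ch)
    expect_identical(busseg:::col2im(dm, k, pad, dim(x)),
                     busseg:::col2im_ref(dm, k, pad, dim(x)))
  }
})

test_that("prediction is bounded, deterministic and spatially constant on constant input", {
  cfg <- scale_profile(rng_seed = 21)
  model <- build_network(cfg)
  x <- standardize(matrix(runif(64 * 64), 64, 64))
  p1 <- predict_map(model, x)
  p2 <- predict_map(model, x)
  expect_true(all(p1$pixels >= 0 & p1$pixels <= 1))
  expect_identical(p1$pixels, p2$pixels)
  expect_error(predict_map(model, matrix(0, 32, 32)), "64x64")
  # zero the biases: constant input then yields a constant map
  model$params <- rapply(model$params, function(p) {
    if (is.null(dim(p))) p * 0 else p
  }, how = "replace")
  pc <- predict_map(model, matrix(0, 64, 64))
  expect_lt(diff(range(pc$pixels)), 1e-12)
})

test_that("training rejects patient overlap and an empty training set", {
  ds <- generate_dataset(4, 1, rng_seed = 3)
  model <- build_network(scale_profile(rng_seed = 1))
  expect_error(train_member(model, ds, ds), "share patients")
  expect_error(train_member(model, ds[0, ], ds), "empty")
})

test_that("a member learns on high-contrast phantoms and is seed-reproducible", {
  ds <- generate_dataset(12, 2, spec_ranges = list(contrast = c(0.25, 0.35)),
                         rng_seed = 77)
  tr <- ds[ds$patient_id <= "P010", ]
  va <- ds[ds$patient_id > "P010", ]
  cfg <- scale_profile(rng_seed = 9, epochs = 6)
  m1 <- train_member(build_network(cfg), tr, va)
  expect_gt(m1$val_dice, m1$history$val_dice[1])
  expect_gt(m1$val_dice, 0.15)
  m2 <- train_member(build_network(cfg), tr, va)
  # repeatable to floating-point reproducibility on one platform
  expect_equal(m1$history$train_loss, m2$history$train_loss, tolerance = 1e-10)
  expect_equal(m1$params$out$w, m2$params$out$w, tolerance = 1e-10)
})
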