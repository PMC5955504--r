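#' U-net configuration
#'
#' Collects every architecture and training hyperparameter of the two
#' network variants. `"multi_unet"` is the ensemble member: zero-padded
#' 3x3 convolutions (output grid equals input grid), one-channel sigmoid
#' output, negative soft-Dice loss, RMSprop, LeCun-uniform initialisation,
#' dropout 0.6 at the deepest layer. `"original_unet"` is the classic
#' comparator: unpadded convolutions with cropped skip connections,
#' two-channel softmax output, categorical cross-entropy, SGD with
#' momentum 0.99, Xavier-normal initialisation, dropout 0.5. Layer `l`
#' carries `2^(filter_exponent_base + l)` filters, so the default base 5
#' gives 64, 128, 256, 512, 1024 filters down the encoder.
#'
#' Loss, optimizer, initialisation and dropout can be overridden
#' independently of the variant, which is how a padded desk-scale network
#' can be trained with the comparator's recipe.
#'
#' @param variant `"multi_unet"` or `"original_unet"`.
#' @param depth Number of encoder levels (default 5).
#' @param filter_exponent_base Integer `b`: level `l` has `2^(b+l)` filters.
#' @param input_size Side of the square input grid (208 for multi_unet,
#'   572 for original_unet).
#' @param dropout_rate Dropout at the deepest level (default 0.6 / 0.5).
#' @param optimizer `"rmsprop"` or `"sgd"`.
#' @param learning_rate Optimizer step size (default 5e-6 for RMSprop per
#'   the multi U-net recipe; 0.01 for SGD, whose published recipe states
#'   only the momentum).
#' @param momentum SGD momentum (default 0.99).
#' @param rmsprop_rho RMSprop decay (default 0.9).
#' @param loss `"negative_dice"` or `"categorical_crossentropy"`.
#' @param init `"lecun_uniform"` or `"xavier_normal"`.
#' @param leaky_slope Negative-side slope of the leaky ReLU (default 0.01).
#' @param dice_smooth Smoothing constant of the soft-Dice loss (default 1,
#'   avoiding 0/0 on empty masks).
#' @param epochs,batch_size,patience Training-loop controls; training stops
#'   early when validation Dice has not improved for `patience` epochs.
#' @param augment Apply horizontal-flip / equal-axis-zoom augmentation
#'   during training.
#' @param crop_per_edge_by_layer Integer crops per edge for the skip
#'   connections of `original_unet` (derived from shape propagation when
#'   `NULL`; 88, 40, 16, 4 for the 572-pixel input).
#' @param rng_seed Seed for weight initialisation and training randomness.
#' @return An object of class `network_config`.
#' @export
network_config <- function(variant = c("multi_unet", "original_unet"),
                           depth = 5, filter_exponent_base = 5,
                           input_size = NULL, dropout_rate = NULL,
                           optimizer = NULL, learning_rate = NULL,
                           momentum = 0.99, rmsprop_rho = 0.9,
                           loss = NULL, init = NULL,
                           leaky_slope = 0.01, dice_smooth = 1,
                           epochs = 50, batch_size = 8, patience = 10,
                           augment = TRUE,
                           crop_per_edge_by_layer = NULL,
                           rng_seed = 1L) {
  variant <- match.arg(variant)
  is_multi <- variant == "multi_unet"
  input_size <- input_size %||% if (is_multi) 208L else 572L
  dropout_rate <- dropout_rate %||% if (is_multi) 0.6 else 0.5
  optimizer <- optimizer %||% if (is_multi) "rmsprop" else "sgd"
  learning_rate <- learning_rate %||% if (optimizer == "rmsprop") 5e-6 else 0.01
  loss <- loss %||% if (is_multi) "negative_dice" else "categorical_crossentropy"
  init <- init %||% if (is_multi) "lecun_uniform" else "xavier_normal"
  if (!loss %in% c("negative_dice", "categorical_crossentropy")) {
    abort("`loss` must be 'negative_dice' or 'categorical_crossentropy'")
  }
  if (!init %in% c("lecun_uniform", "xavier_normal")) {
    abort("`init` must be 'lecun_uniform' or 'xavier_normal'")
  }
  if (!optimizer %in% c("rmsprop", "sgd")) {
    abort("`optimizer` must be 'rmsprop' or 'sgd'")
  }
  if (!is_multi && is.null(crop_per_edge_by_layer) && depth == 5 &&
      input_size == 572) {
    crop_per_edge_by_layer <- c(88L, 40L, 16L, 4L)
  }
  if (is_multi && !is.null(crop_per_edge_by_layer)) {
    abort("`crop_per_edge_by_layer` applies only to original_unet")
  }
  structure(list(
    variant = variant, depth = as.integer(depth),
    filter_exponent_base = as.integer(filter_exponent_base),
    input_size = as.integer(input_size),
    conv_size = 3L, conv_stride = 1L,
    padding_mode = if (is_multi) "zero" else "none",
    pool_size = 2L, dropout_rate = dropout_rate, upsample_size = 2L,
    optimizer = optimizer, learning_rate = learning_rate,
    momentum = momentum, rmsprop_rho = rmsprop_rho,
    loss = loss, init = init, leaky_slope = leaky_slope,
    dice_smooth = dice_smooth, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), patience = as.integer(patience),
    augment = isTRUE(augment),
    crop_per_edge_by_layer = crop_per_edge_by_layer,
    rng_seed = as.integer(rng_seed)
  ), class = "network_config")
}

#' Desk-scale network profile
#'
#' A reduced multi-U-net configuration (64-pixel input, filter base 2 --
#' 8, 16, 32, 64 filters -- depth 4) that trains in minutes on one CPU
#' while exercising every architectural element of the full network. The
#' learning rate is raised to 2e-4: at this width and sample size the
#' published 5e-6 step, tuned for the full-scale network, moves the
#' soft-Dice loss imperceptibly, while steps much above 2e-4 destabilise
#' the negative-Dice objective (it collapses into the empty-mask
#' attractor).
#'
#' @param ... Overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
scale_profile <- function(...) {
  args <- list(...)
  defaults <- list(variant = "multi_unet", depth = 4, filter_exponent_base = 2,
                   input_size = 64L, learning_rate = 2e-4, epochs = 8,
                   batch_size = 8, patience = 4)
  do.call(network_config, modifyList(defaults, args))
}

n_filters <- function(config, level) 2L^(config$filter_exponent_base + level)

# Shape propagation. Returns list(shapes = tibble, crops = integer vector
# indexed by decoder level, output_size). Errors name the first layer whose
# grid becomes non-integral or collapses.
propagate_shapes <- function(config) {
  d <- config$depth
  pad <- config$padding_mode == "zero"
  shrink <- if (pad) 0L else 4L   # two 3x3 convs
  s <- config$input_size
  enc <- integer(d)
  rows <- list()
  for (l in seq_len(d)) {
    s <- s - shrink
    if (s < 1) abort(sprintf("encoder layer %d: grid collapsed to %d", l, s))
    enc[l] <- s
    rows[[length(rows) + 1]] <- tibble::tibble(
      stage = if (l == d) "bottleneck" else "encoder", level = l,
      height = s, width = s, filters = n_filters(config, l), crop_per_edge = NA_integer_)
    if (l < d) {
      if (s %% 2 != 0) {
        abort(sprintf("encoder layer %d: grid %d is odd, cannot max-pool", l, s))
      }
      s <- s %/% 2L
    }
  }
  crops <- integer(d - 1)
  for (l in rev(seq_len(d - 1))) {
    s <- 2L * s
    cr <- enc[l] - s
    if (cr < 0 || cr %% 2 != 0) {
      abort(sprintf("decoder level %d: skip grid %d does not align with upsampled grid %d",
                    l, enc[l], s))
    }
    crops[l] <- cr %/% 2L
    s <- s - shrink
    if (s < 1) abort(sprintf("decoder level %d: grid collapsed to %d", l, s))
    rows[[length(rows) + 1]] <- tibble::tibble(
      stage = "decoder", level = l, height = s, width = s,
      filters = n_filters(config, l), crop_per_edge = crops[l])
  }
  list(shapes = dplyr::bind_rows(rows), crops = crops, output_size = s)
}

init_weights <- function(fan_in, fan_out, n_row, n_col, init) {
  if (init == "lecun_uniform") {
    lim <- sqrt(3 / fan_in)
    matrix(runif(n_row * n_col, -lim, lim), n_row, n_col)
  } else {
    matrix(rnorm(n_row * n_col, sd = sqrt(2 / (fan_in + fan_out))), n_row, n_col)
  }
}

#' Build a U-net model
#'
#' Instantiates weights (seeded) for the configured variant and records a
#' shape table from static propagation: encoder/bottleneck/decoder grid
#' sizes, per-level filter counts and -- for the unpadded variant -- the
#' crop applied to each skip connection.
#'
#' @param config A [network_config()].
#' @return An object of class `unet_model` with elements `config`,
#'   `params`, `shapes` (tibble), `crops`, `output_size`.
#' @export
build_network <- function(config) {
  prop <- propagate_shapes(config)
  if (!is.null(config$crop_per_edge_by_layer) &&
      !identical(as.integer(config$crop_per_edge_by_layer), as.integer(prop$crops))) {
    abort(sprintf("configured skip crops (%s) disagree with shape propagation (%s)",
                  paste(config$crop_per_edge_by_layer, collapse = ","),
                  paste(prop$crops, collapse = ",")))
  }
  d <- config$depth
  n_out <- if (config$loss == "categorical_crossentropy") 2L else 1L
  withr::with_seed(config$rng_seed, {
    conv_init <- function(cin, cout) {
      k2 <- 9L
      list(w = init_weights(k2 * cin, k2 * cout / 1, k2 * cin, cout, config$init),
           b = rep(0, cout))
    }
    enc <- lapply(seq_len(d), function(l) {
      cin <- if (l == 1) 1L else n_filters(config, l - 1)
      f <- n_filters(config, l)
      list(conv1 = conv_init(cin, f), conv2 = conv_init(f, f))
    })
    dec <- lapply(seq_len(d - 1), function(l) {
      cin <- n_filters(config, l + 1) + n_filters(config, l)
      f <- n_filters(config, l)
      list(conv1 = conv_init(cin, f), conv2 = conv_init(f, f))
    })
    f1 <- n_filters(config, 1)
    out <- list(w = init_weights(f1, n_out, f1, n_out, config$init),
                b = rep(0, n_out))
    structure(list(config = config,
                   params = list(enc = enc, dec = dec, out = out),
                   shapes = prop$shapes, crops = prop$crops,
                   output_size = prop$output_size, n_out = n_out,
                   history = NULL, val_dice = NA_real_),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %s, depth %d, input %d -> output %d, %s params\n",
              x$config$variant, x$config$depth, x$config$input_size,
              x$output_size, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `unet_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  total <- 0
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else total <<- total + length(p)
    invisible(NULL)
  }
  walk(model$params)
  total
}

# Full forward pass. x: (H, W, N, 1) tensor. Returns list(y, cache) where
# y is the probability output ((H,W,N,1) sigmoid or (H,W,N,2) softmax).
unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  pad <- if (cfg$padding_mode == "zero") 1L else 0L
  slope <- cfg$leaky_slope
  d <- cfg$depth
  keep <- training
  cache <- list(enc = vector("list", d), pool = vector("list", d - 1),
                dec = vector("list", max(d - 1, 0)), skip_dim = vector("list", d - 1))
  a <- x
  skips <- vector("list", d - 1)
  for (l in seq_len(d)) {
    p <- model$params$enc[[l]]
    c1 <- conv_fwd(a, p$conv1$w, p$conv1$b, pad, keep)
    a1 <- lrelu_fwd(c1$y, slope)
    c2 <- conv_fwd(a1, p$conv2$w, p$conv2$b, pad, keep)
    a2 <- lrelu_fwd(c2$y, slope)
    cache$enc[[l]] <- list(c1 = c1, z1 = c1$y, c2 = c2, z2 = c2$y)
    if (l < d) {
      skips[[l]] <- a2
      cache$skip_dim[[l]] <- dim(a2)
      pl <- pool_fwd(a2)
      cache$pool[[l]] <- pl
      a <- pl$y
    } else {
      if (training && cfg$dropout_rate > 0) {
        dp <- dropout_fwd(a2, cfg$dropout_rate)
        cache$dropout_mask <- dp$mask
        a <- dp$y
      } else {
        a <- a2
      }
    }
  }
  for (l in rev(seq_len(d - 1))) {
    u <- upsample_fwd(a)
    skc <- crop_tensor(skips[[l]], model$crops[l])
    cc <- concat_channels(u, skc)
    p <- model$params$dec[[l]]
    c1 <- conv_fwd(cc, p$conv1$w, p$conv1$b, pad, keep)
    a1 <- lrelu_fwd(c1$y, slope)
    c2 <- conv_fwd(a1, p$conv2$w, p$conv2$b, pad, keep)
    a2 <- lrelu_fwd(c2$y, slope)
    cache$dec[[l]] <- list(c1 = c1, z1 = c1$y, c2 = c2, z2 = c2$y,
                           n_up = dim(u)[4])
    a <- a2
  }
  pout <- model$params$out
  cf <- conv_fwd(a, pout$w, pout$b, 0L, keep)
  cache$out <- cf
  y <- if (model$n_out == 1) sigmoid(cf$y) else softmax_channels(cf$y)
  list(y = y, cache = cache)
}

# Reverse-mode pass. dz is the gradient of the loss w.r.t. the final conv
# logits. Returns gradients with the same nesting as model$params.
unet_backward <- function(model, cache, dz) {
  cfg <- model$config
  pad <- if (cfg$padding_mode == "zero") 1L else 0L
  slope <- cfg$leaky_slope
  d <- cfg$depth
  grads <- list(enc = vector("list", d), dec = vector("list", max(d - 1, 0)))

  g <- conv_bwd(dz, cache$out, model$params$out$w, 0L)
  grads$out <- list(w = g$dw, b = g$db)
  da <- g$dx

  dskip <- vector("list", d - 1)
  for (l in seq_len(d - 1)) {
    cc <- cache$dec[[l]]
    p <- model$params$dec[[l]]
    dz2 <- lrelu_bwd(da, cc$z2, slope)
    g2 <- conv_bwd(dz2, cc$c2, p$conv2$w, pad)
    dz1 <- lrelu_bwd(g2$dx, cc$z1, slope)
    g1 <- conv_bwd(dz1, cc$c1, p$conv1$w, pad)
    grads$dec[[l]] <- list(conv1 = list(w = g1$dw, b = g1$db),
                           conv2 = list(w = g2$dw, b = g2$db))
    n_up <- cc$n_up
    du <- g1$dx[, , , seq_len(n_up), drop = FALSE]
    dskc <- g1$dx[, , , -seq_len(n_up), drop = FALSE]
    dskip[[l]] <- uncrop_tensor(dskc, model$crops[l], cache$skip_dim[[l]])
    da <- upsample_bwd(du)
  }

  if (!is.null(cache$dropout_mask)) da <- da * cache$dropout_mask
  for (l in rev(seq_len(d))) {
    ce <- cache$enc[[l]]
    p <- model$params$enc[[l]]
    dz2 <- lrelu_bwd(da, ce$z2, slope)
    g2 <- conv_bwd(dz2, ce$c2, p$conv2$w, pad)
    dz1 <- lrelu_bwd(g2$dx, ce$z1, slope)
    g1 <- conv_bwd(dz1, ce$c1, p$conv1$w, pad, need_dx = l > 1)
    grads$enc[[l]] <- list(conv1 = list(w = g1$dw, b = g1$db),
                           conv2 = list(w = g2$dw, b = g2$db))
    if (l > 1) {
      da <- pool_bwd(g1$dx, cache$pool[[l - 1]]) + dskip[[l - 1]]
    }
  }
  grads
}

#' Negative soft-Dice loss
#'
#' Differentiable surrogate of the Dice overlap:
#' `-(2 * sum(p*g) + smooth) / (sum(p) + sum(g) + smooth)`. Perfect
#' agreement approaches -1; the smoothing constant keeps the ratio defined
#' on empty masks.
#'
#' @param prediction Probability raster (matrix or [probability_map()]).
#' @param truth Binary raster of the same shape.
#' @param smooth Positive smoothing constant.
#' @return Scalar loss in \[-1, 0\].
#' @export
soft_dice_loss <- function(prediction, truth, smooth = 1) {
  p <- as_raster(prediction); g <- as_raster(truth)
  if (!all(dim(p) == dim(g))) abort("prediction and truth shapes differ")
  -(2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
}

# Batch loss + gradient at the sigmoid output, mean of per-image soft Dice.
negative_dice_batch <- function(p, g, smooth) {
  n <- dim(p)[3]
  loss <- 0
  dp <- array(0, dim(p))
  for (i in seq_len(n)) {
    pi <- p[, , i, , drop = FALSE]
    gi <- g[, , i, , drop = FALSE]
    num <- 2 * sum(pi * gi) + smooth
    den <- sum(pi) + sum(gi) + smooth
    loss <- loss - num / den
    dp[, , i, ] <- -(2 * gi * den - num) / den^2
  }
  list(loss = loss / n, dp = dp / n)
}

# Categorical cross-entropy over a 2-channel softmax; g is the binary mask
# (channel 1 = mass, channel 2 = background). Returns loss and gradient at
# the logits directly (softmax folded in).
crossentropy_batch <- function(p, g) {
  eps <- 1e-12
  one <- concat_channels(g, 1 - g)
  npix <- prod(dim(g))
  loss <- -sum(one * log(p + eps)) / npix
  dz <- (p - one) / npix
  list(loss = loss, dz = dz)
}

#' Predict a lesion-probability map
#'
#' Runs the network in inference mode (dropout disabled, deterministic).
#' For the two-channel softmax variant the mass-channel probability is
#' returned.
#'
#' @param model A trained or freshly built `unet_model`.
#' @param raster Standardised input matrix of size
#'   `input_size x input_size`.
#' @param model_id Label stored in the returned map.
#' @return A [probability_map()] on the model's output grid.
#' @export
predict_map <- function(model, raster, model_id = "member") {
  x <- as_raster(raster)
  s <- model$config$input_size
  if (!all(dim(x) == c(s, s))) {
    abort(sprintf("input must be %dx%d, got %dx%d", s, s, nrow(x), ncol(x)))
  }
  fw <- unet_forward(model, as_tensor(x), training = FALSE)
  pm <- fw$y[, , 1, 1]
  probability_map(pmin(pmax(pm, 0), 1), model_id = model_id)
}

#' @export
predict.unet_model <- function(object, newdata, ...) {
  predict_map(object, newdata, ...)
}

optimizer_step <- function(params, grads, state, cfg) {
  lr <- cfg$learning_rate
  if (cfg$optimizer == "rmsprop") {
    rho <- cfg$rmsprop_rho
    fun <- function(p, g, s) {
      v <- if (is.null(s)) g * 0 else s$v
      v <- rho * v + (1 - rho) * g * g
      list(p = p - lr * g / (sqrt(v) + 1e-8), s = list(v = v))
    }
  } else {
    mom <- cfg$momentum
    fun <- function(p, g, s) {
      v <- if (is.null(s)) g * 0 else s$v
      v <- mom * v - lr * g
      list(p = p + v, s = list(v = v))
    }
  }
  update_tree(params, grads, state, fun)
}

update_tree <- function(p, g, s, fun) {
  if (is.list(p) && !is.null(names(p)) && all(c("w", "b") %in% names(p)) &&
      !is.list(p$w)) {
    rw <- fun(p$w, g$w, s$w)
    rb <- fun(p$b, g$b, s$b)
    list(p = list(w = rw$p, b = rb$p), s = list(w = rw$s, b = rb$s))
  } else if (is.list(p)) {
    sp <- if (is.null(s)) vector("list", length(p)) else s
    out_p <- p
    for (i in seq_along(p)) {
      r <- update_tree(p[[i]], g[[i]], sp[i][[1]], fun)
      out_p[[i]] <- r$p
      sp[i] <- list(r$s)
    }
    list(p = out_p, s = sp)
  } else {
    fun(p, g, s)
  }
}

# Preprocess dataset rows to network-grid training samples.
prepare_samples <- function(dataset, input_size) {
  purrr::pmap(dataset, function(image, mask, patient_id, ...) {
    pr <- preprocess_record(image, mask, input_size)
    list(x = pr$x, mask = pr$mask, patient_id = patient_id)
  })
}

#' Train one U-net member
#'
#' Mini-batch training with the configured optimizer and loss, per-epoch
#' validation Dice, early stopping on validation patience, and return of
#' the best-validation snapshot. Training and validation sets must be
#' disjoint by patient, mirroring the grouped cross-validation protocol.
#'
#' @param model A `unet_model` from [build_network()].
#' @param train_set,validation_set Dataset tibbles (rows with `patient_id`,
#'   `image`, `mask`) as produced by [generate_dataset()].
#' @param rng_seed Seed for shuffling, augmentation and dropout; defaults
#'   to the model's configured seed.
#' @return The model with updated `params`, a `history` tibble
#'   (epoch, train_loss, val_dice) and the best `val_dice`.
#' @export
train_member <- function(model, train_set, validation_set,
                         rng_seed = model$config$rng_seed) {
  cfg <- model$config
  if (nrow(train_set) == 0) abort("training set is empty")
  overlap <- intersect(unique(train_set$patient_id),
                       unique(validation_set$patient_id))
  if (length(overlap) > 0) {
    abort(sprintf("train and validation sets share patients: %s",
                  paste(head(overlap, 3), collapse = ", ")))
  }
  train <- prepare_samples(train_set, cfg$input_size)
  val <- prepare_samples(validation_set, cfg$input_size)
  aug_cfg <- preprocess_config(target_size = cfg$input_size)

  withr::with_seed(rng_seed, {
    state <- NULL
    best <- list(params = model$params, val_dice = -Inf, epoch = 0L)
    history <- vector("list", cfg$epochs)
    stall <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample(length(train))
      losses <- c()
      for (start in seq(1, length(idx), by = cfg$batch_size)) {
        bidx <- idx[start:min(start + cfg$batch_size - 1, length(idx))]
        xs <- vector("list", length(bidx)); ms <- xs
        for (j in seq_along(bidx)) {
          smp <- train[[bidx[j]]]
          if (cfg$augment) {
            ag <- augment(smp$x, smp$mask, aug_cfg)
            xs[[j]] <- ag$image; ms[[j]] <- ag$mask
          } else {
            xs[[j]] <- smp$x; ms[[j]] <- smp$mask
          }
        }
        x <- array(unlist(xs), c(dim(xs[[1]]), length(xs), 1L))
        g <- array(unlist(ms), c(dim(ms[[1]]), length(ms), 1L))
        if (model$output_size != cfg$input_size) {
          cr <- (cfg$input_size - model$output_size) %/% 2L
          g <- crop_tensor(g, cr)
        }
        fw <- unet_forward(model, x, training = TRUE)
        if (cfg$loss == "negative_dice") {
          lb <- negative_dice_batch(fw$y, g, cfg$dice_smooth)
          dz <- lb$dp * fw$y * (1 - fw$y)   # through the sigmoid
        } else {
          lb <- crossentropy_batch(fw$y, g)
          dz <- lb$dz
        }
        grads <- unet_backward(model, fw$cache, dz)
        up <- optimizer_step(model$params, grads, state, cfg)
        model$params <- up$p
        state <- up$s
        losses <- c(losses, lb$loss)
      }
      vd <- mean(vapply(val, function(smp) {
        pm <- predict_map(model, smp$x)
        truth <- smp$mask
        if (model$output_size != cfg$input_size) {
          cr <- (cfg$input_size - model$output_size) %/% 2L
          truth <- truth[(cr + 1):(cr + model$output_size),
                         (cr + 1):(cr + model$output_size)]
        }
        dice_coef((pm$pixels >= 0.5) * 1L, truth)
      }, numeric(1)))
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dice = vd)
      if (vd > best$val_dice) {
        best <- list(params = model$params, val_dice = vd, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    model$params <- best$params
    model$val_dice <- best$val_dice
    model$history <- dplyr::bind_rows(history)
    model
  })
}
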