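#' Preprocessing configuration
#'
#' Controls the conversion of arbitrary-size B-mode images to the square
#' network input and the two ultrasound-safe augmentations (horizontal flip
#' and equal-axis zoom -- the only transforms that preserve acoustic
#' features such as posterior shadowing and mass size statistics).
#'
#' @param target_size Side of the square network input in pixels; must be
#'   divisible by 16 so that four 2x pooling stages land on integer grids.
#' @param zoom_range Length-2 numeric `(low, high)`, both > 0: range of the
#'   equal-axis zoom factor drawn during augmentation.
#' @param flip_probability Probability in \[0, 1\] of a horizontal flip.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 208, zoom_range = c(0.9, 1.1),
                              flip_probability = 0.5) {
  if (target_size %% 16 != 0) {
    abort("`target_size` must be divisible by 16 (four 2x poolings)")
  }
  if (length(zoom_range) != 2 || any(zoom_range <= 0) || zoom_range[1] > zoom_range[2]) {
    abort("`zoom_range` must be (low, high) with 0 < low <= high")
  }
  if (flip_probability < 0 || flip_probability > 1) {
    abort("`flip_probability` must lie in [0, 1]")
  }
  structure(list(target_size = as.integer(target_size),
                 zoom_range = as.numeric(zoom_range),
                 flip_probability = as.numeric(flip_probability)),
            class = "preprocess_config")
}

#' Downsample to the square network grid with zero padding
#'
#' The longer image dimension is scaled to `target_size` (bilinear); the
#' shorter dimension is scaled by the same factor, preserving the aspect
#' ratio, and centred with zero padding (odd remainders put the extra
#' row/column at bottom/right). Masks travel through the identical geometry
#' with nearest-neighbour resampling so they stay binary. The returned
#' placement record allows predictions to be mapped back to original
#' coordinates with [map_back()].
#'
#' @param image A [bmode_image()] or numeric matrix.
#' @param mask Optional [segmentation_mask()] or 0/1 matrix on the same grid.
#' @param config A [preprocess_config()].
#' @return List with `image` (target x target matrix), `mask` (or `NULL`)
#'   and `placement` (scale, pad offsets, content and original sizes).
#' @export
resize_pad <- function(image, mask = NULL, config = preprocess_config()) {
  img <- as_raster(image)
  stopifnot_matrix(img, "image")
  t <- config$target_size
  h <- nrow(img); w <- ncol(img)
  scale <- t / max(h, w)
  content_h <- if (h >= w) t else max(1L, as.integer(round(h * scale)))
  content_w <- if (w > h) t else max(1L, as.integer(round(w * scale)))
  pad_top <- (t - content_h) %/% 2
  pad_left <- (t - content_w) %/% 2

  out <- matrix(0, t, t)
  out[pad_top + seq_len(content_h), pad_left + seq_len(content_w)] <-
    resize_matrix(img, content_h, content_w, "bilinear")

  placement <- list(scale = scale, pad_top = pad_top, pad_left = pad_left,
                    content_h = content_h, content_w = content_w,
                    orig_h = h, orig_w = w)

  out_mask <- NULL
  if (!is.null(mask)) {
    mk <- as_binary_raster(mask)
    if (!all(dim(mk) == c(h, w))) abort("mask must share the image grid")
    mm <- matrix(0L, t, t)
    mm[pad_top + seq_len(content_h), pad_left + seq_len(content_w)] <-
      as.integer(resize_matrix(mk, content_h, content_w, "nearest"))
    out_mask <- mm
  }
  list(image = out, mask = out_mask, placement = placement)
}

#' Map a network-grid mask back to original image coordinates
#'
#' Inverts the geometry of [resize_pad()]: crops the content region out of
#' the padded square and resamples it (nearest neighbour) to the original
#' image size.
#'
#' @param mask Binary matrix on the `target_size` grid.
#' @param placement Placement record returned by [resize_pad()].
#' @return Binary matrix of the original image size.
#' @export
map_back <- function(mask, placement) {
  mk <- as_binary_raster(mask)
  p <- placement
  content <- mk[p$pad_top + seq_len(p$content_h), p$pad_left + seq_len(p$content_w),
                drop = FALSE]
  out <- resize_matrix(content, p$orig_h, p$orig_w, "nearest")
  matrix(as.integer(out), p$orig_h, p$orig_w)
}

#' Standard-score normalisation of an image raster
#'
#' Subtracts the raster mean and divides by its (population) standard
#' deviation, so the output has mean 0 and standard deviation 1 over all
#' pixels, padding included. A constant raster has no scale; it is returned
#' as all zeros with a warning.
#'
#' @param raster Numeric matrix.
#' @return Matrix of the same size with mean 0, sd 1.
#' @export
standardize <- function(raster) {
  x <- as_raster(raster)
  stopifnot_matrix(x, "raster")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    warn("constant image: standard deviation is zero, returning all zeros")
    return(matrix(0, nrow(x), ncol(x)))
  }
  (x - m) / s
}

#' Ultrasound-safe augmentation: horizontal flip and equal-axis zoom
#'
#' With probability `flip_probability` both raster and mask are mirrored
#' left-right; a single zoom factor drawn uniformly from `zoom_range` is
#' then applied identically to both axes (so lesion aspect ratio and
#' relative size statistics are preserved), re-centred, and cropped or
#' zero-padded back to the input shape. These are the only two transforms
#' the augmentation surface exposes.
#'
#' @param raster Numeric matrix (image on the network grid).
#' @param mask Binary matrix of the same shape.
#' @param config A [preprocess_config()].
#' @return List with `image`, `mask`, and the applied `flipped` flag and
#'   `zoom` factor.
#' @export
augment <- function(raster, mask, config = preprocess_config()) {
  x <- as_raster(raster); mk <- as_binary_raster(mask)
  if (!all(dim(x) == dim(mk))) abort("raster and mask must share a shape")
  flipped <- runif(1) < config$flip_probability
  zoom <- runif(1, config$zoom_range[1], config$zoom_range[2])
  res <- apply_flip_zoom(x, mk, flipped, zoom)
  c(res, list(flipped = flipped, zoom = zoom))
}

# Deterministic core of augment(): exposed so tests can verify that every
# augmented sample equals flip^k followed by an equal-axis zoom.
#' Apply a given horizontal flip and equal-axis zoom
#'
#' Deterministic transform underlying [augment()].
#'
#' @inheritParams augment
#' @param flipped Logical: mirror left-right first.
#' @param zoom Positive zoom factor applied to both axes.
#' @return List with `image` and `mask`, same shape as the input.
#' @export
apply_flip_zoom <- function(raster, mask, flipped, zoom) {
  if (zoom <= 0) abort("zoom factor must be > 0")
  x <- as_raster(raster); mk <- as_binary_raster(mask)
  if (flipped) {
    x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    mk <- mk[, rev(seq_len(ncol(mk))), drop = FALSE]
  }
  if (zoom != 1) {
    h <- nrow(x); w <- ncol(x)
    zh <- max(1L, as.integer(round(h * zoom)))
    zw <- max(1L, as.integer(round(w * zoom)))
    zx <- resize_matrix(x, zh, zw, "bilinear")
    zm <- as.integer(resize_matrix(mk, zh, zw, "nearest"))
    zm <- matrix(zm, zh, zw)
    x <- center_fit(zx, h, w, fill = 0)
    mk <- center_fit(zm, h, w, fill = 0L)
  }
  list(image = x, mask = matrix(as.integer(mk), nrow(mk), ncol(mk)))
}

# Centre-crop (larger input) or centre-pad (smaller input) to (h, w).
center_fit <- function(m, h, w, fill = 0) {
  mh <- nrow(m); mw <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(min(mh, h)) + max(0L, (mh - h) %/% 2)
  src_c <- seq_len(min(mw, w)) + max(0L, (mw - w) %/% 2)
  dst_r <- seq_len(min(mh, h)) + max(0L, (h - mh) %/% 2)
  dst_c <- seq_len(min(mw, w)) + max(0L, (w - mw) %/% 2)
  out[dst_r, dst_c] <- m[src_r, src_c]
  out
}

# Preprocess one dataset row to the network grid: resize/pad then
# standard-score; returns list(x, mask, placement).
preprocess_record <- function(image, mask, target_size) {
  cfg <- preprocess_config(target_size = target_size)
  rp <- resize_pad(image, mask, cfg)
  list(x = standardize(rp$image), mask = rp$mask, placement = rp$placement)
}
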