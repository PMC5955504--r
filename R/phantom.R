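#' Specification of a synthetic B-mode phantom
#'
#' Describes one ultrasound-like test image: a hypoechoic (darker) elliptical
#' lesion with optionally irregular margins, multiplicative speckle, optional
#' posterior acoustic shadowing below the lesion and an optional hyperechoic
#' halo around it. Coordinates are row-major `(row, col)` on the image grid.
#'
#' @param image_height,image_width Image size in pixels (>= 16).
#' @param lesion_center Numeric `(row, col)` of the lesion centre.
#' @param lesion_radii Numeric `(a, b)`: semi-axes in pixels along rows/cols.
#' @param margin_irregularity Amplitude (>= 0) of the band-limited radial
#'   boundary perturbation; 0 gives an exact ellipse, values around 0.1-0.3
#'   give the spiculated margins typical of malignant masses.
#' @param contrast Ratio in (0, 1] of lesion mean intensity to background
#'   mean; values below 1 make the lesion hypoechoic.
#' @param shadow_strength Attenuation in \[0, 1\] of the column band beneath
#'   the lesion (posterior acoustic shadowing).
#' @param halo_width Width in pixels (>= 0) of an additive bright rim around
#'   the lesion (hyperechoic halo).
#' @param speckle_scale Relative amplitude (> 0) of the multiplicative
#'   speckle; the speckle field has unit mean by construction.
#' @param rng_seed Integer; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(image_height = 64, image_width = 64,
                         lesion_center = c(32, 32), lesion_radii = c(12, 12),
                         margin_irregularity = 0, contrast = 0.4,
                         shadow_strength = 0, halo_width = 0,
                         speckle_scale = 0.4, rng_seed = 1L) {
  spec <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    lesion_center = as.numeric(lesion_center),
    lesion_radii = as.numeric(lesion_radii),
    margin_irregularity = as.numeric(margin_irregularity),
    contrast = as.numeric(contrast),
    shadow_strength = as.numeric(shadow_strength),
    halo_width = as.numeric(halo_width),
    speckle_scale = as.numeric(speckle_scale),
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$image_height < 16 || spec$image_width < 16) {
    abort("phantom image must be at least 16x16")
  }
  if (length(spec$lesion_center) != 2 || length(spec$lesion_radii) != 2) {
    abort("`lesion_center` and `lesion_radii` must each have length 2")
  }
  if (any(spec$lesion_radii <= 0)) abort("lesion radii must be positive")
  if (spec$margin_irregularity < 0) abort("`margin_irregularity` must be >= 0")
  if (spec$contrast <= 0 || spec$contrast > 1) abort("`contrast` must lie in (0, 1]")
  if (spec$shadow_strength < 0 || spec$shadow_strength > 1) {
    abort("`shadow_strength` must lie in [0, 1]")
  }
  if (spec$halo_width < 0) abort("`halo_width` must be >= 0")
  if (spec$speckle_scale <= 0) abort("`speckle_scale` must be > 0")
  # worst-case lesion extent given the perturbation amplitude bound below
  max_mult <- 1 + 3 * spec$margin_irregularity
  ext <- spec$lesion_radii * max_mult + spec$halo_width
  lo_r <- spec$lesion_center[1] - ext[1]
  hi_r <- spec$lesion_center[1] + ext[1]
  lo_c <- spec$lesion_center[2] - ext[2]
  hi_c <- spec$lesion_center[2] + ext[2]
  if (lo_r < 1) abort(sprintf("lesion extends out of frame: row %.1f < 1", lo_r))
  if (hi_r > spec$image_height) {
    abort(sprintf("lesion extends out of frame: row %.1f > %d", hi_r, spec$image_height))
  }
  if (lo_c < 1) abort(sprintf("lesion extends out of frame: col %.1f < 1", lo_c))
  if (hi_c > spec$image_width) {
    abort(sprintf("lesion extends out of frame: col %.1f > %d", hi_c, spec$image_width))
  }
  invisible(spec)
}

# Band-limited radial boundary perturbation: harmonics 2..6 with Gaussian
# coefficients, normalised to unit RMS and clipped to +-3 so the worst-case
# lesion extent used by the frame check is a hard bound.
margin_perturbation <- function(theta, irregularity) {
  if (irregularity <= 0) return(rep(1, length(theta)))
  harmonics <- 2:6
  a <- rnorm(length(harmonics))
  b <- rnorm(length(harmonics))
  p <- rep(0, length(theta))
  for (i in seq_along(harmonics)) {
    p <- p + a[i] * cos(harmonics[i] * theta) + b[i] * sin(harmonics[i] * theta)
  }
  p <- p / sqrt(sum(a^2 + b^2) / 2)  # unit RMS over theta
  p <- pmin(pmax(p, -3), 3)
  pmax(1 + irregularity * p, 0.2)
}

#' Generate one synthetic B-mode phantom
#'
#' Builds a noise-free echogenicity field (background, hypoechoic lesion,
#' optional halo and posterior shadow), multiplies it by a unit-mean
#' speckle field (gamma-distributed, lightly smoothed by a point-spread
#' kernel -- the standard multi-look envelope model), and returns the image
#' together with the exact lesion mask.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id Patient label stored in the image metadata.
#' @return A list with elements `image` (a [bmode_image()] whose `field`
#'   element holds the noise-free intensities) and `mask` (a
#'   [segmentation_mask()] with role `"truth"`).
#' @export
generate_phantom <- function(spec, patient_id = "phantom") {
  validate_phantom_spec(spec)
  withr::with_seed(spec$rng_seed, generate_phantom_impl(spec, patient_id))
}

generate_phantom_impl <- function(spec, patient_id) {
  h <- spec$image_height; w <- spec$image_width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- (rows - spec$lesion_center[1]) / spec$lesion_radii[1]
  dc <- (cols - spec$lesion_center[2]) / spec$lesion_radii[2]
  rho <- sqrt(dr^2 + dc^2)          # normalised elliptical radius
  theta <- atan2(dc, dr)

  # irregular boundary: radius multiplier as a band-limited series in theta
  mult <- matrix(margin_perturbation(as.vector(theta), spec$margin_irregularity), h, w)
  mask <- (rho <= mult) * 1L

  background <- 0.55
  field <- matrix(background, h, w)
  field[mask == 1] <- spec$contrast * background

  if (spec$halo_width > 0) {
    ring <- EBImage::dilate(mask, disc_kernel(spec$halo_width)) - mask
    field[ring == 1] <- field[ring == 1] + 0.35 * background
  }

  # posterior acoustic shadowing: attenuate each lesion column below its
  # deepest lesion pixel, ramping in over ~8 px of depth
  if (spec$shadow_strength > 0) {
    for (j in seq_len(w)) {
      in_col <- which(mask[, j] == 1)
      if (length(in_col) == 0) next
      bottom <- max(in_col)
      if (bottom < h) {
        depth <- seq_len(h - bottom)
        atten <- 1 - spec$shadow_strength * pmin(depth / 8, 1)
        field[(bottom + 1):h, j] <- field[(bottom + 1):h, j] * atten
      }
    }
  }

  field <- gaussian_blur(field, sigma = 0.8)  # finite beam resolution

  # unit-mean multiplicative speckle: gamma envelope smoothed by a small PSF
  shape <- 1 / spec$speckle_scale^2
  noise <- matrix(rgamma(h * w, shape = shape, rate = shape), h, w)
  noise <- gaussian_blur(noise, sigma = 0.7)
  noise <- noise / mean(noise)
  pixels <- pmax(field * noise, 0)

  list(
    image = bmode_image(pixels, patient_id = patient_id, source = "phantom",
                        field = field),
    mask = segmentation_mask(mask, role = "truth")
  )
}

#' Generate a phantom dataset emulating a multi-orientation cohort
#'
#' Each synthetic patient has one underlying lesion geometry; their
#' `images_per_patient` images view it with jittered centre, radii and
#' speckle realisations, emulating clinical scans of one mass from several
#' probe orientations. All randomness derives from `rng_seed`.
#'
#' @param n_patients Number of synthetic patients (>= 1).
#' @param images_per_patient Images per patient.
#' @param spec_ranges Named list overriding any of the sampling ranges in
#'   [phantom_ranges()].
#' @param rng_seed Integer master seed.
#' @return A tibble with one row per image: `patient_id`, `image_id`,
#'   `class` (`"benign"`-like smooth or `"malignant"`-like irregular
#'   margins), `spec` (the drawn [phantom_spec()]), `image`, `mask`
#'   (list-columns).
#' @export
generate_dataset <- function(n_patients = 50, images_per_patient = 2,
                             spec_ranges = list(), rng_seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be >= 1")
  if (images_per_patient < 1) abort("`images_per_patient` must be >= 1")
  rg <- modifyList(phantom_ranges(), spec_ranges)
  withr::with_seed(rng_seed, {
    rows <- purrr::map(seq_len(n_patients), function(p) {
      pid <- sprintf("P%03d", p)
      cls <- if (runif(1) < rg$malignant_fraction) "malignant" else "benign"
      irr <- if (cls == "malignant") runif(1, rg$irregularity[1], rg$irregularity[2]) else 0
      base_radii <- runif(2, rg$radii[1], rg$radii[2])
      contrast <- runif(1, rg$contrast[1], rg$contrast[2])
      shadow <- if (runif(1) < rg$shadow_probability) {
        runif(1, rg$shadow_strength[1], rg$shadow_strength[2])
      } else 0
      halo <- if (runif(1) < rg$halo_probability) rg$halo_width else 0
      speckle <- runif(1, rg$speckle[1], rg$speckle[2])
      # the whole lesion (worst-case margin perturbation, halo and view
      # jitter included) must fit the field of view: cap the radii
      r_max <- (min(rg$image_size) / 2 - 1.5 - halo - rg$center_jitter) /
        ((1 + 3 * irr) * 1.1)
      if (max(base_radii) > r_max) {
        base_radii <- base_radii * (r_max / max(base_radii))
      }
      margin <- (1 + 3 * irr) * max(base_radii) * 1.1 + halo + rg$center_jitter
      center <- c(
        runif(1, 1 + margin, rg$image_size[1] - margin),
        runif(1, 1 + margin, rg$image_size[2] - margin)
      )
      purrr::map(seq_len(images_per_patient), function(i) {
        spec <- phantom_spec(
          image_height = rg$image_size[1], image_width = rg$image_size[2],
          lesion_center = center + runif(2, -rg$center_jitter, rg$center_jitter),
          lesion_radii = base_radii * runif(2, 0.9, 1.1),
          margin_irregularity = irr, contrast = contrast,
          shadow_strength = shadow, halo_width = halo,
          speckle_scale = speckle,
          rng_seed = derive_seed(rng_seed, p * 1000 + i)
        )
        ph <- generate_phantom(spec, patient_id = pid)
        tibble::tibble(
          patient_id = pid,
          image_id = sprintf("%s_I%02d", pid, i),
          class = cls,
          spec = list(spec),
          image = list(ph$image),
          mask = list(ph$mask)
        )
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })
}

#' Default sampling ranges for [generate_dataset()]
#'
#' The ranges describe a desk-scale cohort of clearly hypoechoic masses:
#' 64x64 images, lesion semi-axes 8-16 px, lesion/background contrast
#' 0.3-0.5, moderate speckle, posterior shadowing in half the patients and
#' an occasional hyperechoic halo. Roughly 40% of patients get irregular
#' ("malignant"-like) margins.
#'
#' @return Named list of ranges.
#' @export
phantom_ranges <- function() {
  list(
    image_size = c(64, 64),
    radii = c(8, 16),
    contrast = c(0.3, 0.5),
    irregularity = c(0.08, 0.2),
    malignant_fraction = 0.4,
    shadow_probability = 0.5,
    shadow_strength = c(0.2, 0.5),
    halo_probability = 0.2,
    halo_width = 2,
    speckle = c(0.3, 0.5),
    center_jitter = 3
  )
}

#' Write a phantom dataset to disk
#'
#' Images are written as 8-bit grayscale PNG, masks as PNG with values
#' \{0, 255\}, and a `manifest.csv` (filename, patient_id, role, class)
#' indexes the files.
#'
#' @param dataset Tibble from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::pmap(dataset, function(patient_id, image_id, class, image, mask, ...) {
    img_file <- paste0(image_id, ".png")
    mask_file <- paste0(image_id, "_mask.png")
    png::writePNG(pmin(pmax(image$pixels, 0), 1), file.path(dir, img_file))
    png::writePNG(mask$pixels + 0, file.path(dir, mask_file))
    tibble::tibble(
      filename = c(img_file, mask_file),
      patient_id = patient_id,
      role = c("image", "truth"),
      class = class
    )
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing PNGs and `manifest.csv`.
#' @return A tibble with `patient_id`, `image_id`, `class`, `image`, `mask`.
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  imgs <- manifest[manifest$role == "image", ]
  rows <- purrr::pmap(imgs, function(filename, patient_id, role, class) {
    image_id <- sub("\\.png$", "", filename)
    px <- png::readPNG(file.path(dir, filename))
    if (length(dim(px)) == 3) px <- px[, , 1]
    mk <- png::readPNG(file.path(dir, paste0(image_id, "_mask.png")))
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    tibble::tibble(
      patient_id = patient_id,
      image_id = image_id,
      class = class,
      image = list(bmode_image(px, patient_id = patient_id, source = "file")),
      mask = list(segmentation_mask((mk > 0.5) * 1L, role = "truth"))
    )
  })
  dplyr::bind_rows(rows)
}
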