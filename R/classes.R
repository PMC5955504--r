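#' B-mode image container
#'
#' Wraps a 2-D nonnegative intensity raster together with the provenance
#' metadata the pipeline needs: a patient identifier (which drives the
#' patient-grouped cross-validation split) and the image source. Phantom
#' images additionally carry the noise-free echogenicity field they were
#' built from, which property tests use to check the multiplicative speckle
#' model.
#'
#' @param pixels Numeric matrix of nonnegative intensities, at least 16x16.
#' @param patient_id Character scalar grouping all images of one patient.
#' @param source Either `"phantom"` or `"file"`.
#' @param field Optional noise-free intensity field (phantoms only).
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(pixels, patient_id, source = c("file", "phantom"),
                        field = NULL) {
  source <- match.arg(source)
  stopifnot_matrix(pixels, "pixels")
  if (any(dim(pixels) < 16)) {
    abort(sprintf("image must be at least 16x16, got %dx%d",
                  nrow(pixels), ncol(pixels)))
  }
  if (any(pixels < 0)) abort("image intensities must be nonnegative")
  if (missing(patient_id) || is.null(patient_id) || !nzchar(patient_id[1])) {
    abort("`patient_id` is required (it drives grouped splitting)")
  }
  structure(list(pixels = pixels, patient_id = as.character(patient_id[1]),
                 source = source, field = field),
            class = "bmode_image")
}

#' Binary segmentation mask
#'
#' A 0/1 raster aligned to an image grid, with a role recording whether it
#' is a ground-truth annotation, a level-set seed, or a model prediction.
#'
#' @param pixels Matrix whose values are exactly 0 or 1.
#' @param role One of `"truth"`, `"seed"`, `"prediction"`.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(pixels, role = c("truth", "seed", "prediction")) {
  role <- match.arg(role)
  stopifnot_matrix(pixels, "pixels")
  if (!all(pixels %in% c(0, 1))) {
    abort("mask values must be exactly 0 or 1")
  }
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
                 role = role),
            class = "segmentation_mask")
}

#' Per-pixel lesion-probability map
#'
#' Output of a single U-net member: each pixel holds the probability, in
#' \[0, 1\], that it belongs to the suspicious mass.
#'
#' @param pixels Numeric matrix with values in \[0, 1\].
#' @param model_id Label of the fold/member that produced the map.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(pixels, model_id = "member") {
  stopifnot_matrix(pixels, "pixels")
  if (any(pixels < 0 | pixels > 1)) abort("probabilities must lie in [0, 1]")
  structure(list(pixels = pixels, model_id = as.character(model_id)),
            class = "probability_map")
}

# Accept a mask/map object or a bare matrix and return the raster.
as_raster <- function(x) {
  if (inherits(x, c("bmode_image", "segmentation_mask", "probability_map"))) {
    x$pixels
  } else if (is.matrix(x)) {
    x
  } else {
    abort("expected an image/mask/map object or a matrix")
  }
}

as_binary_raster <- function(x, arg = "mask") {
  m <- as_raster(x)
  if (!all(m %in% c(0, 1))) abort(sprintf("`%s` must be binary (0/1)", arg))
  m
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %dx%d px, patient %s, source %s\n",
              nrow(x$pixels), ncol(x$pixels), x$patient_id, x$source))
  invisible(x)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %dx%d px, role %s, area %d px\n",
              nrow(x$pixels), ncol(x$pixels), x$role, sum(x$pixels)))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %dx%d px, model %s, mean p %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$model_id, mean(x$pixels)))
  invisible(x)
}
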