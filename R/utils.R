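#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm runif rgamma quantile sd setNames
#' @importFrom utils head modifyList write.csv read.csv
NULL

# Derive a child seed from a parent seed and a stream index, staying inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

# Resize a numeric matrix keeping the (row, col) orientation of the caller.
# EBImage addresses the first array dimension as x; for a plain matrix that
# is the row index, so passing target nrow as `w` and ncol as `h` is
# orientation-preserving.
resize_matrix <- function(m, new_nrow, new_ncol, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(m, w = new_nrow, h = new_ncol, filter = filt)
  matrix(as.numeric(out), new_nrow, new_ncol)
}

disc_kernel <- function(radius) {
  r <- as.integer(radius)
  outer(-r:r, -r:r, function(i, j) as.numeric(i^2 + j^2 <= r^2))
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  matrix(as.numeric(EBImage::gblur(m, sigma = sigma)), nrow(m), ncol(m))
}

stopifnot_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x) || any(dim(x) < 1)) {
    abort(sprintf("`%s` must be a nonempty numeric matrix", arg))
  }
}
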