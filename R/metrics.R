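#' Dice overlap coefficient
#'
#' `2 |P ∩ T| / (|P| + |T|)` between a predicted and a true binary mask.
#' When both masks are empty the overlap is defined as 1 (no lesion, none
#' predicted) and a message is emitted.
#'
#' @param prediction,truth Binary masks ([segmentation_mask()] or 0/1
#'   matrices) on one grid.
#' @return Scalar in \[0, 1\].
#' @export
dice_coef <- function(prediction, truth) {
  p <- as_binary_raster(prediction, "prediction")
  g <- as_binary_raster(truth, "truth")
  if (!all(dim(p) == dim(g))) abort("prediction and truth shapes differ")
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) {
    inform("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(p * g) / (sp + sg)
}

#' True positive fraction (pixel sensitivity)
#'
#' `|P ∩ T| / |T|`: the fraction of true lesion pixels the prediction
#' recovers.
#'
#' @inheritParams dice_coef
#' @return Scalar in \[0, 1\].
#' @export
tpf <- function(prediction, truth) {
  p <- as_binary_raster(prediction, "prediction")
  g <- as_binary_raster(truth, "truth")
  if (!all(dim(p) == dim(g))) abort("prediction and truth shapes differ")
  if (sum(g) == 0) abort("TPF is undefined for an empty truth mask")
  sum(p * g) / sum(g)
}

#' False positive fraction (1 - pixel specificity)
#'
#' By default `|P \\ T| / |grid \\ T|`: false-positive pixels over the
#' true-negative background — the normalisation under which published
#' whole-image values land near 0.01. The alternative lesion-relative
#' normalisation `|P \\ T| / |T|` is available via `denominator`.
#'
#' @inheritParams dice_coef
#' @param denominator `"background"` (default) or `"truth"`.
#' @return Scalar (in \[0, 1\] for the background normalisation).
#' @export
fpf <- function(prediction, truth, denominator = c("background", "truth")) {
  denominator <- match.arg(denominator)
  p <- as_binary_raster(prediction, "prediction")
  g <- as_binary_raster(truth, "truth")
  if (!all(dim(p) == dim(g))) abort("prediction and truth shapes differ")
  fp <- sum(p * (1 - g))
  if (denominator == "background") {
    bg <- sum(1 - g)
    if (bg == 0) abort("FPF is undefined when the truth covers the whole grid")
    fp / bg
  } else {
    if (sum(g) == 0) abort("FPF with truth normalisation needs a nonempty truth")
    fp / sum(g)
  }
}

#' Evaluate a set of segmentations
#'
#' Computes Dice, TPF and FPF for every prediction/truth pair and returns
#' one tidy record per image, carrying any stratum labels supplied.
#'
#' @param predictions,truths Lists of masks on matching grids.
#' @param image_ids Optional identifiers (default `img001`, ...).
#' @param strata Optional data frame / tibble of per-image stratum labels
#'   (e.g. `class`, pathology, a BI-RADS analogue), one row per image.
#' @param fpf_denominator Passed to [fpf()].
#' @return A tibble with `image_id`, strata columns, `dice`, `tpf`, `fpf`.
#' @export
evaluate_set <- function(predictions, truths, image_ids = NULL, strata = NULL,
                         fpf_denominator = "background") {
  n <- length(predictions)
  if (n == 0) abort("empty evaluation set")
  if (length(truths) != n) abort("predictions and truths differ in length")
  image_ids <- image_ids %||% sprintf("img%03d", seq_len(n))
  out <- tibble::tibble(
    image_id = as.character(image_ids),
    dice = purrr::map2_dbl(predictions, truths, dice_coef),
    tpf = purrr::map2_dbl(predictions, truths, tpf),
    fpf = purrr::map2_dbl(predictions, truths, fpf,
                          denominator = fpf_denominator)
  )
  if (!is.null(strata)) {
    strata <- tibble::as_tibble(strata)
    if (nrow(strata) != n) abort("`strata` must have one row per image")
    out <- dplyr::bind_cols(out[, "image_id"], strata,
                            out[, c("dice", "tpf", "fpf")])
  }
  class(out) <- c("evaluation_records", class(out))
  out
}

#' Stratified mean / spread summary of evaluation records
#'
#' Mean, standard deviation and boxplot-ready quantiles of each metric per
#' stratum (plus an `all` stratum), in the shape of a published
#' per-pathology summary table. Strata with no members are dropped with a
#' warning.
#'
#' @param records Tibble from [evaluate_set()].
#' @param by Name of the stratum column, or `NULL` for the pooled summary
#'   only.
#' @return A tibble with `stratum`, `metric`, `n`, `mean`, `sd`, `q25`,
#'   `median`, `q75`.
#' @export
summarize_evaluation <- function(records, by = NULL) {
  long <- tidyr::pivot_longer(records, cols = c("dice", "tpf", "fpf"),
                              names_to = "metric", values_to = "value")
  summarise_group <- function(df, label) {
    df |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$value),
        sd = if (dplyr::n() > 1) sd(.data$value) else 0,
        q25 = quantile(.data$value, 0.25),
        median = quantile(.data$value, 0.5),
        q75 = quantile(.data$value, 0.75),
        .groups = "drop"
      ) |>
      dplyr::mutate(stratum = label, .before = 1)
  }
  out <- summarise_group(long, "all")
  if (!is.null(by)) {
    if (!by %in% names(records)) abort(sprintf("no stratum column `%s`", by))
    for (lv in unique(records[[by]])) {
      sub <- long[long[[by]] == lv, ]
      if (nrow(sub) == 0) {
        warn(sprintf("stratum `%s` has no members; omitted", lv))
        next
      }
      out <- dplyr::bind_rows(out, summarise_group(sub, as.character(lv)))
    }
  }
  out
}

#' Paired two-tailed comparison of per-image Dice values
#'
#' Compares two methods on the same images with a paired two-tailed test:
#' Wilcoxon signed-rank by default, or a paired t-test. Records are paired
#' by `image_id`; unpaired inputs are an error. When every per-image
#' difference is zero the methods are indistinguishable and `p = 1` is
#' returned by convention.
#'
#' @param records_a,records_b Tibbles from [evaluate_set()] with matching
#'   `image_id` sets.
#' @param metric Metric column to compare (default `"dice"`).
#' @param method `"wilcoxon"` or `"t"`.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `n`.
#' @export
paired_comparison <- function(records_a, records_b, metric = "dice",
                              method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (!setequal(records_a$image_id, records_b$image_id) ||
      nrow(records_a) != nrow(records_b)) {
    abort("records are not paired: image_id sets differ")
  }
  b <- records_b[match(records_a$image_id, records_b$image_id), ]
  x <- records_a[[metric]]
  y <- b[[metric]]
  n <- length(x)
  if (all(x == y)) {
    return(tibble::tibble(method = method, statistic = 0, p_value = 1, n = n))
  }
  res <- if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                        alternative = "two.sided"))
  } else {
    stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  }
  tibble::tibble(method = method, statistic = unname(res$statistic),
                 p_value = res$p.value, n = n)
}
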