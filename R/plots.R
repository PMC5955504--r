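#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_boxplot geom_errorbar labs scale_fill_gradient theme_minimal
#'   facet_wrap coord_fixed
NULL

#' Plot a B-mode image, optionally with mask contours
#'
#' @param image A [bmode_image()] or matrix.
#' @param mask Optional binary mask drawn as a semi-transparent overlay.
#' @return A ggplot object.
#' @export
plot_bmode <- function(image, mask = NULL) {
  img <- as_raster(image)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- as.vector(t(img))[(df$row - 1) * ncol(img) + df$col]
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    coord_fixed() +
    theme_minimal() +
    labs(x = NULL, y = NULL, fill = "echo")
  if (!is.null(mask)) {
    mk <- as_binary_raster(mask)
    on <- which(mk == 1, arr.ind = TRUE)
    p <- p + ggplot2::annotate("point", x = on[, 2], y = on[, 1],
                               colour = "red", alpha = 0.15, size = 0.3)
  }
  p
}

#' Voting-threshold sweep curve
#' @param object A `vote_sweep` tibble.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.vote_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$threshold, y = .data$mean_dice)) +
    geom_line() + geom_point() +
    theme_minimal() +
    labs(x = "majority-voting threshold", y = "mean Dice coefficient",
         title = "Dice against majority-voting threshold")
}

#' Ensemble-size sweep curve
#' @param object A `member_sweep` tibble.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.member_sweep <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$n_members, y = .data$mean_dice)) +
    geom_line() + geom_point() +
    theme_minimal() +
    labs(x = "models in majority vote", y = "mean Dice coefficient",
         title = "Ensemble size against Dice")
  if (any(object$sd_dice > 0)) {
    p <- p + geom_errorbar(aes(ymin = .data$mean_dice - .data$sd_dice,
                               ymax = .data$mean_dice + .data$sd_dice),
                           width = 0.2)
  }
  p
}

#' Stratified metric boxplots for evaluation records
#'
#' @param records Tibble from [evaluate_set()].
#' @param by Stratum column name (optional).
#' @return A ggplot object with one panel per metric.
#' @export
plot_evaluation <- function(records, by = NULL) {
  long <- tidyr::pivot_longer(records, cols = c("dice", "tpf", "fpf"),
                              names_to = "metric", values_to = "value")
  if (is.null(by)) {
    ggplot(long, aes(x = .data$metric, y = .data$value)) +
      geom_boxplot() + theme_minimal() +
      labs(x = NULL, y = "value")
  } else {
    ggplot(long, aes(x = .data[[by]], y = .data$value)) +
      geom_boxplot() +
      facet_wrap(~metric, scales = "free_y") +
      theme_minimal() +
      labs(x = by, y = "value")
  }
}
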