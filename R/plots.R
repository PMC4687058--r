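#' Plot the corrected 4DTV distribution
#'
#' Histogram of corrected 4DTV values with the WGD classification window
#' shaded, the usual visual for choosing or checking the duplicate-age
#' window.
#'
#' @param divergence Divergence tibble with `four_dtv_corr`.
#' @param low,high Window endpoints to shade.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_dtv_distribution <- function(divergence, low = 0.04, high = 0.2,
                                  binwidth = 0.01) {
  dat <- divergence[!is.na(divergence$four_dtv_corr), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$four_dtv_corr)) +
    ggplot2::annotate("rect", xmin = low, xmax = high,
                      ymin = -Inf, ymax = Inf,
                      fill = "grey85") +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = "corrected 4DTV", y = "pairs",
                  title = "Duplicate-pair 4DTV distribution",
                  subtitle = sprintf("shaded: WGD window [%.2f, %.2f]",
                                     low, high)) +
    ggplot2::theme_minimal()
}

#' Plot the Ka/Ks distribution of retained pairs
#'
#' @param divergence Divergence tibble with an `omega` column (pre-filter to
#'   the pairs of interest).
#' @param binwidth Histogram bin width.
#' @return A ggplot object with the median marked.
#' @export
plot_kaks_distribution <- function(divergence, binwidth = 0.05) {
  dat <- divergence[!is.na(divergence$omega), , drop = FALSE]
  med <- stats::median(dat$omega)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$omega)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed") +
    ggplot2::labs(x = "Ka/Ks", y = "pairs",
                  title = "Ka/Ks distribution",
                  subtitle = sprintf("dashed: median = %.2f", med)) +
    ggplot2::theme_minimal()
}

#' Plot differential-expression magnitude per condition
#'
#' Bar chart of the fold-change bins (|log2 FC| below 0.4, 0.4-2, 2-8, 8+)
#' per tissue x genotype condition.
#'
#' @param de DE results from [de_test_pairs()].
#' @param significant_only Restrict to significant tests (default TRUE).
#' @return A ggplot object.
#' @export
plot_fc_bins <- function(de, significant_only = TRUE) {
  dat <- if (significant_only) de[de$significant, , drop = FALSE] else de
  dat$condition <- paste(dat$tissue, dat$genotype)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fc_bin)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "|log2 FC| bin", y = "pairs",
                  title = "Copy-vs-copy expression divergence") +
    ggplot2::theme_minimal()
}

#' Autoplot a WGD pipeline result
#'
#' The 4DTV distribution of all candidate pairs with the classification
#' window used by the run.
#'
#' @param object A `wgd_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wgd_result
#' @export
autoplot.wgd_result <- function(object, ...) {
  plot_dtv_distribution(object$divergence,
                        low = object$thresholds$dtv_low,
                        high = object$thresholds$dtv_high)
}
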