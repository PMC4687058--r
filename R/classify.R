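#' Flag pairs inside the WGD 4DTV window
#'
#' A pair is in the window when its corrected 4DTV satisfies
#' `low <= 4DTV <= high` (both endpoints inclusive). Pairs whose 4DTV is
#' saturated or undefined are never in the window; their status is kept in
#' `dtv_flag`.
#'
#' @param divergence Divergence tibble from [pair_divergence()] (needs
#'   `four_dtv_corr` and `dtv_flag`).
#' @param low,high Window endpoints (defaults 0.04 and 0.2).
#' @return The input with a logical `in_window` column added.
#' @export
window_classify <- function(divergence, low = 0.04, high = 0.2) {
  if (low >= high) stop("window low (", low, ") must be below high (",
                        high, ")", call. = FALSE)
  dplyr::mutate(
    divergence,
    in_window = !is.na(.data$four_dtv_corr) &
      .data$four_dtv_corr >= low & .data$four_dtv_corr <= high
  )
}

#' Flag tandem duplicates by genomic proximity
#'
#' A pair is flagged tandem when both members lie on the same chromosome and
#' the gap between their gene intervals (end of the upstream gene to start
#' of the downstream gene; 0 for overlapping genes) is strictly below
#' `max_dist`. Pairs with one or both members unplaced are not tandem and
#' are noted as `"unplaced"`.
#'
#' @param pairs Tibble with `pair_id`, `id_a`, `id_b`.
#' @param positions Placement tibble (`id`, `chromosome`, `start`, `end`) in
#'   0-based half-open coordinates.
#' @param max_dist Distance threshold in bp (default 100,000; strict `<`).
#' @return The input with `chrom_a`, `chrom_b`, `distance_bp` (same
#'   chromosome only), `is_tandem` and `placement` (`"placed"` /
#'   `"unplaced"`) added.
#' @export
tandem_filter <- function(pairs, positions, max_dist = 100000) {
  pos_a <- dplyr::select(positions, id_a = "id", chrom_a = "chromosome",
                         start_a = "start", end_a = "end")
  pos_b <- dplyr::select(positions, id_b = "id", chrom_b = "chromosome",
                         start_b = "start", end_b = "end")
  out <- pairs |>
    dplyr::left_join(pos_a, by = "id_a") |>
    dplyr::left_join(pos_b, by = "id_b")
  placed <- !is.na(out$chrom_a) & !is.na(out$chrom_b)
  same_chrom <- placed & out$chrom_a == out$chrom_b
  gap <- pmax(pmax(out$start_a, out$start_b) -
                pmin(out$end_a, out$end_b), 0)
  out$distance_bp <- ifelse(same_chrom, gap, NA_real_)
  out$is_tandem <- same_chrom & gap < max_dist
  out$placement <- ifelse(placed, "placed", "unplaced")
  dplyr::select(out, -"start_a", -"end_a", -"start_b", -"end_b")
}

#' Classify candidate pairs as retained WGD duplicates
#'
#' Combines the 4DTV window ([window_classify()]) and the tandem proximity
#' rule ([tandem_filter()]): a pair is a retained WGD duplicate when it lies
#' inside the window and is not tandem. The cascade is count-conserving:
#' candidates split into out-of-window/saturated/undefined and in-window,
#' and the in-window pairs split into tandem-flagged and WGD-retained.
#'
#' @param divergence Divergence tibble from [pair_divergence()].
#' @param positions Placement tibble (`id`, `chromosome`, `start`, `end`),
#'   or `NULL` to skip the tandem rule (no pair is then tandem).
#' @param dtv_low,dtv_high 4DTV window (inclusive).
#' @param tandem_max_dist Tandem distance threshold in bp (strict).
#' @return Classified tibble: divergence columns plus `in_window`,
#'   `is_tandem`, `distance_bp`, `placement`, `wgd_retained`.
#' @export
classify_pairs <- function(divergence, positions = NULL,
                           dtv_low = 0.04, dtv_high = 0.2,
                           tandem_max_dist = 100000) {
  out <- window_classify(divergence, low = dtv_low, high = dtv_high)
  if (!is.null(positions)) {
    out <- tandem_filter(out, positions, max_dist = tandem_max_dist)
  } else {
    out$chrom_a <- NA_character_
    out$chrom_b <- NA_character_
    out$distance_bp <- NA_real_
    out$is_tandem <- FALSE
    out$placement <- "unplaced"
  }
  out$wgd_retained <- out$in_window & !out$is_tandem
  out
}

#' Summarize the chromosome pairing of classified pairs
#'
#' Counts, for the placed pairs in `classified` (by default the
#' WGD-retained ones), how often the two copies land on each chromosome
#' combination, and the fraction of pairs whose copies lie on different
#' chromosomes. Unplaced pairs are excluded from the denominator.
#'
#' @param classified Output of [classify_pairs()].
#' @param subset Which pairs to summarize: `"wgd_retained"` (default),
#'   `"in_window"`, or `"all"`.
#' @return List with `counts` (tibble `chrom_a`, `chrom_b`, `n`, with the
#'   chromosome pair in sorted order), `n_placed`, `n_different_chromosome`
#'   and `fraction_different_chromosome`.
#' @export
chromosome_pairing_summary <- function(classified,
                                       subset = c("wgd_retained",
                                                  "in_window", "all")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
                 wgd_retained = classified$wgd_retained,
                 in_window = classified$in_window,
                 all = rep(TRUE, nrow(classified)))
  placed <- classified[keep & classified$placement == "placed", ,
                       drop = FALSE]
  lo <- pmin(placed$chrom_a, placed$chrom_b)
  hi <- pmax(placed$chrom_a, placed$chrom_b)
  counts <- dplyr::count(tibble::tibble(chrom_a = lo, chrom_b = hi),
                         .data$chrom_a, .data$chrom_b, name = "n")
  n_diff <- sum(placed$chrom_a != placed$chrom_b)
  list(
    counts = counts,
    n_placed = nrow(placed),
    n_different_chromosome = n_diff,
    fraction_different_chromosome =
      if (nrow(placed) > 0L) n_diff / nrow(placed) else NA_real_
  )
}

#' Histogram of corrected 4DTV values
#'
#' Bins the corrected 4DTV values of a divergence table, for inspecting the
#' duplicate-age distribution and choosing a WGD window.
#'
#' @param divergence Divergence tibble with `four_dtv_corr`.
#' @param binwidth Bin width (default 0.01).
#' @return Tibble with `bin_low`, `bin_high`, `count`.
#' @export
dtv_histogram <- function(divergence, binwidth = 0.01) {
  x <- divergence$four_dtv_corr
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(tibble::tibble(bin_low = numeric(), bin_high = numeric(),
                          count = integer()))
  }
  bin <- floor(x / binwidth)
  tab <- table(bin)
  idx <- as.numeric(names(tab))
  tibble::tibble(
    bin_low = idx * binwidth,
    bin_high = (idx + 1) * binwidth,
    count = as.integer(tab)
  )
}
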