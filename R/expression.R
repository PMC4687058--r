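#' Compute transcripts per million
#'
#' `tpm_g = (count_g / len_g) / sum_h(count_h / len_h) * 1e6`, per sample.
#' TPM sums to one million in every sample. A sample with zero total counts
#' has undefined TPM (`NA`, with a warning).
#'
#' @param expression Long expression tibble with `gene_id`, `sample_id`,
#'   `count`, `effective_length` (> 0).
#' @return The input with a `tpm` column added.
#' @export
compute_tpm <- function(expression) {
  stopifnot(all(expression$effective_length > 0))
  out <- expression |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      tpm = {
        rate <- .data$count / .data$effective_length
        denom <- sum(rate)
        if (denom > 0) rate / denom * 1e6 else NA_real_
      }
    ) |>
    dplyr::ungroup()
  if (anyNA(out$tpm)) {
    warning("sample(s) with zero total counts: TPM undefined",
            call. = FALSE)
  }
  out
}

#' Call genes expressed per condition
#'
#' A gene is called expressed in a tissue x genotype condition when its mean
#' TPM over that condition's replicates is strictly above `threshold`
#' (a mean of exactly `threshold` is not expressed).
#'
#' @param expression Long expression tibble with a `tpm` column
#'   ([compute_tpm()] is applied when it is missing).
#' @param threshold Mean-TPM threshold (default 1, strict `>`).
#' @return Tibble with `gene_id`, `tissue`, `genotype`, `mean_tpm`,
#'   `expressed`.
#' @export
call_expressed <- function(expression, threshold = 1) {
  if (!"tpm" %in% names(expression)) expression <- compute_tpm(expression)
  expression |>
    dplyr::group_by(.data$gene_id, .data$tissue, .data$genotype) |>
    dplyr::summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    dplyr::mutate(expressed = !is.na(.data$mean_tpm) &
                    .data$mean_tpm > threshold)
}

#' Classify expression partitioning of duplicate pairs across two tissues
#'
#' For each pair, each copy's set of tissues with expression (expressed in
#' at least one genotype of that tissue) determines the class:
#' `both_silent` (neither copy expressed anywhere), `one_silent` (one copy
#' silent, the other expressed), `partitioned` (the two copies expressed in
#' disjoint, non-empty tissue sets: reciprocal tissue specialization),
#' `single_tissue_<t>` (both copies expressed only in tissue `<t>`), and
#' `both_both` (the copies share at least one tissue and are not confined
#' together to a single tissue).
#'
#' @param pairs Tibble with `pair_id`, `id_a`, `id_b`.
#' @param calls Expressed calls from [call_expressed()]; must cover exactly
#'   two tissues.
#' @return Tibble with `pair_id`, `tissues_a`, `tissues_b` (comma-separated)
#'   and `partition_class`.
#' @export
classify_partitioning <- function(pairs, calls) {
  tissues <- sort(unique(calls$tissue))
  if (length(tissues) != 2L) {
    stop("partitioning classification expects exactly 2 tissues, got ",
         length(tissues), call. = FALSE)
  }
  by_tissue <- calls |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(expressed = any(.data$expressed), .groups = "drop")
  tissue_set <- function(gene) {
    sort(by_tissue$tissue[by_tissue$gene_id == gene & by_tissue$expressed])
  }
  classify_one <- function(ta, tb) {
    if (length(ta) == 0L && length(tb) == 0L) return("both_silent")
    if (length(ta) == 0L || length(tb) == 0L) return("one_silent")
    common <- intersect(ta, tb)
    if (length(common) == 0L) return("partitioned")
    if (length(ta) == 1L && length(tb) == 1L && ta == tb) {
      return(paste0("single_tissue_", ta))
    }
    "both_both"
  }
  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ta <- tissue_set(pairs$id_a[i])
    tb <- tissue_set(pairs$id_b[i])
    tibble::tibble(
      pair_id = pairs$pair_id[i],
      tissues_a = paste(ta, collapse = ","),
      tissues_b = paste(tb, collapse = ","),
      partition_class = classify_one(ta, tb)
    )
  })
  dplyr::bind_rows(out)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, order-preserving
#' by original index (a validated front end to the standard step-up
#' procedure).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Exact negative-binomial test for a two-group count split
#'
#' Conditional exact test of equal means between two groups of
#' negative-binomial counts with common dispersion and equal library sizes:
#' the group sums are conditioned on their total, the probability of every
#' split is computed from the NB distribution of group sums (size
#' `n/dispersion`), and the p-value is the total probability of all splits
#' at most as probable as the observed one. With `dispersion = 0` the test
#' reduces to an exact binomial split test with probability
#' `n_a / (n_a + n_b)`.
#'
#' @param sum_a,sum_b Non-negative integer group sums.
#' @param n_a,n_b Number of replicates per group.
#' @param dispersion Common NB dispersion (`>= 0`).
#' @return Two-sided p-value.
#' @export
exact_nb_test <- function(sum_a, sum_b, n_a, n_b, dispersion) {
  stopifnot(sum_a >= 0, sum_b >= 0, n_a >= 1, n_b >= 1, dispersion >= 0)
  z <- sum_a + sum_b
  if (z == 0) return(1)
  if (dispersion <= 1e-12) {
    probs <- stats::dbinom(0:z, z, n_a / (n_a + n_b))
  } else {
    mu <- z / (n_a + n_b)
    probs <- stats::dnbinom(0:z, size = n_a / dispersion, mu = n_a * mu) *
      stats::dnbinom(z:0, size = n_b / dispersion, mu = n_b * mu)
    probs <- probs / sum(probs)
  }
  p_obs <- probs[sum_a + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Quantile-free common-dispersion estimate by conditional maximum likelihood
# (equal library sizes assumed after normalization): maximizes the summed
# conditional log-likelihood of every replicate group given its total.
# `y` is the vector of (normalized) counts, `group` an id per group.
estimate_common_dispersion <- function(y, group) {
  group <- as.integer(factor(group))
  n_g <- tabulate(group)
  z_g <- as.numeric(rowsum(y, group))
  cond_ll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    sum(lgamma(y + r)) - sum(n_g) * lgamma(r) +
      sum(lgamma(n_g * r)) - sum(lgamma(z_g + n_g * r))
  }
  opt <- stats::optimize(cond_ll, interval = c(log(1e-6), log(5)),
                         maximum = TRUE)
  exp(opt$maximum)
}

#' Bin absolute log2 fold changes
#'
#' Left-closed bins on `|log2 FC|`: `low` below 0.4, `mid` in `[0.4, 2)`,
#' `high` in `[2, 8)`, `extreme` at 8 and above. The bins partition the
#' line.
#'
#' @param log2_fc Numeric vector of log2 fold changes (sign ignored).
#' @return Factor with levels `low`, `mid`, `high`, `extreme`.
#' @export
fc_bin <- function(log2_fc) {
  cut(abs(log2_fc), breaks = c(0, 0.4, 2, 8, Inf),
      labels = c("low", "mid", "high", "extreme"),
      right = FALSE, include.lowest = TRUE)
}

#' Test copy-vs-copy differential expression per condition
#'
#' For every pair and every tissue x genotype condition, the two copies'
#' replicate counts are compared with the exact negative-binomial test
#' ([exact_nb_test()]): counts are library-size normalized to a common
#' (geometric-mean) library size, a common dispersion is estimated across
#' all pairs and conditions by conditional maximum likelihood unless a fixed
#' `dispersion` is supplied, and p-values are BH-adjusted within each
#' condition. The log2 fold change is `log2((mean_b + pc) / (mean_a + pc))`
#' on normalized means with pseudo-count `pc`.
#'
#' @param expression Long expression tibble (`gene_id`, `sample_id`,
#'   `tissue`, `genotype`, `count`). At least 2 replicates per condition.
#' @param pairs Tibble with `pair_id`, `id_a`, `id_b`.
#' @param dispersion Fixed common NB dispersion, or `NULL` to estimate it.
#' @param fdr_threshold Significance threshold on the BH-adjusted values
#'   (default 0.05, `<=`).
#' @param pseudo_count Pseudo-count for the fold change (default 0.5).
#' @return Tibble with one row per pair x condition: `pair_id`, `tissue`,
#'   `genotype`, `sum_a`, `sum_b`, `n_reps`, `log2_fc`, `p_value`, `fdr`,
#'   `significant`, `fc_bin`, plus the `dispersion` used (as an attribute
#'   `dispersion`).
#' @export
de_test_pairs <- function(expression, pairs, dispersion = NULL,
                          fdr_threshold = 0.05, pseudo_count = 0.5) {
  libs <- expression |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(lib = sum(.data$count), .groups = "drop")
  if (any(libs$lib <= 0)) {
    stop("sample(s) with zero library size", call. = FALSE)
  }
  ref <- exp(mean(log(libs$lib)))
  norm <- expression |>
    dplyr::left_join(libs, by = "sample_id") |>
    dplyr::mutate(norm_count = .data$count * ref / .data$lib)

  members <- dplyr::bind_rows(
    tibble::tibble(pair_id = pairs$pair_id, gene_id = pairs$id_a,
                   copy = "a"),
    tibble::tibble(pair_id = pairs$pair_id, gene_id = pairs$id_b,
                   copy = "b")
  )
  dat <- dplyr::inner_join(members, norm, by = "gene_id",
                           relationship = "many-to-many")
  n_reps <- dat |>
    dplyr::distinct(.data$tissue, .data$genotype, .data$sample_id) |>
    dplyr::count(.data$tissue, .data$genotype, name = "n_reps")
  if (any(n_reps$n_reps < 2L)) {
    stop("every condition needs at least 2 replicates", call. = FALSE)
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      dat$norm_count,
      paste(dat$pair_id, dat$copy, dat$tissue, dat$genotype)
    )
  }
  sums <- dat |>
    dplyr::group_by(.data$pair_id, .data$tissue, .data$genotype,
                    .data$copy) |>
    dplyr::summarise(total = sum(.data$norm_count),
                     mean_norm = mean(.data$norm_count),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "copy",
                       values_from = c("total", "mean_norm", "n"))
  res <- sums |>
    dplyr::mutate(
      sum_a = round(.data$total_a),
      sum_b = round(.data$total_b),
      n_reps = .data$n_a,
      log2_fc = ifelse(
        .data$sum_a + .data$sum_b == 0, 0,
        log2((.data$mean_norm_b + pseudo_count) /
               (.data$mean_norm_a + pseudo_count))
      ),
      p_value = purrr::pmap_dbl(
        list(.data$sum_a, .data$sum_b, .data$n_a, .data$n_b),
        exact_nb_test, dispersion = dispersion
      )
    ) |>
    dplyr::group_by(.data$tissue, .data$genotype) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      significant = .data$fdr <= fdr_threshold,
      fc_bin = fc_bin(.data$log2_fc)
    ) |>
    dplyr::select("pair_id", "tissue", "genotype", "sum_a", "sum_b",
                  "n_reps", "log2_fc", "p_value", "fdr", "significant",
                  "fc_bin")
  attr(res, "dispersion") <- dispersion
  res
}
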