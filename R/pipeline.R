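#' Run the full WGD paralog-retention pipeline
#'
#' Chains every stage: contig filtering (length, expression, ORF),
#' reciprocal second-best-hit pairing, peptide alignment and
#' back-translation, 4DTV and NG86 Ka/Ks estimation, 4DTV-window and tandem
#' classification, chromosome-pairing summary, TPM and expressed calls,
#' tissue partitioning of the retained pairs, and copy-vs-copy differential
#' expression per condition.
#'
#' @param sequences Tibble with `id`, `cds` and optionally `peptide`;
#'   placement columns are ignored here (supply `positions`).
#' @param hits All-vs-all protein similarity table (see [read_hits()]).
#' @param positions Optional placement tibble (`id`, `chromosome`, `start`,
#'   `end`); without it the tandem rule and chromosome summary are skipped.
#' @param expression Optional long expression tibble (`gene_id`,
#'   `sample_id`, `tissue`, `genotype`, `count`, `effective_length`);
#'   without it the expression stages are skipped.
#' @param min_len,min_fpkm,fpkm_rule,min_codons Contig filter settings
#'   ([filter_contigs()]).
#' @param evalue_max Pairing threshold ([reciprocal_second_best()]).
#' @param dtv_low,dtv_high,tandem_max_dist Classification thresholds
#'   ([classify_pairs()]).
#' @param tpm_threshold Expressed-call threshold ([call_expressed()]).
#' @param fdr_threshold,dispersion DE settings ([de_test_pairs()]).
#' @param gap_open,gap_extend Alignment penalties ([align_peptides()]).
#' @param verbose Emit one message per stage with record counts.
#' @return Object of class `wgd_result`: a list with `filter_report`,
#'   `candidate_pairs`, `divergence`, `classified`, `pairing`,
#'   `expressed_calls`, `partitioning`, `de`, `thresholds`.
#' @export
run_wgd_pipeline <- function(sequences, hits, positions = NULL,
                             expression = NULL,
                             min_len = 500, min_fpkm = 1,
                             fpkm_rule = "any", min_codons = 100,
                             evalue_max = 1e-10,
                             dtv_low = 0.04, dtv_high = 0.2,
                             tandem_max_dist = 100000,
                             tpm_threshold = 1,
                             fdr_threshold = 0.05, dispersion = NULL,
                             gap_open = 10, gap_extend = 1,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(...)

  filt <- filter_contigs(sequences, expression = expression,
                         min_len = min_len, min_fpkm = min_fpkm,
                         fpkm_rule = fpkm_rule, min_codons = min_codons)
  retained <- filt$contigs
  say("filter: ", filt$report$n_input, " contigs in, ",
      filt$report$n_after_length, " after length, ",
      filt$report$n_after_expression, " after expression, ",
      filt$report$n_after_orf, " after ORF")

  hits_kept <- hits[hits$query_id %in% retained$id &
                      hits$subject_id %in% retained$id, , drop = FALSE]
  pairs <- reciprocal_second_best(rank_hits(hits_kept),
                                  evalue_max = evalue_max)
  say("pairs: ", nrow(pairs), " reciprocal second-best candidate pairs")

  divergence <- pair_divergence(pairs, retained,
                                gap_open = gap_open,
                                gap_extend = gap_extend)
  classified <- classify_pairs(divergence, positions,
                               dtv_low = dtv_low, dtv_high = dtv_high,
                               tandem_max_dist = tandem_max_dist)
  say("classify: ", sum(classified$in_window), " in the 4DTV window, ",
      sum(classified$in_window & classified$is_tandem),
      " tandem, ", sum(classified$wgd_retained), " WGD-retained")
  pairing <- if (!is.null(positions)) {
    chromosome_pairing_summary(classified)
  } else {
    NULL
  }

  calls <- NULL
  partitioning <- NULL
  de <- NULL
  if (!is.null(expression)) {
    expr <- compute_tpm(expression)
    calls <- call_expressed(expr, threshold = tpm_threshold)
    retained_pairs <- classified[classified$wgd_retained, , drop = FALSE]
    if (nrow(retained_pairs) > 0L) {
      if (length(unique(expr$tissue)) == 2L) {
        partitioning <- classify_partitioning(retained_pairs, calls)
      }
      de <- de_test_pairs(expression, retained_pairs,
                          dispersion = dispersion,
                          fdr_threshold = fdr_threshold)
      say("expression: ", sum(de$significant), " of ", nrow(de),
          " pair x condition tests significant at FDR <= ", fdr_threshold)
    }
  }

  structure(
    list(
      filter_report = filt$report,
      candidate_pairs = pairs,
      divergence = divergence,
      classified = classified,
      pairing = pairing,
      expressed_calls = calls,
      partitioning = partitioning,
      de = de,
      thresholds = list(
        min_len = min_len, min_fpkm = min_fpkm, fpkm_rule = fpkm_rule,
        min_codons = min_codons, evalue_max = evalue_max,
        dtv_low = dtv_low, dtv_high = dtv_high,
        tandem_max_dist = tandem_max_dist, tpm_threshold = tpm_threshold,
        fdr_threshold = fdr_threshold
      )
    ),
    class = "wgd_result"
  )
}

#' @export
print.wgd_result <- function(x, ...) {
  r <- x$filter_report
  cat("WGD paralog-retention analysis\n")
  cat("  contigs: ", r$n_input, " in -> ", r$n_after_length,
      " (length) -> ", r$n_after_expression, " (expression) -> ",
      r$n_after_orf, " (ORF)\n", sep = "")
  cat("  candidate pairs:", nrow(x$candidate_pairs), "\n")
  cat("  in 4DTV window [", x$thresholds$dtv_low, ", ",
      x$thresholds$dtv_high, "]: ", sum(x$classified$in_window),
      "  (tandem: ", sum(x$classified$in_window & x$classified$is_tandem),
      ", WGD-retained: ", sum(x$classified$wgd_retained), ")\n", sep = "")
  if (!is.null(x$pairing)) {
    cat("  copies on different chromosomes: ",
        x$pairing$n_different_chromosome, "/", x$pairing$n_placed,
        sprintf(" (%.0f%%)\n",
                100 * x$pairing$fraction_different_chromosome), sep = "")
  }
  if (!is.null(x$de)) {
    cat("  DE tests significant (FDR <= ", x$thresholds$fdr_threshold,
        "): ", sum(x$de$significant), "/", nrow(x$de), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a WGD pipeline result
#'
#' One row per candidate pair with its divergence statistics, window/tandem
#' classification and, when expression was analysed, the number of
#' conditions in which the copies were significantly differentially
#' expressed.
#'
#' @param x A `wgd_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wgd_result
#' @export
tidy.wgd_result <- function(x, ...) {
  out <- tibble::as_tibble(x$classified)
  if (!is.null(x$de)) {
    de_sum <- x$de |>
      dplyr::group_by(.data$pair_id) |>
      dplyr::summarise(
        n_conditions_de = sum(.data$significant),
        max_abs_log2_fc = max(abs(.data$log2_fc)),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, de_sum, by = "pair_id")
  }
  out
}

#' Glance at a WGD pipeline result
#'
#' @param x A `wgd_result`.
#' @param ... Unused.
#' @return One-row tibble with the cascade counts and headline statistics:
#'   contig counts, candidate/in-window/tandem/WGD-retained pair counts,
#'   fraction of placed pairs on different chromosomes, mean and median
#'   Ka/Ks of retained pairs, and the mean fraction of retained pairs
#'   significantly DE per condition.
#' @method glance wgd_result
#' @export
glance.wgd_result <- function(x, ...) {
  retained <- x$classified[x$classified$wgd_retained, , drop = FALSE]
  frac_de <- if (!is.null(x$de) && nrow(x$de) > 0L) {
    mean(tapply(x$de$significant,
                paste(x$de$tissue, x$de$genotype), mean))
  } else {
    NA_real_
  }
  tibble::tibble(
    n_contigs_input = x$filter_report$n_input,
    n_contigs_retained = x$filter_report$n_after_orf,
    n_candidate_pairs = nrow(x$candidate_pairs),
    n_in_window = sum(x$classified$in_window),
    n_tandem = sum(x$classified$in_window & x$classified$is_tandem),
    n_wgd_retained = sum(x$classified$wgd_retained),
    fraction_different_chromosome =
      if (is.null(x$pairing)) NA_real_ else
        x$pairing$fraction_different_chromosome,
    mean_ka_ks = mean(retained$omega, na.rm = TRUE),
    median_ka_ks = stats::median(retained$omega, na.rm = TRUE),
    mean_fraction_de = frac_de
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
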