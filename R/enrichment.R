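#' Spearman rank correlation between expression and sequence divergence
#'
#' Correlates a per-pair differential-expression metric (default the
#' absolute log2 fold change) with each sequence-divergence measure, per
#' tissue x genotype condition, using Spearman rank correlation with
#' average ranks for ties. P-values use the exact null distribution where
#' available (no ties) and the large-sample t approximation otherwise.
#'
#' @param de DE results from [de_test_pairs()].
#' @param divergence Divergence tibble from [pair_divergence()].
#' @param measures Divergence columns to correlate against (defaults:
#'   `omega` i.e. Ka/Ks, `ka`, `ks`, `four_dtv_corr`).
#' @param metric Expression-divergence metric: `"abs_log2_fc"` (default),
#'   `"log2_fc"`, or `"fdr"`.
#' @return Tibble with `tissue`, `genotype`, `measure`, `rho`, `p_value`,
#'   `n` (pairs with both values defined; `rho` is `NA` with fewer than 3 or
#'   a constant input).
#' @export
spearman_assoc <- function(de, divergence,
                           measures = c("omega", "ka", "ks",
                                        "four_dtv_corr"),
                           metric = c("abs_log2_fc", "log2_fc", "fdr")) {
  metric <- match.arg(metric)
  de$de_metric <- switch(metric,
                         abs_log2_fc = abs(de$log2_fc),
                         log2_fc = de$log2_fc,
                         fdr = de$fdr)
  joined <- dplyr::inner_join(de, divergence, by = "pair_id")
  conds <- dplyr::distinct(de, .data$tissue, .data$genotype)
  out <- list()
  for (i in seq_len(nrow(conds))) {
    sub <- joined[joined$tissue == conds$tissue[i] &
                    joined$genotype == conds$genotype[i], , drop = FALSE]
    for (m in measures) {
      x <- sub$de_metric
      y <- sub[[m]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3L || length(unique(x[ok])) < 2L ||
          length(unique(y[ok])) < 2L) {
        rho <- NA_real_
        p <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman")
        )
        rho <- unname(ct$estimate)
        p <- ct$p.value
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        tissue = conds$tissue[i], genotype = conds$genotype[i],
        measure = m, rho = rho, p_value = p, n = n
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Transfer functional annotations by best hit
#'
#' Annotates each query with the GO term set of its single best hit against
#' an annotation reference, keeping only hits with `evalue < evalue_max` and
#' `bitscore > bitscore_min` (both strict). The best hit per query is the
#' one with the lowest e-value, ties broken by highest bitscore and then by
#' subject id. Queries without a qualifying hit are absent from the result.
#'
#' @param hits Hit tibble (query = gene, subject = reference protein).
#' @param go_map Reference annotation tibble (`gene_id` = reference protein
#'   id, `go_id`).
#' @param evalue_max E-value ceiling (default 1e-10, strict `<`).
#' @param bitscore_min Bitscore floor (default 40, strict `>`).
#' @return Tibble with `gene_id`, `go_id`, plus the provenance columns
#'   `subject_id`, `evalue`, `bitscore` of the best hit.
#' @export
transfer_annotations <- function(hits, go_map, evalue_max = 1e-10,
                                 bitscore_min = 40) {
  best <- hits |>
    dplyr::filter(.data$evalue < evalue_max,
                  .data$bitscore > bitscore_min) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  best |>
    dplyr::inner_join(go_map, by = c(subject_id = "gene_id"),
                      relationship = "many-to-many") |>
    dplyr::select(gene_id = "query_id", "go_id", "subject_id", "evalue",
                  "bitscore")
}

#' GO term enrichment by one-sided Fisher's exact test
#'
#' For every term annotated in the reference, builds the 2x2 table of
#' test-set membership against term membership and computes the one-sided
#' (overrepresentation) Fisher exact p-value, i.e. the hypergeometric upper
#' tail. By default the comparison margin is the reference minus the test
#' set (disjoint margins); `mode = "inclusive"` keeps the test genes in the
#' reference margin. P-values are BH-adjusted across terms.
#'
#' @param test_genes Character vector of test-set gene ids (must be a subset
#'   of the reference).
#' @param reference_genes Character vector of reference gene ids.
#' @param annotations Annotation tibble (`gene_id`, `go_id`), e.g. from
#'   [transfer_annotations()] or [simulate_go_map()].
#' @param mode Margin construction, `"exclusive"` (default) or
#'   `"inclusive"`.
#' @param alternative `"greater"` (one-sided overrepresentation, default) or
#'   `"two.sided"`.
#' @param alpha Threshold on the adjusted p-value for the `overrepresented`
#'   call (default 0.05, `<=`).
#' @return Tibble with one row per term: `go_id`, `test_with`,
#'   `test_without`, `ref_with`, `ref_without`, `odds_ratio`, `p_value`,
#'   `p_adjusted`, `overrepresented`.
#' @export
fisher_enrichment <- function(test_genes, reference_genes, annotations,
                              mode = c("exclusive", "inclusive"),
                              alternative = c("greater", "two.sided"),
                              alpha = 0.05) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  test_genes <- unique(test_genes)
  reference_genes <- unique(reference_genes)
  if (!all(test_genes %in% reference_genes)) {
    stop("the test set must be a subset of the reference set",
         call. = FALSE)
  }
  if (length(test_genes) == 0L) {
    return(tibble::tibble(
      go_id = character(), test_with = integer(), test_without = integer(),
      ref_with = integer(), ref_without = integer(), odds_ratio = numeric(),
      p_value = numeric(), p_adjusted = numeric(),
      overrepresented = logical()
    ))
  }
  bg <- if (mode == "exclusive") setdiff(reference_genes, test_genes)
        else reference_genes
  ann <- annotations[annotations$gene_id %in% reference_genes, ,
                     drop = FALSE]
  terms <- unique(ann$go_id)
  genes_with <- split(ann$gene_id, ann$go_id)
  n_test <- length(test_genes)
  n_bg <- length(bg)
  a <- vapply(terms, function(t) sum(test_genes %in% genes_with[[t]]), 0L)
  c_ <- vapply(terms, function(t) sum(bg %in% genes_with[[t]]), 0L)
  b <- n_test - a
  d <- n_bg - c_
  if (alternative == "greater") {
    # one-sided Fisher p = hypergeometric upper tail
    p <- stats::phyper(a - 1, a + c_, b + d, n_test, lower.tail = FALSE)
  } else {
    p <- vapply(seq_along(terms), function(i) {
      stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), nrow = 2),
                         alternative = "two.sided")$p.value
    }, 0)
  }
  or <- (a * d) / pmax(b * c_, .Machine$double.xmin)
  adj <- bh_fdr(p)
  tibble::tibble(
    go_id = terms,
    test_with = as.integer(a), test_without = as.integer(b),
    ref_with = as.integer(c_), ref_without = as.integer(d),
    odds_ratio = or,
    p_value = unname(p), p_adjusted = adj,
    overrepresented = adj <= alpha
  ) |>
    dplyr::arrange(.data$p_value, .data$go_id)
}
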