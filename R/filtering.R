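#' Compute FPKM from counts and lengths
#'
#' Fragments per kilobase of contig per million mapped fragments:
#' `count * 1e9 / (effective_length * total_mapped_fragments)`, the total
#' taken per sample.
#'
#' @param expression Long expression tibble with `gene_id`, `sample_id`,
#'   `count`, `effective_length`.
#' @return The input with an `fpkm` column added.
#' @export
compute_fpkm <- function(expression) {
  dplyr::mutate(
    dplyr::group_by(expression, .data$sample_id),
    fpkm = .data$count * 1e9 /
      (.data$effective_length * sum(.data$count)),
    .keep = "all"
  ) |>
    dplyr::ungroup()
}

#' Filter contigs by minimum length
#'
#' Retains contigs whose sequence length is at least `min_len` (inclusive).
#'
#' @param contigs Tibble with an `id` column and a sequence column.
#' @param min_len Minimum length in bp (default 500).
#' @param seq_col Name of the sequence column.
#' @return The retained rows, order preserved.
#' @export
filter_by_length <- function(contigs, min_len = 500, seq_col = "cds") {
  contigs[nchar(contigs[[seq_col]]) >= min_len, , drop = FALSE]
}

#' Filter contigs by expression level
#'
#' A contig counts as expressed when its FPKM reaches `min_fpkm` in at least
#' one sample (`rule = "any"`, the default), in every sample (`"all"`), or on
#' average over samples (`"mean"`). Contigs absent from the FPKM table are
#' treated as unexpressed with a warning.
#'
#' @param contigs Tibble with an `id` column.
#' @param fpkm Long tibble with `gene_id`, `sample_id`, `fpkm` (see
#'   [compute_fpkm()]).
#' @param min_fpkm Threshold (default 1; the comparison is `>=`).
#' @param rule Aggregation over samples.
#' @return The retained rows, order preserved.
#' @export
filter_by_expression <- function(contigs, fpkm, min_fpkm = 1,
                                 rule = c("any", "all", "mean")) {
  rule <- match.arg(rule)
  agg <- dplyr::summarise(
    dplyr::group_by(fpkm, .data$gene_id),
    stat = switch(rule,
                  any = max(.data$fpkm),
                  all = min(.data$fpkm),
                  mean = mean(.data$fpkm)),
    .groups = "drop"
  )
  stat <- stats::setNames(agg$stat, agg$gene_id)
  missing <- setdiff(contigs$id, names(stat))
  if (length(missing) > 0L) {
    warning(length(missing), " contig(s) absent from the FPKM table, ",
            "treated as unexpressed", call. = FALSE)
  }
  val <- stat[contigs$id]
  val[is.na(val)] <- 0
  contigs[val >= min_fpkm, , drop = FALSE]
}

# Longest ATG-to-stop ORF in the three forward frames of one strand.
# Returns NULL or list(start0, end0, frame, peptide) in 0-based half-open
# coordinates on the scanned strand.
scan_orfs_forward <- function(seq, min_codons) {
  n <- nchar(seq)
  best <- NULL
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3L
    if (n_codons < min_codons + 1L) next
    starts <- f + seq.int(1L, by = 3L, length.out = n_codons)
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg_start <- 1L  # first codon index of the current stop-free segment
    for (j in which(is_stop)) {
      atg <- which(is_atg[seg_start:(j - 1L)])
      if (length(atg) > 0L) {
        j1 <- seg_start + atg[1L] - 1L
        len <- j - j1  # peptide codons, ATG through last sense codon
        if (len >= min_codons && (is.null(best) || len > best$len)) {
          best <- list(
            len = len,
            start0 = f + 3L * (j1 - 1L),
            end0 = f + 3L * j,  # includes the stop codon
            frame = f + 1L,
            peptide = paste(CODON_TABLE[codons[j1:(j - 1L)]], collapse = "")
          )
        }
      }
      seg_start <- j + 1L
    }
  }
  best
}

#' Find the longest open reading frame
#'
#' Scans all six frames for the longest ATG-to-stop open reading frame with a
#' peptide of at least `min_codons` codons. Coordinates are 0-based half-open
#' on the forward strand and include the stop codon; reverse-strand ORFs are
#' reported with negative frames.
#'
#' @param seq A DNA string.
#' @param min_codons Minimum peptide length in codons (default 100).
#' @return One-row tibble (`start`, `end`, `frame`, `peptide`) or `NULL`
#'   when no qualifying ORF exists.
#' @export
find_orf <- function(seq, min_codons = 100) {
  seq <- toupper(seq)
  n <- nchar(seq)
  fwd <- scan_orfs_forward(seq, min_codons)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev <- scan_orfs_forward(rc, min_codons)
  if (is.null(fwd) && is.null(rev)) return(NULL)
  use_rev <- is.null(fwd) || (!is.null(rev) && rev$len > fwd$len)
  hit <- if (use_rev) rev else fwd
  if (use_rev) {
    tibble::tibble(
      start = n - hit$end0, end = n - hit$start0,
      frame = -hit$frame, peptide = hit$peptide
    )
  } else {
    tibble::tibble(
      start = hit$start0, end = hit$end0,
      frame = hit$frame, peptide = hit$peptide
    )
  }
}

#' Apply the contig filtering cascade
#'
#' Reproduces the assembly filtering cascade: minimum length, minimum
#' expression (FPKM), and presence of an open reading frame, applied in that
#' order. Each filter is a pure predicate, so the retained set does not
#' depend on the order; the per-stage counts in the report do.
#'
#' @param contigs Tibble with `id` and a sequence column (`seq_col`).
#' @param expression Optional long expression tibble used to compute FPKM
#'   when `fpkm` is not supplied; if both are `NULL` the expression filter is
#'   skipped.
#' @param fpkm Optional precomputed FPKM tibble (`gene_id`, `sample_id`,
#'   `fpkm`).
#' @param min_len,min_fpkm,fpkm_rule,min_codons Filter thresholds (defaults:
#'   500 bp, FPKM >= 1 in any sample, 100-codon ORF).
#' @param seq_col Name of the sequence column.
#' @return List with `contigs` (retained rows plus `orf_peptide`) and
#'   `report`: a list holding the cascade counts (`n_input`,
#'   `n_after_length`, `n_after_expression`, `n_after_orf`) and a
#'   per-contig `reasons` tibble (`id`, `reason`; reason `retained` for
#'   survivors).
#' @export
filter_contigs <- function(contigs, expression = NULL, fpkm = NULL,
                           min_len = 500, min_fpkm = 1,
                           fpkm_rule = c("any", "all", "mean"),
                           min_codons = 100, seq_col = "cds") {
  fpkm_rule <- match.arg(fpkm_rule)
  n_input <- nrow(contigs)
  reasons <- stats::setNames(rep("retained", n_input), contigs$id)

  after_len <- filter_by_length(contigs, min_len = min_len, seq_col = seq_col)
  reasons[setdiff(contigs$id, after_len$id)] <- "too_short"

  if (is.null(fpkm) && !is.null(expression)) {
    fpkm <- compute_fpkm(expression)
  }
  after_expr <- if (!is.null(fpkm)) {
    filter_by_expression(after_len, fpkm, min_fpkm = min_fpkm,
                         rule = fpkm_rule)
  } else {
    after_len
  }
  reasons[setdiff(after_len$id, after_expr$id)] <- "low_expression"

  orfs <- purrr::map(after_expr[[seq_col]], find_orf, min_codons = min_codons)
  has_orf <- !purrr::map_lgl(orfs, is.null)
  after_orf <- after_expr[has_orf, , drop = FALSE]
  after_orf$orf_peptide <- purrr::map_chr(orfs[has_orf], "peptide")
  reasons[setdiff(after_expr$id, after_orf$id)] <- "no_orf"

  list(
    contigs = after_orf,
    report = list(
      n_input = n_input,
      n_after_length = nrow(after_len),
      n_after_expression = nrow(after_expr),
      n_after_orf = nrow(after_orf),
      reasons = tibble::tibble(id = names(reasons),
                               reason = unname(reasons))
    )
  )
}
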