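#' Raw transversion proportion at fourfold-degenerate sites
#'
#' The raw 4DTV of a pair is the proportion of its fourfold-degenerate sites
#' whose third-position bases differ by a transversion (purine vs
#' pyrimidine). Transversions accumulate more slowly than transitions, so
#' this statistic saturates later than overall synonymous divergence.
#'
#' @param sites Tibble of 4D sites from [find_4d_sites()] (columns `base_a`,
#'   `base_b`).
#' @return One-row tibble: `n_4d_sites`, `n_transversions`, `four_dtv_raw`
#'   (`NA` when there are no sites).
#' @export
raw_4dtv <- function(sites) {
  stopifnot(all(c(sites$base_a, sites$base_b) %in% c("A", "C", "G", "T")))
  n <- nrow(sites)
  tv <- sum(is_transversion(sites$base_a, sites$base_b))
  tibble::tibble(
    n_4d_sites = n,
    n_transversions = tv,
    four_dtv_raw = if (n > 0L) tv / n else NA_real_
  )
}

#' Correct a raw 4DTV value for multiple substitutions
#'
#' Applies Kimura's two-state (purine/pyrimidine) distance correction for a
#' pure-transversion proportion, `-log(1 - 2q) / 2`: the transversion
#' analogue of the Jukes-Cantor correction. It is monotone increasing, at
#' least as large as the raw value, and tends to `q` as `q` tends to 0.
#' Values at or above 0.5 are saturated and return `NA`.
#'
#' @param q Raw 4DTV proportion(s) in `[0, 0.5)`.
#' @return Corrected transversion rate(s); `NA` where `q >= 0.5` or `q` is
#'   `NA`.
#' @seealso [uncorrect_4dtv()] for the inverse.
#' @export
correct_4dtv <- function(q) {
  stopifnot(all(q >= 0 | is.na(q)))
  out <- ifelse(q < 0.5, -log(1 - 2 * q) / 2, NA_real_)
  out[is.na(q)] <- NA_real_
  out
}

#' @rdname correct_4dtv
#' @param d Corrected transversion rate(s) (non-negative).
#' @return `uncorrect_4dtv()` returns the raw proportion whose correction is
#'   `d`, i.e. `(1 - exp(-2 d)) / 2`. Useful to plant simulated pairs whose
#'   *corrected* 4DTV hits a target value.
#' @export
uncorrect_4dtv <- function(d) {
  stopifnot(all(d >= 0 | is.na(d)))
  (1 - exp(-2 * d)) / 2
}

# --- NG86 machinery ---------------------------------------------------------

# Per-codon synonymous/nonsynonymous site counts: at each codon position the
# three single-nucleotide neighbours are enumerated; neighbours that are stop
# codons are excluded from both numerator and denominator, and the position
# contributes (synonymous fraction, nonsynonymous fraction) of one site.
ng86_site_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bases <- c("A", "C", "G", "T")
    syn <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
    for (codon in SENSE_CODONS) {
      aa <- CODON_TABLE[[codon]]
      s <- 0
      for (pos in 1:3) {
        nb <- codon
        cur <- substr(codon, pos, pos)
        n_ok <- 0L
        n_syn <- 0L
        for (b in setdiff(bases, cur)) {
          substr(nb, pos, pos) <- b
          aa_nb <- CODON_TABLE[[nb]]
          if (aa_nb == "*") next
          n_ok <- n_ok + 1L
          if (aa_nb == aa) n_syn <- n_syn + 1L
        }
        if (n_ok > 0L) s <- s + n_syn / n_ok
      }
      syn[codon] <- s
    }
    cache <<- syn
    cache
  }
})

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair. All orderings of the differing positions are enumerated; orderings
# passing through a stop codon are excluded and the synonymous/nonsynonymous
# step counts are averaged over the remaining orderings with equal weight.
# When every ordering is blocked by stops, each differing position is
# classified against the first codon's background, with a warning.
ng86_path_diffs <- function(codon_a, codon_b) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0, blocked = 0))
  perms <- switch(as.character(d),
    "1" = list(diff_pos),
    "2" = list(diff_pos, diff_pos[c(2, 1)]),
    "3" = lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                 function(o) diff_pos[o])
  )
  sd_tot <- 0
  nd_tot <- 0
  n_valid <- 0L
  for (path in perms) {
    cur <- codon_a
    sd <- 0L
    nd <- 0L
    ok <- TRUE
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (CODON_TABLE[[nxt]] == "*") {
        ok <- FALSE
        break
      }
      if (CODON_TABLE[[nxt]] == CODON_TABLE[[cur]]) sd <- sd + 1L
      else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd
      nd_tot <- nd_tot + nd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) {
    # all substitution orderings pass through a stop codon; fall back to
    # classifying each differing position against codon_a's background
    sd <- 0
    nd <- 0
    for (pos in diff_pos) {
      nxt <- codon_a
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (CODON_TABLE[[nxt]] != "*" &&
          CODON_TABLE[[nxt]] == CODON_TABLE[[codon_a]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
    }
    return(c(sd = sd, nd = nd, blocked = 1))
  }
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid, blocked = 0)
}

ng86_diff_cache <- new.env(parent = emptyenv())

ng86_diffs_cached <- function(codon_a, codon_b) {
  key <- paste0(codon_a, codon_b)
  hit <- ng86_diff_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- ng86_path_diffs(codon_a, codon_b)
  assign(key, val, envir = ng86_diff_cache)
  val
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Proportion of differing sites (per site class).
#' @return `-3/4 * log(1 - 4/3 p)`; `NA` where `p >= 3/4` (saturated).
#' @keywords internal
jukes_cantor <- function(p) {
  ifelse(!is.na(p) & p < 0.75, -0.75 * log(1 - 4 / 3 * p), NA_real_)
}

#' Estimate Ka, Ks and Ka/Ks by the NG86 counting method
#'
#' Nei-Gojobori (1986) counting estimator on a pairwise codon alignment:
#' synonymous and nonsynonymous site counts come from enumerating each
#' codon's nine single-nucleotide neighbours under the standard code
#' (mutations to stop codons are excluded from both numerator and site
#' counts), observed differences are partitioned by averaging over all
#' minimal substitution pathways that avoid stop codons, and the resulting
#' proportions receive the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4/3 p)`. Gapped columns are ignored.
#'
#' @param aln A `codon_alignment` from [back_translate()].
#' @return One-row tibble: site counts (`s_sites`, `n_sites`), difference
#'   counts (`sd`, `nd`), proportions (`ps`, `pn`), corrected rates `ka`,
#'   `ks`, the ratio `omega` (`NA` when `ks` is 0 or undefined), and a
#'   `kaks_flag` (`"ok"`, `"saturated"`, or `"undefined"`).
#' @export
estimate_ka_ks <- function(aln) {
  cols <- aln[aln$ungapped, , drop = FALSE]
  if (nrow(cols) == 0L) {
    return(tibble::tibble(
      s_sites = NA_real_, n_sites = NA_real_, sd = NA_real_, nd = NA_real_,
      ps = NA_real_, pn = NA_real_, ka = NA_real_, ks = NA_real_,
      omega = NA_real_, kaks_flag = "undefined"
    ))
  }
  if (!all(c(cols$codon_a, cols$codon_b) %in% SENSE_CODONS)) {
    stop("codon alignment contains a stop or ambiguous codon", call. = FALSE)
  }
  site_tab <- ng86_site_table()
  s_a <- sum(site_tab[cols$codon_a])
  s_b <- sum(site_tab[cols$codon_b])
  s_sites <- (s_a + s_b) / 2
  n_sites <- 3 * nrow(cols) - s_sites
  differing <- cols$codon_a != cols$codon_b
  sd <- 0
  nd <- 0
  blocked <- 0
  if (any(differing)) {
    res <- vapply(which(differing), function(i) {
      ng86_diffs_cached(cols$codon_a[i], cols$codon_b[i])
    }, c(sd = 0, nd = 0, blocked = 0))
    sd <- sum(res["sd", ])
    nd <- sum(res["nd", ])
    blocked <- sum(res["blocked", ])
  }
  if (blocked > 0L) {
    warning(blocked, " codon pair(s) had every substitution pathway ",
            "blocked by stop codons; differences classified by ",
            "single-position substitution", call. = FALSE)
  }
  ps <- if (s_sites > 0) sd / s_sites else NA_real_
  pn <- if (n_sites > 0) nd / n_sites else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  flag <- if ((is.na(ks) && !is.na(ps)) || (is.na(ka) && !is.na(pn))) {
    "saturated"
  } else {
    "ok"
  }
  omega <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  tibble::tibble(
    s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
    ps = ps, pn = pn, ka = ka, ks = ks, omega = omega, kaks_flag = flag
  )
}

#' Compute divergence statistics for a set of candidate pairs
#'
#' For each pair: align the peptides globally, back-translate to a codon
#' alignment, locate fourfold-degenerate sites, and compute raw and
#' corrected 4DTV plus the NG86 Ka/Ks estimates.
#'
#' @param pairs Candidate pairs from [reciprocal_second_best()] (columns
#'   `pair_id`, `id_a`, `id_b`).
#' @param sequences Sequence tibble with `id`, `cds` and optionally
#'   `peptide` (translated from `cds` when absent).
#' @param gap_open,gap_extend Alignment gap penalties (see
#'   [align_peptides()]).
#' @param correction Function applied to the raw 4DTV proportion; defaults
#'   to [correct_4dtv()] and can be swapped for another multiple-hit
#'   correction.
#' @return Tibble with one row per pair: 4D site counts, `four_dtv_raw`,
#'   `four_dtv_corr`, `dtv_flag` (`"ok"`, `"saturated"` when the raw value
#'   is at least 0.5, `"undefined"` when there are no 4D sites), and the
#'   [estimate_ka_ks()] columns.
#' @export
pair_divergence <- function(pairs, sequences, gap_open = 10, gap_extend = 1,
                            correction = correct_4dtv) {
  seqs <- sequences
  if (!"peptide" %in% names(seqs)) {
    seqs$peptide <- purrr::map_chr(seqs$cds, translate_cds)
  }
  lookup <- stats::setNames(seq_len(nrow(seqs)), seqs$id)
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ia <- lookup[[pairs$id_a[i]]]
    ib <- lookup[[pairs$id_b[i]]]
    pa <- align_peptides(seqs$peptide[ia], seqs$peptide[ib],
                         gap_open = gap_open, gap_extend = gap_extend)
    aln <- back_translate(pa$a, pa$b, seqs$cds[ia], seqs$cds[ib],
                          pair_id = pairs$pair_id[i])
    sites <- find_4d_sites(aln)
    dtv <- raw_4dtv(sites)
    corr <- if (is.na(dtv$four_dtv_raw)) NA_real_ else
      correction(dtv$four_dtv_raw)
    flag <- if (is.na(dtv$four_dtv_raw)) "undefined"
            else if (is.na(corr)) "saturated" else "ok"
    dplyr::bind_cols(
      tibble::tibble(pair_id = pairs$pair_id[i],
                     id_a = pairs$id_a[i], id_b = pairs$id_b[i]),
      dtv,
      tibble::tibble(four_dtv_corr = corr, dtv_flag = flag),
      estimate_ka_ks(aln)
    )
  })
  dplyr::bind_rows(rows)
}
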