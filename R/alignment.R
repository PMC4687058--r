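AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Globally align two peptides
#'
#' Needleman-Wunsch global alignment with the BLOSUM62 substitution matrix
#' and affine gap penalties: a gap run of length L costs
#' `gap_open + L * gap_extend` (defaults 10 and 1, the ClustalW-style
#' pairwise settings). Deterministic for given inputs.
#'
#' @param pep_a,pep_b Peptide strings (standard 20 amino acids).
#' @param gap_open,gap_extend Gap opening and per-residue extension
#'   penalties (positive numbers).
#' @return List with the two aligned strings `a` and `b` (gaps as `-`) and
#'   the alignment `score`.
#' @export
align_peptides <- function(pep_a, pep_b, gap_open = 10, gap_extend = 1) {
  for (p in list(pep_a, pep_b)) {
    if (!nzchar(p)) stop("cannot align an empty peptide", call. = FALSE)
    bad <- setdiff(strsplit(p, "")[[1]], AA_ALPHABET20)
    if (length(bad) > 0L) {
      stop("invalid residue '", bad[1L], "' in peptide", call. = FALSE)
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pep_a), Biostrings::AAString(pep_b),
    type = "global", substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

#' Back-translate an aligned peptide pair to a codon alignment
#'
#' Replaces every residue column of a peptide alignment by the source codon
#' and every gap by `---`, after verifying that each CDS translates exactly
#' to its ungapped peptide (a single terminal stop codon on the CDS is
#' stripped first). Removing the gaps from either row of the result recovers
#' the input CDS.
#'
#' @param aln_a,aln_b Aligned peptide strings of equal length (gaps as `-`).
#' @param cds_a,cds_b The corresponding coding sequences.
#' @param pair_id Optional identifier used in error messages.
#' @return Tibble of class `codon_alignment`: one row per alignment column
#'   with `column`, `codon_a`, `codon_b`, `ungapped`, `fourfold`.
#' @export
back_translate <- function(aln_a, aln_b, cds_a, cds_b, pair_id = NULL) {
  if (nchar(aln_a) != nchar(aln_b)) {
    stop("aligned peptides have different lengths", call. = FALSE)
  }
  tag <- if (is.null(pair_id)) "" else paste0(" for pair ", pair_id)
  expand <- function(aln, cds) {
    codons <- split_codons(toupper(cds))
    if (length(codons) > 0L &&
        CODON_TABLE[codons[length(codons)]] == "*") {
      codons <- codons[-length(codons)]
    }
    residues <- strsplit(aln, "")[[1]]
    n_res <- sum(residues != "-")
    if (n_res != length(codons)) {
      stop("peptide/CDS length mismatch", tag, ": ", n_res,
           " aligned residues vs ", length(codons), " codons", call. = FALSE)
    }
    pep <- translate_cds(paste(codons, collapse = ""),
                         drop_terminal_stop = FALSE)
    if (pep != paste(residues[residues != "-"], collapse = "")) {
      stop("CDS does not translate to the aligned peptide", tag,
           call. = FALSE)
    }
    out <- rep("---", length(residues))
    out[residues != "-"] <- codons
    out
  }
  col_a <- expand(aln_a, cds_a)
  col_b <- expand(aln_b, cds_b)
  aln <- tibble::tibble(
    column = seq_along(col_a),
    codon_a = col_a,
    codon_b = col_b
  )
  aln$ungapped <- aln$codon_a != "---" & aln$codon_b != "---"
  prefix_a <- substr(aln$codon_a, 1L, 2L)
  aln$fourfold <- aln$ungapped &
    prefix_a == substr(aln$codon_b, 1L, 2L) &
    prefix_a %in% FOURFOLD_PREFIXES
  class(aln) <- c("codon_alignment", class(aln))
  aln
}

#' Locate fourfold-degenerate sites in a codon alignment
#'
#' A column contributes one fourfold-degenerate (4D) site when both codons
#' are ungapped, their first two bases are identical, and that shared prefix
#' belongs to one of the eight fourfold-degenerate families of the standard
#' code (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN). The site is the pair of
#' third-position bases.
#'
#' @param aln A `codon_alignment` from [back_translate()].
#' @return Tibble with `column`, `base_a`, `base_b`, one row per 4D site.
#' @export
find_4d_sites <- function(aln) {
  ff <- aln[aln$fourfold, , drop = FALSE]
  tibble::tibble(
    column = ff$column,
    base_a = substr(ff$codon_a, 3L, 3L),
    base_b = substr(ff$codon_b, 3L, 3L)
  )
}
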