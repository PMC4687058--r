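# Standard nuclear genetic code, hard-coded (the study organisms are plants,
# nuclear genes). Kept as a plain named vector so every consumer in the
# package classifies codons identically.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE == "*"]
SENSE_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]

# The eight fourfold-degenerate codon families of the standard code: any
# third-position base after one of these dinucleotide prefixes encodes the
# same amino acid.
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# base -> its transition partner
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
# base -> its two transversion partners
TRANSVERSIONS_OF <- list(
  A = c("C", "T"), G = c("C", "T"),
  C = c("A", "G"), T = c("A", "G")
)

#' Split a coding sequence into codons
#'
#' @param cds A single DNA string whose length is a multiple of three.
#' @return Character vector of codons.
#' @keywords internal
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a multiple of three", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(cds, starts, starts + 2L)
}

#' Translate a coding sequence
#'
#' Translates a CDS under the standard genetic code. By default the single
#' terminal stop codon, if present, is dropped so that the result is the
#' mature peptide; internal stop codons raise an error.
#'
#' @param cds A DNA string (A/C/G/T), length a multiple of three.
#' @param drop_terminal_stop Drop a trailing stop codon before returning.
#' @return The peptide as a single string.
#' @examples
#' translate_cds("ATGGCTTAA")
#' @export
translate_cds <- function(cds, drop_terminal_stop = TRUE) {
  codons <- split_codons(toupper(cds))
  if (length(codons) == 0L) return("")
  aa <- unname(CODON_TABLE[codons])
  if (anyNA(aa)) {
    bad <- codons[is.na(aa)][1L]
    stop("unrecognised codon '", bad, "' in CDS", call. = FALSE)
  }
  internal <- aa[-length(aa)]
  if (any(internal == "*")) {
    stop("internal stop codon at codon position ",
         which(internal == "*")[1L], call. = FALSE)
  }
  if (drop_terminal_stop && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

#' Classify a base difference as transition or transversion
#'
#' @param base_a,base_b Single-character base vectors (A/C/G/T).
#' @return Logical vector, `TRUE` where the two bases differ by a
#'   transversion (purine vs pyrimidine).
#' @keywords internal
is_transversion <- function(base_a, base_b) {
  (base_a %in% PURINES) != (base_b %in% PURINES) & base_a != base_b
}
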