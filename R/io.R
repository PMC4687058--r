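#' Read sequences from a FASTA file
#'
#' Sequences are uppercased on read. DNA files are validated to contain only
#' A/C/G/T/N; duplicate identifiers are an error. The identifier is the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` (validated alphabet) or `"aa"`.
#' @return Tibble with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  if (type == "dna") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("non-ACGTN character in record '", ids[bad][1L], "'",
           call. = FALSE)
    }
  }
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with an id column and a sequence column.
#' @param path Output path.
#' @param seq_col,id_col Column names holding the sequence and identifier.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, seq_col = "seq", id_col = "id") {
  stopifnot(all(c(id_col, seq_col) %in% names(records)))
  set <- Biostrings::BStringSet(stats::setNames(records[[seq_col]],
                                                records[[id_col]]))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "align_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Read an all-vs-all similarity table (12-column tabular format)
#'
#' Reads the standard 12-column tab-separated hit table (the BLAST
#' "outfmt 6" dialect). Lines starting with `#` are skipped. A row with a
#' column count other than 12 is an error reporting the line number.
#'
#' @param path Path to the tabular file.
#' @return Tibble with columns `query_id`, `subject_id`, `pct_identity`,
#'   `align_len`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) {
    return(tibble::as_tibble(stats::setNames(
      c(rep(list(character()), 2L), rep(list(numeric()), 10L)), HIT_COLUMNS)))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 12L)) {
    bad <- which(keep)[which(n_fields != 12L)[1L]]
    stop("expected 12 tab-separated columns but found ",
         n_fields[n_fields != 12L][1L], " on line ", bad, " of ", path,
         call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  tibble::tibble(
    query_id = mat[, 1L], subject_id = mat[, 2L],
    pct_identity = as.numeric(mat[, 3L]), align_len = as.numeric(mat[, 4L]),
    mismatches = as.numeric(mat[, 5L]), gap_opens = as.numeric(mat[, 6L]),
    q_start = as.numeric(mat[, 7L]), q_end = as.numeric(mat[, 8L]),
    s_start = as.numeric(mat[, 9L]), s_end = as.numeric(mat[, 10L]),
    evalue = as.numeric(mat[, 11L]), bitscore = as.numeric(mat[, 12L])
  )
}

#' Write an all-vs-all similarity table
#'
#' @param hits Tibble as returned by [read_hits()] or [simulate_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  readr::write_tsv(hits[HIT_COLUMNS], path, col_names = FALSE)
  invisible(path)
}

#' Read genomic gene placements from BED or GFF3
#'
#' Coordinates are converted to the package-wide 0-based half-open
#' convention: BED coordinates are used as-is, GFF3 1-based closed
#' coordinates have 1 subtracted from the start. For GFF3, rows of type
#' `gene` are used (all rows if no `gene` rows are present) and the
#' identifier is the `ID` attribute, falling back to `Name`.
#'
#' @param path Path to the file.
#' @param dialect `"bed"` or `"gff3"`.
#' @return Tibble with columns `id`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_positions <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "bed" else "gff3")
  meta <- S4Vectors::mcols(gr)
  id <- if (dialect == "bed") {
    as.character(meta$name)
  } else {
    if ("type" %in% names(meta) && any(meta$type == "gene")) {
      gr <- gr[meta$type == "gene"]
      meta <- S4Vectors::mcols(gr)
    }
    id <- as.character(meta$ID)
    if (all(is.na(id)) && "Name" %in% names(meta)) id <- as.character(meta$Name)
    id
  }
  out <- tibble::tibble(
    id = id,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  out$strand[out$strand == "*"] <- NA_character_
  if (any(out$end <= out$start)) {
    bad <- out$id[out$end <= out$start][1L]
    stop("end <= start for record '", bad, "' in ", path, call. = FALSE)
  }
  if (anyNA(out$id)) stop("record without an identifier in ", path, call. = FALSE)
  out
}

#' Write gene placements as BED
#'
#' Writes 0-based half-open placements to a BED file with the gene id in the
#' name column.
#'
#' @param positions Tibble with `id`, `chromosome`, `start`, `end` and
#'   optionally `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(positions, path) {
  strand <- if ("strand" %in% names(positions)) {
    ifelse(is.na(positions$strand), "*", positions$strand)
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = positions$chromosome,
    ranges = IRanges::IRanges(start = positions$start + 1L,
                              end = positions$end),
    strand = strand,
    name = positions$id
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a counts matrix as TSV
#'
#' One row per gene with `gene_id`, `effective_length`, then one column per
#' sample named `tissue_genotype_replicate`.
#'
#' @param expression Long expression tibble (see [simulate_counts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(expression, path) {
  wide <- tidyr::pivot_wider(
    dplyr::select(expression, "gene_id", "effective_length", "sample_id",
                  "count"),
    names_from = "sample_id", values_from = "count"
  )
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a counts matrix written by [write_counts()]
#'
#' Sample metadata (`tissue`, `genotype`, `replicate`) is recovered from the
#' `tissue_genotype_replicate` column names.
#'
#' @param path Path to the TSV file.
#' @return Long expression tibble (`gene_id`, `sample_id`, `tissue`,
#'   `genotype`, `replicate`, `count`, `effective_length`).
#' @export
read_counts <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -c("gene_id", "effective_length"),
                              names_to = "sample_id", values_to = "count")
  parts <- stringr::str_match(long$sample_id, "^(.+)_(.+)_(\\d+)$")
  if (anyNA(parts[, 1L])) {
    stop("sample column '", long$sample_id[is.na(parts[, 1L])][1L],
         "' is not named tissue_genotype_replicate", call. = FALSE)
  }
  long$tissue <- parts[, 2L]
  long$genotype <- parts[, 3L]
  long$replicate <- as.integer(parts[, 4L])
  dplyr::select(long, "gene_id", "sample_id", "tissue", "genotype",
                "replicate", "count", "effective_length")
}

#' Read / write a two-column gene-to-GO mapping
#'
#' @param path Path to a two-column TSV (`gene_id`, `go_id`), one row per
#'   assignment, no header.
#' @return Tibble with columns `gene_id`, `go_id`.
#' @export
read_go_map <- function(path) {
  readr::read_tsv(path, col_names = c("gene_id", "go_id"),
                  col_types = "cc")
}

#' @rdname read_go_map
#' @param go_map Tibble with columns `gene_id`, `go_id`.
#' @export
write_go_map <- function(go_map, path) {
  readr::write_tsv(go_map[c("gene_id", "go_id")], path, col_names = FALSE)
  invisible(path)
}

#' Read / write simulation ground truth as JSON
#'
#' @param truth Ground-truth tibble from [simulate_genes()].
#' @param path Output path.
#' @return [read_ground_truth()] returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
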