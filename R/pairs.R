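#' Rank similarity hits per query
#'
#' Prepares an all-vs-all hit table for reciprocal pairing: self hits
#' (query equal to subject) are removed by id, multiple HSP rows for one
#' query-subject combination are collapsed to the row with the lowest
#' e-value (ties: highest bitscore), and the remaining hits are ranked per
#' query by ascending e-value, ties broken by descending bitscore and then
#' by subject id.
#'
#' @param hits Hit tibble with at least `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @return The ranked hits with a `rank` column (1 = best non-self hit).
#' @export
rank_hits <- function(hits) {
  hits |>
    dplyr::filter(.data$query_id != .data$subject_id) |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Detect duplicate pairs by the reciprocal second-best-hit rule
#'
#' Two genes A and B are predicted to be duplicates when B is A's top
#' non-self hit, A is B's top non-self hit, and both e-values are below
#' `evalue_max`. The best hit of an all-vs-all search is the query itself,
#' so the top *non-self* hit is the search's "second best hit"; self-hit
#' removal is by id equality (see [rank_hits()]) so the rule is unaffected
#' by tools that suppress self hits. Reciprocity implies a matching: every
#' gene occurs in at most one pair.
#'
#' @param ranked Ranked hits from [rank_hits()] (a raw hit table is ranked
#'   automatically).
#' @param evalue_max Pairing threshold; both directions must satisfy
#'   `evalue < evalue_max` (strict).
#' @return Tibble of candidate pairs: `pair_id`, `id_a`, `id_b`
#'   (lexicographically ordered), `evalue_ab`, `evalue_ba`, `bitscore_ab`,
#'   `bitscore_ba`.
#' @export
reciprocal_second_best <- function(ranked, evalue_max = 1e-10) {
  if (!"rank" %in% names(ranked)) ranked <- rank_hits(ranked)
  top <- dplyr::filter(ranked, .data$rank == 1L)
  fwd <- dplyr::select(top, "query_id", "subject_id",
                       evalue_ab = "evalue", bitscore_ab = "bitscore")
  rev <- dplyr::select(top, query_id = "subject_id",
                       subject_id = "query_id",
                       evalue_ba = "evalue", bitscore_ba = "bitscore")
  pairs <- dplyr::inner_join(fwd, rev,
                             by = c("query_id", "subject_id")) |>
    dplyr::filter(.data$evalue_ab < evalue_max,
                  .data$evalue_ba < evalue_max,
                  .data$query_id < .data$subject_id)
  tibble::tibble(
    pair_id = paste(pairs$query_id, pairs$subject_id, sep = "|"),
    id_a = pairs$query_id,
    id_b = pairs$subject_id,
    evalue_ab = pairs$evalue_ab,
    evalue_ba = pairs$evalue_ba,
    bitscore_ab = pairs$bitscore_ab,
    bitscore_ba = pairs$bitscore_ba
  ) |>
    dplyr::arrange(.data$id_a, .data$id_b)
}
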