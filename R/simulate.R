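#' Configuration for the synthetic WGD transcriptome generator
#'
#' Bundles and validates every tunable of the synthetic-data generator. The
#' generator emulates the inputs of a WGD paralog-retention study: coding
#' sequences containing planted whole-genome-duplication (WGD) pairs of known
#' fourfold-degenerate transversion divergence, planted tandem duplicates at a
#' controlled genomic distance, singleton genes, an all-vs-all protein
#' similarity table, negative-binomial read counts over tissue x genotype
#' conditions with planted copy-vs-copy fold changes, and a gene-to-GO map.
#'
#' @param seed Integer seed; a fixed seed makes every `simulate_*` output
#'   byte-identical across runs.
#' @param n_wgd_pairs,n_tandem_pairs,n_singletons Numbers of planted WGD
#'   pairs, tandem pairs, and unpaired genes.
#' @param n_codons_range Length-2 integer vector; per-gene codon counts
#'   (excluding the start and stop codon) are drawn uniformly in this range.
#' @param branch_transversion_rate Target raw 4DTV of a planted pair: the
#'   expected proportion of fourfold-degenerate third-codon sites that differ
#'   by a transversion between the two copies, before multiple-hit
#'   correction. Must lie in (0, 0.5) or the correction is undefined.
#' @param ts_tv_ratio Transition/transversion rate ratio kappa of the
#'   substitution process.
#' @param nonsyn_rate_scale Acceptance probability of a nonsynonymous
#'   proposal relative to a synonymous one; values below 1 emulate purifying
#'   selection and set the true Ka/Ks of planted pairs.
#' @param n_chromosomes Number of chromosomes genes are placed on.
#' @param tandem_distance_bp Genomic gap (bp) separating the two members of a
#'   planted tandem pair; must be below 100,000 so planted tandems fall under
#'   the tandem filter.
#' @param conditions Data frame with columns `tissue` and `genotype` plus
#'   `n_replicates`, one row per expression condition.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param mean_expression Baseline expected count per replicate for a gene of
#'   1 kb effective length.
#' @param fc_log2_mean,fc_log2_sd Planted copy-vs-copy |log2 fold changes| are
#'   drawn from N(fc_log2_mean, fc_log2_sd) with a random sign.
#' @param fraction_de_pairs Fraction of planted pairs given a nonzero
#'   expression effect.
#' @param go_n_terms,go_terms_per_gene GO vocabulary size and number of terms
#'   assigned per gene (both copies of a pair share one term set).
#'
#' @return A validated list of class `wgd_sim_config`.
#' @seealso [simulate_genes()], [simulate_counts()], [simulate_hits()],
#'   [simulate_study()]
#' @export
simulation_config <- function(seed = 1L,
                              n_wgd_pairs = 100L,
                              n_tandem_pairs = 20L,
                              n_singletons = 200L,
                              n_codons_range = c(200L, 500L),
                              branch_transversion_rate = 0.10,
                              ts_tv_ratio = 2,
                              nonsyn_rate_scale = 0.23,
                              n_chromosomes = 19L,
                              tandem_distance_bp = 50000L,
                              conditions = default_conditions(),
                              nb_dispersion = 0.05,
                              mean_expression = 500,
                              fc_log2_mean = 1.2,
                              fc_log2_sd = 0.6,
                              fraction_de_pairs = 0.74,
                              go_n_terms = 50L,
                              go_terms_per_gene = 3L) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_wgd_pairs >= 0, n_tandem_pairs >= 0, n_singletons >= 0,
    length(n_codons_range) == 2L, n_codons_range[1] >= 2,
    n_codons_range[1] <= n_codons_range[2],
    ts_tv_ratio > 0, nonsyn_rate_scale >= 0, nonsyn_rate_scale <= 1,
    n_chromosomes >= 2, nb_dispersion >= 0, mean_expression > 0,
    fc_log2_sd >= 0, fraction_de_pairs >= 0, fraction_de_pairs <= 1,
    go_n_terms >= 1, go_terms_per_gene >= 0,
    is.data.frame(conditions),
    all(c("tissue", "genotype", "n_replicates") %in% names(conditions)),
    all(conditions$n_replicates >= 1)
  )
  if (branch_transversion_rate <= 0 || branch_transversion_rate >= 0.5) {
    stop("branch_transversion_rate must lie in (0, 0.5): the multiple-hit ",
         "correction -log(1 - 2q)/2 is undefined at q >= 0.5", call. = FALSE)
  }
  if (tandem_distance_bp >= 100000) {
    stop("tandem_distance_bp must be below 100,000 bp so planted tandems ",
         "fall inside the tandem window", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_wgd_pairs = as.integer(n_wgd_pairs),
      n_tandem_pairs = as.integer(n_tandem_pairs),
      n_singletons = as.integer(n_singletons),
      n_codons_range = as.integer(n_codons_range),
      branch_transversion_rate = branch_transversion_rate,
      ts_tv_ratio = ts_tv_ratio,
      nonsyn_rate_scale = nonsyn_rate_scale,
      n_chromosomes = as.integer(n_chromosomes),
      tandem_distance_bp = as.integer(tandem_distance_bp),
      conditions = tibble::as_tibble(conditions),
      nb_dispersion = nb_dispersion,
      mean_expression = mean_expression,
      fc_log2_mean = fc_log2_mean,
      fc_log2_sd = fc_log2_sd,
      fraction_de_pairs = fraction_de_pairs,
      go_n_terms = as.integer(go_n_terms),
      go_terms_per_gene = as.integer(go_terms_per_gene)
    ),
    class = "wgd_sim_config"
  )
}

#' Default expression conditions
#'
#' Two tissues by two genotypes with the replicate structure of a typical
#' two-genotype leaf/root RNA-seq design (5, 5, 4 and 4 sequenced replicates).
#'
#' @return Tibble with columns `tissue`, `genotype`, `n_replicates`.
#' @export
default_conditions <- function() {
  tibble::tibble(
    tissue = c("leaf", "leaf", "root", "root"),
    genotype = c("g520", "g592", "g520", "g592"),
    n_replicates = c(5L, 5L, 4L, 4L)
  )
}

# One stochastic substitution pass over a single codon position of one
# sequence copy. Proposals are kappa-weighted (transition with probability
# kappa/(kappa+2), otherwise one of the two transversions); proposals that
# create a stop codon are always rejected and nonsynonymous proposals are
# accepted with probability `nonsyn_scale`.
mutate_position <- function(codons, pos, rate, kappa, nonsyn_scale,
                            skip = integer(0)) {
  n <- length(codons)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, skip)
  if (length(hit) == 0L) return(codons)
  cur <- substr(codons[hit], pos, pos)
  p_ts <- kappa / (kappa + 2)
  ts <- stats::runif(length(hit)) < p_ts
  new <- character(length(hit))
  new[ts] <- TRANSITION_OF[cur[ts]]
  if (any(!ts)) {
    pick <- 1L + (stats::runif(sum(!ts)) < 0.5)
    tv_mat <- rbind(
      vapply(TRANSVERSIONS_OF[cur[!ts]], `[`, "", 1L),
      vapply(TRANSVERSIONS_OF[cur[!ts]], `[`, "", 2L)
    )
    new[!ts] <- tv_mat[cbind(pick, seq_len(sum(!ts)))]
  }
  cand <- codons[hit]
  substr(cand, pos, pos) <- new
  aa_old <- CODON_TABLE[codons[hit]]
  aa_new <- CODON_TABLE[cand]
  accept <- aa_new != "*" &
    (aa_new == aa_old | stats::runif(length(hit)) < nonsyn_scale)
  codons[hit[accept]] <- cand[accept]
  codons
}

# Evolve one duplicate pair from a shared ancestor. Codon prefixes (positions
# 1 and 2) and non-fourfold third positions accumulate substitutions under
# the stochastic kappa-weighted process; third positions of columns that
# retain an identical fourfold-degenerate prefix in both copies receive a
# fixed planted count of transversions (and kappa/2 as many transitions), so
# the pair's raw 4DTV equals `rate` up to rounding. All planted third-position
# changes in fourfold families are synonymous and cannot create stops.
evolve_pair <- function(ancestor, rate, kappa, nonsyn_scale) {
  L <- length(ancestor)
  mutable <- if (L > 2L) 2:(L - 1L) else integer(0)
  mu_branch <- rate * (kappa + 2) / 2 / 2  # per-site, per-branch event rate
  copies <- list(a = ancestor, b = ancestor)
  for (nm in names(copies)) {
    body <- copies[[nm]][mutable]
    body <- mutate_position(body, 1L, mu_branch, kappa, nonsyn_scale)
    body <- mutate_position(body, 2L, mu_branch, kappa, nonsyn_scale)
    copies[[nm]][mutable] <- body
  }
  prefix_a <- substr(copies$a[mutable], 1L, 2L)
  prefix_b <- substr(copies$b[mutable], 1L, 2L)
  fourfold <- prefix_a == prefix_b & prefix_a %in% FOURFOLD_PREFIXES
  m_idx <- mutable[fourfold]      # columns measured as 4D sites downstream
  other <- setdiff(mutable, m_idx)
  for (nm in names(copies)) {
    if (length(other) > 0L) {
      body <- copies[[nm]][other]
      body <- mutate_position(body, 3L, mu_branch, kappa, nonsyn_scale)
      copies[[nm]][other] <- body
    }
  }
  n4 <- length(m_idx)
  if (n4 > 0L) {
    n_tv <- round(rate * n4)
    n_ts <- round(rate * kappa / 2 * n4)
    n_ts <- min(n_ts, n4 - n_tv)
    planted <- m_idx[sample.int(n4, n_tv + n_ts)]
    tv_sites <- planted[seq_len(n_tv)]
    ts_sites <- planted[seq_len(n_ts) + n_tv]
    for (site in tv_sites) {
      copy <- sample(c("a", "b"), 1L)
      codon <- copies[[copy]][site]
      base <- substr(codon, 3L, 3L)
      substr(codon, 3L, 3L) <- sample(TRANSVERSIONS_OF[[base]], 1L)
      copies[[copy]][site] <- codon
    }
    for (site in ts_sites) {
      copy <- sample(c("a", "b"), 1L)
      codon <- copies[[copy]][site]
      base <- substr(codon, 3L, 3L)
      substr(codon, 3L, 3L) <- TRANSITION_OF[[base]]
      copies[[copy]][site] <- codon
    }
  }
  copies
}

random_ancestor <- function(n_codons) {
  c("ATG", sample(SENSE_CODONS, n_codons, replace = TRUE),
    sample(STOP_CODONS, 1L))
}

#' Simulate coding sequences with planted duplicate pairs
#'
#' Generates ancestral coding sequences (ATG start, no internal stops,
#' terminal stop) and evolves each planted pair into two copies under a
#' kappa-weighted substitution process with rejection of stop-creating
#' proposals and purifying rejection of nonsynonymous proposals. Fourfold-
#' degenerate third positions receive a planted substitution count so that
#' each pair's raw 4DTV equals `branch_transversion_rate` up to rounding.
#' WGD pair members are placed on distinct chromosomes, tandem pair members
#' on one chromosome separated by `tandem_distance_bp`, singletons anywhere.
#'
#' @param config A [simulation_config()].
#' @return List with `sequences` (tibble: `id`, `cds`, `peptide`,
#'   `chromosome`, `start`, `end`, `strand`) and `truth` (tibble: one row per
#'   planted pair with `pair_id`, `class`, `gene_a`, `gene_b`,
#'   `target_4dtv_raw`, genomic placements, and planted expression effects
#'   `fc_log2`/`is_de` filled in for downstream count simulation).
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "wgd_sim_config"))
  withr::with_seed(config$seed, simulate_genes_impl(config))
}

simulate_genes_impl <- function(config) {
  n_pairs <- config$n_wgd_pairs + config$n_tandem_pairs
  classes <- rep(c("wgd", "tandem"),
                 c(config$n_wgd_pairs, config$n_tandem_pairs))
  ids <- list()
  rows <- list()
  truth <- list()
  cursor <- rep(10000L, config$n_chromosomes)  # next free bp per chromosome
  spacing <- 200000L
  place_gene <- function(chrom, len, at = NULL) {
    start <- unname(if (is.null(at)) cursor[chrom] else at)
    end <- start + len
    cursor[chrom] <<- max(cursor[chrom], end + spacing)
    c(start = start, end = end)
  }
  k <- 0L
  for (i in seq_len(n_pairs)) {
    k <- k + 1L
    n_codons <- sample(config$n_codons_range[1]:config$n_codons_range[2], 1L)
    anc <- random_ancestor(n_codons)
    pair <- evolve_pair(anc, config$branch_transversion_rate,
                        config$ts_tv_ratio, config$nonsyn_rate_scale)
    cds_a <- paste(pair$a, collapse = "")
    cds_b <- paste(pair$b, collapse = "")
    id_a <- sprintf("gene%04d_a", k)
    id_b <- sprintf("gene%04d_b", k)
    len <- nchar(cds_a)
    if (classes[i] == "wgd") {
      chroms <- sample(config$n_chromosomes, 2L)
      pos_a <- place_gene(chroms[1], len)
      pos_b <- place_gene(chroms[2], len)
    } else {
      chroms <- rep(sample(config$n_chromosomes, 1L), 2L)
      pos_a <- place_gene(chroms[1], len)
      pos_b <- place_gene(chroms[1], len,
                          at = pos_a["end"] + config$tandem_distance_bp)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = c(id_a, id_b),
      cds = c(cds_a, cds_b),
      peptide = c(translate_cds(cds_a), translate_cds(cds_b)),
      chromosome = paste0("chr", chroms),
      start = unname(c(pos_a["start"], pos_b["start"])),
      end = unname(c(pos_a["end"], pos_b["end"])),
      strand = "+"
    )
    truth[[length(truth) + 1L]] <- tibble::tibble(
      pair_id = sprintf("gene%04d_a|gene%04d_b", k, k),
      class = classes[i],
      gene_a = id_a,
      gene_b = id_b,
      target_4dtv_raw = config$branch_transversion_rate,
      chrom_a = paste0("chr", chroms[1]),
      chrom_b = paste0("chr", chroms[2])
    )
  }
  for (i in seq_len(config$n_singletons)) {
    k <- k + 1L
    n_codons <- sample(config$n_codons_range[1]:config$n_codons_range[2], 1L)
    cds <- paste(random_ancestor(n_codons), collapse = "")
    chrom <- sample(config$n_chromosomes, 1L)
    pos <- place_gene(chrom, nchar(cds))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("gene%04d_s", k),
      cds = cds,
      peptide = translate_cds(cds),
      chromosome = paste0("chr", chrom),
      start = unname(pos["start"]),
      end = unname(pos["end"]),
      strand = "+"
    )
  }
  sequences <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(id = character(), cds = character(), peptide = character(),
                   chromosome = character(), start = integer(),
                   end = integer(), strand = character())
  truth_tbl <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(pair_id = character(), class = character(),
                   gene_a = character(), gene_b = character(),
                   target_4dtv_raw = numeric(), chrom_a = character(),
                   chrom_b = character())
  # planted expression effects, fixed here so counts are reproducible from
  # the same truth object
  n_tr <- nrow(truth_tbl)
  if (n_tr > 0L) {
    is_de <- stats::runif(n_tr) < config$fraction_de_pairs
    fc <- ifelse(
      is_de,
      sign(stats::runif(n_tr) - 0.5) *
        stats::rnorm(n_tr, config$fc_log2_mean, config$fc_log2_sd),
      0
    )
    truth_tbl$is_de <- is_de
    truth_tbl$fc_log2 <- fc
  } else {
    truth_tbl$is_de <- logical(0)
    truth_tbl$fc_log2 <- numeric(0)
  }
  list(sequences = sequences, truth = truth_tbl)
}

#' Simulate negative-binomial read counts
#'
#' Draws per-gene, per-replicate counts from a negative-binomial model with
#' mean `mean_expression * (effective_length / 1000) * baseline * 2^(+-fc/2)`,
#' where `baseline` is a per-gene (per-pair: shared by both copies) lognormal
#' expression level and the planted log2 fold change `fc` from `truth` is
#' split evenly between the two copies of a pair. Effective length equals the
#' CDS length. Pairs with `fc_log2 = 0` have identical expected counts for
#' both copies.
#'
#' @param sequences,truth Output of [simulate_genes()].
#' @param config The same [simulation_config()].
#' @return Long tibble with one row per gene x sample: `gene_id`,
#'   `sample_id`, `tissue`, `genotype`, `replicate`, `count`,
#'   `effective_length`.
#' @export
simulate_counts <- function(sequences, truth, config) {
  stopifnot(inherits(config, "wgd_sim_config"))
  bad <- setdiff(c(truth$gene_a, truth$gene_b), sequences$id)
  if (length(bad) > 0L) {
    stop("truth refers to unknown gene id(s): ",
         paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, simulate_counts_impl(sequences, truth, config))
}

simulate_counts_impl <- function(sequences, truth, config) {
  genes <- tibble::tibble(
    gene_id = sequences$id,
    effective_length = nchar(sequences$cds)
  )
  # per-pair baseline shared by both copies; singletons get their own
  pair_of <- stats::setNames(rep(truth$pair_id, 2L),
                             c(truth$gene_a, truth$gene_b))
  genes$unit <- ifelse(genes$gene_id %in% names(pair_of),
                       pair_of[genes$gene_id], genes$gene_id)
  units <- unique(genes$unit)
  baseline <- stats::setNames(2^stats::rnorm(length(units), 0, 1), units)
  half_fc <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  if (nrow(truth) > 0L) {
    half_fc[truth$gene_a] <- -truth$fc_log2 / 2
    half_fc[truth$gene_b] <- +truth$fc_log2 / 2
  }
  genes$mu <- config$mean_expression * (genes$effective_length / 1000) *
    baseline[genes$unit] * 2^half_fc[genes$gene_id]

  samples <- tidyr::uncount(config$conditions,
                            weights = .data$n_replicates, .id = "replicate")
  samples$sample_id <- paste(samples$tissue, samples$genotype,
                             samples$replicate, sep = "_")
  grid <- tidyr::expand_grid(genes, samples)
  mu <- grid$mu
  if (config$nb_dispersion <= 0) {
    grid$count <- stats::rpois(nrow(grid), mu)
  } else {
    grid$count <- stats::rnbinom(nrow(grid), mu = mu,
                                 size = 1 / config$nb_dispersion)
  }
  dplyr::select(grid, "gene_id", "sample_id", "tissue", "genotype",
                "replicate", "count", "effective_length")
}

#' Simulate an all-vs-all protein similarity table
#'
#' Emulates the tabular output of an all-vs-all protein search: every gene
#' gets a self hit with the top bitscore; the two members of each planted
#' pair get mutual hits with e-values far below the pairing threshold and
#' bitscores below self; optional decoy hits connect random non-paired genes
#' at an e-value above the threshold, to exercise the e-value filter.
#'
#' @param sequences,truth Output of [simulate_genes()].
#' @param n_decoys Number of decoy hit pairs to add.
#' @param decoy_evalue E-value given to decoy hits (default fails the
#'   1e-10 pairing threshold).
#' @param seed Integer seed for decoy placement.
#' @return Tibble in 12-column tabular hit format (`query_id`, `subject_id`,
#'   `pct_identity`, `align_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`).
#' @export
simulate_hits <- function(sequences, truth, n_decoys = 0L,
                          decoy_evalue = 1e-5, seed = 1L) {
  plen <- nchar(sequences$peptide)
  names(plen) <- sequences$id
  self <- tibble::tibble(
    query_id = sequences$id, subject_id = sequences$id,
    pct_identity = 100, align_len = unname(plen),
    mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = unname(plen), s_start = 1L, s_end = unname(plen),
    evalue = 0, bitscore = round(2 * unname(plen), 1)
  )
  cross <- NULL
  if (nrow(truth) > 0L) {
    qa <- truth$gene_a
    qb <- truth$gene_b
    cross <- tibble::tibble(
      query_id = c(qa, qb), subject_id = c(qb, qa),
      pct_identity = 95,
      align_len = unname(plen[c(qa, qb)]),
      mismatches = round(0.05 * unname(plen[c(qa, qb)])),
      gap_opens = 0L,
      q_start = 1L, q_end = unname(plen[c(qa, qb)]),
      s_start = 1L, s_end = unname(plen[c(qb, qa)]),
      evalue = 1e-150,
      bitscore = round(1.8 * unname(plen[c(qa, qb)]), 1)
    )
  }
  decoys <- NULL
  if (n_decoys > 0L) {
    decoys <- withr::with_seed(seed + 2L, {
      q <- sample(sequences$id, n_decoys, replace = TRUE)
      s <- sample(sequences$id, n_decoys, replace = TRUE)
      keep <- q != s
      tibble::tibble(
        query_id = q[keep], subject_id = s[keep],
        pct_identity = 30, align_len = 100L, mismatches = 70L,
        gap_opens = 2L, q_start = 1L, q_end = 100L,
        s_start = 1L, s_end = 100L,
        evalue = decoy_evalue, bitscore = 35
      )
    })
  }
  dplyr::bind_rows(self, cross, decoys)
}

#' Simulate a gene-to-GO mapping
#'
#' Assigns each pair a random set of GO terms shared by both copies (the
#' annotation-symmetry property of low-divergence duplicates) and each
#' singleton its own set, independently of expression effects.
#'
#' @param sequences,truth Output of [simulate_genes()].
#' @param config The same [simulation_config()].
#' @return Tibble with columns `gene_id`, `go_id` (one row per assignment).
#' @export
simulate_go_map <- function(sequences, truth, config) {
  stopifnot(inherits(config, "wgd_sim_config"))
  if (config$go_terms_per_gene == 0L) {
    return(tibble::tibble(gene_id = character(), go_id = character()))
  }
  withr::with_seed(config$seed + 3L, {
    vocab <- sprintf("GO:%07d", seq_len(config$go_n_terms))
    k <- min(config$go_terms_per_gene, config$go_n_terms)
    paired <- c(truth$gene_a, truth$gene_b)
    out <- list()
    for (i in seq_len(nrow(truth))) {
      terms <- sample(vocab, k)
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = rep(c(truth$gene_a[i], truth$gene_b[i]), each = k),
        go_id = rep(terms, 2L)
      )
    }
    for (g in setdiff(sequences$id, paired)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = g, go_id = sample(vocab, k)
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running every generator stage with one configuration.
#'
#' @param config A [simulation_config()].
#' @param n_decoys Decoy hits passed to [simulate_hits()].
#' @return List with `sequences`, `truth`, `positions`, `hits`, `expression`,
#'   `go_map`, and the `config`.
#' @export
simulate_study <- function(config, n_decoys = 0L) {
  sim <- simulate_genes(config)
  positions <- dplyr::select(sim$sequences, id = "id",
                             chromosome = "chromosome",
                             start = "start", end = "end", strand = "strand")
  list(
    sequences = sim$sequences,
    truth = sim$truth,
    positions = positions,
    hits = simulate_hits(sim$sequences, sim$truth, n_decoys = n_decoys,
                         seed = config$seed),
    expression = simulate_counts(sim$sequences, sim$truth, config),
    go_map = simulate_go_map(sim$sequences, sim$truth, config),
    config = config
  )
}
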