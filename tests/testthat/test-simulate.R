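test_that("gene simulation conserves counts and is deterministic", {
  cfg0 <- simulation_config(seed = 5, n_wgd_pairs = 0, n_tandem_pairs = 0,
                            n_singletons = 5, n_codons_range = c(60, 80))
  sim0 <- simulate_genes(cfg0)
  expect_equal(nrow(sim0$sequences), 5L)
  expect_equal(nrow(sim0$truth), 0L)

  cfg <- tiny_config()
  sim1 <- simulate_genes(cfg)
  sim2 <- simulate_genes(cfg)
  expect_identical(sim1$sequences, sim2$sequences)
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(nrow(sim1$sequences), 2 * 7 + 5)
  expect_equal(nrow(sim1$truth), 7L)

  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim1$sequences, f1, seq_col = "cds")
  write_fasta(sim2$sequences, f2, seq_col = "cds")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated coding sequences are clean ORFs", {
  sim <- simulate_genes(tiny_config())
  for (i in seq_len(nrow(sim$sequences))) {
    cds <- sim$sequences$cds[i]
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- strsplit(translate_cds(cds, drop_terminal_stop = FALSE), "")[[1]]
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
    expect_equal(sim$sequences$peptide[i], translate_cds(cds))
  }
})

test_that("pair members are placed according to their class", {
  sim <- simulate_genes(tiny_config())
  pos <- sim$sequences
  for (i in seq_len(nrow(sim$truth))) {
    a <- pos[pos$id == sim$truth$gene_a[i], ]
    b <- pos[pos$id == sim$truth$gene_b[i], ]
    if (sim$truth$class[i] == "wgd") {
      expect_false(a$chromosome == b$chromosome)
    } else {
      expect_equal(a$chromosome, b$chromosome)
      expect_equal(b$start - a$end, 50000)
    }
  }
})

test_that("planted raw 4DTV matches the configured rate", {
  cfg <- simulation_config(seed = 21, n_wgd_pairs = 40, n_tandem_pairs = 0,
                           n_singletons = 0, n_codons_range = c(280, 320),
                           branch_transversion_rate = 0.10)
  sim <- simulate_genes(cfg)
  pairs <- tibble::tibble(pair_id = sim$truth$pair_id,
                          id_a = sim$truth$gene_a, id_b = sim$truth$gene_b)
  div <- pair_divergence(pairs, sim$sequences)
  # each pair's raw 4DTV is its target up to count rounding
  expect_true(all(abs(div$four_dtv_raw - 0.10) <=
                    0.5 / div$n_4d_sites + 1e-9))
  se <- sqrt(0.1 * 0.9 / sum(div$n_4d_sites))
  expect_lt(abs(mean(div$four_dtv_raw) - 0.10), 3 * se)
})

test_that("simulated counts follow the planted expression model", {
  cfg <- simulation_config(
    seed = 9, n_wgd_pairs = 100, n_tandem_pairs = 0, n_singletons = 0,
    n_codons_range = c(100, 120), mean_expression = 500,
    fraction_de_pairs = 1, fc_log2_mean = 4, fc_log2_sd = 0,
    nb_dispersion = 0.05,
    conditions = tibble::tibble(tissue = "leaf", genotype = "g1",
                                n_replicates = 5L)
  )
  sim <- simulate_genes(cfg)
  expect_true(all(abs(sim$truth$fc_log2) == 4))
  expr <- simulate_counts(sim$sequences, sim$truth, cfg)
  means <- tapply(expr$count, expr$gene_id, mean)
  ratio <- log2(means[sim$truth$gene_b] / means[sim$truth$gene_a])
  expect_lt(abs(mean(sign(sim$truth$fc_log2) * ratio) - 4), 0.2)

  cfg_null <- simulation_config(seed = 9, n_wgd_pairs = 50,
                                n_tandem_pairs = 0, n_singletons = 0,
                                n_codons_range = c(100, 120),
                                fraction_de_pairs = 0)
  sim_null <- simulate_genes(cfg_null)
  expect_true(all(sim_null$truth$fc_log2 == 0))
})

test_that("counts simulation rejects unknown gene ids", {
  cfg <- tiny_config()
  sim <- simulate_genes(cfg)
  truth_bad <- sim$truth
  truth_bad$gene_a[1] <- "nonexistent"
  expect_error(simulate_counts(sim$sequences, truth_bad, cfg),
               "unknown gene id")
})

test_that("simulated hits contain self and mutual pair rows", {
  cfg <- simulation_config(seed = 2, n_wgd_pairs = 1, n_tandem_pairs = 0,
                           n_singletons = 1, n_codons_range = c(60, 70))
  sim <- simulate_genes(cfg)
  hits <- simulate_hits(sim$sequences, sim$truth)
  a <- sim$truth$gene_a[1]
  b <- sim$truth$gene_b[1]
  s <- setdiff(sim$sequences$id, c(a, b))
  expect_equal(nrow(hits), 5L)  # 3 self + 2 mutual
  expect_setequal(
    paste(hits$query_id, hits$subject_id),
    c(paste(a, a), paste(b, b), paste(s, s), paste(a, b), paste(b, a))
  )
  cross <- hits[hits$query_id != hits$subject_id, ]
  self <- hits[hits$query_id == hits$subject_id, ]
  expect_true(all(cross$evalue < 1e-10))
  expect_true(all(cross$bitscore <
                    self$bitscore[match(cross$query_id, self$query_id)]))
})

test_that("decoy hits above the e-value threshold do not create pairs", {
  cfg <- tiny_config()
  st <- simulate_study(cfg, n_decoys = 50)
  pairs <- reciprocal_second_best(rank_hits(st$hits))
  expect_setequal(pairs$pair_id, st$truth$pair_id)
})

test_that("both copies of a pair share one GO term set", {
  cfg <- tiny_config()
  sim <- simulate_genes(cfg)
  go <- simulate_go_map(sim$sequences, sim$truth, cfg)
  for (i in seq_len(nrow(sim$truth))) {
    terms_a <- sort(go$go_id[go$gene_id == sim$truth$gene_a[i]])
    terms_b <- sort(go$go_id[go$gene_id == sim$truth$gene_b[i]])
    expect_equal(terms_a, terms_b)
    expect_length(terms_a, 3L)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(branch_transversion_rate = 0.5),
               "branch_transversion_rate")
  expect_error(simulation_config(tandem_distance_bp = 100000),
               "tandem_distance_bp")
  expect_error(simulation_config(n_wgd_pairs = -1))
})
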