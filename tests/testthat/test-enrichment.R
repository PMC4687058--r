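test_that("Spearman correlation handles perfect and tied rankings", {
  de <- tibble::tibble(
    pair_id = paste0("p", 1:3), tissue = "leaf", genotype = "g1",
    log2_fc = c(1, 2, 3), fdr = c(0.5, 0.5, 0.5)
  )
  div <- tibble::tibble(pair_id = paste0("p", 1:3),
                        omega = c(3, 2, 1), ka = c(1, 2, 3),
                        ks = c(1, 1, 1), four_dtv_corr = c(0.1, 0.1, 0.2))
  got <- spearman_assoc(de, div)
  expect_equal(got$rho[got$measure == "omega"], -1)
  expect_equal(got$rho[got$measure == "ka"], 1)
  # constant divergence vector: undefined
  expect_true(is.na(got$rho[got$measure == "ks"]))

  # ties: average-rank formula computed by hand
  de2 <- tibble::tibble(
    pair_id = paste0("p", 1:4), tissue = "leaf", genotype = "g1",
    log2_fc = c(1, 1, 2, 3), fdr = 0.5
  )
  div2 <- tibble::tibble(pair_id = paste0("p", 1:4),
                         omega = c(2, 1, 4, 8), ka = 1, ks = 1,
                         four_dtv_corr = 0.1)
  got2 <- spearman_assoc(de2, div2, measures = "omega")
  rx <- rank(c(1, 1, 2, 3))
  ry <- rank(c(2, 1, 4, 8))
  expect_equal(got2$rho, stats::cor(rx, ry))
})

test_that("Spearman correlation is invariant to monotone transforms", {
  set.seed(8)
  de <- tibble::tibble(
    pair_id = paste0("p", 1:50), tissue = "leaf", genotype = "g1",
    log2_fc = rnorm(50), fdr = runif(50)
  )
  div <- tibble::tibble(pair_id = paste0("p", 1:50),
                        omega = runif(50), ka = 1, ks = 1,
                        four_dtv_corr = 0.1)
  base <- spearman_assoc(de, div, measures = "omega")
  div$omega <- exp(5 * div$omega)  # strictly monotone transform
  trans <- spearman_assoc(de, div, measures = "omega")
  expect_equal(base$rho, trans$rho, tolerance = 1e-12)
  expect_equal(base$p_value, trans$p_value, tolerance = 1e-12)
})

test_that("annotation transfer keeps only the qualifying best hit", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q2", "q3", "q3"),
    subject_id = c("r1", "r2", "r3", "r4", "r5"),
    evalue = c(1e-20, 1e-30, 1e-20, 1e-40, 1e-40),
    bitscore = c(80, 90, 35, 50, 90)
  )
  go_map <- tibble::tibble(
    gene_id = c("r1", "r2", "r3", "r4", "r5"),
    go_id = c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5")
  )
  ann <- transfer_annotations(hits, go_map)
  # q1: r2 wins on e-value; q2: bitscore 35 fails the > 40 rule
  expect_equal(ann$go_id[ann$gene_id == "q1"], "GO:2")
  expect_false("q2" %in% ann$gene_id)
  # q3: equal e-values, higher bitscore wins
  expect_equal(ann$go_id[ann$gene_id == "q3"], "GO:5")

  # boundary: e-value exactly 1e-10 fails the strict rule
  edge <- tibble::tibble(query_id = "q", subject_id = "r1",
                         evalue = 1e-10, bitscore = 100)
  expect_equal(nrow(transfer_annotations(edge, go_map)), 0L)
})

test_that("Fisher enrichment equals the hypergeometric oracle", {
  genes <- paste0("g", 1:100)
  test_set <- genes[1:10]
  ann <- tibble::tibble(
    gene_id = c(genes[1:5], genes[11:15]),
    go_id = "GO:X"
  )
  got <- fisher_enrichment(test_set, genes, ann)
  expect_equal(got$test_with, 5L)
  expect_equal(got$ref_with, 5L)
  expect_equal(got$p_value, oracle_fisher_tail(5, 5, 5, 85),
               tolerance = 1e-12)

  # term in every gene: p = 1
  all_ann <- tibble::tibble(gene_id = genes, go_id = "GO:ALL")
  expect_equal(fisher_enrichment(test_set, genes, all_ann)$p_value, 1)

  # term exclusive to the test set: tiny p, matches the oracle
  excl <- tibble::tibble(gene_id = genes[1:10], go_id = "GO:T")
  got2 <- fisher_enrichment(test_set, genes, excl)
  expect_lt(got2$p_value, 1e-6)
  expect_equal(got2$p_value, oracle_fisher_tail(10, 0, 0, 90),
               tolerance = 1e-12)

  expect_error(fisher_enrichment(c("zz"), genes, ann), "subset")
  expect_equal(nrow(fisher_enrichment(character(0), genes, ann)), 0L)
})

test_that("Fisher enrichment matches the oracle across a table grid", {
  for (N in c(10, 25, 60)) {
    for (K in unique(c(1, 3, N %/% 2, N - 1))) {
      for (n in unique(c(1, N %/% 3, N %/% 2))) {
        for (a in 0:min(K, n)) {
          if (n - a > N - K) next
          genes <- paste0("g", seq_len(N))
          test_set <- genes[seq_len(n)]
          with_term <- c(genes[seq_len(a)],
                         genes[n + seq_len(K - a)])
          ann <- tibble::tibble(gene_id = with_term, go_id = "GO:G")
          got <- fisher_enrichment(test_set, genes, ann)
          expect_equal(
            got$p_value,
            oracle_fisher_tail(a, n - a, K - a, N - K - (n - a)),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("no term is enriched under independent annotation", {
  cfg <- simulation_config(seed = 17, n_wgd_pairs = 150, n_tandem_pairs = 0,
                           n_singletons = 100, n_codons_range = c(60, 80),
                           go_n_terms = 40)
  sim <- simulate_genes(cfg)
  go <- simulate_go_map(sim$sequences, sim$truth, cfg)
  # a random "DE" subset, independent of the annotations
  set.seed(18)
  test_set <- sample(sim$sequences$id, 120)
  got <- fisher_enrichment(test_set, sim$sequences$id, go)
  expect_lte(mean(got$p_adjusted <= 0.05), 0.05 + 0.05)
  # raw p-values roughly uniform: the lower tail is not inflated
  expect_lte(mean(got$p_value <= 0.05), 0.20)
})
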