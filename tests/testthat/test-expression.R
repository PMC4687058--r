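mk_expr <- function(counts, lengths, sample_id = "s1", tissue = "leaf",
                    genotype = "g1", replicate = 1L) {
  tibble::tibble(
    gene_id = paste0("g", seq_along(counts)),
    sample_id = sample_id, tissue = tissue, genotype = genotype,
    replicate = replicate, count = counts, effective_length = lengths
  )
}

test_that("TPM follows its definition and sums to one million", {
  equal <- compute_tpm(mk_expr(c(10, 10), c(100, 100)))
  expect_equal(equal$tpm, c(5e5, 5e5))

  single <- compute_tpm(mk_expr(c(25, 0), c(100, 100)))
  expect_equal(single$tpm, c(1e6, 0))

  uneven <- compute_tpm(mk_expr(c(10, 10), c(100, 200)))
  expect_equal(uneven$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  cfg <- tiny_config()
  sim <- simulate_genes(cfg)
  expr <- compute_tpm(simulate_counts(sim$sequences, sim$truth, cfg))
  sums <- tapply(expr$tpm, expr$sample_id, sum)
  expect_true(all(abs(sums - 1e6) < 1e-6 * 1e6 * 1e-3 + 1e-3))

  expect_warning(compute_tpm(mk_expr(c(0, 0), c(100, 100))), "zero total")
})

test_that("expressed calls use a strict mean-TPM threshold", {
  expr <- dplyr::bind_rows(
    mk_expr(c(10, 1), c(100, 100), "s1", replicate = 1L),
    mk_expr(c(10, 1), c(100, 100), "s2", replicate = 2L)
  )
  expr$tpm <- c(0.5, 3, 1.6, 1)  # injected per-replicate TPMs
  calls <- call_expressed(expr, threshold = 1)
  # gene 1: mean(0.5, 1.6) = 1.05 > 1 -> expressed
  expect_true(calls$expressed[calls$gene_id == "g1"])
  # gene 2: mean(3, 1) = 2 -> expressed; now force a boundary mean of 1
  expr$tpm <- c(0.5, 1.0, 1.5, 1.0)
  calls2 <- call_expressed(expr, threshold = 1)
  expect_false(calls2$expressed[calls2$gene_id == "g2"])
  expr$tpm <- c(0, 0, 0, 0)
  expect_false(any(call_expressed(expr)$expressed))
})

test_that("partitioning classes cover the tissue combinations", {
  pairs <- tibble::tibble(pair_id = "p1", id_a = "A", id_b = "B")
  mk_calls <- function(a_leaf, a_root, b_leaf, b_root) {
    tibble::tibble(
      gene_id = rep(c("A", "B"), each = 2),
      tissue = rep(c("leaf", "root"), 2),
      genotype = "g1",
      mean_tpm = 5,
      expressed = c(a_leaf, a_root, b_leaf, b_root)
    )
  }
  cls <- function(...) {
    classify_partitioning(pairs, mk_calls(...))$partition_class
  }
  expect_equal(cls(TRUE, TRUE, TRUE, TRUE), "both_both")
  expect_equal(cls(TRUE, FALSE, FALSE, TRUE), "partitioned")
  expect_equal(cls(FALSE, TRUE, TRUE, FALSE), "partitioned")
  expect_equal(cls(TRUE, FALSE, TRUE, FALSE), "single_tissue_leaf")
  expect_equal(cls(FALSE, TRUE, FALSE, TRUE), "single_tissue_root")
  expect_equal(cls(TRUE, TRUE, FALSE, FALSE), "one_silent")
  expect_equal(cls(FALSE, FALSE, FALSE, FALSE), "both_silent")
  expect_equal(cls(TRUE, TRUE, TRUE, FALSE), "both_both")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  # step-up by hand: sorted p * m / rank, cumulative minimum from the top
  p <- c(0.005, 0.011, 0.02, 0.04, 0.9)
  expect_equal(bh_fdr(p), c(0.025, 0.0275, 0.0333333333, 0.05, 0.9),
               tolerance = 1e-8)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the exact NB test reduces to a binomial split at dispersion 0", {
  for (z in c(5, 20, 50)) {
    for (a in c(0, 1, floor(z / 3), z)) {
      p_nb <- exact_nb_test(a, z - a, 3, 3, 0)
      probs <- dbinom(0:z, z, 0.5)
      p_or <- sum(probs[probs <= probs[a + 1] * (1 + 1e-10)])
      expect_equal(p_nb, min(1, p_or), tolerance = 1e-12)
    }
  }
  # asymmetric replicate numbers shift the split probability
  p_asym <- exact_nb_test(10, 30, 1, 3, 0)
  probs <- dbinom(0:40, 40, 0.25)
  expect_equal(p_asym, sum(probs[probs <= probs[11] * (1 + 1e-10)]),
               tolerance = 1e-12)
  expect_equal(exact_nb_test(0, 0, 3, 3, 0.1), 1)
})

test_that("the exact NB test matches edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(13)
  phi <- 0.08
  y1 <- matrix(rnbinom(60, mu = 80, size = 1 / phi), ncol = 3)
  y2 <- matrix(rnbinom(60, mu = 80, size = 1 / phi), ncol = 3)
  p_edger <- edgeR::exactTestBySmallP(y1, y2, dispersion = phi)
  p_ours <- vapply(seq_len(nrow(y1)), function(i) {
    exact_nb_test(sum(y1[i, ]), sum(y2[i, ]), 3, 3, phi)
  }, 0)
  expect_equal(p_ours, p_edger, tolerance = 1e-9)
})

test_that("identical copies give p = 1 and zero fold change", {
  expr <- dplyr::bind_rows(lapply(1:3, function(r) {
    mk_expr(c(100, 100), c(300, 300), paste0("s", r), replicate = r)
  }))
  pairs <- tibble::tibble(pair_id = "p1", id_a = "g1", id_b = "g2")
  de <- de_test_pairs(expr, pairs, dispersion = 0.05)
  expect_equal(de$p_value, 1)
  expect_equal(de$log2_fc, 0)
  expect_false(de$significant)
})

test_that("DE testing requires two replicates per condition", {
  expr <- mk_expr(c(100, 100), c(300, 300))
  pairs <- tibble::tibble(pair_id = "p1", id_a = "g1", id_b = "g2")
  expect_error(de_test_pairs(expr, pairs, dispersion = 0.05),
               "2 replicates")
})

test_that("common-dispersion estimation recovers the simulated value", {
  set.seed(99)
  phi <- 0.1
  n_units <- 600
  y <- rnbinom(n_units * 5, mu = 200, size = 1 / phi)
  group <- rep(seq_len(n_units), each = 5)
  est <- wgdpairs:::estimate_common_dispersion(y, group)
  expect_lt(abs(est - phi) / phi, 0.25)
})

test_that("fold-change bins partition the line at 0.4, 2 and 8", {
  x <- c(0, 0.39, 0.4, 1.9, 2, 7.9, 8, 12, -3)
  expect_equal(
    as.character(fc_bin(x)),
    c("low", "low", "mid", "mid", "high", "high", "extreme", "extreme",
      "high")
  )
  expect_false(anyNA(fc_bin(seq(-20, 20, by = 0.1))))
})
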