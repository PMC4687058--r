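test_that("raw 4DTV counts transversions by the purine/pyrimidine rule", {
  sites <- tibble::tibble(base_a = c("A", "A", "C"),
                          base_b = c("T", "G", "C"))
  got <- raw_4dtv(sites)
  expect_equal(got$n_4d_sites, 3L)
  expect_equal(got$n_transversions, 1L)
  expect_equal(got$four_dtv_raw, 1 / 3)

  same <- tibble::tibble(base_a = c("A", "G"), base_b = c("A", "G"))
  expect_equal(raw_4dtv(same)$four_dtv_raw, 0)

  one <- tibble::tibble(base_a = "A", base_b = "C")
  got1 <- raw_4dtv(one)
  expect_equal(got1$four_dtv_raw, 1)
  expect_true(is.na(correct_4dtv(got1$four_dtv_raw)))

  none <- tibble::tibble(base_a = character(), base_b = character())
  expect_true(is.na(raw_4dtv(none)$four_dtv_raw))
})

test_that("the multiple-hit correction matches its closed form", {
  expect_equal(correct_4dtv(0), 0)
  expect_equal(correct_4dtv(0.1), 0.111571776, tolerance = 1e-8)
  expect_equal(correct_4dtv(0.49), 1.956011503, tolerance = 1e-8)
  expect_true(is.na(correct_4dtv(0.5)))

  q <- seq(0, 0.49, by = 0.01)
  d <- correct_4dtv(q)
  expect_true(all(diff(d) > 0))       # monotone increasing
  expect_true(all(d >= q))            # at least the raw value
  expect_equal(correct_4dtv(1e-6), 1e-6, tolerance = 1e-4)
  # exact inverse
  expect_equal(uncorrect_4dtv(d), q, tolerance = 1e-12)
})

test_that("NG86 handles identity and single-codon cases", {
  same <- codon_aln_from_codons(c("ATG", "GGA"), c("ATG", "GGA"))
  est <- estimate_ka_ks(same)
  expect_equal(est$ka, 0)
  expect_equal(est$ks, 0)
  expect_true(is.na(est$omega))

  # TTT -> TTC is one synonymous difference; on a one-codon alignment the
  # synonymous proportion exceeds 3/4, so Ks saturates while Ka stays 0
  one <- codon_aln_from_codons("TTT", "TTC")
  est1 <- estimate_ka_ks(one)
  expect_equal(est1$sd, 1)
  expect_equal(est1$nd, 0)
  expect_equal(est1$ka, 0)
  expect_equal(est1$s_sites, 1 / 3)
  expect_equal(est1$kaks_flag, "saturated")

  empty <- codon_aln_from_codons(c("ATG"), c("ATG"))
  empty$ungapped <- FALSE
  expect_equal(estimate_ka_ks(empty)$kaks_flag, "undefined")
})

test_that("NG86 equals the pathway-enumeration oracle on random pairs", {
  set.seed(101)
  for (i in 1:60) {
    pr <- random_codon_pair(30, p_mut = 0.3)
    est <- suppressWarnings(
      estimate_ka_ks(codon_aln_from_codons(pr$a, pr$b))
    )
    orc <- oracle_kaks(pr$a, pr$b)
    expect_equal(est$sd, unname(orc["sd"]), tolerance = 1e-12)
    expect_equal(est$nd, unname(orc["nd"]), tolerance = 1e-12)
    expect_equal(est$s_sites, unname(orc["s_sites"]), tolerance = 1e-12)
    expect_equal(est$ka, unname(orc["ka"]), tolerance = 1e-9)
    expect_equal(est$ks, unname(orc["ks"]), tolerance = 1e-9)
  }
})

test_that("omega recovery tracks the planted selection strength", {
  # NG86 assumes no transition bias, so the neutral check runs at kappa = 1
  cfg_neutral <- simulation_config(
    seed = 31, n_wgd_pairs = 60, n_tandem_pairs = 0, n_singletons = 0,
    n_codons_range = c(280, 320), branch_transversion_rate = 0.12,
    ts_tv_ratio = 1, nonsyn_rate_scale = 1
  )
  sim <- simulate_genes(cfg_neutral)
  pairs <- tibble::tibble(pair_id = sim$truth$pair_id,
                          id_a = sim$truth$gene_a, id_b = sim$truth$gene_b)
  div <- pair_divergence(pairs, sim$sequences)
  expect_lt(abs(stats::median(div$omega, na.rm = TRUE) - 1), 0.15)

  cfg_sel <- simulation_config(
    seed = 32, n_wgd_pairs = 40, n_tandem_pairs = 0, n_singletons = 0,
    n_codons_range = c(280, 320), branch_transversion_rate = 0.12,
    ts_tv_ratio = 1, nonsyn_rate_scale = 0.25
  )
  sim2 <- simulate_genes(cfg_sel)
  pairs2 <- tibble::tibble(pair_id = sim2$truth$pair_id,
                           id_a = sim2$truth$gene_a,
                           id_b = sim2$truth$gene_b)
  div2 <- pair_divergence(pairs2, sim2$sequences)
  expect_lt(stats::median(div2$omega, na.rm = TRUE), 0.5)
})

test_that("Ks and corrected 4DTV co-vary across divergence levels", {
  divs <- list()
  for (rate in c(0.05, 0.10, 0.15, 0.20)) {
    cfg <- simulation_config(
      seed = 40 + round(100 * rate), n_wgd_pairs = 15, n_tandem_pairs = 0,
      n_singletons = 0, n_codons_range = c(200, 260),
      branch_transversion_rate = rate
    )
    sim <- simulate_genes(cfg)
    pairs <- tibble::tibble(pair_id = sim$truth$pair_id,
                            id_a = sim$truth$gene_a,
                            id_b = sim$truth$gene_b)
    divs[[length(divs) + 1L]] <- pair_divergence(pairs, sim$sequences)
  }
  div <- dplyr::bind_rows(divs)
  rho <- stats::cor(div$four_dtv_corr, div$ks, method = "spearman",
                    use = "complete.obs")
  expect_gt(rho, 0.5)
})
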