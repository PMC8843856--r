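test_that("neutral coalescent: degenerate inputs and determinism", {
  expect_error(simulate_neutral_window(1, 1, 1000), "n_haps")
  b0 <- simulate_neutral_window(6, 0, 1000, seed = 1)
  expect_identical(b0$S, 0L)
  b1 <- simulate_neutral_window(8, 5, 10000, seed = 99)
  b2 <- simulate_neutral_window(8, 5, 10000, seed = 99)
  expect_identical(b1$mat, b2$mat)
  expect_identical(b1$positions, b2$positions)
  expect_true(all(b1$positions >= 0 & b1$positions < 10000))
  cs <- colSums(b1$mat)
  expect_true(all(cs > 0 & cs < b1$n))
})

test_that("Watterson consistency and pi recovery on neutral windows", {
  set.seed(202)
  S <- replicate(800, simulate_neutral_window(2, 4, 5000)$S)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - 4), 3 * se)   # E[S] = theta * a1, a1(2) = 1
  set.seed(203)
  pis <- replicate(500, pairwise_pi(simulate_neutral_window(10, 8, 5000))$pi_raw)
  se_pi <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 8), 3 * se_pi)
})

test_that("neutral scan: per-window Tajima's D centred at 0", {
  set.seed(204)
  d <- replicate(600, tajimas_d(simulate_neutral_window(12, 6, 5000)))
  d <- d[is.finite(d)]
  expect_gt(length(d), 500)
  se <- sd(d) / sqrt(length(d))
  # small negative bias of the D estimator is within the 3-SE band
  expect_lt(abs(mean(d)), 3 * se + 0.05)
})

test_that("sim_params validates its invariants", {
  expect_error(sim_params(sweep_f_red = 1.5), "f_red")
  expect_error(sim_params(n_haps_per_pop = 1), "n_haps_per_pop")
  expect_error(sim_params(theta_per_bp = 0), "theta_per_bp")
  expect_error(sim_params(n_regions = 10, sweep_region_index = 11),
               "out of range")
})

test_that("sweep dataset: structure, determinism, planted carrier frequency", {
  p <- sim_params(n_regions = 6, sweep_region_index = 2, seed = 31)
  sim <- simulate_sweep_dataset(p)
  expect_length(sim$blocks, 6)
  expect_named(sim$blocks[[1]], c("NE", "NW", "S"))
  expect_identical(nrow(sim$te$loci), 6L)
  expect_identical(sim$truth$adaptive_te_ids, "TE_rgn002")
  # same params -> identical artifacts
  sim2 <- simulate_sweep_dataset(p)
  expect_identical(sim$panel$ac, sim2$panel$ac)
  expect_identical(sim$te$geno, sim2$te$geno)
  # planted carrier frequency within a binomial CI across seeds
  carriers <- unlist(lapply(1:20, function(s) {
    d <- simulate_sweep_dataset(sim_params(n_regions = 2,
                                           sweep_region_index = 1,
                                           seed = 400 + s), gt_strings = FALSE)
    g <- d$te$geno[d$populations$population == "NE", "TE_rgn001"]
    g
  }))
  ci <- binom_ci(sum(carriers), length(carriers))
  expect_true(ci[1] <= 0.9 && 0.9 <= ci[2])
})

test_that("f_red = 0 leaves the target/ref pi ratio at 1 on average", {
  set.seed(51)
  ratios <- replicate(60, {
    d <- simulate_sweep_dataset(sim_params(n_regions = 1,
                                           sweep_region_index = 1,
                                           sweep_f_red = 0,
                                           seed = sample.int(1e6, 1)),
                                gt_strings = FALSE)
    bt <- d$blocks[[1]]$NE; br <- d$blocks[[1]]$NW
    pairwise_pi(bt)$pi_raw / pairwise_pi(br)$pi_raw
  })
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)) + 0.02)
})

test_that("TE genotype matrix simulator plants category bias and specificity", {
  expect_error(simulate_te_genotype_matrix(
    category_mix = c(CDS = 0.5, UTR = 0.2, intron = 0.1, promoter = 0.1,
                     downstream = 0.05, intergenic = 0.1) * 2), "sum to 1")
  M <- simulate_te_genotype_matrix(n_loci = 400, seed = 77)
  expect_identical(ncol(M$te$geno), 400L)
  expect_identical(nrow(M$te$geno), 87L)           # 23 + 35 + 29 accessions
  # planted pop-specific loci carry only in their population
  fr <- insertion_frequencies(M$te)
  for (lid in M$truth$pop_specific_ids[1:10]) {
    own <- M$truth$specific_pop[[lid]]
    other <- setdiff(c("NE", "NW", "S"), own)
    f_other <- unlist(fr[fr$locus_id == lid, paste0("freq_", other)])
    expect_true(all(f_other == 0))
    expect_gt(fr[fr$locus_id == lid, paste0("freq_", own)], 0)
  }
  # with bias off the low-frequency share is homogeneous across categories
  M0 <- simulate_te_genotype_matrix(
    n_loci = 600, bias_params = list(low_freq_prob = 0.4), seed = 78)
  low <- M0$truth$true_freq <= 0.1
  tab <- table(M0$truth$category, low)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
  # with bias on, the planted low proportions are recovered within a
  # binomial CI of the nominal parameters (0.9 CDS vs 0.4 intergenic)
  Mb <- simulate_te_genotype_matrix(n_loci = 1500, seed = 79)
  tf <- Mb$truth$true_freq; ct <- Mb$truth$category
  for (pair in list(c("CDS", 0.9), c("intergenic", 0.4))) {
    x <- tf[ct == pair[1]] <= 0.1
    ci <- binom_ci(sum(x), length(x))
    expect_true(ci[1] <= as.numeric(pair[2]) &&
                as.numeric(pair[2]) <= ci[2])
  }
})

test_that("landscape simulator: geometry and planted labels", {
  L <- simulate_landscape(n_genes = 80, n_tes = 90, sirna_fraction = 0,
                          seed = 5)
  # no gene overlap by construction
  g <- L$genes$genes[order(L$genes$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  # sirna_fraction = 0 -> every TE labelled siRNA- downstream
  cl <- call_clusters(L$sirna_reads)
  loci <- merge_loci(cl)
  lab <- label_tes(L$tes, loci)
  expect_true(all(lab$sirna == "siRNA-"))
  # surplus TEs live on the TE-only chromosome
  expect_identical(sum(L$tes$chrom == "chrU"), 10L)
  # planted distances are the realised nearest distances
  nd <- nearest_te_distance(L$genes, L$tes)
  expect_equal(unname(nd$distance), unname(L$truth$distance[nd$gene_id]))
})

test_that("fixture bundle: manifest, determinism, tamper detection", {
  p <- sim_params(n_regions = 2, sweep_region_index = 1, seed = 13,
                  n_haps_per_pop = 8)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_fixture_bundle(simulate_sweep_dataset(p), d1)
  m2 <- write_fixture_bundle(simulate_sweep_dataset(p), d2)
  expect_true(all(c("snps.vcf", "populations.tsv", "te_loci.bed",
                    "te_genotypes.tsv", "truth.json") %in% m1$file))
  expect_identical(m1$md5, m2$md5)
  expect_true(attr(verify_fixture_bundle(d1), "all_ok"))
  # tamper with one file -> mismatch reported
  cat("x\n", file = file.path(d1, "populations.tsv"), append = TRUE)
  v <- verify_fixture_bundle(d1)
  expect_false(attr(v, "all_ok"))
  expect_false(v$ok[v$file == "populations.tsv"])
})
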