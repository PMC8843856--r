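mini_tem <- function(geno, pops = NULL) {
  n_loci <- ncol(geno)
  loci <- data.frame(chrom = "c", start = seq_len(n_loci) * 1000,
                     end = seq_len(n_loci) * 1000 + 100, strand = ".",
                     locus_id = sprintf("L%d", seq_len(n_loci)),
                     superfamily = "Gypsy", genic_category = "intergenic",
                     stringsAsFactors = FALSE)
  colnames(geno) <- loci$locus_id
  if (is.null(pops))
    pops <- data.frame(accession_id = rownames(geno),
                       population = rep(c("NE", "NW"),
                                        length.out = nrow(geno)))
  te_genotype_matrix(loci, geno, populations = pops)
}

test_that("complete-case carrier frequencies", {
  g <- matrix(0L, 10, 3, dimnames = list(sprintf("a%02d", 1:10), NULL))
  g[1:3, 1] <- 1L                      # 3 of 10
  g[1:3, 2] <- 1L; g[9:10, 2] <- NA    # 3 of 8
  g[, 3] <- NA                         # all-NA
  fr <- insertion_frequencies(mini_tem(g))
  expect_equal(fr$freq, c(0.3, 0.375, NaN))
  expect_equal(fr$n_genotyped, c(10, 8, 0))
  expect_false(fr$defined[3])
})

test_that("sharing classification rule", {
  pops <- data.frame(accession_id = sprintf("a%02d", 1:9),
                     population = rep(c("NE", "NW", "S"), each = 3))
  g <- matrix(0L, 9, 3, dimnames = list(pops$accession_id, NULL))
  g[1, 1] <- 1L                        # NE only -> pop-specific:NE
  g[c(1, 4, 7), 2] <- 1L               # present everywhere -> all-shared
  g[c(1, 4), 3] <- 1L                  # two of three -> partial
  sh <- classify_sharing(insertion_frequencies(mini_tem(g, pops)))
  expect_equal(sh$records$sharing_class,
               c("pop-specific:NE", "all-shared", "partial"))
  expect_error(classify_sharing(data.frame(freq_NE = 1)), ">=2 populations")
})

test_that("planted population-specific fraction is recovered", {
  M <- simulate_te_genotype_matrix(n_loci = 500, seed = 88,
                                   bias_params = list(prop_pop_specific = 0.1))
  sh <- classify_sharing(insertion_frequencies(M$te))
  n_spec <- sum(startsWith(sh$records$sharing_class, "pop-specific"))
  # some planted-shared loci are sampled into apparent specificity at low f,
  # so compare against the generator's truth, not the nominal rate
  truth_ids <- M$truth$pop_specific_ids
  called <- sh$records$locus_id[startsWith(sh$records$sharing_class,
                                           "pop-specific")]
  expect_true(all(truth_ids %in% called))
  ci <- binom_ci(length(truth_ids), 500)
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
  expect_gte(n_spec, length(truth_ids))
})

test_that("low-frequency bias test: worked table, null, oracle", {
  # CDS 8 low / 2 high vs intergenic 20 low / 80 high -> OR 16
  freqs <- data.frame(
    locus_id = sprintf("L%03d", 1:110),
    freq = c(rep(0.05, 8), rep(0.5, 2), rep(0.05, 20), rep(0.5, 80)))
  cats <- setNames(c(rep("CDS", 10), rep("intergenic", 100)), freqs$locus_id)
  res <- low_frequency_bias_test(freqs, cats)
  expect_equal(res$odds_ratio, 16)
  expect_equal(res$p_value, oracle_fisher_greater(8, 2, 20, 80),
               tolerance = 1e-12)
  # identical proportions -> OR 1, one-sided p >= 0.5
  freqs2 <- data.frame(
    locus_id = sprintf("M%03d", 1:80),
    freq = rep(c(0.05, 0.5), 40))
  cats2 <- setNames(rep(c("CDS", "intergenic"), each = 40), freqs2$locus_id)
  res2 <- low_frequency_bias_test(freqs2, cats2)
  expect_equal(res2$odds_ratio, 1)
  expect_gte(res2$p_value, 0.5)
  expect_error(low_frequency_bias_test(freqs2, cats2, reference = "promoter"),
               "reference")
})

test_that("Fisher p equals the hypergeometric-sum oracle on random tables", {
  set.seed(55)
  for (i in 1:200) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c_ <- sample(0:30, 1); d <- sample(0:30, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    freqs <- data.frame(
      locus_id = sprintf("x%d", seq_len(a + b + c_ + d)),
      freq = c(rep(0.01, a), rep(0.9, b), rep(0.01, c_), rep(0.9, d)))
    cats <- setNames(c(rep("CDS", a + b), rep("intergenic", c_ + d)),
                     freqs$locus_id)
    res <- low_frequency_bias_test(freqs, cats)
    expect_equal(res$p_value, oracle_fisher_greater(a, b, c_, d),
                 tolerance = 1e-12)
  }
})

test_that("frequency spectrum mass and composition normalisation", {
  g <- matrix(0L, 10, 4, dimnames = list(sprintf("a%02d", 1:10), NULL))
  g[1, 1:4] <- 1L   # all four loci at f = 0.1, inside the first decile bin
  tem <- mini_tem(g)
  fr <- insertion_frequencies(tem)
  sh <- classify_sharing(fr)
  sc <- sfs_and_composition(sh$records, tem)
  expect_equal(sc$sfs$count[1], 4)          # mass entirely in the first bin
  expect_equal(sum(sc$sfs$count), 4)
  agg <- tapply(sc$composition$fraction, sc$composition$group, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
})

test_that("U-shaped Beta(0.3, 0.3) spectrum concentrates in the outer bins", {
  set.seed(66)
  hits <- replicate(40, {
    f <- rbeta(400, 0.3, 0.3)
    h <- hist(f, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
    sum(h[c(1, 10)]) > max(h[2:9]) * 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("distance-sharing correlation over upper-triangle pairs", {
  set.seed(77)
  n <- 12
  d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  st <- -d
  res <- distance_sharing_correlation(d, st)
  expect_equal(res$r, -1)
  expect_equal(res$n_pairs, n * (n - 1) / 2)
  expect_error(distance_sharing_correlation(d[1:2, 1:2] * 0 + 1,
                                            st[1:2, 1:2]))
  expect_error(distance_sharing_correlation(d, st[1:3, 1:3]), "dimensions")
  con <- distance_sharing_correlation(matrix(1, 5, 5), d[1:5, 1:5])
  expect_true(is.nan(con$r))
  # null property: independent matrices give small |r|
  rs <- replicate(30, {
    a <- as.matrix(dist(rnorm(20))); b <- as.matrix(dist(rnorm(20)))
    distance_sharing_correlation(a, b)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
  # shared_te_counts is symmetric and bounded by the locus count
  M <- simulate_te_genotype_matrix(n_loci = 50, seed = 3)
  sc <- shared_te_counts(M$te)
  expect_true(isSymmetric(sc))
  expect_true(all(sc <= 50))
})
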