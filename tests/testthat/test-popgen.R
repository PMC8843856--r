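test_that("pairwise_pi matches enumeration on the worked examples", {
  expect_equal(pairwise_pi(haplotype_block(rbind(c(0, 1), c(0, 1))))$pi_raw, 0)
  b <- haplotype_block(rbind(c(0, 0), c(0, 1), c(1, 1)))
  expect_equal(pairwise_pi(b)$pi_raw, 4 / 3)  # pair diffs 1,2,1 over 3 pairs
  b2 <- haplotype_block(matrix(c(0, 0, 1, 1), 4, 1))
  expect_equal(pairwise_pi(b2)$pi_raw, 2 / 3) # 4 of 6 pairs differ
  expect_error(pairwise_pi(haplotype_block(matrix(1, 1, 1), prune = FALSE)),
               "n >= 2")
})

test_that("watterson_theta and Tajima constants", {
  expect_equal(watterson_theta(0, 5), 0)
  expect_equal(watterson_theta(5, 4), 30 / 11)
  expect_equal(watterson_theta(1, 2), 1)
  expect_error(watterson_theta(1, 1), "n >= 2")
  k <- tajima_constants(4)
  expect_equal(k$a1, 11 / 6)
  expect_true(all(vapply(k, is.finite, TRUE)))
  expect_true(k$e1 > 0 && k$e2 > 0)
})

test_that("tajimas_d: undefined cases, zero numerator, rare-variant sign", {
  b0 <- haplotype_block(matrix(0, 4, 2), prune = FALSE)
  expect_true(is.nan(tajimas_d(b0)))
  expect_warning(d <- tajimas_d(pi_raw = 1, S = 2, n = 3), "n < 4")
  expect_true(is.nan(d))
  # numerator exactly zero -> D exactly zero
  expect_identical(tajimas_d(pi_raw = watterson_theta(3, 4), S = 3, n = 4), 0)
  # n = 4 with 3 singleton sites: pi = 1.5 < theta = 18/11 -> D < 0
  m <- matrix(0, 4, 3); m[1, 1] <- m[2, 2] <- m[3, 3] <- 1
  b <- haplotype_block(m)
  expect_equal(pairwise_pi(b)$pi_raw, 1.5)
  expect_equal(watterson_theta(b$S, b$n), 18 / 11)
  expect_lt(tajimas_d(b), 0)
  expect_equal(tajimas_d(b), oracle_tajd(m), tolerance = 1e-12)
})

test_that("pi and D match brute-force oracles on random matrices", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:12, 1); S <- sample(1:30, 1)
    m <- random_hap_matrix(n, S)
    b <- haplotype_block(m)
    expect_equal(pairwise_pi(b)$pi_raw, oracle_pi(m), tolerance = 1e-9)
    if (b$S > 0)
      expect_equal(tajimas_d(b), oracle_tajd(m), tolerance = 1e-9)
    expect_equal(watterson_theta(b$S, n), oracle_theta_w(b$S, n),
                 tolerance = 1e-12)
  }
})

test_that("Hudson Fst: analytic cases, symmetry, undefined case", {
  fixA <- haplotype_block(matrix(0, 2, 1), positions = 0, prune = FALSE)
  fixB <- haplotype_block(matrix(1, 2, 1), positions = 0, prune = FALSE)
  expect_identical(pairwise_fst(fixA, fixB), 1)
  het <- haplotype_block(matrix(c(0, 1), 2, 1), positions = 0)
  expect_identical(pairwise_fst(het, het), -1)
  expect_identical(pairwise_fst(het, het, clip = TRUE), 0)
  # Hudson estimator is symmetric under label swap
  set.seed(7)
  a <- haplotype_block(random_hap_matrix(6, 12))
  b <- haplotype_block(matrix(rbinom(8 * 12, 1, 0.3), 8, 12),
                       positions = seq_len(12) - 1)
  a2 <- haplotype_block(a$mat, positions = a$positions)
  expect_equal(pairwise_fst(a, b), pairwise_fst(b, a2))
  # both monomorphic for the same allele -> undefined
  mono <- haplotype_block(matrix(0, 3, 1), positions = 0, prune = FALSE)
  expect_true(is.nan(pairwise_fst(mono, mono)))
})

test_that("Weir-Cockerham Fst behaves at the boundaries", {
  fixA <- haplotype_block(matrix(0, 4, 1), positions = 0, prune = FALSE)
  fixB <- haplotype_block(matrix(1, 4, 1), positions = 0, prune = FALSE)
  expect_equal(pairwise_fst(fixA, fixB, method = "wc"), 1)
  set.seed(9)
  a <- haplotype_block(random_hap_matrix(6, 10))
  b <- haplotype_block(matrix(rbinom(6 * 10, 1, 0.5), 6, 10),
                       positions = seq_len(10) - 1)
  a2 <- haplotype_block(a$mat, positions = a$positions)
  expect_equal(pairwise_fst(a, b, method = "wc"),
               pairwise_fst(b, a2, method = "wc"))
})

test_that("rod limits and strict monotonicity", {
  expect_equal(rod(0.004, 0.004), 0)
  expect_equal(rod(0, 0.004), 1)
  expect_equal(rod(0.002, 0.004), 0.5)
  expect_true(is.nan(rod(0.1, 0)))
  grid <- seq(0, 0.01, by = 0.0005)
  vals <- rod(grid, 0.004)
  expect_true(all(diff(vals) < 0))
})

test_that("windowed_scan places windows from 0 and flags empty windows", {
  pos <- 2500 * (0:9) + 1250          # 10 SNPs evenly over 25 kb
  gt <- matrix(rep(c(0, 1, 0, 1), each = 10), 10, 4)
  panel <- fixture_panel(pos, gt)
  res <- windowed_scan(panel, window_bp = 5000, step_bp = 5000, maf_min = 0)
  w <- res$window_stats[res$window_stats$population == "P1", ]
  expect_equal(nrow(w), 5)
  expect_equal(w$start, seq(0, 20000, 5000))
  expect_true(all(w$n_sites == 2))
  # empty window: pull all SNPs into the first two windows
  pos2 <- c(1:5 * 100, 6000 + 1:5 * 10)
  panel2 <- fixture_panel(pos2, gt)
  res2 <- windowed_scan(panel2, window_bp = 5000, step_bp = 5000, maf_min = 0)
  w2 <- res2$window_stats[res2$window_stats$population == "P1", ]
  expect_equal(nrow(w2), 2)
  # a chromosome tail window with sites only at the start:
  pos3 <- c(100, 200, 300, 12000, 12100, 12200, 12300, 12400, 12500, 12600)
  res3 <- windowed_scan(fixture_panel(pos3, gt), window_bp = 5000,
                        step_bp = 5000, maf_min = 0)
  w3 <- res3$window_stats[res3$window_stats$population == "P1", ]
  expect_equal(nrow(w3), 3)
  expect_true(is.nan(w3$pi_raw[2]))   # [5000,10000) has no SNP but is present
  expect_error(windowed_scan(fixture_panel(numeric(0),
                                           matrix(character(0), 0, 4))),
               "empty")
})

test_that("MAF filter drops rare sites from SNP statistics", {
  pos <- c(100, 200)
  gt <- cbind(c(1, 1), c(0, 1), c(0, 0), c(0, 0), c(0, 0),
              c(0, 1), c(0, 1), c(0, 1), c(0, 0), c(0, 0))
  panel <- fixture_panel(pos, gt, pop = rep(c("P1", "P2"), each = 5))
  res <- windowed_scan(panel, window_bp = 5000, step_bp = 5000, maf_min = 0.2)
  w <- res$window_stats
  expect_true(all(w$n_sites == 1))   # site 1 (freq .1 at pos 100) filtered
  res0 <- windowed_scan(panel, window_bp = 5000, step_bp = 5000, maf_min = 0)
  w0 <- res0$window_stats
  expect_equal(w0$n_sites[w0$population == "P1"], 2)  # rare site only in P1
})
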