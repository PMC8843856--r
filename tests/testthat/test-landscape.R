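make_gm <- function() read_gff3_genes(fixture_gff3())

te_row <- function(start, end, id = "t1", chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = ".",
             te_id = id, superfamily = "Helitron", stringsAsFactors = FALSE)
}

test_that("genic classification follows coding-most precedence", {
  gm <- make_gm()
  # g1 (+): CDS [20,50)+[60,80), UTR5 [0,20), UTR3 [80,100), intron [50,60)
  expect_equal(classify_genic_region(te_row(25, 40), gm)$category, "CDS")
  # overlapping CDS and UTR -> CDS wins
  expect_equal(classify_genic_region(te_row(10, 30), gm)$category, "CDS")
  expect_equal(classify_genic_region(te_row(0, 15), gm)$category,
               "five_prime_UTR")
  expect_equal(classify_genic_region(te_row(52, 58), gm)$category, "intron")
  # 1,500 bp upstream of a + strand TSS is promoter2kb... here the TSS is at 0
  # so use g2 (-, TSS at 300): upstream means higher coordinates
  expect_equal(classify_genic_region(te_row(1400, 1500), gm)$category,
               "promoter2kb")   # 1,100-1,200 bp upstream of g2 TSS (300)
  expect_equal(classify_genic_region(te_row(7000, 7100), gm)$category,
               "intergenic")
  # downstream of g2 (-) is below its start
  gm2 <- gene_models(
    data.frame(chrom = "chr1", start = 10000, end = 12000, strand = "+",
               gene_id = "g3"),
    data.frame(chrom = "chr1", start = 10000, end = 12000, strand = "+",
               type = "exon", gene_id = "g3", tx_id = "g3.t1"))
  expect_equal(classify_genic_region(te_row(12500, 12600), gm2)$category,
               "downstream2kb")
  expect_equal(classify_genic_region(te_row(8500, 8600), gm2)$category,
               "promoter2kb")
})

test_that("classification partitions any TE set", {
  gm <- make_gm()
  set.seed(11)
  tes <- data.frame(chrom = "chr1", start = sample(0:8000, 60),
                    stringsAsFactors = FALSE)
  tes$end <- tes$start + 120
  tes$strand <- "."
  tes$te_id <- sprintf("t%02d", seq_len(60))
  tes$superfamily <- "other"
  cls <- classify_genic_region(tes, gm)
  expect_identical(nrow(cls), 60L)
  expect_identical(sum(table(cls$category)), 60L)
  expect_true(all(cls$category %in% c("CDS", "five_prime_UTR",
                                      "three_prime_UTR", "intron",
                                      "promoter2kb", "downstream2kb",
                                      "intergenic")))
})

test_that("flank bins: edge distances, half-open outer boundary, totals", {
  gm <- gene_models(
    data.frame(chrom = "chr1", start = 10000, end = 12000, strand = "+",
               gene_id = "g"),
    data.frame(chrom = "chr1", start = 10000, end = 12000, strand = "+",
               type = c("exon", "CDS"), gene_id = "g", tx_id = "g.t1"))
  # TE edge 50 bp upstream of the start codon -> upstream bin [0,100)
  fb <- flank_bin_profile(te_row(9800, 9950), gm)
  expect_equal(fb$count[fb$side == "upstream" & fb$bin_lo == 0], 1)
  expect_equal(sum(fb$count), 1)
  # exactly 2,000 bp away is excluded (half-open boundary)
  fb2 <- flank_bin_profile(te_row(7800, 8000), gm)
  expect_equal(sum(fb2$count), 0)
  fb3 <- flank_bin_profile(te_row(7800, 8001), gm)
  expect_equal(fb3$count[fb3$side == "upstream" & fb3$bin_lo == 1900], 1)
  # downstream side uses the stop codon
  fb4 <- flank_bin_profile(te_row(12250, 12350), gm)
  expect_equal(fb4$count[fb4$side == "downstream" & fb4$bin_lo == 200], 1)
  # totals equal the number of in-flank assignments
  set.seed(3)
  tes <- te_row(sample(8000:14000, 40), 0)
  tes$end <- tes$start + 50
  tes$te_id <- sprintf("r%02d", 1:40)
  fb5 <- flank_bin_profile(tes, gm)
  in_flank <- sum((tes$end <= 10000 & 10000 - tes$end < 2000) |
                  (tes$start >= 12000 & tes$start - 12000 < 2000))
  expect_equal(sum(fb5$count), in_flank)
})

test_that("window density merges covers and is order/split invariant", {
  f <- data.frame(chrom = "c", start = c(10000, 50000), end = c(30000, 52000))
  d <- window_density(f, window_bp = 100000, chrom_lengths = c(c = 100000))
  expect_equal(d$density, 0.22)
  expect_equal(window_density(data.frame(chrom = "c", start = 1, end = 2),
                              window_bp = 1000,
                              chrom_lengths = c(c = 3000))$density,
               c(0.001, 0, 0))
  ov <- data.frame(chrom = "c", start = c(0, 5), end = c(10, 15))
  expect_equal(window_density(ov, window_bp = 100,
                              chrom_lengths = c(c = 100))$density, 0.15)
  # invariance to order and to splitting a feature into adjacent pieces
  split1 <- data.frame(chrom = "c", start = c(10000, 50000, 20000),
                       end = c(20000, 52000, 30000))
  expect_equal(window_density(split1, 100000, c(c = 100000))$density, 0.22)
  expect_true(all(d$density >= 0 & d$density <= 1))
})

test_that("nearest gene distance: overlap, sign convention, brute force", {
  gm <- make_gm()
  expect_equal(nearest_gene_distance(te_row(40, 70), gm)$distance, 0)
  # TE ending 1 bp before g1's start on + strand... g1 starts at 0, use a
  # shifted gene model
  gm2 <- gene_models(
    data.frame(chrom = "chr1", start = 5000, end = 6000, strand = "+",
               gene_id = "g"),
    data.frame(chrom = "chr1", start = 5000, end = 6000, strand = "+",
               type = "exon", gene_id = "g", tx_id = "g.t1"))
  expect_equal(nearest_gene_distance(te_row(4900, 4999), gm2)$distance, -1)
  expect_equal(nearest_gene_distance(te_row(6100, 6200), gm2)$distance, 100)
  # minus strand flips the sign
  gm3 <- gene_models(
    data.frame(chrom = "chr1", start = 5000, end = 6000, strand = "-",
               gene_id = "g"),
    data.frame(chrom = "chr1", start = 5000, end = 6000, strand = "-",
               type = "exon", gene_id = "g", tx_id = "g.t1"))
  expect_equal(nearest_gene_distance(te_row(4900, 4999), gm3)$distance, 1)
  # no gene on the chromosome -> NA
  expect_true(is.na(nearest_gene_distance(te_row(0, 10, chrom = "chrZ"),
                                          gm2)$distance))
  # brute force over a random fixture
  set.seed(8)
  genes <- data.frame(chrom = "chr1", start = sort(sample(seq(0, 9e4, 500), 8)),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 400
  genes$strand <- "+"
  genes$gene_id <- sprintf("g%d", 1:8)
  gm4 <- gene_models(genes, data.frame(
    chrom = "chr1", start = genes$start, end = genes$end, strand = "+",
    type = "exon", gene_id = genes$gene_id, tx_id = paste0(genes$gene_id, ".t")))
  tes <- te_row(sample(0:95000, 30), 0)
  tes$end <- tes$start + 100
  tes$te_id <- sprintf("t%02d", 1:30)
  nd <- nearest_gene_distance(tes, gm4)
  for (i in seq_len(nrow(tes))) {
    gaps <- pmax(0, pmax(genes$start - tes$end[i], tes$start[i] - genes$end))
    expect_equal(abs(nd$distance[i]), min(gaps))
  }
})
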