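# In-code fixtures; everything is written to tempfiles at test time.

fixture_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "101", ".", "A", "T", ".", "PASS", ".", "GT", "0|0", "0|1",
          sep = "\t"),
    paste("chr1", "205", ".", "C", "G", ".", "PASS", ".", "GT", "1|1", "0|0",
          sep = "\t"),
    paste("chr1", "311", ".", "G", "A", ".", "PASS", ".", "GT", "0|1", "1|1",
          sep = "\t"))
}

write_fixture_vcf <- function(path = tempfile(fileext = ".vcf"),
                              extra = character(0)) {
  lines <- fixture_vcf_lines()
  writeLines(c(lines, extra), path)
  path
}

fixture_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  g <- function(...) paste(..., sep = "\t")
  writeLines(c(
    "##gff-version 3",
    g("chr1", ".", "gene", 1, 100, ".", "+", ".", "ID=g1"),
    g("chr1", ".", "mRNA", 1, 100, ".", "+", ".", "ID=g1.t1;Parent=g1"),
    g("chr1", ".", "exon", 1, 50, ".", "+", ".", "ID=g1.e1;Parent=g1.t1"),
    g("chr1", ".", "exon", 61, 100, ".", "+", ".", "ID=g1.e2;Parent=g1.t1"),
    g("chr1", ".", "CDS", 21, 50, ".", "+", ".", "ID=g1.c1;Parent=g1.t1"),
    g("chr1", ".", "CDS", 61, 80, ".", "+", ".", "ID=g1.c2;Parent=g1.t1"),
    g("chr1", ".", "gene", 201, 300, ".", "-", ".", "ID=g2"),
    g("chr1", ".", "mRNA", 201, 300, ".", "-", ".", "ID=g2.t1;Parent=g2"),
    g("chr1", ".", "exon", 201, 300, ".", "-", ".", "ID=g2.e1;Parent=g2.t1"),
    g("chr1", ".", "CDS", 221, 280, ".", "-", ".", "ID=g2.c1;Parent=g2.t1")),
    path)
  path
}

fixture_te_files <- function(dir = tempfile()) {
  dir.create(dir)
  bed <- file.path(dir, "te.bed")
  tsv <- file.path(dir, "te.tsv")
  writeLines(c(paste("chr1", 1000, 1300, "L1", 0, "+", "Gypsy", sep = "\t"),
               paste("chr1", 5000, 5400, "L2", 0, "-", "Helitron", sep = "\t")),
             bed)
  writeLines(c(paste("locus_id", "a1", "a2", "a3", sep = "\t"),
               paste("L1", 1, 0, "NA", sep = "\t"),
               paste("L2", 0, 1, 1, sep = "\t")),
             tsv)
  list(bed = bed, tsv = tsv)
}

# tiny haploid two-population panel built directly
fixture_panel <- function(positions, gt, chrom = "chr1",
                          samples = paste0("a", seq_len(ncol(gt))),
                          pop = rep(c("P1", "P2"), each = ncol(gt) / 2)) {
  k <- length(positions)
  sites <- data.frame(chrom = rep_len(chrom, k), pos = positions,
                      id = rep_len(".", k), ref = rep_len("A", k),
                      alt = rep_len("T", k), qual = rep_len(".", k),
                      filter = rep_len("PASS", k), info = rep_len(".", k),
                      stringsAsFactors = FALSE)
  pops <- data.frame(accession_id = samples, population = pop,
                     stringsAsFactors = FALSE)
  snp_panel(sites, matrix(as.character(gt), nrow(gt), ncol(gt)),
            samples, populations = pops, ploidy = 1L)
}
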