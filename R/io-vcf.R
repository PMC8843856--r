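# Minimal VCF v4.2 reader/writer for the biallelic-SNP subset the pipeline
# consumes. Hand-rolled deliberately: the io contract requires that
# write_vcf(read_vcf_genotypes(x)) reproduces retained body lines byte for
# byte, which a re-formatting writer cannot guarantee. Positions are converted
# to 0-based internally and back to 1-based POS on write.

#' SNP genotype panel
#'
#' Container for a biallelic-SNP genotype panel: per-site metadata (0-based
#' positions), raw per-sample GT strings (kept for lossless round-trips), and
#' the derived alternate-allele count matrix used by all statistics.
#'
#' @param sites data.frame with columns chrom, pos (0-based), id, ref, alt,
#'   qual, filter, info.
#' @param gt character matrix, sites x samples, of VCF GT strings.
#' @param samples sample (accession) identifiers, one per gt column.
#' @param populations optional population assignment data.frame
#'   (accession_id, population).
#' @param ploidy 1 or 2.
#' @return an object of class `snp_panel` with elements sites, gt, ac (alt
#'   allele counts, NA where any allele is missing), an (called allele number
#'   per site x sample), samples, populations, ploidy.
#' @export
snp_panel <- function(sites, gt, samples, populations = NULL, ploidy = 2L) {
  stopifnot(nrow(gt) == nrow(sites), ncol(gt) == length(samples))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  parsed <- parse_gt_matrix(gt, ploidy)
  if (!is.null(populations)) check_populations(populations, samples)
  structure(list(sites = sites, gt = gt, ac = parsed$ac, an = parsed$an,
                 samples = samples, populations = populations,
                 ploidy = as.integer(ploidy)),
            class = "snp_panel")
}

parse_gt_matrix <- function(gt, ploidy) {
  core <- sub(":.*$", "", gt)
  if (ploidy == 1L) {
    ac <- matrix(match(core, c("0", "1")) - 1L, nrow(gt), ncol(gt))
    an <- matrix(ifelse(is.na(ac), 0L, 1L), nrow(gt), ncol(gt))
  } else {
    a1 <- substr(core, 1, 1)
    a2 <- substr(core, 3, 3)
    n1 <- match(a1, c("0", "1")) - 1L
    n2 <- match(a2, c("0", "1")) - 1L
    ac <- matrix(n1 + n2, nrow(gt), ncol(gt))
    an <- matrix(ifelse(is.na(ac), 0L, 2L), nrow(gt), ncol(gt))
  }
  list(ac = ac, an = an)
}

check_populations <- function(populations, samples) {
  stopifnot(all(c("accession_id", "population") %in% names(populations)))
  if (anyDuplicated(populations$accession_id))
    stop("duplicate accession_id in population assignment")
  missing <- setdiff(populations$accession_id, samples)
  if (length(missing))
    stop("sample(s) in population assignment absent from panel: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Multi-allelic records and non-SNP records (indels, symbolic alleles) are
#' skipped and the skip count is logged. VCF POS is converted to 0-based.
#'
#' @param path VCF file (uncompressed, v4.x).
#' @param populations optional population assignment data.frame
#'   (accession_id, population); every listed accession must be a VCF sample.
#' @param ploidy 1 (haploid GT) or 2.
#' @return an [snp_panel].
#' @export
read_vcf_genotypes <- function(path, populations = NULL, ploidy = 2L) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1) stop("missing #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("VCF has no sample columns")
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  n_skip <- 0L
  keep <- character(0)
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    ok <- vapply(f, function(x) {
      nchar(x[4]) == 1 && nchar(x[5]) == 1 &&
        x[4] %in% c("A", "C", "G", "T") && x[5] %in% c("A", "C", "G", "T")
    }, logical(1))
    n_skip <- sum(!ok)
    f <- f[ok]
    keep <- body[ok]
  } else {
    f <- list()
  }
  if (n_skip) log_msg(sprintf("read_vcf_genotypes: skipped %d non-biallelic-SNP record(s)", n_skip))
  if (!length(f)) {
    sites <- data.frame(chrom = character(0), pos = numeric(0), id = character(0),
                        ref = character(0), alt = character(0), qual = character(0),
                        filter = character(0), info = character(0),
                        stringsAsFactors = FALSE)
    gt <- matrix(character(0), 0, length(samples))
  } else {
    m <- do.call(rbind, f)
    sites <- data.frame(chrom = m[, 1], pos = as.numeric(m[, 2]) - 1,
                        id = m[, 3], ref = m[, 4], alt = m[, 5], qual = m[, 6],
                        filter = m[, 7], info = m[, 8], stringsAsFactors = FALSE)
    gt <- m[, -(1:9), drop = FALSE]
  }
  panel <- snp_panel(sites, gt, samples, populations = populations,
                     ploidy = ploidy)
  panel$n_skipped <- n_skip
  log_msg(sprintf("read_vcf_genotypes: %d SNP site(s), %d sample(s)",
                  nrow(sites), length(samples)))
  panel
}

#' Write a SNP panel as VCF
#'
#' Emits the records exactly as stored (GT strings untouched), so a
#' read -> write cycle is byte-stable on the retained body lines.
#'
#' @param panel an [snp_panel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  s <- panel$sites
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$samples), collapse = "\t"))
  if (nrow(s)) {
    fixed <- paste(s$chrom, format(s$pos + 1, scientific = FALSE, trim = TRUE),
                   s$id, s$ref, s$alt, s$qual, s$filter, s$info, "GT",
                   sep = "\t")
    gtcol <- apply(panel$gt, 1, paste, collapse = "\t")
    body <- paste(fixed, gtcol, sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a population assignment table
#'
#' TSV with header columns `accession_id` and `population`.
#'
#' @param path file path.
#' @return data.frame(accession_id, population).
#' @export
read_populations <- function(path) {
  if (!file.exists(path)) stop("population file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession_id", "population") %in% names(df)))
    stop("population file needs accession_id and population columns")
  if (anyDuplicated(df$accession_id)) stop("duplicate accession_id")
  df[, c("accession_id", "population")]
}

#' @rdname read_populations
#' @param populations data.frame to write.
#' @export
write_populations <- function(populations, path) {
  utils::write.table(populations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
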