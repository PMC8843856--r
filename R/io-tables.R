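#' Polymorphic TE genotype matrix
#'
#' Presence/absence genotypes of polymorphic TE insertion loci. TE presence is
#' a dominant per-accession marker (carrier / non-carrier); NA marks a locus
#' not genotyped in that accession and is excluded from both numerator and
#' denominator of frequency calculations.
#'
#' @param loci data.frame with columns chrom, start, end, strand, locus_id and
#'   optionally superfamily, genic_category.
#' @param geno integer matrix, accessions x loci, values in \{0, 1, NA\};
#'   column names = locus ids, row names = accession ids.
#' @param populations optional data.frame(accession_id, population).
#' @return an object of class `te_genotype_matrix`.
#' @export
te_genotype_matrix <- function(loci, geno, populations = NULL) {
  stopifnot(all(c("chrom", "start", "end", "locus_id") %in% names(loci)))
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_id")
  if (ncol(geno) != nrow(loci)) stop("geno/loci dimension mismatch")
  if (is.null(colnames(geno))) colnames(geno) <- loci$locus_id
  if (!identical(colnames(geno), loci$locus_id))
    geno <- geno[, loci$locus_id, drop = FALSE]
  if (is.null(rownames(geno))) stop("geno needs accession row names")
  if (!all(geno %in% c(0L, 1L, NA))) stop("geno values must be 0, 1 or NA")
  if (!is.null(populations)) {
    check_populations(populations, rownames(geno))
  }
  if (!"superfamily" %in% names(loci)) loci$superfamily <- "other"
  if (!"strand" %in% names(loci)) loci$strand <- "."
  structure(list(loci = loci, geno = geno, populations = populations),
            class = "te_genotype_matrix")
}

#' Read a polymorphic TE genotype matrix
#'
#' Joins a BED6(+superfamily) file of TE loci with a TSV of presence codes.
#' The TSV has a `locus_id` column followed by one column per accession with
#' values 0, 1 or NA; row order is immaterial (the join is on locus id).
#'
#' @param bed_path BED file of TE loci (name column = locus id).
#' @param tsv_path genotype TSV.
#' @param populations optional data.frame(accession_id, population).
#' @return a [te_genotype_matrix].
#' @export
read_te_matrix <- function(bed_path, tsv_path, populations = NULL) {
  te <- read_te_annotations(bed_path)
  names(te)[names(te) == "te_id"] <- "locus_id"
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!nrow(tab)) stop("no genotype rows in ", tsv_path)
  if (names(tab)[1] != "locus_id") stop("first TSV column must be locus_id")
  unknown <- setdiff(tab$locus_id, te$locus_id)
  if (length(unknown))
    stop("locus id(s) in TSV absent from BED: ", paste(unknown, collapse = ", "))
  tab <- tab[match(te$locus_id, tab$locus_id), , drop = FALSE]
  if (anyNA(tab$locus_id)) {
    te <- te[te$locus_id %in% tab$locus_id, , drop = FALSE]
    tab <- tab[!is.na(tab$locus_id), , drop = FALSE]
  }
  geno <- t(as.matrix(tab[, -1, drop = FALSE]))
  storage.mode(geno) <- "integer"
  colnames(geno) <- tab$locus_id
  te_genotype_matrix(te, geno, populations = populations)
}

#' Write a TE genotype matrix as BED + TSV
#'
#' @param tem a [te_genotype_matrix].
#' @param bed_path,tsv_path output paths.
#' @return invisibly, the two paths.
#' @export
write_te_matrix <- function(tem, bed_path, tsv_path) {
  bed <- data.frame(chrom = tem$loci$chrom, start = tem$loci$start,
                    end = tem$loci$end, name = tem$loci$locus_id,
                    score = 0, strand = tem$loci$strand,
                    superfamily = tem$loci$superfamily)
  write_bed(bed, bed_path)
  tab <- data.frame(locus_id = tem$loci$locus_id,
                    t(tem$geno), check.names = FALSE)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed_path, tsv_path))
}

#' Gene expression table (FPKM per gene x timepoint)
#'
#' @param fpkm numeric matrix, genes x timepoints; row names = gene ids,
#'   column names = timepoint labels.
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm))) stop("fpkm needs gene-id row names")
  if (anyDuplicated(rownames(fpkm))) stop("duplicate gene ids")
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM must be >= 0")
  structure(list(fpkm = fpkm, gene_ids = rownames(fpkm),
                 timepoints = colnames(fpkm)),
            class = "expression_table")
}

#' Read / write an expression table
#'
#' TSV with a `gene_id` column followed by one numeric column per timepoint.
#'
#' @param path file path.
#' @return an [expression_table].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_table(m)
}

#' @rdname read_expression
#' @param expr an [expression_table].
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = expr$gene_ids, expr$fpkm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
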