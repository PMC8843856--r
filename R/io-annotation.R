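# BED / GFF3 boundary. BED is already 0-based half-open and passes through;
# GFF3 (1-based closed) is converted on read/write. GFF3 parsing itself is
# delegated to rtracklayer; gene-model assembly (parent links, UTR derivation,
# introns) is done here.

#' Read a BED file (3-7 columns)
#'
#' Columns beyond the sixth are read into a `superfamily` column when present
#' (the convention used for TE annotation BEDs).
#'
#' @param path file path.
#' @return data.frame(chrom, start, end, name, score, strand[, superfamily]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand", "superfamily")
  names(df) <- cols[seq_len(min(ncol(df), 7))]
  if (!"name" %in% names(df)) df$name <- paste0("feat", seq_len(nrow(df)))
  if (!"score" %in% names(df)) df$score <- "."
  if (!"strand" %in% names(df)) df$strand <- "."
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid BED intervals (need 0 <= start < end)")
  df
}

#' Write a BED file
#'
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand, superfamily (written in that order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand",
                      "superfamily"), names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TE annotations from BED
#'
#' BED6+1: name = te_id, optional seventh column = superfamily (one of Gypsy,
#' Copia, other-LTR, Helitron, other-DNA, other; anything else is mapped to
#' "other" with a log note).
#'
#' @param path BED file.
#' @return data.frame(chrom, start, end, strand, te_id, superfamily).
#' @export
read_te_annotations <- function(path) {
  df <- read_bed(path)
  if (!"superfamily" %in% names(df)) df$superfamily <- "other"
  bad <- !df$superfamily %in% te_superfamilies()
  if (any(bad)) {
    log_msg(sprintf("read_te_annotations: %d unknown superfamily label(s) mapped to 'other'", sum(bad)))
    df$superfamily[bad] <- "other"
  }
  if (anyDuplicated(df$name)) stop("duplicate te_id in TE BED")
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             strand = df$strand, te_id = df$name,
             superfamily = df$superfamily, stringsAsFactors = FALSE)
}

#' Closed vocabulary of TE superfamily labels
#' @return character vector.
#' @export
te_superfamilies <- function() {
  c("Gypsy", "Copia", "other-LTR", "Helitron", "other-DNA", "other")
}

# ---- GFF3 gene models -------------------------------------------------------

#' Read gene models from GFF3
#'
#' Parses gene / mRNA / exon / CDS / UTR features (via rtracklayer), resolves
#' parent-child links, converts to 0-based half-open coordinates, derives
#' 5'/3' UTRs from exon minus CDS where not explicit, and derives introns.
#' Children whose parent cannot be resolved are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return a `gene_models` object: list with data.frames `genes`
#'   (chrom, start, end, strand, gene_id) and `features`
#'   (chrom, start, end, strand, type, gene_id, tx_id) where type is one of
#'   exon, CDS, five_prime_UTR, three_prime_UTR, intron.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- iv0_from_gr(gr)
  df$type <- as.character(df$type)
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  genes_i <- which(df$type == "gene")
  genes <- data.frame(chrom = df$chrom[genes_i], start = df$start[genes_i],
                      end = df$end[genes_i], strand = df$strand[genes_i],
                      gene_id = ids[genes_i], stringsAsFactors = FALSE)
  tx_i <- which(df$type %in% c("mRNA", "transcript"))
  tx_gene <- parent[tx_i]
  bad_tx <- !(tx_gene %in% genes$gene_id)
  if (any(bad_tx)) {
    warning(sprintf("%d transcript(s) with unresolvable gene parent skipped", sum(bad_tx)))
    tx_i <- tx_i[!bad_tx]; tx_gene <- tx_gene[!bad_tx]
  }
  tx_ids <- ids[tx_i]
  tx_map <- stats::setNames(tx_gene, tx_ids)
  child_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  ch_i <- which(df$type %in% child_types)
  ch_par <- parent[ch_i]
  bad_ch <- !(ch_par %in% tx_ids)
  if (any(bad_ch)) {
    warning(sprintf("%d feature(s) with unresolvable parent skipped", sum(bad_ch)))
    ch_i <- ch_i[!bad_ch]; ch_par <- ch_par[!bad_ch]
  }
  feats <- data.frame(chrom = df$chrom[ch_i], start = df$start[ch_i],
                      end = df$end[ch_i], strand = df$strand[ch_i],
                      type = df$type[ch_i], tx_id = ch_par,
                      gene_id = unname(tx_map[ch_par]),
                      stringsAsFactors = FALSE)
  gene_models(genes, feats)
}

#' Assemble a gene_models object
#'
#' Derives UTRs (exon set-minus CDS, split 5'/3' by strand) for transcripts
#' with CDS but no explicit UTR features, and introns (transcript span minus
#' exons).
#'
#' @param genes data.frame(chrom, start, end, strand, gene_id).
#' @param features data.frame(chrom, start, end, strand, type, gene_id, tx_id).
#' @return a `gene_models` object.
#' @export
gene_models <- function(genes, features) {
  stopifnot(all(c("gene_id") %in% names(genes)))
  out <- list()
  for (tx in unique(features$tx_id)) {
    f <- features[features$tx_id == tx, , drop = FALSE]
    strand <- f$strand[1]; chrom <- f$chrom[1]; gid <- f$gene_id[1]
    ex <- f[f$type == "exon", , drop = FALSE]
    cds <- f[f$type == "CDS", , drop = FALSE]
    utr <- f[f$type %in% c("five_prime_UTR", "three_prime_UTR"), , drop = FALSE]
    keep <- f
    if (nrow(cds) && !nrow(utr) && nrow(ex)) {
      diff <- iv0_subtract(ex[, c("start", "end")], cds[, c("start", "end")])
      if (nrow(diff)) {
        cds_lo <- min(cds$start); cds_hi <- max(cds$end)
        d <- data.frame(chrom = chrom, start = diff$start, end = diff$end,
                        strand = strand, stringsAsFactors = FALSE)
        five_side <- if (strand == "-") d$start >= cds_hi else d$end <= cds_lo
        d$type <- ifelse(five_side, "five_prime_UTR", "three_prime_UTR")
        d$tx_id <- tx; d$gene_id <- gid
        keep <- rbind(keep, d[, names(features)])
      }
    }
    if (nrow(ex) > 1) {
      span <- data.frame(start = min(ex$start), end = max(ex$end))
      introns <- iv0_subtract(span, ex[, c("start", "end")])
      if (nrow(introns)) {
        d <- data.frame(chrom = chrom, start = introns$start,
                        end = introns$end, strand = strand,
                        type = "intron", tx_id = tx, gene_id = gid,
                        stringsAsFactors = FALSE)
        keep <- rbind(keep, d[, names(features)])
      }
    }
    out[[tx]] <- keep
  }
  features <- if (length(out)) do.call(rbind, out) else features
  rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

# GRanges accessors on gene models
gm_gr <- function(gm, type = NULL) {
  if (is.null(type)) return(gr_from_iv0(gm$genes))
  f <- gm$features[gm$features$type %in% type, , drop = FALSE]
  gr_from_iv0(f)
}

# start/stop codon anchor positions (0-based point just at CDS boundary),
# strand-aware; falls back to the gene span when no CDS is annotated.
gene_codon_anchors <- function(gm) {
  g <- gm$genes
  cds <- gm$features[gm$features$type == "CDS", , drop = FALSE]
  start_anchor <- numeric(nrow(g)); stop_anchor <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    ci <- cds[cds$gene_id == g$gene_id[i], , drop = FALSE]
    lo <- if (nrow(ci)) min(ci$start) else g$start[i]
    hi <- if (nrow(ci)) max(ci$end) else g$end[i]
    if (g$strand[i] == "-") { start_anchor[i] <- hi; stop_anchor[i] <- lo }
    else { start_anchor[i] <- lo; stop_anchor[i] <- hi }
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             gene_start = g$start, gene_end = g$end,
             start_anchor = start_anchor, stop_anchor = stop_anchor,
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Canonical, deterministic layout (gene, its mRNA, then child features sorted
#' by start and type), so write -> read -> write is byte-stable.
#'
#' @param gm a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gm, path) {
  lines <- "##gff-version 3"
  g <- gm$genes[order(gm$genes$chrom, gm$genes$start), , drop = FALSE]
  type_order <- c(exon = 1, CDS = 2, five_prime_UTR = 3, three_prime_UTR = 4,
                  intron = 5)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, gff_line(g$chrom[i], "gene", g$start[i], g$end[i],
                               g$strand[i], sprintf("ID=%s", gid)))
    f <- gm$features[gm$features$gene_id == gid, , drop = FALSE]
    for (tx in unique(f$tx_id)) {
      ft <- f[f$tx_id == tx & f$type != "intron", , drop = FALSE]
      lines <- c(lines, gff_line(g$chrom[i], "mRNA", min(ft$start), max(ft$end),
                                 g$strand[i], sprintf("ID=%s;Parent=%s", tx, gid)))
      ft <- ft[order(ft$start, type_order[ft$type]), , drop = FALSE]
      for (j in seq_len(nrow(ft))) {
        lines <- c(lines, gff_line(ft$chrom[j], ft$type[j], ft$start[j],
                                   ft$end[j], ft$strand[j],
                                   sprintf("ID=%s.%s%d;Parent=%s", tx,
                                           tolower(substr(ft$type[j], 1, 3)), j, tx)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gff_line <- function(chrom, type, start0, end, strand, attrs) {
  paste(chrom, "tepop", type,
        format(start0 + 1, scientific = FALSE, trim = TRUE),
        format(end, scientific = FALSE, trim = TRUE),
        ".", strand, ".", attrs, sep = "\t")
}
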