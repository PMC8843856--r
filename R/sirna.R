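# 24-nt siRNA locus construction: overlapping-read connected components with
# a minimum coverage, merged across gaps of at most merge_bp, then TE
# labelling by >= 1-bp overlap. "Matched" is genomic-interval overlap; the
# gap is measured between cluster bounding intervals, boundary inclusive
# (a gap of exactly merge_bp merges).

#' Call candidate 24-nt siRNA clusters from read placements
#'
#' Reads that are not exactly 24 bp are dropped with a logged count.
#' Overlapping reads (>= 1 bp; mere adjacency does not connect) form
#' connected components; components with fewer than `min_reads` reads are
#' discarded.
#'
#' @param reads data.frame(chrom, start, end, ...) of read placements.
#' @param min_reads minimum coverage per cluster.
#' @return data.frame(chrom, start, end, read_count), sorted.
#' @export
call_clusters <- function(reads, min_reads = 10) {
  is24 <- (reads$end - reads$start) == 24
  if (any(!is24))
    log_msg(sprintf("call_clusters: dropped %d non-24-nt read(s)", sum(!is24)))
  reads <- reads[is24, , drop = FALSE]
  if (!nrow(reads))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), read_count = integer(0)))
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start + 1, reads$end))
  comp <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  cnt <- GenomicRanges::countOverlaps(comp, gr)
  keep <- cnt >= min_reads
  comp <- comp[keep]
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(comp)),
                    start = GenomicRanges::start(comp) - 1,
                    end = GenomicRanges::end(comp),
                    read_count = cnt[keep], stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Merge siRNA clusters into loci
#'
#' Single linear pass per chromosome: any two clusters whose edge-to-edge gap
#' is <= `merge_bp` are merged (transitively). Idempotent.
#'
#' @param clusters data.frame(chrom, start, end, read_count).
#' @param merge_bp maximum merged gap (bp).
#' @return data.frame(chrom, start, end, n_clusters, total_reads), sorted;
#'   successive loci are separated by more than `merge_bp`.
#' @export
merge_loci <- function(clusters, merge_bp = 150) {
  if (!nrow(clusters))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_clusters = integer(0),
                      total_reads = integer(0)))
  if (!"read_count" %in% names(clusters)) clusters$read_count <- 1L
  cl <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
  new_locus <- c(TRUE, cl$chrom[-1] != cl$chrom[-nrow(cl)] |
                   cl$start[-1] - cummax_by(cl$end, cl$chrom)[-nrow(cl)] > merge_bp)
  grp <- cumsum(new_locus)
  idx <- split(seq_len(nrow(cl)), factor(grp, levels = unique(grp)))
  out <- data.frame(
    chrom = vapply(idx, function(i) cl$chrom[i[1]], character(1)),
    start = vapply(idx, function(i) min(cl$start[i]), numeric(1)),
    end = vapply(idx, function(i) max(cl$end[i]), numeric(1)),
    n_clusters = vapply(idx, length, integer(1)),
    total_reads = vapply(idx, function(i) as.integer(sum(cl$read_count[i])),
                         integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# running maximum of end coordinates within each chromosome block (handles
# clusters nested in a predecessor)
cummax_by <- function(x, g) {
  out <- numeric(length(x))
  cur_g <- NULL; cur <- -Inf
  for (i in seq_along(x)) {
    if (!identical(g[i], cur_g)) { cur_g <- g[i]; cur <- -Inf }
    cur <- max(cur, x[i])
    out[i] <- cur
  }
  out
}

#' Label TEs as siRNA+ / siRNA-
#'
#' A TE is siRNA+ iff it overlaps (>= 1 bp) at least one siRNA locus.
#'
#' @param tes TE annotation data.frame (chrom, start, end, te_id).
#' @param loci siRNA locus data.frame (chrom, start, end).
#' @return data.frame(te_id, sirna) with sirna in \{"siRNA+", "siRNA-"\}.
#' @export
label_tes <- function(tes, loci) {
  lab <- rep("siRNA-", nrow(tes))
  if (nrow(loci)) {
    te_gr <- GenomicRanges::GRanges(tes$chrom,
                                    IRanges::IRanges(tes$start + 1, tes$end))
    lo_gr <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$start + 1, loci$end))
    hit <- GenomicRanges::countOverlaps(te_gr, lo_gr) > 0
    lab[hit] <- "siRNA+"
  }
  data.frame(te_id = tes$te_id, sirna = lab, stringsAsFactors = FALSE)
}
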