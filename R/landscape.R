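# Genic-landscape classification of TE insertions: category assignment with
# coding-most precedence, flank-bin profiles around start/stop codons, and
# covered-bp feature density per genomic window.

genic_categories <- function() {
  c("CDS", "five_prime_UTR", "three_prime_UTR", "intron", "promoter2kb",
    "downstream2kb", "intergenic")
}

# promoter/downstream flank intervals per gene, strand-aware
gene_flank_intervals <- function(gm, flank_bp = 2000,
                                 promoter_from = c("tss", "start_codon")) {
  promoter_from <- match.arg(promoter_from)
  g <- gm$genes
  anc <- gene_codon_anchors(gm)
  plus <- g$strand != "-"
  p_anchor <- if (promoter_from == "tss")
    ifelse(plus, g$start, g$end) else
    ifelse(plus, anc$start_anchor, anc$start_anchor)
  prom <- data.frame(
    chrom = g$chrom,
    start = pmax(0, ifelse(plus, p_anchor - flank_bp, p_anchor)),
    end = ifelse(plus, p_anchor, p_anchor + flank_bp),
    strand = g$strand, gene_id = g$gene_id, stringsAsFactors = FALSE)
  down <- data.frame(
    chrom = g$chrom,
    start = pmax(0, ifelse(plus, g$end, g$start - flank_bp)),
    end = ifelse(plus, g$end + flank_bp, g$start),
    strand = g$strand, gene_id = g$gene_id, stringsAsFactors = FALSE)
  list(promoter2kb = prom[prom$start < prom$end, , drop = FALSE],
       downstream2kb = down[down$start < down$end, , drop = FALSE])
}

#' Classify TE insertions into genic-region categories
#'
#' Assigns exactly one category per TE by >= 1-bp overlap, with coding-most
#' precedence CDS > 5'UTR > 3'UTR > intron > promoter2kb (2-kb upstream of
#' the TSS, strand-aware) > downstream2kb (2-kb past the transcript end) >
#' intergenic. A TE overlapping features of two genes within the winning
#' category goes to the gene with the larger overlap, ties to the smaller
#' start coordinate.
#'
#' @param tes TE annotation data.frame (chrom, start, end, te_id, ...).
#' @param genes a `gene_models` object.
#' @param flank_bp promoter/downstream flank width.
#' @param promoter_from measure the promoter flank from the "tss" (default)
#'   or from the "start_codon".
#' @return data.frame(te_id, category, gene_id).
#' @export
classify_genic_region <- function(tes, genes, flank_bp = 2000,
                                  promoter_from = c("tss", "start_codon")) {
  promoter_from <- match.arg(promoter_from)
  flanks <- gene_flank_intervals(genes, flank_bp, promoter_from)
  cat_feats <- list(
    CDS = genes$features[genes$features$type == "CDS", , drop = FALSE],
    five_prime_UTR = genes$features[genes$features$type == "five_prime_UTR", , drop = FALSE],
    three_prime_UTR = genes$features[genes$features$type == "three_prime_UTR", , drop = FALSE],
    intron = genes$features[genes$features$type == "intron", , drop = FALSE],
    promoter2kb = flanks$promoter2kb,
    downstream2kb = flanks$downstream2kb)
  out <- data.frame(te_id = tes$te_id, category = "intergenic",
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  assigned <- rep(FALSE, nrow(tes))
  for (cat in names(cat_feats)) {
    f <- cat_feats[[cat]]
    if (!nrow(f)) next
    todo <- which(!assigned)
    if (!length(todo)) break
    for (i in todo) {
      on <- f$chrom == tes$chrom[i] & f$start < tes$end[i] & f$end > tes$start[i]
      if (!any(on)) next
      fo <- f[on, , drop = FALSE]
      ow <- pmin(fo$end, tes$end[i]) - pmax(fo$start, tes$start[i])
      per_gene <- tapply(ow, fo$gene_id, sum)
      gstart <- tapply(fo$start, fo$gene_id, min)
      best <- names(per_gene)[order(-per_gene, gstart)][1]
      out$category[i] <- cat
      out$gene_id[i] <- best
      assigned[i] <- TRUE
    }
  }
  out
}

#' TE counts in distance bins flanking start/stop codons
#'
#' For each TE whose nearest gene places it entirely upstream of the start
#' codon or downstream of the stop codon (strand-aware) and within
#' `flank_bp`, the distance from the TE's nearest edge to the codon is
#' binned. The outer boundary is half-open: a TE exactly `flank_bp` away is
#' excluded.
#'
#' @param tes TE annotation data.frame.
#' @param genes a `gene_models` object.
#' @param bin_bp bin width; must divide `flank_bp`.
#' @param flank_bp flank width per side.
#' @return data.frame(side, bin_lo, bin_hi, count) for both sides.
#' @export
flank_bin_profile <- function(tes, genes, bin_bp = 100, flank_bp = 2000) {
  if (flank_bp %% bin_bp != 0) stop("bin_bp must divide flank_bp")
  anc <- gene_codon_anchors(genes)
  n_bins <- flank_bp %/% bin_bp
  up <- integer(n_bins); down <- integer(n_bins)
  for (i in seq_len(nrow(tes))) {
    a <- anc[anc$chrom == tes$chrom[i], , drop = FALSE]
    if (!nrow(a)) next
    plus <- a$strand != "-"
    d_up <- ifelse(plus, a$start_anchor - tes$end[i],
                   tes$start[i] - a$start_anchor)
    d_down <- ifelse(plus, tes$start[i] - a$stop_anchor,
                     a$stop_anchor - tes$end[i])
    d_up[d_up < 0] <- NA; d_down[d_down < 0] <- NA
    d_best <- pmin(d_up, d_down, na.rm = TRUE)
    d_best[is.infinite(d_best)] <- NA
    if (all(is.na(d_best))) next
    j <- which.min(d_best)
    d <- d_best[j]
    if (is.na(d) || d >= flank_bp) next
    b <- d %/% bin_bp + 1L
    if (!is.na(d_up[j]) && d == d_up[j]) up[b] <- up[b] + 1L
    else down[b] <- down[b] + 1L
  }
  lo <- (seq_len(n_bins) - 1L) * bin_bp
  rbind(data.frame(side = "upstream", bin_lo = lo, bin_hi = lo + bin_bp,
                   count = up),
        data.frame(side = "downstream", bin_lo = lo, bin_hi = lo + bin_bp,
                   count = down))
}

#' Covered-bp feature density per genomic window
#'
#' Features are merged to a non-overlapping cover first, so overlapping
#' intervals are counted once; density = covered bp / window_bp, in [0, 1].
#'
#' @param features data.frame(chrom, start, end).
#' @param window_bp window size (default 100 kb).
#' @param chrom_lengths optional named vector; defaults to the last covered
#'   position rounded up to a full window.
#' @return data.frame(chrom, start, end, density).
#' @export
window_density <- function(features, window_bp = 100000,
                           chrom_lengths = NULL) {
  out <- list()
  chroms <- if (is.null(chrom_lengths)) unique(features$chrom)
            else names(chrom_lengths)
  for (chrom in chroms) {
    f <- features[features$chrom == chrom, , drop = FALSE]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]]
           else max(f$end)
    n_win <- max(1, ceiling(len / window_bp))
    cov <- numeric(n_win)
    if (nrow(f)) {
      ir <- IRanges::reduce(IRanges::IRanges(f$start + 1, f$end))
      ms <- IRanges::start(ir) - 1; me <- IRanges::end(ir)
      for (w in seq_len(n_win)) {
        w0 <- (w - 1) * window_bp; w1 <- w0 + window_bp
        cov[w] <- sum(pmax(0, pmin(me, w1) - pmax(ms, w0)))
      }
    }
    out[[chrom]] <- data.frame(chrom = chrom,
                               start = (seq_len(n_win) - 1) * window_bp,
                               end = seq_len(n_win) * window_bp,
                               density = cov / window_bp,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed distance from each TE to its nearest gene
#'
#' 0 when the TE overlaps the gene body; otherwise the gap in bp to the gene
#' (or to the nearer start/stop codon with `anchor = "codon"`), with sign
#' upstream(-) / downstream(+) relative to the gene's strand.
#'
#' @param tes TE annotation data.frame.
#' @param genes a `gene_models` object.
#' @param anchor "gene" (gene-body edges, default) or "codon".
#' @return data.frame(te_id, distance, gene_id); distance NA (flagged in a
#'   log message) for chromosomes without genes.
#' @export
nearest_gene_distance <- function(tes, genes, anchor = c("gene", "codon")) {
  anchor <- match.arg(anchor)
  anc <- gene_codon_anchors(genes)
  res <- data.frame(te_id = tes$te_id, distance = NA_real_,
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tes))) {
    a <- anc[anc$chrom == tes$chrom[i], , drop = FALSE]
    if (!nrow(a)) next
    ov <- a$gene_start < tes$end[i] & a$gene_end > tes$start[i]
    if (any(ov)) {
      ao <- a[ov, , drop = FALSE]
      w <- pmin(ao$gene_end, tes$end[i]) - pmax(ao$gene_start, tes$start[i])
      best <- order(-w, ao$gene_start)[1]
      res$distance[i] <- 0
      res$gene_id[i] <- ao$gene_id[best]
      next
    }
    plus <- a$strand != "-"
    if (anchor == "gene") {
      left <- a$gene_start - tes$end[i]   # TE entirely left of gene
      right <- tes$start[i] - a$gene_end  # TE entirely right of gene
      gap <- pmax(left, right)
      upstream <- ifelse(plus, left >= 0, right >= 0)
    } else {
      d_start <- ifelse(plus, a$start_anchor - tes$end[i],
                        tes$start[i] - a$start_anchor)
      d_stop <- ifelse(plus, tes$start[i] - a$stop_anchor,
                       a$stop_anchor - tes$end[i])
      gap <- pmin(ifelse(d_start >= 0, d_start, Inf),
                  ifelse(d_stop >= 0, d_stop, Inf))
      upstream <- is.finite(gap) & gap == ifelse(d_start >= 0, d_start, Inf)
    }
    ok <- is.finite(gap) & gap >= 0
    if (!any(ok)) next
    j <- which(ok)[order(gap[ok], a$gene_start[ok])][1]
    res$distance[i] <- if (upstream[j]) -gap[j] else gap[j]
    res$gene_id[i] <- a$gene_id[j]
  }
  if (anyNA(res$distance))
    log_msg(sprintf("nearest_gene_distance: %d TE(s) without a same-chromosome gene",
                    sum(is.na(res$distance))))
  res
}
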