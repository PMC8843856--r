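# TE-proximity gene-expression analysis: nearest-TE distances (0 = TE within
# the gene body, i.e. intron or UTR), binned mean FPKM, siRNA+/- stratified
# contrasts per distance bin, and timepoint contrasts.

#' Distance from each gene to its nearest TE
#'
#' 0 when a TE overlaps the gene's transcribed region (gene body: union of
#' exons and introns); otherwise the minimum edge gap to any TE on the same
#' chromosome. Genes on chromosomes without TEs get NA and are logged.
#'
#' @param genes a `gene_models` object.
#' @param tes TE annotation data.frame (chrom, start, end, te_id).
#' @return data.frame(gene_id, distance, te_id).
#' @export
nearest_te_distance <- function(genes, tes) {
  g <- genes$genes
  res <- data.frame(gene_id = g$gene_id, distance = NA_real_,
                    te_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    t <- tes[tes$chrom == g$chrom[i], , drop = FALSE]
    if (!nrow(t)) next
    gap <- iv0_gap(g$start[i], g$end[i], t$start, t$end)
    j <- order(gap, t$start)[1]
    res$distance[i] <- gap[j]
    res$te_id[i] <- t$te_id[j]
  }
  if (anyNA(res$distance))
    log_msg(sprintf("nearest_te_distance: %d gene(s) without a same-chromosome TE excluded",
                    sum(is.na(res$distance))))
  res
}

#' Mean expression in TE-distance bins
#'
#' Bins tile [0, max_bp) in `bin_bp` steps; genes at distance >= `max_bp`
#' are pooled into a terminal open bin. Empty bins are reported with
#' n_genes = 0 and an undefined mean.
#'
#' @param distances data.frame(gene_id, distance) as from
#'   [nearest_te_distance]; NA distances are dropped.
#' @param expr an [expression_table].
#' @param timepoint column of `expr` to summarise.
#' @param bin_bp,max_bp bin width and last closed-bin boundary.
#' @param strata optional data.frame(gene_id, stratum) to also summarise per
#'   stratum (e.g. siRNA+/-).
#' @return data.frame(bin_lo, bin_hi, stratum, n_genes, mean_fpkm).
#' @export
bin_mean_expression <- function(distances, expr, timepoint, bin_bp = 500,
                                max_bp = 5000, strata = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  if (!timepoint %in% expr$timepoints)
    stop("timepoint not in expression table: ", timepoint)
  d <- distances[!is.na(distances$distance), , drop = FALSE]
  d <- d[d$gene_id %in% expr$gene_ids, , drop = FALSE]
  v <- expr$fpkm[d$gene_id, timepoint]
  lo <- seq(0, max_bp - bin_bp, by = bin_bp)
  hi <- c(lo[-1], max_bp)
  bins <- data.frame(bin_lo = c(lo, max_bp), bin_hi = c(hi, Inf))
  bin_of <- findInterval(d$distance, c(bins$bin_lo, Inf))
  strat_list <- list(all = seq_len(nrow(d)))
  if (!is.null(strata)) {
    s <- strata$stratum[match(d$gene_id, strata$gene_id)]
    for (lv in unique(stats::na.omit(s)))
      strat_list[[lv]] <- which(!is.na(s) & s == lv)
  }
  out <- list()
  for (sn in names(strat_list)) {
    sel <- strat_list[[sn]]
    n <- vapply(seq_len(nrow(bins)), function(b) sum(bin_of[sel] == b),
                integer(1))
    m <- vapply(seq_len(nrow(bins)), function(b) {
      x <- v[sel][bin_of[sel] == b]
      if (length(x)) mean(x) else NaN
    }, numeric(1))
    out[[sn]] <- data.frame(bins, stratum = sn, n_genes = n, mean_fpkm = m,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' siRNA+/- stratified expression contrast per distance bin
#'
#' Per bin, a two-sample location test between the FPKM of genes whose
#' nearest TE is siRNA+ and siRNA-, plus the ratio of stratum means. Bins
#' where either stratum has fewer than 2 genes are skipped with a flag.
#'
#' @param distances data.frame(gene_id, distance, te_id).
#' @param labels data.frame(te_id, sirna) from [label_tes].
#' @param expr an [expression_table].
#' @param timepoint expression column.
#' @param bin_bp,max_bp distance binning (1,000-bp bins by default).
#' @param test "t" (Student's t, equal variances) or "wilcox".
#' @param log2p1 apply log2(x+1) before testing.
#' @return data.frame(bin_lo, bin_hi, n_plus, n_minus, mean_plus, mean_minus,
#'   ratio, statistic, p_value, skipped).
#' @export
sirna_stratified_contrast <- function(distances, labels, expr, timepoint,
                                      bin_bp = 1000, max_bp = 5000,
                                      test = c("t", "wilcox"),
                                      log2p1 = FALSE) {
  test <- match.arg(test)
  stopifnot(inherits(expr, "expression_table"))
  d <- distances[!is.na(distances$distance), , drop = FALSE]
  d$sirna <- labels$sirna[match(d$te_id, labels$te_id)]
  d <- d[!is.na(d$sirna) & d$gene_id %in% expr$gene_ids, , drop = FALSE]
  v <- expr$fpkm[d$gene_id, timepoint]
  if (log2p1) v <- log2(v + 1)
  lo <- seq(0, max_bp - bin_bp, by = bin_bp)
  bins <- data.frame(bin_lo = c(lo, max_bp),
                     bin_hi = c(lo[-1], max_bp, Inf))
  bin_of <- findInterval(d$distance, c(bins$bin_lo, Inf))
  out <- lapply(seq_len(nrow(bins)), function(b) {
    xp <- v[bin_of == b & d$sirna == "siRNA+"]
    xm <- v[bin_of == b & d$sirna == "siRNA-"]
    r <- data.frame(bin_lo = bins$bin_lo[b], bin_hi = bins$bin_hi[b],
                    n_plus = length(xp), n_minus = length(xm),
                    mean_plus = if (length(xp)) mean(xp) else NaN,
                    mean_minus = if (length(xm)) mean(xm) else NaN,
                    ratio = NaN, statistic = NaN, p_value = NaN,
                    skipped = TRUE)
    if (length(xp) >= 2 && length(xm) >= 2) {
      r$ratio <- mean(xp) / mean(xm)
      tt <- if (test == "t")
        stats::t.test(xp, xm, var.equal = TRUE) else
        stats::wilcox.test(xp, xm, exact = FALSE)
      r$statistic <- unname(tt$statistic)
      r$p_value <- tt$p.value
      r$skipped <- FALSE
    }
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired timepoint contrast of expression
#'
#' Paired Student's t-test over the genes shared by two timepoints (the same
#' genes are measured at both, so pairing matches the design; set
#' `paired = FALSE` for the unpaired variant). When the per-gene differences
#' have zero variance the t statistic is undefined and p is reported as 1
#' for a zero mean difference and 0 otherwise.
#'
#' @param expr an [expression_table].
#' @param t_a,t_b timepoint labels.
#' @param paired paired test (default) or two-sample.
#' @return list(mean_diff, statistic, p_value, n, direction).
#' @export
timepoint_contrast <- function(expr, t_a, t_b, paired = TRUE) {
  stopifnot(inherits(expr, "expression_table"))
  for (t in c(t_a, t_b)) if (!t %in% expr$timepoints)
    stop("timepoint not present: ", t)
  a <- expr$fpkm[, t_a]; b <- expr$fpkm[, t_b]
  ok <- stats::complete.cases(a, b)
  if (sum(ok) != length(a))
    log_msg(sprintf("timepoint_contrast: intersecting to %d complete gene(s)", sum(ok)))
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("insufficient n for timepoint contrast")
  diffs <- b - a
  md <- mean(diffs)
  if (paired && stats::sd(diffs) == 0) {
    return(list(mean_diff = md, statistic = NaN,
                p_value = if (md == 0) 1 else 0, n = length(a),
                direction = sign(md)))
  }
  tt <- stats::t.test(b, a, paired = paired)
  list(mean_diff = md, statistic = unname(tt$statistic),
       p_value = tt$p.value, n = length(a), direction = sign(md))
}
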