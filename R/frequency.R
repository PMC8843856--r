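# Population-level TE insertion-frequency analysis: complete-case carrier
# frequencies, shared/specific classification, the low-frequency
# purifying-selection bias test (one-sided Fisher's exact vs the intergenic
# reference, Benjamini-Hochberg corrected), the frequency spectrum and
# superfamily composition, and the genetic-distance / shared-insertion
# correlation.

#' Per-locus TE insertion frequencies
#'
#' Complete-case carrier frequency (carriers / genotyped accessions; NA
#' genotypes excluded from numerator and denominator), overall and per
#' population. Loci genotyped in no accession are flagged undefined.
#'
#' @param tem a [te_genotype_matrix] with populations.
#' @return data.frame(locus_id, n_genotyped, freq, freq_<pop>..., defined).
#' @export
insertion_frequencies <- function(tem) {
  stopifnot(inherits(tem, "te_genotype_matrix"))
  g <- tem$geno
  pops <- tem$populations
  if (is.null(pops)) stop("population assignment required")
  n_gt <- colSums(!is.na(g))
  freq <- colSums(g == 1L, na.rm = TRUE) / n_gt
  freq[n_gt == 0] <- NaN
  out <- data.frame(locus_id = tem$loci$locus_id, n_genotyped = n_gt,
                    freq = freq, stringsAsFactors = FALSE)
  for (lb in sort(unique(pops$population))) {
    acc <- pops$accession_id[pops$population == lb]
    gp <- g[acc, , drop = FALSE]
    np <- colSums(!is.na(gp))
    fp <- colSums(gp == 1L, na.rm = TRUE) / np
    fp[np == 0] <- NaN
    out[[paste0("freq_", lb)]] <- fp
  }
  out$defined <- n_gt > 0
  if (any(!out$defined))
    log_msg(sprintf("insertion_frequencies: %d all-NA locus/loci flagged undefined",
                    sum(!out$defined)))
  rownames(out) <- NULL
  out
}

#' Classify loci as shared or population-specific
#'
#' pop-specific iff carrier frequency > 0 in exactly one population;
#' all-shared iff > 0 in every population; otherwise partial.
#'
#' @param freqs output of [insertion_frequencies].
#' @return list(records = freqs + sharing_class column,
#'   counts = per-class table).
#' @export
classify_sharing <- function(freqs) {
  fcols <- grep("^freq_", names(freqs), value = TRUE)
  if (length(fcols) < 2) stop(">=2 populations required")
  labs <- sub("^freq_", "", fcols)
  fm <- as.matrix(freqs[, fcols, drop = FALSE])
  pos <- !is.na(fm) & fm > 0
  n_pos <- rowSums(pos)
  cls <- rep("partial", nrow(freqs))
  cls[n_pos == length(fcols)] <- "all-shared"
  one <- which(n_pos == 1)
  cls[one] <- paste0("pop-specific:", labs[apply(pos[one, , drop = FALSE], 1,
                                                 which)])
  cls[n_pos == 0] <- "absent"
  rec <- freqs
  rec$sharing_class <- cls
  list(records = rec, counts = table(cls))
}

#' Low-frequency purifying-selection bias test
#'
#' For each genic category except the reference, a 2x2 table of
#' (low: freq <= threshold vs high) x (category vs reference) is tested with
#' a one-sided Fisher's exact test for enrichment of low-frequency insertions
#' in the category, Benjamini-Hochberg corrected across categories (Bonferroni
#' selectable). The reported odds ratio is the cross-product ratio.
#'
#' @param freqs output of [insertion_frequencies] (or records thereof).
#' @param categories named character vector locus_id -> genic category, or a
#'   `te_genotype_matrix` (its loci$genic_category is used).
#' @param threshold low-frequency cutoff (default 0.1, inclusive).
#' @param reference reference category (default "intergenic").
#' @param correction "BH" or "bonferroni".
#' @param alternative "greater" (low-frequency enrichment, default) or
#'   "two.sided".
#' @return data.frame(category, n_low, n_high, ref_low, ref_high, odds_ratio,
#'   p_value, p_adjusted, skipped).
#' @export
low_frequency_bias_test <- function(freqs, categories, threshold = 0.1,
                                    reference = "intergenic",
                                    correction = c("BH", "bonferroni"),
                                    alternative = c("greater", "two.sided")) {
  correction <- match.arg(correction)
  alternative <- match.arg(alternative)
  if (inherits(categories, "te_genotype_matrix"))
    categories <- stats::setNames(categories$loci$genic_category,
                                  categories$loci$locus_id)
  cat_of <- categories[freqs$locus_id]
  ok <- !is.na(freqs$freq) & !is.na(cat_of)
  f <- freqs$freq[ok]; cat_of <- cat_of[ok]
  low <- f <= threshold
  if (!sum(cat_of == reference)) stop("reference category not populated")
  ref_low <- sum(low & cat_of == reference)
  ref_high <- sum(!low & cat_of == reference)
  cats <- setdiff(unique(cat_of), reference)
  if (!length(cats)) {
    log_msg("low_frequency_bias_test: no non-reference category present")
    return(data.frame(category = character(0), n_low = integer(0),
                      n_high = integer(0), ref_low = integer(0),
                      ref_high = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      skipped = logical(0)))
  }
  rows <- lapply(cats, function(cc) {
    a <- sum(low & cat_of == cc); b <- sum(!low & cat_of == cc)
    r <- data.frame(category = cc, n_low = a, n_high = b,
                    ref_low = ref_low, ref_high = ref_high,
                    odds_ratio = NaN, p_value = NA_real_, skipped = TRUE,
                    stringsAsFactors = FALSE)
    if (a + b > 0) {
      r$odds_ratio <- (a * ref_high) / (b * ref_low)
      r$p_value <- fisher_low_high_p(a, b, ref_low, ref_high,
                                     alternative = alternative)
      r$skipped <- FALSE
    }
    r
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- NA_real_
  tested <- !res$skipped
  res$p_adjusted[tested] <- stats::p.adjust(res$p_value[tested],
                                            method = correction)
  res <- res[, c("category", "n_low", "n_high", "ref_low", "ref_high",
                 "odds_ratio", "p_value", "p_adjusted", "skipped")]
  rownames(res) <- NULL
  res
}

#' Fisher's exact p for a low/high x category/reference table
#'
#' The 2x2 table is rows (low, high) x columns (category, reference);
#' "greater" tests enrichment of low-frequency loci in the category.
#'
#' @param n_low,n_high low/high counts in the category.
#' @param ref_low,ref_high low/high counts in the reference.
#' @param alternative passed to [stats::fisher.test].
#' @return the p-value.
#' @export
fisher_low_high_p <- function(n_low, n_high, ref_low, ref_high,
                              alternative = "greater") {
  tab <- matrix(c(n_low, n_high, ref_low, ref_high), 2,
                dimnames = list(c("low", "high"), c("cat", "ref")))
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Frequency spectrum and superfamily composition by sharing class
#'
#' @param records records with sharing_class (from [classify_sharing]).
#' @param tem the [te_genotype_matrix] (for superfamily labels).
#' @param breaks frequency histogram breaks (default deciles of (0, 1]).
#' @return list(sfs = data.frame(bin_lo, bin_hi, count),
#'   composition = data.frame(group, superfamily, fraction)).
#' @export
sfs_and_composition <- function(records, tem, breaks = seq(0, 1, 0.1)) {
  f <- records$freq[!is.na(records$freq)]
  bin <- cut(f, breaks = breaks, include.lowest = TRUE, right = TRUE)
  sfs <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    count = as.integer(table(bin)))
  sf <- stats::setNames(tem$loci$superfamily, tem$loci$locus_id)
  grp <- list(all = records$locus_id,
              shared = records$locus_id[records$sharing_class == "all-shared"])
  for (cls in grep("^pop-specific:", unique(records$sharing_class),
                   value = TRUE))
    grp[[cls]] <- records$locus_id[records$sharing_class == cls]
  comp <- list()
  for (gn in names(grp)) {
    ids <- grp[[gn]]
    if (!length(ids)) next
    tab <- table(factor(sf[ids], levels = te_superfamilies()))
    comp[[gn]] <- data.frame(group = gn,
                             superfamily = names(tab),
                             fraction = as.numeric(tab) / length(ids),
                             stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, comp)
  rownames(comp) <- NULL
  list(sfs = sfs, composition = comp)
}

#' Correlation between genetic distance and shared TE insertions
#'
#' Pearson correlation over the upper-triangle accession pairs of two
#' symmetric matrices.
#'
#' @param genetic_distance,shared_te_counts symmetric matrices with the same
#'   accession order.
#' @return list(r, p_value, n_pairs).
#' @export
distance_sharing_correlation <- function(genetic_distance, shared_te_counts) {
  gd <- as.matrix(genetic_distance); st <- as.matrix(shared_te_counts)
  if (!all(dim(gd) == dim(st))) stop("matrix dimensions differ")
  ut <- upper.tri(gd)
  x <- gd[ut]; y <- st[ut]
  if (length(x) < 2) stop("insufficient accession pairs (need >= 2)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NaN, p_value = NaN, n_pairs = length(x)),
                     undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = length(x))
}

#' Pairwise shared-insertion counts between accessions
#'
#' Number of loci at which both accessions carry the insertion
#' (complete-case per pair of genotypes).
#'
#' @param tem a [te_genotype_matrix].
#' @return symmetric accession x accession matrix.
#' @export
shared_te_counts <- function(tem) {
  g <- tem$geno
  g[is.na(g)] <- 0L
  m <- g %*% t(g)
  diag(m) <- rowSums(tem$geno == 1L, na.rm = TRUE)
  m
}
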