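# Internal coordinate convention: 0-based, half-open [start, end), like BED.
# GFF3 (1-based, closed) and VCF POS (1-based) are converted at the boundary.
# GRanges objects are 1-based closed; gr_from_iv0 / iv0_from_gr convert.

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open, the convention used throughout the
#' package. Validity (0 <= start < end, non-empty chrom) is enforced.
#'
#' @param chrom chromosome identifiers.
#' @param start 0-based start positions.
#' @param end half-open end positions (exclusive).
#' @param strand "+", "-" or "." (unstranded). Recycled.
#' @param ... further per-interval columns (e.g. `name`).
#' @return a `data.frame` with columns chrom, start, end, strand and extras.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".", ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  strand <- rep_len(as.character(strand), length(chrom))
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  data.frame(chrom = chrom, start = start, end = end, strand = strand, ...,
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
gr_from_iv0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  str <- if ("strand" %in% names(df)) df$strand else "."
  str[str == "."] <- "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = str)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

# GRanges -> 0-based half-open data.frame
iv0_from_gr <- function(gr) {
  str <- as.character(GenomicRanges::strand(gr))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = str, stringsAsFactors = FALSE)
  m <- S4Vectors::mcols(gr)
  if (ncol(m)) df <- cbind(df, as.data.frame(m, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

# gap in bp between two half-open intervals on the same chrom; 0 if they
# overlap. [a1,a2) vs [b1,b2): gap = max(0, b1-a2, a1-b2).
iv0_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmax(b_start - a_end, a_start - b_end))
}

# set-subtract half-open intervals b from intervals a (both data.frames with
# start/end). a's intervals are assumed disjoint; b need not be.
iv0_subtract <- function(a, b) {
  b <- b[order(b$start), , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(a))) {
    cur <- a$start[i]; e <- a$end[i]
    for (j in seq_len(nrow(b))) {
      bs <- b$start[j]; be <- b$end[j]
      if (be <= cur || bs >= e) next
      if (bs > cur) res[[length(res) + 1L]] <- c(cur, bs)
      cur <- max(cur, be)
      if (cur >= e) break
    }
    if (cur < e) res[[length(res) + 1L]] <- c(cur, e)
  }
  if (!length(res)) return(data.frame(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}
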