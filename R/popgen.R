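# Windowed population-genetic statistics, implemented from first principles.
# pi (mean pairwise differences), Watterson's theta, Tajima's D, Hudson- and
# Weir-Cockerham-type Fst, and the reduction-of-diversity statistic
# ROD = 1 - pi_target/pi_ref. For a binary haplotype matrix the per-site
# identity sum_pairs Hamming / C(n,2) = sum_sites 2p(1-p) n/(n-1) is exact,
# so all statistics reduce to allele-count sums; the same count formulas apply
# to unphased diploid data with the two alleles per site treated as
# exchangeable (documented approximation).

#' Haplotype block
#'
#' A phased binary haplotype matrix for one genomic window, the substrate of
#' the diversity statistics. Monomorphic columns are pruned on construction.
#'
#' @param mat binary matrix, haplotypes x sites.
#' @param positions 0-based site positions within the chromosome (one per
#'   retained column).
#' @param chrom chromosome identifier.
#' @param window_start,window_end window bounds (0-based half-open). Defaults:
#'   0 and max(positions) + 1.
#' @param prune drop monomorphic columns (default). Set FALSE to retain them,
#'   e.g. for cross-population Fst where a site fixed within one population
#'   still differentiates it from the other; S always counts segregating
#'   columns only.
#' @return an object of class `haplotype_block` with elements mat, positions,
#'   window (chrom/start/end), n (haplotypes), S (segregating sites).
#' @export
haplotype_block <- function(mat, positions = NULL, chrom = "chr1",
                            window_start = 0, window_end = NULL,
                            prune = TRUE) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(positions)) positions <- seq_len(ncol(mat)) - 1
  if (length(positions) != ncol(mat)) stop("positions/column mismatch")
  cs <- colSums(mat)
  seg <- cs > 0 & cs < nrow(mat)
  if (prune) {
    mat <- mat[, seg, drop = FALSE]
    positions <- positions[seg]
    seg <- rep(TRUE, ncol(mat))
  }
  if (is.null(window_end))
    window_end <- if (length(positions)) max(positions) + 1 else window_start + 1
  structure(list(mat = mat, positions = positions,
                 window = list(chrom = chrom, start = window_start,
                               end = window_end),
                 n = nrow(mat), S = sum(seg)),
            class = "haplotype_block")
}

#' Nucleotide diversity pi of a haplotype block
#'
#' Average number of pairwise differences between any two sequences, computed
#' over all unordered haplotype pairs; also returned per bp of window length.
#'
#' @param block a [haplotype_block].
#' @return list(pi_raw, pi_bp).
#' @export
pairwise_pi <- function(block) {
  stopifnot(inherits(block, "haplotype_block"))
  n <- block$n
  if (n < 2) stop("pairwise_pi needs n >= 2 haplotypes")
  p <- colMeans(block$mat)
  pi_raw <- sum(2 * p * (1 - p)) * n / (n - 1)
  len <- block$window$end - block$window$start
  list(pi_raw = pi_raw, pi_bp = pi_raw / len)
}

#' Watterson's theta
#'
#' @param S segregating-site count.
#' @param n sample size (haplotypes).
#' @return S / a1(n) with a1 = sum_(i=1)^(n-1) 1/i.
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("watterson_theta needs n >= 2")
  S / sum(1 / seq_len(n - 1))
}

#' Constants of Tajima's neutrality test
#'
#' @param n sample size (haplotypes), n >= 2.
#' @return list(a1, a2, b1, b2, c1, c2, e1, e2).
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("tajima_constants needs n >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' D = (pi_raw - theta_W) / sqrt(e1 S + e2 S (S-1)). Undefined (NaN) when
#' S = 0; undefined with a warning when n < 4 (variance constants degenerate).
#'
#' @param block a [haplotype_block], or NULL when supplying summaries.
#' @param pi_raw,S,n optional pre-computed summaries (used when block is NULL).
#' @return scalar D, NaN when undefined.
#' @export
tajimas_d <- function(block = NULL, pi_raw = NULL, S = NULL, n = NULL) {
  if (!is.null(block)) {
    stopifnot(inherits(block, "haplotype_block"))
    n <- block$n; S <- block$S
    if (S == 0) return(NaN)
    pi_raw <- pairwise_pi(block)$pi_raw
  }
  if (S == 0) return(NaN)
  if (n < 4) {
    warning("Tajima's D undefined for n < 4")
    return(NaN)
  }
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  num <- pi_raw - S / k$a1
  if (denom == 0) return(NaN)
  if (abs(num) < 1e-12) return(0)
  num / denom
}

#' Pairwise Fst between two haplotype blocks
#'
#' Default Hudson-type ratio-of-averages estimator
#' Fst = (Hb - Hw) / Hb with Hw the mean of the two within-population pi per
#' site and Hb the mean cross-population pairwise difference per site.
#' Negative estimates are reported raw unless `clip = TRUE`. A
#' Weir-Cockerham-weighted estimator is selectable with `method = "wc"`.
#'
#' @param blockA,blockB [haplotype_block]s over the same positions.
#' @param method "hudson" or "wc".
#' @param clip clip negative estimates to zero.
#' @return scalar Fst; NaN (flagged via attribute "undefined") when there is
#'   no variation.
#' @export
pairwise_fst <- function(blockA, blockB, method = c("hudson", "wc"),
                         clip = FALSE) {
  method <- match.arg(method)
  # align on the union of positions; absent sites are monomorphic (freq 0)
  posA <- blockA$positions; posB <- blockB$positions
  pos <- sort(union(posA, posB))
  cA <- cB <- numeric(length(pos))
  cA[match(posA, pos)] <- colSums(blockA$mat)
  cB[match(posB, pos)] <- colSums(blockB$mat)
  fst_from_counts(cA, blockA$n, cB, blockB$n, method = method, clip = clip)
}

# Fst from per-site alternate counts and allele numbers (scalars or vectors)
fst_from_counts <- function(acA, anA, acB, anB, method = "hudson",
                            clip = FALSE) {
  anA <- rep_len(anA, length(acA)); anB <- rep_len(anB, length(acB))
  ok <- anA >= 2 & anB >= 2
  acA <- acA[ok]; anA <- anA[ok]; acB <- acB[ok]; anB <- anB[ok]
  if (!length(acA)) return(structure(NaN, undefined = TRUE))
  p1 <- acA / anA; p2 <- acB / anB
  if (method == "hudson") {
    hw <- (2 * p1 * (1 - p1) * anA / (anA - 1) +
           2 * p2 * (1 - p2) * anB / (anB - 1)) / 2
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    if (sum(hb) == 0) return(structure(NaN, undefined = TRUE))
    fst <- (sum(hb) - sum(hw)) / sum(hb)
  } else {
    # Weir & Cockerham (1984) for allele (haplotype-level) data, r = 2 demes
    n1 <- anA; n2 <- anB
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2)
    if (sum(a + b) == 0) return(structure(NaN, undefined = TRUE))
    fst <- sum(a) / sum(a + b)
  }
  if (clip) fst <- max(0, fst)
  fst
}

#' Reduction of diversity
#'
#' ROD = 1 - pi_target / pi_ref; near 1 when the target population has lost
#' diversity locally. Undefined (NaN, flagged) when pi_ref = 0.
#'
#' @param pi_target,pi_ref per-bp nucleotide diversity of the target and
#'   reference population.
#' @return scalar in (-Inf, 1].
#' @export
rod <- function(pi_target, pi_ref) {
  out <- 1 - pi_target / pi_ref
  out[pi_ref == 0] <- NaN
  if (any(pi_ref == 0)) attr(out, "undefined") <- TRUE
  out
}

# ---- windowed scan over a SNP panel ----------------------------------------

# per-population per-site alt counts / allele numbers for a panel
panel_pop_counts <- function(panel, populations = NULL) {
  pops <- populations %||% panel$populations
  if (is.null(pops)) stop("population assignment required")
  check_populations(pops, panel$samples)
  labs <- sort(unique(pops$population))
  out <- lapply(labs, function(lb) {
    acc <- pops$accession_id[pops$population == lb]
    idx <- match(acc, panel$samples)
    ac <- panel$ac[, idx, drop = FALSE]
    an <- panel$an[, idx, drop = FALSE]
    list(alt = rowSums(ac, na.rm = TRUE), an = rowSums(an))
  })
  names(out) <- labs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# diversity summaries from per-site alt counts / allele numbers
count_diversity <- function(alt, an) {
  ok <- an >= 2
  alt <- alt[ok]; an <- an[ok]
  seg <- alt > 0 & alt < an
  p <- alt / an
  pi_site <- 2 * p * (1 - p) * an / (an - 1)
  n_eff <- if (length(an)) max(an) else 0
  list(pi_raw = sum(pi_site), S = sum(seg), n = n_eff)
}

#' Windowed scan of population-genetic statistics
#'
#' Tiles each chromosome with windows starting at coordinate 0 (width
#' `window_bp`, step `step_bp`) and computes per-window, per-population pi,
#' Watterson's theta and Tajima's D, plus per-window Fst, per-bp pi of target
#' and reference, log pi-ratio and ROD for every ordered population pair.
#' Sites with minor allele frequency below `maf_min` (computed over all
#' samples) are excluded. Windows with no retained site are emitted with
#' undefined (NaN) statistics.
#'
#' @param panel an [snp_panel].
#' @param populations data.frame(accession_id, population); defaults to the
#'   panel's own assignment.
#' @param window_bp,step_bp window width and step in bp.
#' @param maf_min minor-allele-frequency cutoff.
#' @param fst_method "hudson" or "wc".
#' @return list(window_stats, pairwise_stats) of data.frames.
#' @export
windowed_scan <- function(panel, populations = NULL, window_bp = 5000,
                          step_bp = 5000, maf_min = 0.05,
                          fst_method = "hudson") {
  if (!nrow(panel$sites)) stop("empty genotype panel")
  if (window_bp < step_bp) stop("window_bp must be >= step_bp")
  pops <- populations %||% panel$populations
  if (is.null(pops)) stop("population assignment required")
  labs <- sort(unique(pops$population))
  cnt <- panel_pop_counts(panel, pops)
  alt_all <- rowSums(panel$ac, na.rm = TRUE)
  an_all <- rowSums(panel$an)
  p_all <- ifelse(an_all > 0, alt_all / an_all, 0)
  maf <- pmin(p_all, 1 - p_all)
  keep <- maf >= maf_min
  ws <- list(); ps <- list()
  for (chrom in unique(panel$sites$chrom)) {
    on_chr <- panel$sites$chrom == chrom & keep
    pos <- panel$sites$pos[on_chr]
    max_pos <- max(panel$sites$pos[panel$sites$chrom == chrom])
    starts <- seq(0, max(0, max_pos), by = step_bp)
    for (w0 in starts) {
      w1 <- w0 + window_bp
      in_w <- which(on_chr)[pos >= w0 & pos < w1]
      empty <- length(in_w) == 0
      for (lb in labs) {
        d <- count_diversity(cnt[[lb]]$alt[in_w], cnt[[lb]]$an[in_w])
        td <- if (!empty && d$S > 0 && d$n >= 4)
          tajimas_d(pi_raw = d$pi_raw, S = d$S, n = d$n) else NaN
        tw <- if (!empty && d$n >= 2) watterson_theta(d$S, d$n) else NaN
        pr <- if (empty) NaN else d$pi_raw
        ws[[length(ws) + 1L]] <- data.frame(
          chrom = chrom, start = w0, end = w1, population = lb,
          n_sites = d$S, pi_raw = pr, pi_bp = pr / window_bp,
          theta_w = tw, tajima_d = td, stringsAsFactors = FALSE)
      }
      for (t in labs) for (r in labs) {
        if (t == r) next
        dt <- count_diversity(cnt[[t]]$alt[in_w], cnt[[t]]$an[in_w])
        dr <- count_diversity(cnt[[r]]$alt[in_w], cnt[[r]]$an[in_w])
        fst <- fst_from_counts(cnt[[t]]$alt[in_w], cnt[[t]]$an[in_w],
                               cnt[[r]]$alt[in_w], cnt[[r]]$an[in_w],
                               method = fst_method)
        pit <- if (empty) NaN else dt$pi_raw / window_bp
        pir <- if (empty) NaN else dr$pi_raw / window_bp
        lpr <- if (!empty && pit > 0 && pir > 0) log(pir / pit) else NaN
        ps[[length(ps) + 1L]] <- data.frame(
          chrom = chrom, start = w0, end = w1, target = t, ref = r,
          fst = as.numeric(fst), pi_target = pit, pi_ref = pir,
          log_pi_ratio = lpr,
          rod = if (!empty && pir > 0) 1 - pit / pir else NaN,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(window_stats = do.call(rbind, ws), pairwise_stats = do.call(rbind, ps))
}
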