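# Three-stage adaptive-TE detection. Stage 1: joint Fst / log pi-ratio
# top-(1-q) empirical outliers over polymorphic TE regions, per ordered
# (target, reference) population comparison. Stage 2: ROD in 500-bp
# non-overlapping windows over +/- 10-kb flanks; pass when the mean ROD over
# the central +/- 2-kb zone exceeds the empirical (1-q) quantile of that
# quantity across all regions in the comparison. Stage 3: Tajima's D over the
# 20-kb flank region for target and reference; pass when |D_t - D_r| exceeds
# its empirical (1-q) quantile. All thresholds are distribution-free
# empirical percentiles, matching the published procedure's style.

#' Stage-1 joint outlier candidates
#'
#' Per comparison, regions whose Fst AND log pi-ratio (OR selectable) reach
#' the empirical (1-q) quantile; ties at the threshold are included. Regions
#' with undefined Fst or pi-ratio are excluded with a flag.
#'
#' @param region_stats data.frame with te_locus_id, target, ref, fst,
#'   log_pi_ratio.
#' @param q upper-tail mass (default 0.05).
#' @param combine "and" (joint outliers, default) or "or".
#' @return input with fst_percentile, pi_percentile, excluded and
#'   stage1_pass columns added.
#' @export
pairwise_outlier_candidates <- function(region_stats, q = 0.05,
                                        combine = c("and", "or")) {
  combine <- match.arg(combine)
  rs <- region_stats
  rs$fst_percentile <- rep(NA_real_, nrow(rs))
  rs$pi_percentile <- rep(NA_real_, nrow(rs))
  rs$excluded <- !is.finite(rs$fst) | !is.finite(rs$log_pi_ratio)
  rs$stage1_pass <- rep(FALSE, nrow(rs))
  for (cmp in unique(paste(rs$target, rs$ref))) {
    sel <- paste(rs$target, rs$ref) == cmp & !rs$excluded
    if (!sum(sel)) next
    f <- rs$fst[sel]; l <- rs$log_pi_ratio[sel]
    rs$fst_percentile[sel] <- stats::ecdf(f)(f)
    rs$pi_percentile[sel] <- stats::ecdf(l)(l)
    thr_f <- stats::quantile(f, 1 - q, names = FALSE)
    thr_l <- stats::quantile(l, 1 - q, names = FALSE)
    pass <- if (combine == "and") f >= thr_f & l >= thr_l
            else f >= thr_f | l >= thr_l
    rs$stage1_pass[sel] <- pass
  }
  if (any(rs$excluded))
    log_msg(sprintf("pairwise_outlier_candidates: %d region-comparison(s) excluded (undefined stats)",
                    sum(rs$excluded)))
  rs
}

#' Stage-2 ROD screen over one region's flank windows
#'
#' @param windows data.frame(start, end, pi_target, pi_ref) of non-overlapping
#'   flank windows (per-bp pi).
#' @param central_lo,central_hi bounds of the central evaluation zone.
#' @param min_evaluable minimum fraction of central windows with pi_ref > 0
#'   required for a conclusive screen.
#' @return list(rod_profile, central_mean, evaluable_frac, inconclusive).
#' @export
rod_screen <- function(windows, central_lo, central_hi, min_evaluable = 0.5) {
  w <- windows
  w$rod <- ifelse(w$pi_ref > 0, 1 - w$pi_target / w$pi_ref, NaN)
  central <- w$start < central_hi & w$end > central_lo
  ev <- central & is.finite(w$rod)
  frac <- if (sum(central)) sum(ev) / sum(central) else 0
  list(rod_profile = w,
       central_mean = if (sum(ev)) mean(w$rod[ev]) else NaN,
       evaluable_frac = frac,
       inconclusive = frac < min_evaluable)
}

#' Stage-3 Tajima's D confirmation for one region
#'
#' Tajima's D over the flank region (half of `flank_bp` on each side of the
#' TE) for the target and reference populations; inconclusive when either
#' population has no segregating site there.
#'
#' @param panel an [snp_panel].
#' @param populations data.frame(accession_id, population).
#' @param chrom,te_start,te_end the TE locus.
#' @param target,ref population labels.
#' @param flank_bp total flank width (default 20000 = 10 kb per side).
#' @return list(tajd_target, tajd_ref, delta, inconclusive).
#' @export
tajd_confirm <- function(panel, populations, chrom, te_start, te_end,
                         target, ref, flank_bp = 20000) {
  half <- flank_bp / 2
  cnt <- panel_pop_counts(panel, populations)
  sel <- panel$sites$chrom == chrom & panel$sites$pos >= te_start - half &
    panel$sites$pos < te_end + half
  dd <- lapply(c(target, ref), function(lb) {
    d <- count_diversity(cnt[[lb]]$alt[sel], cnt[[lb]]$an[sel])
    if (d$S == 0 || d$n < 4) NaN
    else tajimas_d(pi_raw = d$pi_raw, S = d$S, n = d$n)
  })
  dt <- dd[[1]]; dr <- dd[[2]]
  list(tajd_target = dt, tajd_ref = dr, delta = dt - dr,
       inconclusive = !is.finite(dt) || !is.finite(dr))
}

#' Run the three-stage adaptive-TE scan
#'
#' For every TE locus and every ordered (target, reference) population pair:
#' stage-1 Fst / log pi-ratio statistics over a `sweep_window_bp` region
#' centred on the TE, stage-2 ROD in 500-bp windows over +/- `flank_rod_bp`
#' with the central +/- 2-kb mean screened against the comparison-wide
#' empirical quantile, and stage-3 Tajima's D over the `flank_tajd_bp` region.
#' Verdicts: "none" -> "candidate" (stage 1) -> "rod-supported" (stages 1-2)
#' -> "adaptive" (all three). The full evidence table is returned, including
#' regions that fail early.
#'
#' `maf_min` defaults to 0 here (not the config value): the sweep signature
#' is an excess of rare variants, which a MAF filter would erase.
#'
#' @param te a [te_genotype_matrix] (its loci are the scanned regions).
#' @param panel an [snp_panel].
#' @param populations data.frame(accession_id, population); defaults to the
#'   panel's assignment.
#' @param config a [config_profile].
#' @param maf_min MAF filter for the scan statistics.
#' @param stage1_combine "and" or "or".
#' @param rod_window_bp ROD window width.
#' @param central_bp half-width of the central ROD evaluation zone.
#' @return data.frame, one row per locus x ordered comparison.
#' @export
run_adaptive_scan <- function(te, panel, populations = NULL,
                              config = config_profile(), maf_min = 0,
                              stage1_combine = c("and", "or"),
                              rod_window_bp = 500, central_bp = 2000) {
  stage1_combine <- match.arg(stage1_combine)
  pops <- populations %||% panel$populations
  if (is.null(pops)) stop("population assignment required")
  labs <- sort(unique(pops$population))
  if (length(labs) < 2) stop(">=2 populations required")
  if (!nrow(panel$sites)) stop("empty genotype panel")
  cnt <- panel_pop_counts(panel, pops)
  # MAF mask over all samples
  alt_all <- rowSums(panel$ac, na.rm = TRUE)
  an_all <- rowSums(panel$an)
  p_all <- ifelse(an_all > 0, alt_all / an_all, 0)
  keep <- pmin(p_all, 1 - p_all) >= maf_min
  site_chrom <- panel$sites$chrom
  site_pos <- panel$sites$pos
  q <- config$outlier_quantile
  half_w <- config$sweep_window_bp / 2
  flank_rod <- config$flank_rod_bp
  loci <- te$loci
  per_locus <- vector("list", nrow(loci))
  rod_profiles <- list()
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]; ts <- loci$start[i]; tee <- loci$end[i]
    mid <- (ts + tee) / 2
    on_chr <- which(site_chrom == chrom & keep)
    pos <- site_pos[on_chr]
    # stage-1 region window
    in_w <- on_chr[pos >= mid - half_w & pos < mid + half_w]
    # ROD windows tile [ts - flank, tee + flank) in rod_window_bp steps
    rod_lo <- ts - flank_rod
    n_rw <- ceiling((tee + flank_rod - rod_lo) / rod_window_bp)
    rws <- rod_lo + (seq_len(n_rw) - 1) * rod_window_bp
    # Tajima flank
    half_t <- config$flank_tajd_bp / 2
    in_t <- on_chr[pos >= ts - half_t & pos < tee + half_t]
    pop_stats <- lapply(stats::setNames(labs, labs), function(lb) {
      d1 <- count_diversity(cnt[[lb]]$alt[in_w], cnt[[lb]]$an[in_w])
      rod_pos <- site_pos[on_chr]
      in_rod <- on_chr[rod_pos >= rod_lo & rod_pos < rod_lo + n_rw * rod_window_bp]
      wid <- floor((site_pos[in_rod] - rod_lo) / rod_window_bp) + 1
      pi_w <- numeric(n_rw)
      if (length(in_rod)) {
        alt <- cnt[[lb]]$alt[in_rod]; an <- cnt[[lb]]$an[in_rod]
        p <- ifelse(an > 0, alt / an, 0)
        pi_site <- ifelse(an >= 2, 2 * p * (1 - p) * an / pmax(an - 1, 1), 0)
        agg <- rowsum(pi_site, wid)
        pi_w[as.integer(rownames(agg))] <- agg[, 1]
      }
      dT <- count_diversity(cnt[[lb]]$alt[in_t], cnt[[lb]]$an[in_t])
      list(pi1 = d1$pi_raw / config$sweep_window_bp,
           pi_rod = pi_w / rod_window_bp,
           tajd = if (dT$S > 0 && dT$n >= 4)
             tajimas_d(pi_raw = dT$pi_raw, S = dT$S, n = dT$n) else NaN)
    })
    rows <- list()
    for (t in labs) for (r in labs) {
      if (t == r) next
      fst <- fst_from_counts(cnt[[t]]$alt[in_w], cnt[[t]]$an[in_w],
                             cnt[[r]]$alt[in_w], cnt[[r]]$an[in_w],
                             method = config$fst_method)
      pit <- pop_stats[[t]]$pi1; pir <- pop_stats[[r]]$pi1
      scr <- rod_screen(data.frame(start = rws, end = rws + rod_window_bp,
                                   pi_target = pop_stats[[t]]$pi_rod,
                                   pi_ref = pop_stats[[r]]$pi_rod),
                        central_lo = ts - central_bp,
                        central_hi = tee + central_bp)
      dt <- pop_stats[[t]]$tajd; dr <- pop_stats[[r]]$tajd
      rows[[paste(t, r)]] <- data.frame(
        te_locus_id = loci$locus_id[i], chrom = chrom, te_start = ts,
        te_end = tee, target = t, ref = r, fst = as.numeric(fst),
        pi_target = pit, pi_ref = pir,
        log_pi_ratio = if (pit > 0 && pir > 0) log(pir / pit) else NaN,
        central_rod = scr$central_mean, rod_evaluable = scr$evaluable_frac,
        rod_inconclusive = scr$inconclusive,
        tajd_target = dt, tajd_ref = dr,
        tajd_delta = dt - dr,
        tajd_inconclusive = !is.finite(dt) || !is.finite(dr),
        stringsAsFactors = FALSE)
    }
    per_locus[[i]] <- do.call(rbind, rows)
  }
  ev <- do.call(rbind, per_locus)
  rownames(ev) <- NULL
  ev <- pairwise_outlier_candidates(ev, q = q, combine = stage1_combine)
  ev$stage2_pass <- FALSE
  ev$stage3_pass <- FALSE
  for (cmp in unique(paste(ev$target, ev$ref))) {
    sel <- paste(ev$target, ev$ref) == cmp
    cr <- ev$central_rod[sel]
    ok2 <- is.finite(cr) & !ev$rod_inconclusive[sel]
    if (any(ok2)) {
      thr2 <- stats::quantile(cr[ok2], 1 - q, names = FALSE)
      ev$stage2_pass[sel] <- ok2 & cr > thr2
    }
    dl <- abs(ev$tajd_delta[sel])
    ok3 <- is.finite(dl) & !ev$tajd_inconclusive[sel]
    if (any(ok3)) {
      thr3 <- stats::quantile(dl[ok3], 1 - q, names = FALSE)
      ev$stage3_pass[sel] <- ok3 & dl > thr3
    }
  }
  ev$verdict <- ifelse(!ev$stage1_pass, "none",
                ifelse(!ev$stage2_pass, "candidate",
                ifelse(!ev$stage3_pass, "rod-supported", "adaptive")))
  log_msg(sprintf("run_adaptive_scan: %d region(s) x %d comparison(s); %d adaptive call(s)",
                  nrow(loci), length(labs) * (length(labs) - 1),
                  sum(ev$verdict == "adaptive")))
  ev
}
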