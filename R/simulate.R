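# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with known planted truth: single-population Hudson-coalescent
# haplotype windows; a multi-population regional panel with an optional
# TE-linked sweep; TE presence/absence matrices with genic-category frequency
# bias; and a gene/TE/siRNA/expression landscape with a planted TE-distance
# and siRNA effect.

#' Simulation parameters for the regional sweep panel
#'
#' Defaults emulate the downstream products of a three-subpopulation poplar
#' resequencing panel: populations NE/NW/S, 20 haplotypes (10 diploid
#' accessions) each, per-bp diversity 0.005, weak differentiation
#' (Fst baseline 0.05), 100 independent 24-kb TE regions.
#'
#' @param n_pops number of populations.
#' @param pop_labels population labels.
#' @param n_haps_per_pop haplotypes per population (even; paired to diploids).
#' @param theta_per_bp expected pairwise diversity per bp.
#' @param window_bp stage-1 statistic window (informational; the scan takes
#'   its own config).
#' @param region_len_bp length of each simulated TE region.
#' @param n_regions number of regions.
#' @param sweep_region_index region carrying the planted sweep (NA = none).
#' @param sweep_pop target population of the sweep.
#' @param sweep_f_red maximal expected diversity reduction f_red in [0,1].
#' @param sweep_decay_bp exponential decay length of the sweep footprint.
#' @param sweep_singleton_frac fraction of removed polymorphism mass converted
#'   to singletons (hitchhiking-style skew of the frequency spectrum).
#' @param sweep_carrier_freq planted TE carrier frequency in the target
#'   population; `offtarget_carrier_freq` elsewhere.
#' @param offtarget_carrier_freq see above.
#' @param fst_baseline Balding-Nichols drift parameter between populations.
#' @param te_width_bp width of each TE locus interval.
#' @param seed integer seed.
#' @return a named list of class `sim_params`.
#' @export
sim_params <- function(n_pops = 3, pop_labels = c("NE", "NW", "S"),
                       n_haps_per_pop = 20, theta_per_bp = 0.005,
                       window_bp = 5000, region_len_bp = 24000,
                       n_regions = 100, sweep_region_index = NA,
                       sweep_pop = pop_labels[1], sweep_f_red = 0.9,
                       sweep_decay_bp = 2000, sweep_singleton_frac = 0.7,
                       sweep_carrier_freq = 0.9, offtarget_carrier_freq = 0.05,
                       fst_baseline = 0.05, te_width_bp = 500, seed = 1L) {
  if (length(pop_labels) != n_pops) stop("pop_labels must have n_pops entries")
  if (n_haps_per_pop < 2) stop("n_haps_per_pop must be >= 2")
  if (n_haps_per_pop %% 2 != 0) stop("n_haps_per_pop must be even (diploids)")
  if (theta_per_bp <= 0) stop("theta_per_bp must be > 0")
  if (!is.na(sweep_region_index) &&
      (sweep_region_index < 1 || sweep_region_index > n_regions))
    stop("sweep_region_index out of range")
  if (sweep_f_red < 0 || sweep_f_red > 1) stop("f_red must lie in [0, 1]")
  if (fst_baseline < 0 || fst_baseline >= 1) stop("fst_baseline in [0, 1)")
  structure(list(n_pops = n_pops, pop_labels = pop_labels,
                 n_haps_per_pop = n_haps_per_pop, theta_per_bp = theta_per_bp,
                 window_bp = window_bp, region_len_bp = region_len_bp,
                 n_regions = n_regions, sweep_region_index = sweep_region_index,
                 sweep_pop = sweep_pop, sweep_f_red = sweep_f_red,
                 sweep_decay_bp = sweep_decay_bp,
                 sweep_singleton_frac = sweep_singleton_frac,
                 sweep_carrier_freq = sweep_carrier_freq,
                 offtarget_carrier_freq = offtarget_carrier_freq,
                 fst_baseline = fst_baseline, te_width_bp = te_width_bp,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a neutral haplotype window (Hudson coalescent)
#'
#' Single-population coalescent without recombination under the
#' infinite-sites model: exponential coalescence times with rate C(k,2),
#' mutations Poisson with rate theta/2 per unit branch length, positions
#' uniform on the window. E[S] = theta * a1(n).
#'
#' @param n_haps sample size (>= 2).
#' @param theta per-window scaled mutation rate.
#' @param window_bp window length in bp.
#' @param seed optional seed (set locally for determinism).
#' @param chrom chromosome label for the block.
#' @return a [haplotype_block].
#' @export
simulate_neutral_window <- function(n_haps, theta, window_bp, seed = NULL,
                                    chrom = "sim1") {
  if (n_haps < 2) stop("n_haps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  leafsets <- vector("list", 2 * n_haps - 2)
  lens <- numeric(2 * n_haps - 2)
  nb <- 0L
  active <- as.list(seq_len(n_haps))
  alen <- numeric(n_haps)
  k <- n_haps
  while (k > 1) {
    alen <- alen + stats::rexp(1, k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (i in pair) {
      nb <- nb + 1L
      leafsets[[nb]] <- active[[i]]
      lens[nb] <- alen[i]
    }
    active[[pair[1]]] <- c(active[[pair[1]]], active[[pair[2]]])
    alen[pair[1]] <- 0
    active <- active[-pair[2]]
    alen <- alen[-pair[2]]
    k <- k - 1L
  }
  nmut <- stats::rpois(nb, theta / 2 * lens)
  S <- sum(nmut)
  if (S > window_bp) stop("more mutations than sites in window; enlarge window_bp")
  mat <- matrix(0L, n_haps, S)
  if (S > 0) {
    branch_of <- rep(seq_len(nb), nmut)
    for (j in seq_len(S)) mat[leafsets[[branch_of[j]]], j] <- 1L
    pos <- sort(sample.int(window_bp, S)) - 1L
    ord <- seq_len(S)  # columns already in branch order; order by position
    mat <- mat[, sample(ord), drop = FALSE]
  } else pos <- integer(0)
  haplotype_block(mat, positions = pos, chrom = chrom,
                  window_start = 0, window_end = window_bp)
}

# neutral-SFS ancestral allele counts on a pool of n_anc lineages
r_anc_freq <- function(S, n_anc) {
  cls <- seq_len(n_anc - 1)
  sample(cls, S, replace = TRUE, prob = 1 / cls) / n_anc
}

# Balding-Nichols drifted frequencies
r_bn <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# Sweep transformation of one population's haplotype matrix. Per site at
# distance d from the TE, with h = f_red*exp(-d/decay) and s = 1 - h the
# site is kept intact with prob k, converted to a singleton with prob sigma,
# or removed, where k and sigma solve E[pi_site'] = s * E[pi_site] exactly:
#   sigma = phi * h,  k = s - sigma/(n p(1-p));  if k < 0: k = 0,
#   sigma = s n p(1-p).
apply_sweep <- function(hap, pos, pk, te_s, te_e, f_red, decay, phi) {
  n <- nrow(hap)
  d <- iv0_gap(pos, pos + 1, te_s, te_e)
  h <- f_red * exp(-d / decay)
  s <- 1 - h
  pq <- pmax(pk * (1 - pk), 1e-8)
  sigma <- phi * h
  kkeep <- s - sigma / (n * pq)
  clamp <- kkeep < 0
  sigma[clamp] <- s[clamp] * n * pq[clamp]
  kkeep[clamp] <- 0
  u <- stats::runif(length(pos))
  to_single <- u >= kkeep & u < kkeep + sigma
  to_remove <- u >= kkeep + sigma
  if (any(to_single | to_remove)) {
    hap[, to_single | to_remove] <- 0L
    idx <- which(to_single)
    if (length(idx)) {
      rows <- sample.int(n, length(idx), replace = TRUE)
      hap[cbind(rows, idx)] <- 1L
    }
  }
  hap
}

#' Simulate a multi-population regional panel with an optional planted sweep
#'
#' Each region is an independent chromosome. Ancestral allele frequencies are
#' drawn from the neutral site-frequency spectrum on a pooled ancestral
#' sample, drifted per population with a Balding-Nichols model calibrated to
#' `fst_baseline`, and haplotypes are sampled per site. In the sweep region
#' the target population's expected diversity at distance d from the TE is
#' scaled by 1 - f_red*exp(-d/sweep_decay_bp) via mutation thinning, with part
#' of the removed mass converted to singletons (hitchhiking-style frequency
#' -spectrum skew). The planted TE insertion allele is carried at
#' `sweep_carrier_freq` in the target population and
#' `offtarget_carrier_freq` elsewhere.
#'
#' @param params a [sim_params].
#' @param gt_strings build per-sample VCF GT strings (needed to write the
#'   panel as VCF). FALSE skips them for speed in simulation studies; the
#'   allele-count matrices used by all statistics are always built.
#' @return list with elements `blocks` (per region, a named list of
#'   [haplotype_block] per population), `panel` (diploid [snp_panel]),
#'   `te` ([te_genotype_matrix]), `populations`, `truth`, `params`.
#' @export
simulate_sweep_dataset <- function(params = sim_params(), gt_strings = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  labs <- params$pop_labels
  n <- params$n_haps_per_pop
  L <- params$region_len_bp
  n_anc <- params$n_pops * n
  a1 <- sum(1 / seq_len(n_anc - 1))
  te_w <- params$te_width_bp
  te_s <- floor(L / 2 - te_w / 2)
  te_e <- te_s + te_w
  n_acc <- n %/% 2
  acc_ids <- unlist(lapply(labs, function(lb) sprintf("%s_%02d", lb, seq_len(n_acc))))
  populations <- data.frame(accession_id = acc_ids,
                            population = rep(labs, each = n_acc),
                            stringsAsFactors = FALSE)
  blocks <- vector("list", params$n_regions)
  sites_l <- vector("list", params$n_regions)
  gt_l <- vector("list", params$n_regions)
  loci_l <- vector("list", params$n_regions)
  geno_l <- vector("list", params$n_regions)
  sfam <- default_superfamily_composition()
  for (r in seq_len(params$n_regions)) {
    chrom <- sprintf("rgn%03d", r)
    S <- stats::rpois(1, params$theta_per_bp * L * a1)
    S <- min(S, L)
    pos <- sort(sample.int(L, S)) - 1L
    p_anc <- r_anc_freq(S, n_anc)
    haps <- list()
    for (lb in labs) {
      pk <- r_bn(p_anc, params$fst_baseline)
      hap <- matrix(stats::rbinom(n * S, 1L, rep(pk, each = n)), nrow = n)
      if (!is.na(params$sweep_region_index) &&
          r == params$sweep_region_index && lb == params$sweep_pop) {
        hap <- apply_sweep(hap, pos, pk, te_s, te_e, params$sweep_f_red,
                           params$sweep_decay_bp, params$sweep_singleton_frac)
      }
      haps[[lb]] <- hap
    }
    all_hap <- do.call(rbind, haps)
    seg <- colSums(all_hap) > 0 & colSums(all_hap) < nrow(all_hap)
    all_hap <- all_hap[, seg, drop = FALSE]
    pos_r <- pos[seg]
    blocks[[r]] <- lapply(stats::setNames(labs, labs), function(lb) {
      i0 <- (match(lb, labs) - 1) * n
      haplotype_block(all_hap[i0 + seq_len(n), , drop = FALSE],
                      positions = pos_r, chrom = chrom,
                      window_start = 0, window_end = L)
    })
    # diploid pairing: haplotypes (2j-1, 2j) of each population pair up
    h1 <- all_hap[seq(1, nrow(all_hap), by = 2), , drop = FALSE]
    h2 <- all_hap[seq(2, nrow(all_hap), by = 2), , drop = FALSE]
    gt_l[[r]] <- if (gt_strings)
      matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(all_hap))
    else t(h1) + t(h2)
    sites_l[[r]] <- data.frame(chrom = chrom, pos = pos_r,
                               id = ".", ref = "A", alt = "T", qual = ".",
                               filter = "PASS", info = ".",
                               stringsAsFactors = FALSE)
    # TE locus of this region
    lid <- sprintf("TE_%s", chrom)
    planted <- !is.na(params$sweep_region_index) && r == params$sweep_region_index
    if (planted) {
      pres <- unlist(lapply(labs, function(lb) {
        f <- if (lb == params$sweep_pop) params$sweep_carrier_freq
             else params$offtarget_carrier_freq
        stats::rbinom(n_acc, 1L, f)
      }))
    } else {
      f0 <- min(max(stats::rbeta(1, 0.3, 0.3), 0.02), 0.98)
      pres <- unlist(lapply(labs, function(lb) {
        stats::rbinom(n_acc, 1L, r_bn(f0, params$fst_baseline))
      }))
    }
    loci_l[[r]] <- data.frame(chrom = chrom, start = te_s, end = te_e,
                              strand = ".", locus_id = lid,
                              superfamily = if (planted) "Helitron" else
                                sample(names(sfam), 1, prob = sfam),
                              genic_category = "intergenic",
                              stringsAsFactors = FALSE)
    geno_l[[r]] <- pres
  }
  sites <- do.call(rbind, sites_l)
  gt <- do.call(rbind, gt_l)
  colnames(gt) <- acc_ids
  panel <- if (gt_strings) {
    snp_panel(sites, gt, acc_ids, populations = populations, ploidy = 2L)
  } else {
    storage.mode(gt) <- "integer"
    structure(list(sites = sites, gt = NULL, ac = gt,
                   an = matrix(2L, nrow(gt), ncol(gt)), samples = acc_ids,
                   populations = populations, ploidy = 2L),
              class = "snp_panel")
  }
  loci <- do.call(rbind, loci_l)
  geno <- do.call(cbind, geno_l)
  rownames(geno) <- acc_ids
  colnames(geno) <- loci$locus_id
  te <- te_genotype_matrix(loci, geno, populations = populations)
  truth <- list(
    adaptive_te_ids = if (is.na(params$sweep_region_index)) character(0)
                      else sprintf("TE_rgn%03d", params$sweep_region_index),
    sweep_region_index = params$sweep_region_index,
    sweep_pop = params$sweep_pop, f_red = params$sweep_f_red,
    decay_bp = params$sweep_decay_bp,
    carrier_freq = params$sweep_carrier_freq,
    te_interval = c(te_s, te_e))
  list(blocks = blocks, panel = panel, te = te, populations = populations,
       truth = truth, params = params)
}

#' Default polymorphic-TE superfamily composition
#'
#' Mirrors the reported composition of a poplar polymorphic-TE panel:
#' about 46% DNA transposons (split between Helitron and other cut-and-paste
#' families), 11.4% Gypsy, 11.9% Copia, the rest other LTR / unclassified.
#'
#' @return named numeric vector summing to 1.
#' @export
default_superfamily_composition <- function() {
  c(Gypsy = 0.114, Copia = 0.119, `other-LTR` = 0.227,
    Helitron = 0.210, `other-DNA` = 0.250, other = 0.080)
}

#' Simulate a polymorphic TE genotype matrix with planted frequency bias
#'
#' Per-locus insertion frequency follows a U-shaped Beta(0.3, 0.3) baseline;
#' with probability `bias_params$low_freq_prob[category]` a locus instead
#' draws its frequency uniformly from `bias_params$low_range` (default
#' (0.005, 0.1]), planting the low-frequency bias of CDS/UTR insertions. A
#' fraction of loci is population-specific (present in exactly one
#' population).
#'
#' @param n_loci number of loci.
#' @param pops named integer vector of accessions per population
#'   (default `c(NE = 23, NW = 35, S = 29)`).
#' @param category_mix named probabilities over genic categories
#'   CDS/UTR/intron/promoter/downstream/intergenic; must sum to 1.
#' @param bias_params list(low_freq_prob, low_range, low_threshold,
#'   baseline_shape, prop_pop_specific, na_rate). `low_freq_prob` is a named
#'   vector per category (unnamed scalar = all categories) and is exactly the
#'   probability that a locus's true frequency falls at or below
#'   `low_threshold`.
#' @param seed integer seed.
#' @return list(te = [te_genotype_matrix], truth).
#' @export
simulate_te_genotype_matrix <- function(n_loci = 300,
                                        pops = c(NE = 23, NW = 35, S = 29),
                                        category_mix = c(CDS = 0.2, UTR = 0.1,
                                          intron = 0.1, promoter = 0.05,
                                          downstream = 0.05, intergenic = 0.5),
                                        bias_params = list(), seed = 1L) {
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop("category_mix weights must sum to 1")
  need <- c("CDS", "UTR", "intron", "promoter", "downstream", "intergenic")
  if (!all(need %in% names(category_mix)))
    stop("category_mix must cover ", paste(need, collapse = ", "))
  bp <- utils::modifyList(list(
    low_freq_prob = c(CDS = 0.9, UTR = 0.9, intron = 0.5, promoter = 0.45,
                      downstream = 0.45, intergenic = 0.4),
    low_range = c(0.005, 0.1), low_threshold = 0.1,
    baseline_shape = c(0.3, 0.3),
    prop_pop_specific = 0.1, na_rate = 0), bias_params)
  if (length(bp$low_freq_prob) == 1 && is.null(names(bp$low_freq_prob)))
    bp$low_freq_prob <- stats::setNames(rep(bp$low_freq_prob, length(need)), need)
  set.seed(seed)
  labs <- names(pops)
  cats <- sample(names(category_mix), n_loci, replace = TRUE,
                 prob = category_mix)
  sfam_p <- default_superfamily_composition()
  sfam <- sample(names(sfam_p), n_loci, replace = TRUE, prob = sfam_p)
  low <- stats::rbinom(n_loci, 1, bp$low_freq_prob[cats]) == 1
  # non-low loci draw from the U-shaped baseline truncated above the
  # threshold, so P(f <= threshold) equals low_freq_prob exactly
  p0 <- stats::pbeta(bp$low_threshold, bp$baseline_shape[1],
                     bp$baseline_shape[2])
  f_hi <- stats::qbeta(stats::runif(n_loci, p0, 1), bp$baseline_shape[1],
                       bp$baseline_shape[2])
  f <- ifelse(low,
              stats::runif(n_loci, bp$low_range[1], bp$low_range[2]),
              pmin(f_hi, 0.99))
  specific <- stats::runif(n_loci) < bp$prop_pop_specific
  spec_pop <- sample(labs, n_loci, replace = TRUE)
  geno <- matrix(0L, sum(pops), n_loci)
  rownames(geno) <- unlist(lapply(labs, function(lb)
    sprintf("%s_%02d", lb, seq_len(pops[[lb]]))))
  pop_of <- rep(labs, times = pops)
  for (j in seq_len(n_loci)) {
    if (specific[j]) {
      in_pop <- pop_of == spec_pop[j]
      geno[in_pop, j] <- stats::rbinom(sum(in_pop), 1L, max(f[j], 0.05))
      # guarantee at least one carrier so the locus is observably specific
      if (sum(geno[in_pop, j]) == 0)
        geno[which(in_pop)[sample.int(sum(in_pop), 1)], j] <- 1L
    } else {
      geno[, j] <- stats::rbinom(sum(pops), 1L, f[j])
    }
  }
  if (bp$na_rate > 0) {
    nas <- stats::runif(length(geno)) < bp$na_rate
    geno[nas] <- NA
  }
  loci <- data.frame(chrom = "chrSim",
                     start = (seq_len(n_loci) - 1) * 10000 + 1000,
                     end = (seq_len(n_loci) - 1) * 10000 + 1300,
                     strand = ".",
                     locus_id = sprintf("TE_%05d", seq_len(n_loci)),
                     superfamily = sfam, genic_category = cats,
                     stringsAsFactors = FALSE)
  populations <- data.frame(accession_id = rownames(geno),
                            population = pop_of, stringsAsFactors = FALSE)
  te <- te_genotype_matrix(loci, geno, populations = populations)
  truth <- list(category = stats::setNames(cats, loci$locus_id),
                true_freq = stats::setNames(f, loci$locus_id),
                low_component = stats::setNames(low, loci$locus_id),
                low_freq_prob = bp$low_freq_prob,
                pop_specific_ids = loci$locus_id[specific],
                specific_pop = stats::setNames(spec_pop, loci$locus_id)[specific])
  list(te = te, truth = truth)
}

#' Simulate a gene/TE/siRNA/expression landscape
#'
#' Genes are placed on non-overlapping 20-kb slots of one chromosome, each
#' with a planted nearest TE at a controlled distance (a stated fraction
#' inside an intron, i.e. distance 0). Expression at each timepoint is
#' (baseline + beta * min(d, 1 kb)/1 kb) scaled by `sirna_plus_multiplier`
#' for genes whose TE is siRNA+, by a per-timepoint factor, and by mean-1
#' lognormal noise. siRNA+ TEs receive a stack of >= 12 overlapping 24-bp
#' reads; a fraction of siRNA- TEs receives a sub-threshold stack.
#'
#' @param n_genes number of genes.
#' @param n_tes number of TEs (>= n_genes; surplus TEs go to a TE-only
#'   chromosome so each gene's nearest TE stays its planted one).
#' @param sirna_fraction fraction of TEs that are siRNA+.
#' @param expression_params list(baseline, beta, sirna_plus_multiplier,
#'   noise_sd, tp_effect, inside_fraction, max_d).
#' @param seed integer seed.
#' @return list(genes = gene_models, tes, sirna_reads, expr, truth, params).
#' @export
simulate_landscape <- function(n_genes = 500, n_tes = n_genes,
                               sirna_fraction = 0.5,
                               expression_params = list(), seed = 1L) {
  ep <- utils::modifyList(list(
    baseline = 5, beta = 4, sirna_plus_multiplier = 2, noise_sd = 0.3,
    tp_effect = c(`0` = 1, `4` = 1.05, `8` = 1.1, `12` = 1.1, `24` = 1.15,
                  `36` = 1.3, `48` = 1.25),
    inside_fraction = 0.15, max_d = 5400), expression_params)
  if (n_tes < n_genes) stop("n_tes must be >= n_genes")
  set.seed(seed)
  slot <- 20000
  g0 <- (seq_len(n_genes) - 1) * slot + 8000
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gid <- sprintf("gene%04d", seq_len(n_genes))
  tid <- paste0(gid, ".t1")
  genes <- data.frame(chrom = "chrL", start = g0, end = g0 + 2200,
                      strand = strand, gene_id = gid, stringsAsFactors = FALSE)
  # fixed internal layout (coordinates relative to gene start):
  # UTR [0,200) | CDS [200,800) | intron [800,1200) | CDS [1200,1900) |
  # UTR [1900,2200); UTR identities swap with strand.
  seg <- function(type, s, e) data.frame(
    chrom = "chrL", start = g0 + s, end = g0 + e, strand = strand,
    type = type, gene_id = gid, tx_id = tid, stringsAsFactors = FALSE)
  feats <- rbind(
    seg("exon", 0, 800), seg("exon", 1200, 2200),
    seg("CDS", 200, 800), seg("CDS", 1200, 1900),
    seg("intron", 800, 1200),
    transform(seg("five_prime_UTR", 0, 200),
              type = ifelse(strand == "+", "five_prime_UTR", "three_prime_UTR")),
    transform(seg("three_prime_UTR", 1900, 2200),
              type = ifelse(strand == "+", "three_prime_UTR", "five_prime_UTR")))
  gm <- structure(list(genes = genes, features = feats), class = "gene_models")
  # planted TEs
  te_w <- 300
  inside <- stats::runif(n_genes) < ep$inside_fraction
  d <- ifelse(inside, 0, floor(stats::runif(n_genes, 1, ep$max_d + 1)))
  side <- sample(c(-1, 1), n_genes, replace = TRUE)
  te_start <- ifelse(inside, g0 + 850,
                     ifelse(side < 0, g0 - d - te_w, g0 + 2200 + d))
  te <- data.frame(chrom = "chrL", start = te_start, end = te_start + te_w,
                   strand = ".", te_id = sprintf("te%04d", seq_len(n_genes)),
                   superfamily = sample(names(default_superfamily_composition()),
                                        n_genes, replace = TRUE,
                                        prob = default_superfamily_composition()),
                   stringsAsFactors = FALSE)
  if (n_tes > n_genes) {
    n_x <- n_tes - n_genes
    xs <- (seq_len(n_x) - 1) * 2000 + 500
    te <- rbind(te, data.frame(
      chrom = "chrU", start = xs, end = xs + te_w, strand = ".",
      te_id = sprintf("te%04d", n_genes + seq_len(n_x)),
      superfamily = sample(names(default_superfamily_composition()), n_x,
                           replace = TRUE,
                           prob = default_superfamily_composition()),
      stringsAsFactors = FALSE))
  }
  sirna_plus <- stats::runif(n_tes) < sirna_fraction
  reads <- sim_read_stacks(te, sirna_plus)
  # expression
  tps <- names(ep$tp_effect)
  mu <- ep$baseline + ep$beta * pmin(d, 1000) / 1000
  mu <- mu * ifelse(sirna_plus[seq_len(n_genes)], ep$sirna_plus_multiplier, 1)
  fpkm <- outer(mu, unname(ep$tp_effect)) *
    matrix(stats::rlnorm(n_genes * length(tps), -ep$noise_sd^2 / 2,
                         ep$noise_sd), n_genes)
  rownames(fpkm) <- gid
  colnames(fpkm) <- tps
  truth <- list(beta = ep$beta, multiplier = ep$sirna_plus_multiplier,
                noise_sd = ep$noise_sd,
                distance = stats::setNames(d, gid),
                gene_te = stats::setNames(te$te_id[seq_len(n_genes)], gid),
                sirna_plus = stats::setNames(sirna_plus, te$te_id),
                tp_effect = ep$tp_effect)
  list(genes = gm, tes = te, sirna_reads = reads, expr = expression_table(fpkm),
       truth = truth, params = c(list(n_genes = n_genes, n_tes = n_tes,
                                      sirna_fraction = sirna_fraction,
                                      seed = seed), ep))
}

# stacks of overlapping 24-bp reads on siRNA+ TEs (>= 12 reads) and, for 30%
# of siRNA- TEs, sub-threshold stacks (1-5 reads)
sim_read_stacks <- function(te, sirna_plus) {
  sub_stack <- pmin(1L + stats::rpois(nrow(te), 1.5), 5L)  # stays < 10 reads
  n_reads <- ifelse(sirna_plus, 12L + stats::rpois(nrow(te), 8),
                    ifelse(stats::runif(nrow(te)) < 0.3, sub_stack, 0L))
  idx <- rep(seq_len(nrow(te)), n_reads)
  if (!length(idx))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0), score = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  base <- te$start[idx] + rep(floor(stats::runif(nrow(te), 0,
                                                 (te$end - te$start) - 60)),
                              n_reads)
  off <- sample(0:20, length(idx), replace = TRUE)
  start <- base + off
  data.frame(chrom = te$chrom[idx], start = start, end = start + 24,
             name = sprintf("read%06d", seq_along(idx)), score = 0,
             strand = "+", stringsAsFactors = FALSE)
}

#' Write a fixture bundle to disk
#'
#' Emits whatever components the simulation object carries (VCF, population
#' TSV, TE BED+TSV, GFF3, siRNA read BED, expression TSV), a `truth.json`,
#' and a `MANIFEST.tsv` of md5 checksums.
#'
#' @param sim output of [simulate_sweep_dataset], [simulate_landscape] or
#'   [simulate_te_genotype_matrix].
#' @param dir output directory (created if needed).
#' @return data.frame manifest (file, md5), invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  files <- character(0)
  add <- function(f) files <<- c(files, f)
  if (!is.null(sim[["panel"]])) {
    write_vcf(sim[["panel"]], file.path(dir, "snps.vcf")); add("snps.vcf")
  }
  if (!is.null(sim[["populations"]])) {
    write_populations(sim[["populations"]], file.path(dir, "populations.tsv"))
    add("populations.tsv")
  }
  if (!is.null(sim[["te"]])) {
    write_te_matrix(sim[["te"]], file.path(dir, "te_loci.bed"),
                    file.path(dir, "te_genotypes.tsv"))
    add("te_loci.bed"); add("te_genotypes.tsv")
  }
  if (!is.null(sim[["tes"]])) {
    bed <- data.frame(chrom = sim[["tes"]]$chrom, start = sim[["tes"]]$start,
                      end = sim[["tes"]]$end, name = sim[["tes"]]$te_id, score = 0,
                      strand = sim[["tes"]]$strand,
                      superfamily = sim[["tes"]]$superfamily)
    write_bed(bed, file.path(dir, "te_annotations.bed"))
    add("te_annotations.bed")
  }
  if (!is.null(sim[["genes"]])) {
    write_gff3(sim[["genes"]], file.path(dir, "genes.gff3")); add("genes.gff3")
  }
  if (!is.null(sim[["sirna_reads"]])) {
    write_bed(sim[["sirna_reads"]], file.path(dir, "sirna_reads.bed"))
    add("sirna_reads.bed")
  }
  if (!is.null(sim[["expr"]])) {
    write_expression(sim[["expr"]], file.path(dir, "expression.tsv"))
    add("expression.tsv")
  }
  if (!is.null(sim[["truth"]])) {
    jsonlite::write_json(sim[["truth"]], file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add("truth.json")
  }
  md5 <- tools::md5sum(file.path(dir, files))
  manifest <- data.frame(file = files, md5 = unname(md5),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_msg(sprintf("write_fixture_bundle: %d file(s) in %s", length(files), dir))
  invisible(manifest)
}

#' Verify a fixture bundle against its manifest
#'
#' @param dir bundle directory containing MANIFEST.tsv.
#' @return data.frame(file, ok); attribute "all_ok".
#' @export
verify_fixture_bundle <- function(dir) {
  mf <- utils::read.delim(file.path(dir, "MANIFEST.tsv"),
                          stringsAsFactors = FALSE)
  md5 <- tools::md5sum(file.path(dir, mf$file))
  ok <- !is.na(md5) & md5 == mf$md5
  res <- data.frame(file = mf$file, ok = unname(ok))
  attr(res, "all_ok") <- all(ok)
  res
}
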