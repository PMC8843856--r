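#' Pipeline configuration profile
#'
#' Central container for the tunable parameters of the pipeline. Defaults:
#' 5,000-bp scan step, top-5% empirical
#' outliers, 500-bp ROD windows over 10-kb flanks (per side), Tajima's D over
#' a 20-kb flank region (10-kb each side), 0.1 low-frequency threshold,
#' 10-read / 150-bp siRNA clustering, and MAF >= 0.05 for SNP statistics.
#'
#' @param window_bp scan window size in bp.
#' @param step_bp scan step in bp (= window_bp for non-overlapping windows).
#' @param sweep_window_bp width of the TE region used for stage-1 Fst /
#'   pi-ratio statistics, centred on the TE locus.
#' @param flank_rod_bp ROD flank per side of the TE (profile spans +/- this).
#' @param flank_tajd_bp total width of the Tajima's-D confirmation region
#'   (half on each side of the TE).
#' @param outlier_quantile upper-tail mass used for empirical outliers.
#' @param low_freq_threshold carrier-frequency cutoff defining "low frequency".
#' @param sirna_min_reads minimum reads for a 24-nt siRNA cluster.
#' @param sirna_merge_bp maximum gap merged between siRNA clusters.
#' @param maf_min minor-allele-frequency cutoff for SNP-based statistics.
#' @param fst_method "hudson" (default) or "wc" (Weir-Cockerham).
#' @param seed integer seed recorded with every run.
#' @return a named list with class `tepop_config`.
#' @export
config_profile <- function(window_bp = 5000, step_bp = 5000,
                           sweep_window_bp = 5000,
                           flank_rod_bp = 10000, flank_tajd_bp = 20000,
                           outlier_quantile = 0.05, low_freq_threshold = 0.1,
                           sirna_min_reads = 10, sirna_merge_bp = 150,
                           maf_min = 0.05, fst_method = "hudson", seed = 1L) {
  cfg <- list(window_bp = window_bp, step_bp = step_bp,
              sweep_window_bp = sweep_window_bp,
              flank_rod_bp = flank_rod_bp, flank_tajd_bp = flank_tajd_bp,
              outlier_quantile = outlier_quantile,
              low_freq_threshold = low_freq_threshold,
              sirna_min_reads = sirna_min_reads,
              sirna_merge_bp = sirna_merge_bp,
              maf_min = maf_min, fst_method = fst_method,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "tepop_config")
}

validate_config <- function(cfg) {
  num <- c("window_bp", "step_bp", "sweep_window_bp", "flank_rod_bp",
           "flank_tajd_bp")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("config field %s must be > 0", f))
  }
  if (cfg$outlier_quantile <= 0 || cfg$outlier_quantile >= 1)
    stop("outlier_quantile must lie in (0, 1)")
  if (cfg$low_freq_threshold <= 0 || cfg$low_freq_threshold >= 1)
    stop("low_freq_threshold must lie in (0, 1)")
  if (cfg$maf_min < 0 || cfg$maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  if (!cfg$fst_method %in% c("hudson", "wc"))
    stop("fst_method must be 'hudson' or 'wc'")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Flat `key = value` text format, one pair per line; `#` starts a comment.
#' Unknown keys are rejected. Values override `config_profile()` defaults.
#'
#' @param path file path.
#' @param base configuration to override (defaults to `config_profile()`).
#' @return a `tepop_config`.
#' @export
read_config <- function(path, base = config_profile()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(base)) stop("unknown config key: ", key)
    base[[key]] <- if (key == "fst_method") val else as.numeric(val)
  }
  base$seed <- as.integer(base$seed)
  validate_config(base)
  structure(base, class = "tepop_config")
}

#' Write a configuration file
#'
#' @param cfg a `tepop_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  vals <- vapply(cfg, function(x) as.character(x), character(1))
  writeLines(paste(names(cfg), vals, sep = " = "), path)
  invisible(path)
}
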