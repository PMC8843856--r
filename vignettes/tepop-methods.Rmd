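---
title: "Methods: population genomics of polymorphic TE insertions with tepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of polymorphic TE insertions with tepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepop)
tepop_log_level("quiet")
```

## The problem

Polymorphic transposable-element (TE) insertions — TEs present in some
accessions of a species and absent in others — are a major source of
regulatory and structural variation in plant genomes. Given (i) a SNP
genotype panel for a structured population (here, three subpopulations
labelled NE, NW and S), (ii) a presence/absence matrix of polymorphic TE
loci, (iii) gene models, (iv) 24-nt siRNA read placements and (v) a gene
expression table, `tepop` answers four questions:

1. Which TE insertions sit in selective-sweep regions of one subpopulation —
   i.e. are candidate *adaptive* insertions?
2. Which TEs are targeted by 24-nt siRNAs (the RNA-directed DNA methylation
   pathway), and how does TE proximity relate to gene expression?
3. Where do TE insertions sit relative to genes (CDS, UTRs, introns, 2-kb
   promoter/downstream flanks, intergenic), and at what density?
4. Does the insertion-frequency spectrum show the signature of purifying
   selection against TEs in coding regions?

## Statistics

For a window with `n` haplotypes and `S` segregating sites, the package
computes nucleotide diversity as the mean pairwise difference
$\pi = \binom{n}{2}^{-1}\sum_{i<j} d_{ij}$, which is evaluated through the
exact per-site identity $\pi = \sum_s 2p_s(1-p_s)\,n/(n-1)$; Watterson's
$\theta_W = S/a_1$ with $a_1 = \sum_{i=1}^{n-1} 1/i$; and Tajima's
$D = (\pi - \theta_W)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard constants.
Unphased diploid genotypes are handled by treating the two alleles of an
accession as exchangeable haplotypes; all statistics then depend only on
per-site allele counts, for which that treatment is exact.

Between populations the default differentiation estimator is Hudson-type,
ratio-of-averages: $F_{st} = (H_b - H_w)/H_b$, with $H_w$ the mean of the
two within-population per-site heterozygosities and $H_b$ the
cross-population mean pairwise difference. It is symmetric, stable in small
windows, and negative estimates are reported raw (an optional clip-at-zero
flag exists, and a Weir–Cockerham-weighted estimator is selectable via
`fst_method = "wc"`). The reduction-of-diversity statistic is
$\mathrm{ROD} = 1 - \pi_{target}/\pi_{ref}$, and the pi-ratio is reported as
$\log(\pi_{ref}/\pi_{target})$ so that positive values mean diversity loss
in the target population.

## The three-stage adaptive-TE scan

Per TE locus and per **ordered** (target, reference) population pair:

* **Stage 1** — $F_{st}$ and $\log(\pi_{ref}/\pi_{target})$ over a 5,000-bp
  region centred on the TE; candidates are regions at or above the empirical
  95th percentile of *both* statistics within the comparison (joint AND
  outliers; an OR combination is available as a config switch).
* **Stage 2** — ROD in 500-bp non-overlapping windows over ±10-kb flanks;
  a region passes when its mean ROD over the central ±2-kb zone exceeds the
  empirical 95th percentile of that quantity across all regions of the
  comparison. ROD is profiled over the full ±10-kb flank, while the pass decision
  uses the central ±2-kb zone, where a sweep footprint at the planted
  2-kb decay scale concentrates.
* **Stage 3** — Tajima's D over a 20-kb region (10-kb per side) for target
  and reference; a region passes when $|D_t - D_r|$ exceeds its empirical
  95th percentile across regions.

Verdicts are monotone: `candidate` (stage 1), `rod-supported` (1+2),
`adaptive` (all three). All thresholds are distribution-free empirical
percentiles; no asymptotic null is invoked anywhere in the scan. Two deliberate parameter decisions:

* `maf_min` defaults to 0.05 in `config_profile()` and `windowed_scan()`
  (the value used upstream at the SNP/PCA stage), but `run_adaptive_scan()`
  defaults to `maf_min = 0`: the stage-3 signal *is* an excess of rare
  variants, and a 5% MAF filter on 40 haplotypes would delete every
  singleton and doubleton, erasing it.
* Comparisons are ordered pairs (6 for 3 populations) because the pi-ratio
  and ROD need a direction; the three unordered comparisons (NE–NW, NE–S,
  NW–S) are recovered by reading both orientations.

## The synthetic stated world

`simulate_neutral_window()` is a standard single-population Hudson
coalescent without recombination under infinite sites: exponential
coalescence times at rate $\binom{k}{2}$, mutations Poisson with rate
$\theta/2$ per unit branch length, positions uniform. It preserves full
within-window linkage and is the null model for the diversity statistics
(E[S] = $\theta a_1$, E[$\pi$] = $\theta$).

`simulate_sweep_dataset()` builds the multi-population regional panel: 100
independent 24-kb regions; ancestral allele frequencies drawn from the
neutral SFS on a pooled sample; per-population frequencies drifted with a
Balding–Nichols model at `fst_baseline = 0.05`; haplotypes sampled per site
and paired into diploid accessions. Population sizes default to 20
haplotypes per population, `theta_per_bp = 0.005` (the scale of nucleotide
diversity in outcrossing poplars). Because sites are sampled independently
given their frequencies, within-window linkage is *not* preserved here —
acceptable because every scan statistic is a per-site sum; the coalescent
simulator, not this panel, is used to validate the estimators themselves.
A green sweep-recovery test therefore establishes that the scan recovers a
planted diversity/SFS footprint of the stated size, not that it is calibrated
against real linked genealogies.

**Sweep emulation.** The planted sweep scales expected diversity at distance
$d$ from the TE by $s(d) = 1 - f_{red}\,e^{-d/\lambda}$ (defaults
$f_{red} = 0.9$, $\lambda = 2$ kb). Uniform mutation thinning would scale
$\pi$ and $\theta_W$ identically and leave Tajima's D untouched — a sweep
with no SFS footprint, which the stage-3 confirmation could never detect. We
therefore thin per site with three outcomes — keep intact (probability
$k$), convert to a singleton (probability $\sigma$, emulating post-sweep
recovery mutations), remove (otherwise) — solving
$k \cdot 2p(1-p) + \sigma \cdot 2/n = s \cdot 2p(1-p)$ exactly per site, with
$\sigma = \phi\,(1-s)$ and $\phi$ = `sweep_singleton_frac` = 0.7 (clamped
when $k$ would go negative, keeping the identity exact). Expected
ROD at the TE is exactly $f_{red}$ by construction, and the converted
singletons drive $D_{target}$ below $D_{ref}$, as sweep theory predicts. The
planted TE insertion allele is carried at frequency 0.9 in the target
population and 0.05 elsewhere; carriers are drawn independently of the
haplotypes (locus-level linkage between the TE allele and the swept
haplotypes is not modelled, and no statistic here consumes it).

`simulate_te_genotype_matrix()` plants the purifying-selection signature:
with category-dependent probability `low_freq_prob` (CDS/UTR 0.9 vs
intergenic 0.4 by default) a locus draws its frequency uniformly from
(0.005, 0.1]; otherwise it draws from the U-shaped Beta(0.3, 0.3) baseline
*truncated above 0.1*, so `low_freq_prob` is exactly the planted
P(frequency ≤ 0.1) — the parameter the downstream bias test estimates. 10%
of loci are population-specific; accession counts default to the 23/35/29
NE/NW/S panel.
`simulate_landscape()` plants the expression effect: genes on 20-kb slots,
one TE per gene at a controlled distance (15% inside an intron, distance 0),
expression $= (\beta_0 + \beta\,\min(d, 1\,\mathrm{kb})/1\,\mathrm{kb})
\cdot m^{[\mathrm{siRNA+}]} \cdot$ mean-one lognormal noise, with defaults
$\beta_0 = 5$, $\beta = 4$ FPKM per kb, multiplier $m = 2$, noise SD 0.3,
and per-timepoint factors peaking at 36 h. The multiplier scales the whole
expected expression of siRNA+ genes (not only the distance term), which is
what makes the stratum-mean ratio recover $m$ exactly — the planted
twofold difference is the quantity the downstream contrast estimates. siRNA+ TEs receive
stacks of ≥ 12 mutually overlapping 24-bp reads; 30% of siRNA− TEs receive
sub-threshold stacks (≤ 5 reads) so the 10-read rule is actually exercised.

What the generators do **not** emulate: recombination and linkage maps,
demography beyond symmetric drift, genotyping error, TE dosage (presence is
a dominant carrier marker, as read-signature callers report), mapping-depth
artefacts, and sequence content (haplotypes are binary over sites).

## siRNA, landscape and frequency conventions

* 24-nt reads form clusters as *overlapping*-read connected components
  (adjacency does not connect); clusters below 10 reads are discarded;
  clusters whose edge-to-edge gap is ≤ 150 bp merge transitively (the
  boundary is inclusive: a 150-bp gap merges, 151 does not). "Matched" TE =
  ≥ 1-bp genomic overlap with a locus. A center-to-center reading of the
  merge rule is not used; the edge-gap reading is the config default.
* Genic categories use coding-most precedence CDS > 5′UTR > 3′UTR > intron >
  promoter2kb > downstream2kb > intergenic, with ties between genes resolved
  by larger overlap then smaller start coordinate. The promoter flank is
  measured from the TSS by default (`promoter_from = "start_codon"`
  selectable; annotations differ on the anchor in practice).
* Distances are measured from the TE's nearest edge. A TE overlapping the
  gene body has distance 0 ("TEs in intron or UTRs").
* Insertion frequencies are complete-case carrier frequencies (NA genotypes
  excluded from numerator and denominator; no imputation is attempted). The low-frequency bias test is a one-sided Fisher's exact test
  (enrichment of frequency ≤ 0.1 insertions in each category vs intergenic),
  Benjamini–Hochberg corrected across categories; BH is chosen over
  Bonferroni to match the enrichment framing, and the reported odds ratio is
  the cross-product ratio. The timepoint contrast is a *paired* Student's
  t-test (the same genes are measured at both timepoints); when the
  differences have zero variance the p-value is defined as 1 for a zero mean
  difference and 0 otherwise.

## Numerical choices and degenerate inputs

* Tajima's D returns NaN for S = 0 (flagged undefined) and for n < 4 (with a
  warning); a numerator below 1e−12 in absolute value returns exactly 0 so
  the "D = 0 when π = θ_W" identity holds in floating point.
* Fst is NaN (flagged) when there is no variation at all; windows with no
  retained SNP are emitted with NaN statistics rather than dropped.
* `rod_screen` marks a region inconclusive when fewer than half of its
  central windows have π_ref > 0; `tajd_confirm` is inconclusive when either
  population has no segregating flank site.
* Stage thresholds use `quantile(type = 7)`; ties at the stage-1 threshold
  are included (so tightening q can only shrink the candidate set).
* Coordinates are 0-based half-open everywhere internally; GFF3 and VCF are
  converted at the boundary; BED passes through. UTRs not annotated
  explicitly are derived by exact set subtraction of CDS from exons.

## Known limitations

* The multi-population generator's independent-site approximation understates
  the variance of windowed statistics relative to linked data; empirical
  percentile thresholds absorb the scale but not the genealogical
  correlation.
* The heterozygous handling of TE carriers is carrier/non-carrier; dosage is
  not modelled.
* `nearest_gene_distance` measures gene-body edges by default; the codon
  anchor is available by flag and the two differ for genes with UTRs.
* The CLI covers the pipeline stages one directory at a time; it does not
  orchestrate multi-stage runs in one invocation.
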