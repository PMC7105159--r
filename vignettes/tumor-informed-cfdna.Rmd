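---
title: "Tumor-informed detection of copy-number alterations in plasma cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed detection of copy-number alterations in plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Benign uterine leiomyomas (LM) and malignant leiomyosarcomas (LMS) can be
clinically indistinguishable before surgery. A blood test that detects
tumor-derived DNA circulating in plasma (ctDNA) could help, but it first
has to be established that benign smooth-muscle tumors shed DNA into the
circulation at all, and how much signal shallow (~0.1x) whole-genome
sequencing of plasma cell-free DNA (cfDNA) can recover from them.

`plasmacna` implements the tumor-informed strategy for this setting: the
patient's own tumor is profiled for copy-number alterations (CNAs, e.g.
by SNP array), and plasma cfDNA is then interrogated *only at those
regions*, which dramatically reduces the multiple-testing burden compared
with genome-wide screening. The package also implements the clinical
companion analyses: threshold rules on serum LDH and age, Welch t-tests,
prevalence-adjusted predictive values, and mutation-recurrence tallies.

## The statistic

Plasma and healthy-donor samples are reduced to fragment counts on a
fixed grid of 1 Mb bins over 22 autosomes (sex chromosomes are excluded:
the donor panel is male, patients female). For a sample with corrected
count $c_i$ in bin $i$, the normalized signal is

$$\ell_i = \log_2\!\frac{\max(c_i / \textstyle\sum_j c_j,\ \epsilon)}
                        {\max(m_i,\ \epsilon)},$$

where $m_i$ is the median bin fraction across the donor panel and
$\epsilon$ is a pseudo-count floor (half the smallest positive $m_i$)
guarding empty bins at shallow coverage. For a genomic region $R$ (a
tumor CNA, or a segment), the **segmented Z-score** standardizes the
sample's region mean against the *same region mean computed in every
panel donor*:

$$Z_R = \frac{\bar\ell_R - \mathrm{mean}_d(\bar\ell_{R,d})}
             {\mathrm{SD}_d(\bar\ell_{R,d})}.$$

This donor-projection denominator absorbs inter-bin correlation and any
shared systematic structure; it is *not* the per-bin SD divided by
$\sqrt{n}$, which would be anti-conservative when bins are correlated.
A tumor CNA is called **detected in plasma** when (1) the sign of the
plasma region mean matches the tumor call (gain: positive; loss:
negative), and (2) the sign-specific tail exceeds the cutoff
($Z_R > 1.5$ for gains, $Z_R < -1.5$ for losses). Direction matching
before thresholding mirrors the two-stage logic of tumor-informed
screening and halves the per-region false-positive rate (one-sided
$\approx 6.7\%$ per region under ideal calibration).

By default the Z-score for a CNA is computed over the CNA's own genomic
footprint. This is deterministic and free of selection bias; the
alternative of scoring the overlapping plasma segment with maximal
$|Z|$ is available via `footprint = "max_segment"` in
`evaluate_cna_in_plasma()`.

## Pipeline stages

1. **Binning** (`make_bins`, `count_fragments`): fragments are assigned
   to half-open 1 Mb bins by midpoint. All coordinates are 0-based,
   half-open (BED convention) throughout.
2. **Masking** (`mask_bins`): bins with GC outside [0.30, 0.70] or zero
   median count across the donor panel are excluded from every
   statistic.
3. **GC correction** (`gc_correct`): a lowess fit of count on GC
   fraction is divided out and the result rescaled to the raw mean; a
   per-GC-decile median ratio serves as fallback for inputs too small
   for a stable local fit (fewer than ten distinct GC values). At least
   50 usable bins are required.
4. **Panel normalization** (`build_panel`, `to_log2_ratio`): log2
   ratios against the panel median fraction, as above. The panel
   retains the full donor-by-bin log2 matrix for region statistics, and
   floors per-bin SDs at the 5th percentile of positive SDs so
   degenerate bins cannot yield infinite Z-scores. Region-level donor
   SDs are floored at that value scaled by $1/\sqrt{n_\text{bins}}$.
5. **Segmentation** (`segment_profile`): CBS-style recursive
   segmentation per chromosome. Each step places the inner segment (or
   edge split) maximizing the two-sample t-statistic against the rest
   of the interval and accepts it when a permutation test (default 200
   permutations) gives $p < \alpha$ (default 0.01); accepted splits are
   recursed, and adjacent segments whose means differ by less than
   0.05 log2 units are merged. The permutation stream of each candidate
   interval is seeded by the interval itself, so lowering $\alpha$ can
   only remove breakpoints — never rearrange them.
6. **Tumor CNA calling** (`call_tumor_cnas`): segments of an array-like
   tumor log2 profile are called gains at mean $\ge +0.2$ and losses at
   $\le -0.2$ (single-copy events at moderate purity); pre-called BED
   input is accepted instead via `read_cna_bed()`, since tumor profiling
   is typically done on an external array platform.
7. **Detection and summaries** (`detect_patient`,
   `percent_genome_altered`, `donor_specificity`,
   `tumor_plasma_agreement`): per-CNA records, the patient-level
   any-CNA-detected flag, percent of genome altered (union length of
   detected regions over total genome length), leave-one-out donor
   specificity screens, and the tumor-log2 versus plasma-Z regression.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bin_size` | 1 Mb | grid resolution; ~2,880 autosomal bins |
| `mean_depth` | 30 fragments/bin | desk-scale stand-in for ~0.1x coverage |
| `dispersion` | 0 (Poisson) | negative-binomial overdispersion of bin counts |
| `gc_bias_amplitude` | 0 | strength of the unimodal multiplicative GC bias |
| `z_cut` | 1.5 | direction-matched detection threshold |
| `alpha` | 0.01 | permutation significance for a split |
| `min_seg_bins` | 3 | minimum bins per segment |
| `merge_tol` | 0.05 | log2 closeness below which adjacent segments merge |
| `gain_thresh` / `loss_thresh` | +0.2 / −0.2 | tumor CNA call thresholds |
| LDH cutoff | ≥ 279 U/L (inclusive) | clinical rule, test-positive = LMS |
| age cutoff | > 49 y (strict) | clinical rule, test-positive = LMS |

## The synthetic cohort generator

All validation inputs are generated in code (`simulate_*`), so the full
pipeline runs with no external data:

* **GC track**: a stationary AR(1) process ($\phi = 0.9$, correlation
  length ~10 bins) squashed through tanh into [0.3, 0.7]. This emulates
  isochore-scale GC structure: neighboring megabase bins are similar,
  but a 100-bin region still spans a wide GC range. An unbounded random
  walk would instead trap whole regions inside one narrow GC band and
  let the GC fit absorb genuine CNA signal.
* **Counts**: negative binomial with mean
  `mean_depth * g(gc)`, where `g` is a smooth unimodal curve peaking
  near GC 0.45, normalized to mean one. `dispersion = 0` (the default)
  gives the Poisson limit — the idealized calibration condition used by
  the validation suite; overdispersion and GC bias are switched on
  explicitly where the tests exercise the correction stages.
* **Tumor truth**: non-overlapping CNA regions with copy numbers
  {1, 3} by default (single-copy events dominate leiomyomas; 0–6
  available), boundaries aligned to the bin grid so closed-form
  expectations are exact. Zero-CNA tumors model the tumors this method
  is inherently blind to.
* **Plasma admixture**: the expected count of a bin with tumor copy
  number $c$ is scaled by $1 + \mathrm{tf}\,(c/2 - 1)$ at tumor
  fraction $\mathrm{tf}$; $\mathrm{tf} = 0$ reproduces the donor model
  bit-for-bit under the same seed.
* **Clinical covariates**: zero-truncated Gaussians with means LDH
  191/288 U/L and age 48/54 y for LM/LMS. The SDs (40/80 U/L, 9/10 y)
  are stand-ins chosen to make the group overlap realistic; they are
  not asserted anywhere.

What the generator does **not** emulate: fragment-length and end-motif
biology, mappability artifacts, germline CNVs, read-level errors, and
the between-donor correlation structure of real panels. Passing tests
therefore demonstrate the statistical machinery under the model's own
assumptions, not performance on real sequencing data — in particular,
real-panel correlations are why an observed donor specificity on real
data can exceed the independent-region analytic null.

## Numerical choices

* Every generator is a pure function of its parameters and a seed; the
  RNG state of the caller is saved and restored.
* The pseudo-count is applied as a floor (`pmax`), not additively: at
  ~30 counts per bin the smallest positive bin fraction is a sizeable
  share of a typical fraction, and the additive form would compress all
  log2 ratios by roughly 20%, breaking closed-form expectations such as
  "doubled representation gives log2 of 1".
* Fragment-to-bin assignment uses the midpoint, with a boundary
  midpoint belonging to the right-hand bin (half-open convention).
* Welch t-tests, Wilson intervals (sensitivity/specificity) and
  standard-logit intervals (predictive values) are used for the
  clinical rules; the interval method is switchable, and degenerate
  denominators are flagged rather than raised.
* Validation problem sizes: the suite exercises the default desk-scale
  genome (~2,880 bins) with 25-donor panels for calibration (500
  regions, leave-one-out), spike-in recovery (100 seeded runs), and the
  donor-specificity null (200 replicates on a 600-bin genome, 11 query
  regions — the analytic null $(1 - 0.0668)^{11} \approx 0.47$ is
  layout-independent, so the smaller genome only buys speed).

## Known limitations

* **Power at low tumor fraction.** For a 100-bin single-copy gain at
  tumor fraction 0.10 and 30 fragments per bin, the expected region
  shift is $\log_2 1.05 \approx 0.070$ while the donor-projection SD is
  $\approx 0.026$ (Poisson noise, 100 bins), so $E[Z] \approx 2.5$ and
  the detection probability at the 1.5 cutoff plateaus near 0.85 — the
  25-donor SD estimate (24 df) costs a few points over a known-variance
  ideal. Detecting such events reliably requires deeper sequencing,
  larger regions, or higher tumor fraction; the acceptance suite
  reports the measured rate as-is.
* Patients whose tumors carry no CNAs are invisible to the method by
  construction.
* No mutation-based (deep targeted sequencing) detection arm; the
  copy-number arm is the package's scope.
* The segmentation permutation test has a resolution floor of
  $1/(n_\text{perm}+1)$; exact-recovery comparisons against the
  exhaustive oracle therefore use more permutations at a stricter
  $\alpha$ to suppress the ~1%-per-interval chance split rate.

## A minimal run

```{r example}
library(plasmacna)

layout <- default_layout()
gc <- simulate_gc_track(layout, seed = 11)

donors <- lapply(1:25, function(i)
  simulate_donor_counts(layout, gc, mean_depth = 30, seed = 100 + i,
                        sample_id = sprintf("HD%02d", i)))
panel <- build_panel(donors)

truth <- simulate_tumor_truth(layout, n_cnas = 6, tumor_fraction = 0.2,
                              seed = 5)
tumor <- simulate_array_profile(truth, layout, noise_sd = 0.1, seed = 6)
calls <- call_tumor_cnas(tumor, layout)

plasma <- simulate_plasma_counts(truth, layout, gc, tumor_fraction = 0.2,
                                 seed = 7, sample_id = "LM01")
plasma <- to_log2_ratio(gc_correct(plasma), panel)

det <- detect_patient(calls, plasma, panel, z_cut = 1.5)
det$detected
percent_genome_altered(det$records, layout)$pct_genome_altered
donor_specificity(donors, calls, z_cut = 1.5)$specificity
```
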