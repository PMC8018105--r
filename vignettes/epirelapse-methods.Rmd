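---
title: "Methods: paired primary-relapse methylome comparison"
author: "epirelapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired primary-relapse methylome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirelapse)
```

## The problem

Ependymomas relapse frequently, and it is an open question how much a
relapsed tumor differs from its matched primary at the epigenetic level.
This package implements the comparison of paired primary and relapse DNA
methylation profiles measured on 450K-style arrays, at four levels:

1. **Probe level.** For every CpG probe, a paired test of relapse versus
   primary methylation on the M scale.
2. **Substructure level.** A comparison of mean beta values between the two
   groups within each CpG-island epigenomic substructure (islands, shores,
   shelves). Shores are the regions up to 2 kb on either side of an island
   (N = upstream, S = downstream); shelves are the next 2 kb beyond the
   shores; everything else ("open sea") is treated as unmapped and excluded.
3. **Direction level.** The decomposition of significant probes into hypo-
   and hypermethylated fractions per substructure, which asks *where* in
   the genome methylation is gained or lost at relapse.
4. **Copy-number level.** A per-patient log2 ratio of total probe intensity
   (methylated + unmethylated channel) between relapse and primary, viewed
   over the most variable loci.

Unpaired t-tests for histomorphology scores (cell density, necrosis,
vessel proliferation, Ki67 index) complete the picture on the phenotype
side.

## Scales and statistics

Beta values (methylated share of total signal, in $[0,1]$) are what the
array reports and what humans read; M values,
$M = \log_2\!\big(\beta/(1-\beta)\big)$, are variance-stabilized and are
the scale on which probe-level tests run. The package never mixes the two
scales inside one statistic: probe tests and the hypo/hyper sign
classification use M-value differences ("logFC"), while the substructure
comparison uses group mean betas, which is how such results are usually
displayed. Betas are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-3}$ before the logit, the standard guard for fully
(un)methylated probes; the inverse transform is exact away from the clip.

**Probe test.** Pairing one primary and one relapse sample per patient
reduces the paired linear model to a one-sample t-test on the per-patient
M differences. The default pairing takes each patient's first relapse;
`all_relapses_averaged` instead averages all of a patient's relapse
samples, for cohorts where patients recur repeatedly. A variance floor
(default $10^{-8}$) prevents infinite statistics at near-constant probes;
a probe with mean difference zero and zero variance reports $t=0$, $p=1$.
Empirical-Bayes variance moderation is available (opt-in): a scaled
inverse-chi-square prior is fitted to the per-probe variances by moment
matching on the log variances (digamma/trigamma corrections, Newton
inversion of the trigamma function), and the moderated t gains the prior
degrees of freedom. When the observed log-variances show no excess
dispersion beyond sampling noise, the prior collapses to a point at the
average variance. Multiple testing uses Benjamini-Hochberg throughout.

**Substructure test.** For each substructure the per-probe primary-mean
and relapse-mean vectors are compared with a two-sided t-test.
Whether those two vectors should be treated as paired (each probe
contributes a matched pair of means) or as independent samples is
genuinely ambiguous in this design; the package implements both and
defaults to the paired form, which respects the obvious probe-level
coupling and is by far the more powerful choice. Results label the mode.

**Fractions.** Significant probes (raw $p < \alpha$, default
$\alpha = 0.05$; the adjusted p is available by flag — raw is the default
because the decomposition is a descriptive screen, not a ranked
discovery list) are classified by the sign of their logFC: negative =
hypomethylated, positive = hypermethylated. An exact zero falls in
neither class and is excluded from the fraction denominators, which
preserves the accounting identity hypo + hyper = significant-with-signed-
change. Unmapped probes are excluded, matching the substructure analysis.

**Copy number.** Total intensity is the methylated + unmethylated channel
sum. The per-patient log2 ratio uses a pseudocount of 1 intensity unit,
and each patient column is median-centered by default so the genome-wide
median ratio is zero — a deliberately simple stand-in for the internal
normalization that dedicated CN pipelines perform, stated as such. The
cohort view keeps the top 1000 loci by variance of the ratio across
patients (ties broken by genomic position, so selection is
deterministic); `max_abs` is available as an alternative criterion. No
segmentation is performed: the output is locus-level, as in the heatmap
this view reproduces.

**Morphology.** The unpaired t-test defaults to the pooled-variance
Student form because that variant reproduces the published Ki67
significance from the printed group summaries; Welch and a rank-based
alternative are provided. `t_from_summary()` works directly from
(mean, SEM, n) triples, so printed summaries can be checked without the
raw scores.

## The synthetic cohort generator

`simulate_dataset()` draws paired cohorts with known ground truth. Its
defaults are fixed once and encode the study design the package targets:

* **Cohort structure**: five molecular subgroups with 11/2/23/7/2
  patients (ST-EPN-RELA, PF-SE, PF-EPN-A, PF-EPN-B, SP-MPE), one primary
  and one relapse sample each; multi-relapse patients are available
  through `relapses_per_patient`. The two n = 2 subgroups deliberately
  exercise the df = 1 degenerate paths.
* **Substructure proportions**: the 450K annotation's category counts
  (150,254 islands; 62,870/49,197 N/S shores; 24,844/22,300 N/S shelves;
  176,112 unmapped out of 485,577 probes), scaled to `n_probes`.
* **Baseline betas**: a two-component Beta mixture, $B(1.5, 15)$ (low)
  and $B(15, 1.5)$ (high), with low-component probability 0.8 for
  islands, 0.5 for shores and 0.15 for shelves/open sea. This reproduces
  the canonical bimodal 450K histogram with mostly-unmethylated islands
  and mostly-methylated open sea.
* **Noise**: a per-(probe, patient) random effect on the M scale
  (SD 0.5 log2 units) shared between a patient's samples, plus residual
  noise (SD 0.3) per sample — values in the range of observed
  between-patient and technical-replicate variability on these arrays.
  Because the patient effect cancels in within-patient differences, the
  paired test's calibration follows from the residual term alone.
* **Planted effects**: relapse shifts are specified on the beta scale
  (`delta_island`, `delta_shelf`, per subgroup), applied to the mean
  before the M-scale noise. With the default noise levels the logistic
  smoothing distorts a planted shift of 0.05 by well under 0.001 in the
  recovered group-mean difference, so truth-table comparisons can be made
  on the beta scale directly.
* **Intensities**: log-normal totals (median 5000 units, $\sigma_{\log} =
  0.1$, i.e. ~10% coefficient of variation, typical of within-batch
  total-intensity reproducibility after scaling). A copy-number event
  multiplies totals at covered loci in relapse samples of its subgroup;
  the expected log2 ratio is exactly $\log_2(\text{factor})$.
* **Genome**: 22 equal-length (100 Mb) synthetic autosomes; sex
  chromosomes are excluded so simulated CN events are never
  sex-confounded.

What the generator does **not** model: Infinium I/II probe-chemistry
differences, batch effects, cell-composition heterogeneity, spatial
correlation along the genome (outside planted events), and missingness
mechanisms. Passing recovery tests on this generator therefore
demonstrates the estimators' correctness and calibration under a clean
paired design — not robustness to those real-data artifacts.

## Numerical and design choices

* Degenerate inputs are contracts, not crashes: subgroups with fewer than
  2 complete pairs yield an empty probe table with a warning;
  substructures with fewer than 2 probes yield a flagged row; patients
  without a primary are dropped with a count; loci with zero intensity in
  both pair members are dropped with a count.
* Missing betas are carried as missing; every per-probe statistic uses
  pairwise-complete samples and records the effective n.
* All randomness flows from a single config seed; the pipeline writes
  byte-identical reports for identical seeds, which the test suite
  asserts at cohort scale.
* The test suite validates the analytic p-values against exhaustive
  enumeration: all $2^n$ sign flips for the paired test ($n \le 10$) and
  all $\binom{8}{4}$ label assignments for the unpaired test. The
  discrete permutation p and the continuous Student p differ by a
  discretization error that shrinks roughly like $2^{-n/2}$; the
  assertions bound the deviation at $1.4 \cdot 2^{-(n-2)/2}$ per instance
  plus a mean-deviation bound, rather than pretending the two are equal.
* Variance moderation is cross-checked against an independent
  implementation (limma's `squeezeVar`) and against parameter recovery
  from the generating prior.

### Problem sizes

The packaged validation suites run at 10,000-20,000 probes with 20-45
patients — large enough that a 0.05 beta shift is estimated to three
decimals and binomial bounds on the type-I rate are tight (+-0.4% at
20,000 probes), while a full run stays in seconds. The accounting checks
(485,577-probe partition; 58,505-probe hypo/hyper split) run at full
scale since they are pure bookkeeping.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_probes = 10000,
                  delta_island = c("ST-EPN-RELA" = 0.05),
                  delta_shelf = c("ST-EPN-RELA" = -0.03),
                  cna_events = list(list(subgroup = "ST-EPN-RELA",
                                         chromosome = "chr1",
                                         start = 1, end = 5e7,
                                         factor = 1.5)),
                  seed = 7)
ds <- simulate_dataset(cfg)
fit <- relapse_fit(ds)
summary(fit)
plot(fit, type = "fractions")
```

## Known limitations

* No raw-array (IDAT) support and no normalization: inputs are
  preprocessed beta/intensity matrices, as distributed in public
  repositories.
* The substructure t-test treats probes as independent observations;
  neighboring probes are correlated in real data, so its p-values are
  anti-conservative there. The direction and magnitude of the mean
  difference are unaffected.
* The CN view is locus-level log ratios without segmentation or reference
  calibration; it ranks and visualizes change, it does not call absolute
  copy number.
* Published summary statistics are printed rounded; checks against them
  (e.g. the Ki67 p-value) are asserted at the granularity of the last
  printed digit.
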