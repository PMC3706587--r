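---
title: "Allele-specific copy number from flow-sorted SNP arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number from flow-sorted SNP arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lairseg)
```

## The problem

Tumor genomes carry two kinds of chromosomal aberration that a two-channel
SNP array can see: changes in total copy number (gains and losses) and
changes in allelic balance (allelic imbalance, or loss of heterozygosity,
LOH, where one parental allele is absent regardless of total copy number).
Copy-neutral LOH is invisible to total-intensity methods such as arrayCGH;
it requires per-allele information. `lairseg` implements an integrated
pipeline for cohorts of flow-sorted tumor samples with patient-matched
normals: because the tumor fraction is sorted to purity, allele signals are
not diluted by stroma, and the flow-cytometric DNA index (DI; the ratio of
tumor G0/G1 DNA content to normal stromal content, 1 for diploid, 2 for
tetraploid) provides an external anchor that converts relative array
intensities into absolute, discrete copy numbers.

The pipeline has five analysis stages plus a synthetic-cohort generator
used for testing and power studies:

1. **QC** of SNPs (Hardy-Weinberg, call rate in controls) and assays
   (minimum raw median intensity).
2. **Normalization** of the two dye channels in four steps.
3. **LAIR** computation at informative SNPs and **segmentation** of each
   genome (circular binary segmentation of total intensity, then
   sub-segmentation of LAIR).
4. **Allelic-state calling** per segment, anchored to the DI.
5. **Cohort statistics**: unified breakpoints, permutation global tests of
   genomic profiles against clinical parameters with confounders, and
   arm-level localization under Benjamini-Hochberg FDR.

## Measures

For a SNP with channel intensities $I_A, I_B$ the B-allele ratio is
$b = I_B/(I_A+I_B)$. The **lesser allele intensity ratio** (LAIR) is the
ratio of the weaker to the stronger allele signal,

$$\mathrm{LAIR} = \frac{\min(I_A, I_B)}{\max(I_A, I_B)}
               = \frac{\min(b, 1-b)}{\max(b, 1-b)},$$

i.e. the B-allele ratio mirrored at its symmetry axis 0.5 and rescaled to
$[0,1]$: 1 for a balanced heterozygous locus, 0 under LOH. LAIR is only
meaningful at **informative** SNPs — those heterozygous in the patient's
matched normal. For a segment with allele copy numbers $(p, q)$,
$p \ge q$, the noise-free LAIR expectation is $q/p$. An alternative
mirroring, $2\min(b, 1-b)$, appears in the literature; it differs for
imbalanced states (2/3 instead of 1/2 for state AAB). We use the literal
lesser/greater intensity ratio; the caller's expected values ($q/p$) are
consistent with this choice and the two must be switched together.

The **continuous copy number** of a segment, $r$, is its mean normalized
total intensity divided by the sample mean, so the SNP-weighted genome
average of $r$ is 1 regardless of ploidy. Gains and losses are deviations
of more than 15% from the sample average. The **discrete copy number**
$c = p + q$ is absolute: calling is anchored so that the length-weighted
genome mean of $c$ reflects $2 \times \mathrm{DI}$.

## QC rules

SNPs are filtered on the control (normal) genotypes: a 1-df chi-square
Hardy-Weinberg test without continuity correction (the control sample size,
tens of individuals, is large enough for the asymptotic test; an exact test
is the conservative alternative) at threshold $0.05 / n_\text{analyzed}$,
where $n_\text{analyzed}$ counts SNPs with at least one called genotype —
with a 6000-SNP panel this is $10^{-5}$ — and a minimum call rate of 95%.
Assays are rejected when the raw median intensity of either allele channel
is below 2000 instrument units. The kept SNP set is the intersection of the
filters and does not depend on evaluation order.

## Normalization

Four steps, each with a testable contract:

* **I, between dyes.** Quantile normalization of the two channels: each
  quantile is replaced by the mean of the two channels' quantiles (ties
  get the mean of their ranks' targets). Contract: sorted channel
  distributions are identical afterwards.
* **II, between sub-arrays.** The assay is spread over four sub-arrays
  with their own intensity scales; the pooled (both-channel) distributions
  of the sub-arrays are quantile-normalized within the sample, with
  interpolation when sub-array sizes differ. Note that this step reorders
  intensities *across* sub-arrays by design — that is the batch effect it
  removes; rank order is preserved within each sub-array.
* **III, within sample.** Each channel is divided by its median, so both
  allele channels have sample median 1 (idempotent).
* **IV, per SNP between samples.** Using the reference normals: (a) the
  total intensity at each SNP is scaled in all samples so the reference
  mean equals 2 (the diploid target); (b) the allele-specific bias is
  corrected by a least-squares line of total intensity on B-allele ratio
  across heterozygous references, divided out of every sample's total.
  Homozygous references contribute to (a) only, since their B-allele ratio
  carries no balance information. The line is *interpolated only*: a
  sample's BAF is clamped to the reference BAF range before prediction,
  because the heterozygous references cluster near BAF 0.5 and
  extrapolating the fitted line to BAF 0 or 1 (exactly where tumor LOH
  segments live) would amplify slope noise into large intensity
  distortions. Normal-stroma references are ordinary reference normals.

With zero simulated noise and channel-symmetric genotype counts the full
chain maps a balanced diploid normal to $I_A = I_B = 1$ at every
heterozygous SNP exactly; with unequal homozygote counts the between-dye
quantile normalization leaves $O(1/n)$ effects at the edges of genotype
blocks, a property of quantile normalization on finite panels rather than
a defect.

## Segmentation

Each chromosome's total-intensity track is segmented by circular binary
segmentation (CBS): the arc $(i, j]$ maximizing the circular two-sample
t-statistic between probes inside and outside the arc is accepted as a
split when its permutation p-value (default 10,000 label shuffles, seeded)
is at most $\alpha = 0.01$, and the procedure recurses on the pieces.
Minimum segment width is 2 probes. A sequential early stop abandons the
permutation loop as soon as the exceedance count already guarantees
$p > \alpha$; this changes no decision and makes flat regions cheap. A
noiseless step is found exactly (degenerate zero-variance splits get a
sentinel statistic); constant input is never split. No "undo" pruning step
is applied. Within each intensity segment, the LAIR values of its
informative SNPs are segmented the same way, and the final segmentation is
the refinement of the two — this is what detects copy-neutral LOH, which
total intensity cannot see. Per final segment we report $r$ (mean total
intensity over sample mean; the mean matches copy-number additivity) and
`lair_seg`, the median LAIR over informative SNPs (median for robustness to
residual homozygote misclassification; segments with fewer than
$k_\min = 5$ informative SNPs get a missing LAIR). Segment bp bounds are
1-based inclusive and cut midway between flanking SNPs so segments tile
each chromosome. The X chromosome is treated as an autosome (the intended
cohorts are all female).

## Allelic-state calling

Candidate states are all $(p, q)$ with $p \ge q \ge 0$ and
$1 \le p+q \le c_\max$ plus the homozygous deletion $(0,0)$; the default
$c_\max = 8$ accommodates DNA indices above 2.5. Each state has noise-free
expectations $r^* = c/(2 \cdot \mathrm{DI})$ and $\mathrm{LAIR}^* = q/p$.
A segment is assigned the state minimizing

$$w_r\,(r - r^*)^2 + w_l\,(\mathrm{lair\_seg} - q/p)^2,$$

with the LAIR term dropped when the segment LAIR is missing or $p = 0$
(default weights 1, 1; the measured flow-cytometric DI is used, not any
truth value). Ties resolve to the smaller total copy number, then the
smaller $p - q$: parsimony toward simpler states. Homozygous deletion is
eligible only when $r < 0.25/\mathrm{DI}$, so noise is not labeled
nullisomy. Balance classes follow from $(p,q)$: balanced ($p = q \ge 1$),
LOH ($q = 0$, $p \ge 1$), imbalance ($p > q \ge 1$); $c = 0$ is labeled
"–" with balance unknown.

After calling, the ploidy contract is checked: the length-weighted mean
discrete copy number $m$ must satisfy
$|m/2 - \mathrm{DI}| \le 0.15\,\mathrm{DI}$. On failure the calling is
retried over a global intensity rescale grid ($\times 0.8$ to
$\times 1.25$ in steps of 0.05) and the rescale minimizing the deviation is
kept, with the sample flagged — the upstream data do not specify what to do
when array and flow cytometry disagree, so the fallback is explicit and
always visible in the output.

## Cohort statistics

Breakpoints of every sample are applied to all samples: the unified grid is
the per-chromosome union of all segment boundaries (plus the centromere, so
no cell spans two arms), and each sample's segment values are copied onto
the cells they span. This conserves every sample's length-weighted mean of
every measure exactly and makes samples comparable. Four measures are
tested: continuous CN, discrete CN, LAIR, and balance state (one-hot
encoded as balanced/imbalance/LOH indicator columns per cell, unknowns
mean-imputed).

The **global test** asks whether a samples-by-features matrix $X$ differs
between outcome groups while tolerating strongly correlated features. With
outcome indicators $y_g$ (a single column for two levels, one-vs-rest for
more; multi-level histologies can optionally be merged in configuration)
and null-model fitted values $\hat\mu_g$ from a regression of the outcome
on the confounders $Z$ (logistic; stratum proportions when all confounders
are categorical), the statistic is

$$Q = \frac{1}{m} \sum_g (y_g - \hat\mu_g)^\top X X^\top (y_g - \hat\mu_g).$$

Inference is by permutation of the outcome within confounder strata
(categorical confounders define strata; continuous confounders are binned
into tertiles for stratification — a balance between stratum size and
confounder resolution — while staying continuous in the null fit), with
$p = (1 + \#\{Q_\text{perm} \ge Q_\text{obs}\})/(1 + B)$. Permutation is
the primary inference because it is assumption-light; on small cohorts an
exhaustive enumeration of distinct outcome assignments is available and is
the exact oracle the sampled version is tested against. When all
confounders are categorical, stratum means are invariant under
within-stratum permutation, so residual rows are permuted directly and the
loop is vectorized; a continuous confounder (DI) forces a null-model refit
per permutation.

In the genome-wide parameter scan, ethnic cluster is a confounder in every
test (ancestry affects both genotype informativeness and aberration
patterns); DI is an extra confounder for continuous CN. Discrete CN
already absorbs DI by construction, so adding DI as its confounder is a
secondary analysis option rather than the default. Near-constant clinical
parameters (over 95% one level) are skipped with a logged reason.
Parameters showing a genome-wide difference are localized by per-arm global
tests with Benjamini-Hochberg step-up FDR across tested arms (significant
below 0.05); arms with fewer than 5 panel SNPs — in particular the
acrocentric short arms 13p, 14p, 15p, 21p, 22p, which carry no SNPs — are
excluded, leaving roughly 40 testable arms. Ancestry itself is assigned by
principal components: patient and reference genotype dosages on shared SNPs
are centered and scaled, the top two PCs are taken, and each patient gets
the label of the nearest reference-population centroid, with the two East
Asian reference populations merged a priori into one cluster.

## The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes, so
every stage is testable against ground truth:

* **Genome**: 22 autosomes + X with hg18-like lengths and centromeres,
  scaled down 100-fold by default so that full cohorts segment in seconds
  while keeping realistic relative arm sizes.
* **Panel**: SNPs placed proportionally to chromosome length, four
  sub-arrays assigned round-robin, population allele frequencies from a
  Balding-Nichols model (ancestral frequency Uniform(0.05, 0.95),
  population frequencies Beta-distributed with divergence FST, default
  0.15). Acrocentric short arms carry no SNPs.
* **Truth profiles**: baseline (1,1) everywhere; per-arm events drawn from
  group-specific priors overwrite $(p,q)$ on the whole arm (probability
  0.5) or a random sub-interval. Event states: loss (1,0), gain (2,1),
  copy-neutral LOH (2,0), imbalance (3,1). A whole-genome duplication
  (default prevalence 0.5) doubles all states, which produces the bimodal
  DNA-index distribution with modes near 1 and 2 seen in flow-sorted
  cervical tumor cohorts. Default group structure: 40 "squamous" vs 20
  "adenosquamous" samples with a planted 2q-loss enrichment (priors 0.45
  vs 0.10) over a background of 0.04 per arm per event type — numbers
  chosen to mirror the frequencies reported for bulky cervical carcinomas.
* **Assays**: at heterozygous-normal SNPs the major/minor allele counts go
  to channels A/B uniformly at random per SNP, so the B-allele ratio is
  symmetric around 0.5 as in real data; homozygous SNPs put all copies on
  the called allele. Intensity model:
  $\text{gain} \times \text{dose} \times \text{dye}_A \times f_s \times
  e^{N(0, \sigma_m)} + N(0, \sigma_a)$, floored at 0, with default gain
  3000 units/copy, dye bias 1.2 on channel A, sub-array factors
  (1, 0.9, 1.1, 1.05) and $\sigma_m = 0.1$. The true assay noise
  distribution of the instrument is not known; this lognormal-times-additive
  model is a stand-in with every parameter exposed in `sim_config()`.
* **DNA index**: the truth value is the length-weighted mean total copy
  number over 2, recomputable from the truth segments exactly; a relative
  Gaussian measurement error (`sd_di`) can be added to emulate flow
  cytometry.

What the generator does **not** emulate: subclonal mixtures (flow sorting
yields pure populations), tumor-in-normal contamination, GC waves, and
FFPE-specific artifacts beyond generic noise. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artifact of archival material.

## Numerical choices and degenerate inputs

* Quantile normalization targets the mean of sorted vectors; ties share
  the mean of their ranks' targets; unequal group sizes interpolate the
  empirical quantile functions.
* CBS uses the pooled-variance two-sample t on arcs; zero pooled variance
  with a real mean difference (noiseless steps) gets a large sentinel
  statistic so exact changepoints always win; constant input yields no
  splits. Segmentation seeds derive from the pipeline seed plus the sample
  index, so stages are reproducible independently of execution order.
* The caller's tie-break (smaller $c$, then smaller $p-q$) is applied
  after rounding costs at 1e-12 to make floating-point ties deterministic.
* BH adjustment guards the $\text{fdr} \ge p$ invariant against
  floating-point rounding of $p \cdot n / k$.
* Samples with missing outcome values are dropped per test, not imputed;
  permutation strata with fewer than 2 samples are merged into the largest
  stratum with a warning.

## Problem sizes used by the test suite

The packaged checks run on desk-scale problems chosen to exercise every
code path: parameter-recovery cohorts of 20 samples at 2000 SNPs with
multiplicative noise 0.1 and exact DI (the caller recovers the true
$(p,q)$ on well over 95% of genome length there, and the ploidy contract
holds for every sample); segmentation calibration on 100 replicates of
200-probe tracks with noise sd 0.2; global-test calibration over 1000 null
simulations at $n = 30$, $m = 50$ with 199 permutations each; and
power/false-positive studies of the planted 2q effect on 100 cohorts of
40 + 20 truth profiles evaluated directly on truth-level matrices
(simulating and segmenting intensities for hundreds of cohorts would add
nothing to those statistical questions).

## Known limitations

* **Arm-level power at the planted effect size.** With carrier
  probabilities 0.45 vs 0.10 at $n = 40/20$, the information ceiling for
  any test of the 2q difference is the exact test on carrier counts; its
  typical p-value (~0.007) cannot survive an FDR threshold of 0.05 across
  ~40 arms in most realizations. Detecting such an enrichment reliably at
  arm-level FDR needs either larger cohorts or fewer candidate arms; the
  package reports the honest detection rate rather than overstating it.
  Power is, as expected, monotone in the effect size, which is tested.
* The exact functional form of the step-IV bias correction and the
  per-segment LAIR summary (mean vs median) are under-determined by the
  upstream description; the choices here (interpolated linear correction,
  median) are explicit, logged, and configurable where it matters.
* Multiple tumor populations per case and purity estimation are out of
  scope: inputs are assumed flow-sorted pure, one population per patient.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_per_group = c(squamous = 6, adenosquamous = 4),
                  n_snps = 600, seed = 3)
coh <- simulate_cohort(cfg)
res <- run_pipeline(coh, seg = seg_params(n_perm = 2000),
                    n_perm_scan = 500, seed = 3)
print(res)
plot(res$freq, measure = "cn")
```
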