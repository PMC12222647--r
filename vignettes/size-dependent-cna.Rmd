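---
title: "Size-dependent CNA discovery: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-dependent CNA discovery: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Somatic copy-number alterations (CNAs) are routinely used for cancer risk
stratification, but published models call the "same" CNA — say loss of
chromosome 1p — at very different size thresholds: some require half the arm
to be lost, others call a CNA from a few percent. If the prognostic signal
carried by an arm depends on *how much* of it is altered, the choice of size
threshold is not a nuisance parameter but part of the biomarker definition.
`cnasd` implements a pipeline that treats the threshold as a quantity to be
estimated per chromosome arm and per direction (loss/gain), and then builds
downstream prognostic machinery — focal-region scans, co-occurrence
signatures, burden strata, a boosted risk score — on top of the optimized
calls.

## From segments to calls

Input is a SEG-format segment table (sample, chromosome, start, end, probe
count, mean log-intensity). Segments with mean intensity below −0.1 are
treated as lost and above 0.15 as gained; everything else, including
positions not covered by any segment, is neutral. Sex chromosomes and the p
arms of the acrocentric chromosomes (13, 14, 15, 21, 22) are excluded,
leaving 78 (arm, direction) features on 39 autosomal arms.

Per sample and arm, the *percent-arm-altered* fraction samples the arm at
30 kb intervals anchored at the arm start and counts the classified points,
so disjoint ("non-consecutive") focal events and broad events on the same
arm sum. Numerical conventions, all chosen for determinism:

* coordinates are 0-based half-open internally; SEG input is treated as
  1-based inclusive (the TCGA convention) and converted on read;
* a grid point on a segment boundary belongs to the segment whose half-open
  interval contains it;
* uncovered grid points stay in the denominator as neutral — absence of a
  segment is absence of evidence of alteration, and the denominator must be
  comparable across samples;
* overlapping segments within a sample are repaired by truncating the
  earlier at the later's start (with a warning), and centromere-straddling
  segments are split at arm boundaries, because all computation is per-arm.

A binary call at threshold $T$ is `fraction × 100 ≥ T`, with the boundary
inclusive (a comparison tolerance of 1e−9 absorbs binary-decimal rounding).

## Scoring thresholds: 5-year time-dependent ROC

Each binary marker is scored by the cumulative/dynamic time-dependent ROC
AUC at a 5-year horizon. We use the Kaplan–Meier-based (non-nearest-
neighbour) estimator: at marker cutoff $c$,

$$\widehat{\mathrm{sens}}(c) = \frac{\{1 - \hat S(t^* \mid X > c)\}\,P(X>c)}{1 - \hat S(t^*)},
\qquad
\widehat{\mathrm{spec}}(c) = \frac{\hat S(t^* \mid X \le c)\,P(X \le c)}{\hat S(t^*)},$$

with conditional KM curves fit inside each marker-defined subset and the
AUC obtained by trapezoidal integration over all unique cutoffs, so tied
marker values contribute 1/2. Samples censored before the horizon enter
through the KM redistribution implicit in the estimator; nothing is
imputed. In the no-censoring limit the estimate reduces exactly to the
empirical Mann–Whitney concordance, which the test suite asserts to 1e−10
against an independent `survival::survfit`-based oracle. A threshold at
which either marker class is empty has an *undefined* AUC — we do not
substitute 0.5, which would artificially deflate the variability statistic
below.

Cox models use Efron tie handling wherever coefficients are interpreted;
penalized and boosted fits use the Breslow-type gradient of their standard
implementations.

## The threshold sweep and size-dependence criteria

For each of the 78 features the sweep evaluates thresholds 1–99% in 1%
steps (the step is a parameter; a step of 5 subsamples the step-1 curve
exactly). The optimal threshold is the AUC argmax, ties broken toward the
smallest threshold (more sensitive, and deterministic). A feature is
**size-dependent** when, for at least one endpoint (recurrence-type or
overall survival — the criteria are evaluated per endpoint and OR-combined),

1. maximum AUC ≥ 0.60 at some threshold,
2. standard deviation of the AUC across defined thresholds ≥ 0.01, and
3. prevalence ≥ 2.5% of samples at the optimal threshold.

All three comparisons are inclusive. Prevalence is assessed at the optimum
(not at every threshold), and the SD is computed per endpoint over defined
thresholds only.

The SD cutoff is calibrated by a permutation/bootstrap construction: the
sample-to-fraction pairing is scrambled within each feature — preserving
each arm's background fraction distribution — the sweep is re-run, and the
SD recorded; pooling replicates × features gives a null SD distribution.
`fdr_at_cutoff()` reports the null tail proportion at the cutoff. This is a
per-test false-positive rate used as an FDR proxy, which is how the
original construction is defined; it is labelled as such in the output
metadata rather than silently renamed.

## Focal windows

Arms are tiled with 200 kb bins (about the size of the HLA locus). A bin's
intensity is the weighted mean of overlapping segment means with weight
`overlap length × probe density` — the estimated number of probes inside
the overlap, which honours both stated weighting factors with one formula.
Bins with no overlap are missing: they count as unaltered for cohort
pileup proportions (prevalence is a cohort statement) but are excluded from
AUC medians (an AUC needs a defined marker). Focal prognostic regions are
maximal runs of contiguous *defined* bins whose call AUC is at least 0.04
above the median of the arm's defined bin AUCs; the margin is inclusive and
the criterion is invariant to adding a constant to the whole profile. Where
the text admits two readings of "the median for the entire chromosome arm",
we use the median of the arm's per-bin AUCs, which keeps the criterion
self-contained within one track; the choice is recorded in the run
manifest.

## Co-occurrence, burden and the risk score

Pair (optionally triplet) features are indicators that all members are
called at their optimal thresholds, restricted to tuples containing at
least one size-dependent CNA and filtered at the same 2.5% prevalence
floor. Selection uses penalized Cox regression (`glmnet`) scored by
cross-validated concordance with event-stratified, seeded 10-fold
assignments shared across an alpha grid (0.05–0.95 plus LASSO at 1.0); the
reported model is the sparsest within one standard error of the best CV
concordance. Selected pairs are examined by four-stratum Kaplan–Meier
analysis (neither / A only / B only / both) and by bivariate Cox models
adjusting for total CNA burden.

Burden strata come from a survival tree on the burden count: recursive
binary splits maximizing the log-rank statistic, stopping at leaves of 20,
depth 3, or when the best split's p-value — Bonferroni-corrected for the
candidate cutpoints examined — is not below 0.05. The correction is what
makes the tree's null behaviour match its nominal level: without it, the
maximum over ~8 candidate statistics splits a third of pure-noise cohorts.

The risk score is gradient boosting with a *linear* base learner on the Cox
partial likelihood: per round, the gradient of the log partial likelihood
with respect to the per-sample score is fit by least squares on the
features and added with learning rate 0.009, for 2 rounds. A linear booster
has no tree depth; the score is a linear function of its inputs and
invariant to monotone rescaling of survival times. Risk groups cut the
training-score distribution at its 25th and 50th percentiles
(linear-interpolation percentiles; boundary values go to the upper group,
so exactly the training quartile sits in "intermediate" and the median in
"high").

## The synthetic cohort generator

`simulate_cohort()` draws per-sample alteration profiles and survival times
with planted, recoverable structure:

* **size mixture** — background events per (arm, direction) with
  probability 0.08 are focal (width uniform on 0.2–5 Mb) with probability
  0.3, else broad (Beta(1.2, 1.2) fraction of the arm, anchored at the
  telomeric end by default so distal-versus-proximal confounds can be
  studied);
* **intensities** — losses N(−0.45, 0.1), gains N(+0.3, 0.1), neutral
  N(0, 0.05), emitted in ≤8 Mb neutral chunks so that wholesale
  misclassification of an arm-length neutral segment (which real
  segmentation rarely produces) stays rare while realistic segment-level
  noise remains;
* **probes** — 1 per 10 kb;
* **planted effects** — arm effects switch on when the true altered
  fraction reaches an activation fraction (carriers draw fractions above
  it, a configurable share of non-carriers draw sub-threshold fractions so
  threshold recovery is non-trivial); focal loci are deleted intervals at a
  fixed position; pair effects add log-hazard when both members are
  active; a burden coefficient acts linearly;
* **survival** — two endpoints from Weibull proportional-hazards baselines
  (shape 1; scales 14 and 18 years, giving ≈30%/25% five-year baseline
  event rates typical of recurrence and survival endpoints in long-term
  tumour cohorts) with independent uniform censoring on [0, 12] years.

The generator writes SEG, clinical CSV and a JSON truth ledger, and is
byte-reproducible from its mandatory seed. What it does **not** emulate:
probe-level noise and segmentation itself (segments are emitted directly),
allele-specific or integer copy number, whole-genome doubling,
copy-neutral LOH, correlated censoring, or covariate-dependent alteration
rates. Passing tests on these cohorts therefore demonstrate that the
estimators recover what they claim from segment-level data of realistic
shape — not that any particular clinical cohort will behave likewise.

Simulated validation in the test suite runs at n = 400 (n = 300 for the
end-to-end pipeline check, n = 500–2000 for calibration checks) on a
down-scaled 39-arm table with tens-of-Mb arms; arm fractions are
scale-free, so the code paths are identical to genome-scale input while
simulations stay fast. The permutation-FDR check uses 100 replicates of
the 500-replicate construction; both are parameters.

## Known limitations

* The td-ROC estimator is the KM (non-nearest-neighbour) variant; its
  curve need not be monotone in finite samples, and the trapezoidal AUC of
  a non-monotone curve can differ slightly from other estimators.
* The SD-FDR is a tail-rate proxy, not a BH-style adjusted FDR.
* The focal criterion inherits the tightness of its +0.04 margin; signals
  whose AUC excess over the arm median is near the margin will be called
  inconsistently across cohorts of this size.
* `read_arm_table()` trusts the declared genome build; no liftover is
  performed, and the bundled hg38-like arm table is an approximate,
  synthetic stand-in for simulation use only.
* Pair indicators are computed per endpoint's optimal thresholds; when
  endpoints disagree, both sets of calls are legitimate and the package
  computes whichever the caller passes in.
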