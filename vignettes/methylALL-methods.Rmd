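---
title: "Classifying pediatric ALL subtypes from DNA methylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pediatric ALL subtypes from DNA methylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The recurrent cytogenetic subtypes of pediatric acute lymphoblastic leukemia
(ALL) — T-ALL and the B-cell-precursor subtypes HeH, t(12;21), 11q23/*MLL*,
t(1;19), dic(9;20), t(9;22) and iAMP21 — drive risk stratification, but
karyotyping, FISH and RT-PCR leave a substantial fraction of patients without
a subtype call. Each subtype imprints a characteristic DNA methylation
signature on the leukemic genome, so genome-wide beta values from a 450k-style
array carry enough information to recover the subtype. `methylALL` implements
a complete classifier-design pipeline around that idea: ten one-vs-rest
nearest-shrunken-centroid (NSC) classifiers (one per subtype, plus a
leukemic-vs-normal-blood "reference" task that flags low-blast-count samples
and a female-vs-male task that flags sample mix-ups), consensus CpG selection
by repeated cross-validation, probability-threshold decision logic, nested
external cross-validation, and a copy-number caller from the same array's
signal intensities.

## The NSC model

For a binary task with classes $k \in \{1,2\}$, $n_k$ training samples of
class $k$ out of $n$, per-CpG beta values $x_{ij}$, class centroids
$\bar x_{kj}$ and overall centroid $\bar x_j$:

$$d_{kj} = \frac{\bar x_{kj} - \bar x_j}{m_k\,(s_j + s_0)},\qquad
  m_k = \sqrt{1/n_k - 1/n},$$

where $s_j$ is the pooled within-class standard deviation (denominator
$n - 2$) and $s_0$ a fudge factor guarding against vanishing dispersions; we
use the reference convention $s_0 = \mathrm{median}_j(s_j)$. Offsets are
soft-thresholded at $\Delta \ge 0$,

$$d'_{kj} = \mathrm{sign}(d_{kj})\,\max(|d_{kj}| - \Delta,\, 0),$$

and the shrunken centroids $\bar x'_{kj} = \bar x_j + m_k (s_j + s_0)
d'_{kj}$ define the discriminant

$$\delta_k(x) = \sum_j \frac{(x_j - \bar x'_{kj})^2}{(s_j+s_0)^2}
  - 2\log \pi_k,\qquad
  p_k(x) = \frac{e^{-\delta_k(x)/2}}{\sum_l e^{-\delta_l(x)/2}},$$

with priors $\pi_k$ defaulting to the training class proportions
(configurable to uniform). The smaller discriminant is subtracted before
exponentiation, so the posteriors are numerically stable. Features with
$d'_{kj}=0$ for both classes contribute identically to both discriminants and
cancel from the posterior — shrinkage *is* the feature selection.

Two numerical details matter at the edges. Within-class sums of squares are
computed by the $\sum x^2 - n\bar x^2$ identity (required for the speed of
the repeated-CV loops below) and cancellation residue on near-constant
features is clipped to exact zero at a $10^{-12}$ relative tolerance.
Zero-dispersion features (possible on degenerate or noise-free data) would
otherwise produce infinite offsets; their scale $s_j + s_0$ is floored at the
smallest positive scale in the fit (or 1 if none), which keeps them maximally
discriminative without breaking the arithmetic.

## Threshold tuning and consensus selection

The shrinkage threshold is tuned by stratified cross-validation over a grid
of 30 values spanning no shrinkage to total shrinkage: 0, then points
log-spaced from the 10th percentile of the non-zero $|d_{kj}|$ to their
maximum. Among thresholds attaining the minimum CV misclassification count,
the **largest** is returned (parsimony tie-break).

Feature selection follows a consensus scheme: five-fold cross-validation
repeated five times; in each of the 25 folds the threshold is tuned by a
nested five-fold CV on the fold's training portion, an NSC model is fitted
at the tuned threshold, and its surviving CpGs are tallied. CpGs surviving in
at least 17 of the 25 folds are the task's *consensus CpG sites*. The final
per-task model is the full-feature fit soft-thresholded at the **median** of
the 25 tuned thresholds and restricted to the consensus sites. The restricted
model deliberately inherits the fudge factor and per-feature scale of the
full-feature fit: recomputing $s_0$ on a 30-CpG subset would silently change
the meaning of the tuned threshold (up to total shrinkage in degenerate
cases).

When the minority class is smaller than the fold count (iAMP21-sized groups),
the folds are reduced so each holds one minority sample, and the 17/25
consensus threshold is rescaled proportionally to the reduced fold total.
When even the nested tuning cannot be stratified (fewer than 3 minority
samples in a fold's training portion), tuning falls back to the
resubstitution error. Fold assignment is keyed by sorted sample ids under a
single run seed, so results are independent of input column order and fully
reproducible; every derived seed stays within 32-bit integer range.

The subtype and reference tasks are trained on autosomal probes only; the
sex task on all chromosomes except Y.

## Decision logic

A task is *positive* for a sample when its posterior strictly exceeds the
threshold (default 0.5; a score of exactly 0.5 is negative — where sources
disagree between "$>$" and "$\ge$" we implement the strict inequality and
leave the threshold configurable, the boundary being measure-zero in
practice). Rules apply in order:

1. **reference_flag** — a positive reference score marks a suspected
   low-blast-count sample and preempts any subtype call;
2. **iAMP21 override** — a sample positive for both iAMP21 and HeH counts as
   iAMP21 only. iAMP21 blasts share most of the HeH hypomethylation
   signature (gains of chromosome 21 in both), so the HeH classifier cannot
   exclude them; the override is on by default and can be disabled;
3. counting — exactly one positive subtype gives `single_class`, two or more
   `multi_class`, none `non_class`.

The sex call (female when the sex-task score exceeds the threshold) is
reported separately, never affects the category, and is compared with the
sample sheet to flag potential sample mix-ups.

## Performance estimation

`external_cv()` wraps the *entire* design procedure in an outer stratified
five-fold cross-validation: consensus selection and final fitting are re-run
from scratch inside each outer training set and the held-out samples are
scored once; an assertion guarantees test samples never reach the selection
stage. Per task and fold, sensitivity and specificity come from the raw
scores (before the iAMP21 override), so cross-scoring tasks legitimately
show up as reduced specificity; means and SDs are taken over folds
($n-1$ denominator), and a subtype absent from a fold's test set contributes
no sensitivity term rather than a zero. Because a multi-class call containing
the true label can be counted either way, the summary reports three
fractions that always sum to one (single-correct / multi-including-correct /
incorrect-or-none) alongside a per-task sensitivity that counts
multi-class-including-correct as a success.

## Copy-number calling from array intensities

Methylated and unmethylated intensities are summed per probe, quantile
normalized (classic mean-of-order-statistics; ties receive the mean of their
target quantiles), and expressed as $\log_2$ ratios against the mean of the
non-leukemic reference panel. By default tumors and references are pooled in
one normalization pass (ratio stability); a reference-anchored mode is
available. An arm-level caller — an extension, since the underlying method
inspected the ratio tracks visually in IGV — takes the per-arm median ratio
(built-in hg19 arm table, overridable by a UCSC cytoBand file) and calls a
gain above $+0.15$ and a loss below $-0.20$: both thresholds sit well below
the single-copy-gain signal $\log_2(3/2)\approx 0.585$ so that events remain
callable down to blast fractions near 0.5, and above the noise floor of a
\>20-probe arm median. Arms with fewer than 20 probes are flagged
`insufficient`. A modeled chromosome count ($46 +$ whole-chromosome gains
$-$ losses) supports quick high-hyperdiploidy checks. Tracks export as
per-sample bedGraph (0-based half-open) or multi-sample SEG (1-based
inclusive), both IGV-loadable.

One property of quantile-normalized copy number worth knowing: when a large
fraction of a genome is aberrant (a high-hyperdiploid case with eight
trisomies), rank compression shrinks the apparent amplitude of the gains —
calls survive, but the arm medians sit below the nominal
$\log_2((fc + 2(1-f))/2)$. Calibration claims are therefore made on planted
single trisomies, where compression is negligible.

## The synthetic cohort generator

The generator emulates the statistical structure the classifier assumes, at
a desk scale that runs the full pipeline in minutes. Defaults are the study
conditions: 5000 probes (450k scale is supported at proportional cost),
subtype sample counts 101/189/161/27/21/20/19/8 (T-ALL, HeH, t(12;21),
11q23/*MLL*, t(1;19), dic(9;20), t(9;22), iAMP21; 546 total) plus 139
non-leukemic reference samples, and 30 planted signature CpGs per task.
Signature medians follow the observed pattern: BCP-subtype signature CpGs at
beta 0.19 in the own subtype against a 0.85 background, the T-ALL signature
inverted (0.92 own, 0.04 in BCP samples), a reference signature
distinguishing normal blood, and chrX sites separating the sexes (0.55
female vs 0.12 male, reflecting X-inactivation). 76% of the HeH signature is
shared by iAMP21 samples, which makes iAMP21 samples cross-score on the HeH
task and exercises the override end to end.

Beta noise is a Beta distribution reparameterized by **median** and
concentration $\nu$ (shapes $\mu\nu$, $(1-\mu)\nu$ with $\mu$ solved so the
median hits its target), so values respect $[0,1]$ without clipping and a
noise-free configuration ($\nu = \infty$) hits the target medians exactly.
The default $\nu = 10$ gives a per-site beta SD near 0.10–0.12, typical of
differentially methylated CpGs in tumor cohorts; it also keeps single CpGs
from being individually decisive, which matters because the
largest-threshold-at-minimum-error rule would otherwise collapse each fold's
selection to one or two sites and no consensus would emerge — with ~30
moderately informative sites the tuned threshold settles where most of the
signature survives, which is the regime the consensus scheme is designed
for.

Intensities are per-probe lognormal baselines (meanlog $\log 3000$, sdlog
1.0 — array total intensities span orders of magnitude) times a per-sample
scale factor (removed by quantile normalization), a multiplicative lognormal
noise (sdlog 0.1), and on probes of planted aberrations a copy factor
$(f c + 2(1-f))/2$ for copy number $c$ at blast fraction $f$ (default blast
range 0.6–1.0). Default events follow the subtype biology: HeH trisomies
(chromosomes 4, 6, 10, 14, 17, 18, 21, X), the iAMP21 21q amplification
($c=4$), and the dic(9;20) 9p/20q losses. A configurable fraction of beta
cells (default 0.2%) is masked missing; probes with more than 5% missing
cells are dropped before training and remaining holes are probe-mean
imputed.

What the generator does **not** emulate: probe-level genomic
autocorrelation, between-subtype covariance structure (sites are independent
given their medians), batch effects, and Infinium-design-specific intensity
artifacts. Passing tests therefore demonstrate the correctness and the
statistical behavior of the procedure under its own assumptions, not
performance on GEO-scale real cohorts.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the full design procedure on the
default 5000-probe, 685-sample cohort (consensus selection plus a complete
nested external cross-validation — effectively six full training runs), and
verify the NSC engine against an independently coded scalar-loop oracle on
dozens of small random instances. Copy-number calibration uses dedicated
small cohorts with planted single trisomies at fixed blast fractions 1.0 and
0.5. These sizes keep a complete run in the minutes range on a single core.

## Known limitations

* The consensus procedure's statistical behavior (how many sites survive,
  how stable the tuned threshold is) depends on the signal-to-noise regime;
  very strong per-site signals push the parsimony tie-break toward minimal
  models, which is correct but yields small consensus sets.
* Tasks with very small positive classes (iAMP21-sized) rely on the
  leave-pair-out reduction and the resubstitution fallback; their tuned
  thresholds are noisy, mirroring the instability such groups show in
  practice.
* The arm-level CNA caller is intentionally coarse (arm medians only); focal
  events such as intragenic deletions are out of scope.
* Classifier files are versioned JSON; loading a file from a different
  format version fails loudly rather than attempting migration.
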