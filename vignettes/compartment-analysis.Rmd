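---
title: "Three-state chromatin compartment analysis with hicomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state chromatin compartment analysis with hicomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicomp)
```

## The model

Megabase-scale genome folding segregates chromatin into an active (A) and an
inactive (B) compartment, classically read off the sign of the first
eigenvector (EV) of the per-chromosome Pearson correlation matrix of a
normalized Hi-C contact map.  `hicomp` implements a three-state refinement of
this picture: the genome-wide distribution of EV coefficients, once oriented
and scaled to $[-1, 1]$, is tri-modal, and the middle mode defines an
*intermediate* (I) compartment that is enriched in poised-promoter and
polycomb-repressed chromatin and interacts less exclusively with itself than
either A or B.

The pipeline is:

1. **Correlation and eigenvector.** For each chromosome the contact matrix is
   restricted to usable bins (zero-sum rows are masked), transformed into a
   Pearson correlation matrix of bin contact profiles, and decomposed; the
   rank-1 eigenvector is the compartment axis (`correlation_matrix()`,
   `leading_eigenvector()`).
2. **Orientation and scaling.** The eigenvector sign is arbitrary, so the
   vector is flipped when its correlation with an active-chromatin track
   (H3K4me1 and/or ATAC signal) is negative, then divided by its maximum
   absolute value so coefficients span $[-1, 1]$ (`orient_and_scale()`).
3. **Mixture segmentation.** Pooled genome-wide EV coefficients are fitted
   with a $k$-component Gaussian mixture by expectation-maximization
   (`fit_gaussian_mixture()`); $k$ is selected by minimizing
   $\mathrm{BIC} = p\ln n - 2\ln L$ with $p = 3k - 1$ (`bic_scan()`).  With
   $k = 3$, the two intersection points of adjacent weighted component
   densities give the call thresholds IV1 (A/I) and IV2 (I/B)
   (`mixture_intersections()`); replicate thresholds are averaged into a
   consensus (`consensus_thresholds()`).
4. **Calling.** A bin is A above IV1, B below IV2, I in between (both
   boundaries belong to I); missing EV propagates as non-assigned
   (`call_compartments()`).

Downstream, the compartment interaction score (C-score) of a compartment is
its intra-compartment contact sum divided by all chromosomal contacts
involving it (`compartment_score()`); transitions between cell states are
classified on the activity order $A > I > B$ as activation, inactivation or
stable (`classify_transition()`, `path_dynamics()`, `reversibility()`);
case-control differential regions use a per-region Welch $t$ test with
Benjamini-Hochberg control plus an absolute EV-difference gate
(`differential_compartments()`); subtype-specific regions use a
within-subtype homogenization filter followed by a between-subtype
mean-difference rule (`subtype_regions()`); and enrichment questions are
answered by one-tailed Monte-Carlo resampling of equally sized bin sets
(`chromosome_enrichment_mc()`, `region_gene_enrichment_mc()`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `resolution` | 100 kb | compartment bin width; 50 kb typical for comparison maps |
| `k` | 3 | mixture components (A, I, B); scan 1-10 by BIC |
| `tol`, `max_iter` | 1e-8, 1000 | EM convergence (relative log-likelihood) |
| `alpha` | 0.05 | BH-adjusted significance cutoff |
| `delta_min` | 0.4 | minimum absolute mean EV difference for a call |
| `homog_max` | 0.4 (strict <) | within-subtype EV range allowed by homogenization |
| `subtype_min_delta` | 0.4 (>=) | between-subtype mean EV difference |
| `n_perm` | 10,000 | Monte-Carlo repetitions; smallest attainable p is $1/(n_{perm}+1)$ |
| `sigma` | 1.0 bins | Gaussian smoothing of log-ratio maps |
| `pseudocount` | 1 | added to both maps before the log2 ratio |
| `min_unmasked_frac` | 0.5 | below this usable-bin fraction a chromosome is emitted all-missing |

The 0.4 EV thresholds operate on the $[-1, 1]$ EV scale, i.e. a change of
about one fifth of the full dynamic range; 0.05 is the conventional FDR
level.  Reference consensus thresholds of $+0.43$ and $-0.63$ have been
reported for normal mature B cell Hi-C replicates; they are properties of
that controlled-access data set, so `hicomp` always re-derives thresholds
from the data at hand rather than hard-coding them.

## Numerical choices

* **EM initialization** is deterministic: component means at the
  $1/(k+1), \dots, k/(k+1)$ data quantiles, equal weights, pooled sd.
  Degenerate fits (collapsing variance or weight) restart from a seeded
  jittered initialization up to 5 times and then error.  This makes fits a
  pure function of (data, seed) without random-restart variability.
* **BIC convention**: minimized, with $p = 3k - 1$ free parameters, which is
  `stats::BIC(logLik(fit))` exactly; ties break toward smaller $k$.
* **Density intersections** are solved in closed form: equating two weighted
  Gaussian log-densities is a quadratic in $x$; the root inside the open
  interval between the two means is used.  If no root lies there (extreme
  weight/sd imbalance) the sd-weighted midpoint
  $(\sigma_2\mu_1 + \sigma_1\mu_2)/(\sigma_1 + \sigma_2)$ is used with a
  warning; for coincident means this degenerates to that mean.  Weighted
  (not unweighted) densities are intersected, since the weighted equality is
  what defines the mixture's own classification boundary.
* **Boundary convention**: EV exactly at a threshold is called I, the middle
  class.
* **Ties/degeneracies in testing**: zero variance in both groups with equal
  means yields $p = 1$; with unequal means the region is reported at
  $p = 0$ with an infinite $t$.
* **Pair counting**: all contact sums count each unordered bin pair once and
  the diagonal once, so per-label intra sums plus once-counted cross sums
  reproduce the chromosomal total exactly (tested).
* **Peak binning** uses mean-of-peak-scores per bin (a peak spanning two
  bins contributes its full score to both), not coverage weighting,
  matching `bedmap --mean` semantics.
* **Asymmetric matrices** are symmetrized by $(M + M^\top)/2$, with a
  warning when the asymmetry exceeds float tolerance.
* **Log-ratio maps** use base 2 and pseudocount 1 by default, smoothed by a
  separable 1-D Gaussian ($\sigma = 1$ bin, truncated at $4\sigma$,
  reflected at the edges); masked bins are filled from the nearest unmasked
  bin before the ratio.

## What the synthetic generator emulates — and what it does not

`sim_config()` + `simulate_labels()` / `simulate_contact_matrix()` /
`simulate_tracks()` / `simulate_cohort()` generate complete synthetic inputs
with exhaustively recorded planted truth:

* blocky compartment segments (geometric lengths, mean 8 bins) with label
  proportions 0.35/0.33/0.32 (A/I/B);
* expected contacts $\textrm{depth}\cdot|i-j|^{-\alpha}\cdot
  \textrm{affinity}(L_i, L_j)$ with $\alpha = 1$, depth 100 at distance 1,
  Poisson counting noise and lognormal replicate-depth jitter; the affinity
  matrix (A-A = B-B = 1.0, I-I = 0.6, A-I = B-I = 0.5, A-B = 0.2) makes the
  intermediate compartment promiscuous by construction, so its lower
  C-score is an emergent, testable property;
* label-concordant activity tracks and 200-bp chromatin-state tracks drawn
  from an 11-state alphabet;
* cohorts mirroring a differentiation study: four normal states with
  replicates (naive, germinal-center, memory, plasma-like), planted dynamic
  bins (30% at the first step), a planted reverting fraction (75% of
  first-step-activated bins) at the third state, and two disease entities
  with subtypes carrying entity- and subtype-specific planted switches.
  Per-sample EV values are drawn per label from Gaussians centered at
  $-0.65 / 0 / 0.70$ with sd 0.08, giving mode separation comparable to the
  published threshold geometry.

Two caveats worth knowing:

* The per-step *direction propensity* (default 0.615 toward activation)
  applies where the move is feasible: an A bin cannot activate and a B bin
  cannot inactivate, so the realized activation share depends on the label
  mix (about 52% under the defaults).  The truth table records the realized
  direction of every planted switch, and all tests compare against the
  truth table, not the propensity parameter.
* With the realistic decay exponent $\alpha = 1$, the power-law distance
  trend dominates the raw-matrix correlation structure of the block model,
  so synthetic validation runs the eigenvector step with its
  distance-expected option (`compartment_eigenvector(..., oe = TRUE)`),
  which divides each diagonal by its mean before correlating.  Real
  normalized Hi-C maps at 100 kb typically carry a compartment signal
  strong enough for direct correlation, which is why `oe = FALSE` remains
  the default.

The generator does **not** model TADs, loops, trans-chromosomal contacts,
karyotype abnormalities, coverage biases (inputs are assumed normalized), or
spatially correlated noise; passing tests therefore demonstrate the
correctness of the algorithms under the stated generative assumptions, not
robustness to every artifact of real Hi-C.

## Design choices on genuinely open points

* *Eigenvector choice*: rank 1 by default; `rank = "auto"` picks, among
  ranks 1-3, the one most correlated with the activity track — a
  reproducible stand-in for visual inspection of eigenvectors.
* *Two activity tracks* are combined by averaging the two per-track
  orientation correlations.
* *Scaling* to $[-1, 1]$ divides by the per-chromosome maximum absolute
  coefficient — the simplest monotone map to the stated range.
* *C-score pooling*: the default scores each label pooled per chromosome;
  `mode = "segment"` scores each run of adjacent same-label bins separately,
  since published wording ("compartments sharing the same segmentation were
  merged") admits both readings.  Both are exported; the ambiguity is
  documented rather than silently resolved.
* *State alphabet*: the 12 input states merge active-promoter and
  strong-enhancer-1 into one state, leaving 11; the weak-enhancer state is
  grouped A-related alongside the other active states.
* *t test*: Welch by default (group sizes as small as 2 make the pooled
  variance assumption fragile); `var_equal = TRUE` gives the Student
  variant.
* *Homogenization range* is max-min across a subtype's samples (strict
  `< 0.4`), the natural multi-sample extension of a pairwise difference.
* *Monte-Carlo universe*: draws come from assignable bins only, so the null
  matches the tested universe; p values use the add-one estimator
  $(1 + \#\{\text{count} \ge \text{observed}\})/(n_{perm} + 1)$.
* *Case-control designs*: the four standard designs (normal-conserved vs
  disease 1; vs disease 2; disease-1-specific vs disease 2; and the
  converse) are recipes over one generic engine rather than separate code
  paths: `conserved_compartment_regions()` defines the control universe
  (bins with identical labels across all reference samples),
  `differential_compartments()` tests case against control there, and
  `specificity_partition()` separates entity-specific from shared regions
  by set difference.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(chrom_sizes = c(chr1 = 40e6), seed = 1)
labels <- simulate_labels(cfg)
cm <- simulate_contact_matrix(labels, cfg)
tracks <- simulate_tracks(labels, cfg)

ev <- compartment_eigenvector(cm, tracks$activity, oe = TRUE)
fit <- fit_gaussian_mixture(ev$values, k = 3)
summary(fit)
calls <- call_compartments(ev, mixture_intersections(fit))
print(calls)
compartment_score(cm, calls)
```

## Problem sizes and limitations

The bundled tests and the acceptance script run on simulated genomes of a
few hundred to a few thousand 100-kb bins with cohorts of up to ~25 samples
— large enough for every statistical property under test to be measurable at
its stated tolerance, small enough to run quickly on one CPU.  Known
limitations: the mixture model assumes three Gaussian modes on a common
scale across samples (strong batch effects would need harmonizing
upstream); compartment calls are per-bin with no spatial smoothing (no HMM);
the C-score is a per-chromosome summary and is not normalized for
compartment size; and Monte-Carlo p values are bounded below by
$1/(n_{perm} + 1)$.
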