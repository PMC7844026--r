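# hicomp

Three-state chromatin compartment analysis for Hi-C data.

## The problem

Genome-wide chromosome conformation capture (Hi-C) partitions the genome at
the megabase scale into an active **A** and an inactive **B** compartment,
read off the sign of the first eigenvector (EV) of the per-chromosome
Pearson correlation matrix of the normalized contact map.  In lymphoid
cells, however, the genome-wide EV distribution is clearly tri-modal: a
third, **intermediate (I)** compartment occupies the middle of the EV range,
is enriched in poised-promoter and polycomb-repressed chromatin, and
self-interacts less than either A or B.  `hicomp` is for epigenomics
researchers who want to call and analyze this three-state
compartmentalization: define it reproducibly, score its interaction
behavior, follow it along cell differentiation paths, and test for
disease- or subtype-associated compartment changes.

## The method

For each chromosome with contact matrix $M$: mask zero-sum bins, compute the
Pearson correlation matrix of bin contact profiles, take the leading
eigenvector, orient it by its correlation with an active-chromatin track
(H3K4me1 / ATAC), and scale to $[-1, 1]$.  The pooled EV coefficients are
fitted with a $k$-component Gaussian mixture by EM; $k$ is selected by
minimizing $\mathrm{BIC} = p\ln n - 2\ln L$ ($p = 3k-1$), and $k = 3$
reflects the A/I/B structure.  The thresholds **IV1** (A/I) and **IV2**
(I/B) are the intersection points of adjacent weighted component densities,
solved in closed form; per-replicate thresholds are averaged into a
consensus.  A bin is called A if $\mathrm{EV} > \mathrm{IV1}$, B if
$\mathrm{EV} < \mathrm{IV2}$, I otherwise.

Downstream tools:

* **C-score** — intra-compartment contacts / all contacts involving the
  compartment (`compartment_score()`), with an IA/IB split of the
  intermediate compartment by EV sign (`split_intermediate()`);
* **chromatin-state enrichment** of compartment groups over an 11-state,
  200-bp alphabet (`state_enrichment()`, `state_group_foldchange()`);
* **dynamics** along differentiation paths on the activity order
  $A > I > B$ — activation / inactivation / stable steps, dynamic fraction
  and reversibility (`path_dynamics()`, `reversibility()`);
* **differential compartments** between sample groups — per-region Welch
  *t* test, Benjamini-Hochberg FDR, and an absolute EV-difference gate
  ($|\Delta \mathrm{EV}| > 0.4$, adjusted $p < 0.05$)
  (`differential_compartments()`, `specificity_partition()`);
* **subtype-specific regions** — within-subtype homogenization
  (range $< 0.4$) then between-subtype mean difference ($\ge 0.4$)
  (`subtype_regions()`);
* **Monte-Carlo enrichment** of region sets per chromosome or against
  flagged gene sets, with one-tailed empirical p values
  (`chromosome_enrichment_mc()`, `region_gene_enrichment_mc()`);
* **synthetic cohorts** with planted, exhaustively recorded truth —
  block-model contact matrices with distance decay and label-pair
  affinities, concordant activity/state tracks, differentiation paths with
  planted transitions and reversals, disease entities with subtype-specific
  switches (`sim_config()`, `simulate_cohort()`).

## Worked example

```r
library(hicomp)

cfg    <- sim_config(chrom_sizes = c(chr1 = 40e6), seed = 1)
labels <- simulate_labels(cfg)                  # planted A/I/B truth
cm     <- simulate_contact_matrix(labels, cfg)  # Poisson block-model Hi-C
tracks <- simulate_tracks(labels, cfg)          # activity + chromatin states

ev    <- compartment_eigenvector(cm, tracks$activity, oe = TRUE)
fit   <- fit_gaussian_mixture(ev$values, k = 3)
summary(fit)
#> Gaussian mixture, k = 3 (n = 400, BIC = 314.47)
#>   weight    mean     sd
#> 1 0.4020 -0.7134 0.1179
#> 2 0.3703  0.0243 0.1131
#> 3 0.2276  0.7360 0.1182
#> log-likelihood -133.2674 in 51 EM iterations
#> intersection thresholds: IV1 = 0.3823, IV2 = -0.3362

calls <- call_compartments(ev, mixture_intersections(fit))
print(calls)
#> compartment_call 'sample': A 91, I 148, B 161, NA 0

compartment_score(cm, calls)
#>   chrom label intra_contacts total_contacts    cscore
#> 1  chr1     A          31245          48917 0.6387350
#> 2  chr1     I          35822          65772 0.5446391
#> 3  chr1     B          69701          92205 0.7559351

mean(calls$labels == labels)   # recovery of the planted labels
#> [1] 1
```

The three mixture components sit near $-0.71 / 0.02 / 0.74$ — the planted
B/I/A modes — and the intermediate compartment shows the lowest C-score
(0.54 vs 0.64 and 0.76), its defining interaction signature.

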