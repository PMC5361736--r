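---
title: "Methods: window-based KNN-MDR for epistasis detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based KNN-MDR for epistasis detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(knnmdr)
```

## The problem

Complex diseases can be driven by sets of loci whose joint genotype matters
while every locus, taken alone, shows (almost) no marginal association.
Classic multifactor dimensionality reduction (MDR) targets exactly this
setting in case-control panels: a set of $P$ SNPs defines $3^P$ multi-locus
genotype cells, each cell is labelled high or low risk by a majority vote of
the training individuals falling into it, and the resulting two-class
classifier is scored by cross-validated balanced accuracy.  MDR has two
structural weaknesses that grow with $P$ and with the marker count $M$:
cells become empty (test individuals become unclassifiable) and the number
of candidate sets explodes as roughly $M^P/P!$.

This package implements the KNN variant of MDR: the cell vote is replaced
by a majority vote among a test individual's $K$ nearest training
neighbours under a genotype distance, and single SNPs are replaced by
*windows* of contiguous SNPs, so the scan enumerates window sets (typically
$W \ll M$ windows) instead of marker sets.  Neighbourhoods are never empty,
and LD between nearby markers contributes signal rather than redundancy.

## Distances

For a window $w$ and individuals $i, j$ with minor-allele counts
$g_{im} \in \{0,1,2\}$:

$$ d^2_w(i,j) \;=\; \sum_{m \in w} \omega_m \, \frac{(g_{im}-g_{jm})^2}{s^2_m} $$

with $s^2_m$ the sample variance of marker $m$ and optional weights
$\omega_m$ (default 1; a hook for up-weighting informative rare alleles,
for which no canonical formula exists).  This *normalized Euclidean*
distance is the default; it encodes the biologically sensible spacing
$D(AA,AB) = D(AB,BB) = \tfrac12 D(AA,BB)$ for a single SNP.  A full
Mahalanobis form (inverse in-window marker correlation, optional ridge
$\lambda = 10^{-6}$) is available for populations where modelling local LD
in the metric is worth the extra cost; a "binary" differing-allele-count
metric is provided for completeness and coincides with the normalized
Euclidean metric on biallelic data.

Design choices worth knowing:

* **Squared distances are the stored quantity.**  Neighbour ranking is
  invariant under the square root, and squared distances are additive over
  windows, so the distance of any window set is the elementwise sum of
  per-window matrices, computed once.  This additivity is what makes the
  exhaustive scan and the permutation machinery cheap.
* **Variances (and correlations) are estimated once on the full sample**,
  not per CV training fold.  They are phenotype-free quantities; fold-wise
  re-estimation would perturb the geometry between folds without adding
  information, and would forbid precomputation.
* **Monomorphic markers contribute 0** (their normalization is undefined
  and they carry no discriminative information).
* Distances are invariant to which allele is called "minor" (a coding flip
  $c \mapsto 2-c$ changes the sign of every difference only), so the
  minor-allele coding convention never affects results.

## Classification and scoring

For a candidate window set, each individual is predicted by the majority
status of its $K$ nearest training neighbours (`K = 10` by default,
matching common usage at the 500/500 design; the results are not very
sensitive to $K$ in practice).  All ties have explicit deterministic rules,
because reproducible p-values require a deterministic statistic:

* distance ties break toward the smaller individual index;
* vote ties (even $K$) are resolved by the single nearest neighbour
  (configurable to case-wins / control-wins).

Performance is the 10-fold cross-validated *balanced accuracy*
$\mathrm{BA} = \tfrac12(\mathrm{sensitivity} + \mathrm{specificity})$,
averaged unweighted over folds.  Folds are stratified by status (the
balanced designs used here make fold BA unstable otherwise) with a recorded
seed.  A degenerate fold missing one class contributes rate 0.5 for that
class and triggers a warning.  Classic MDR is provided under the same
interface (`method = "mdr"`): cells are labelled high-risk when the
training case:control ratio strictly exceeds the overall training ratio
(equality is conservatively low-risk), and unclassifiable test individuals
are excluded from the confusion counts.

## Significance

Significance is by phenotype permutation: labels are shuffled, the
statistic is recomputed identically, and
$p = (\#\{ \mathrm{BA}_{perm} \ge \mathrm{BA}_{obs}\} + 1)/(n_{perm}+1)$.
The add-one convention keeps $p > 0$, which the Bonferroni logic needs.
Two nulls are exposed:

* **max-over-models** (default for the power harness): each permutation
  records the maximum BA over all candidate sets, giving a family-wise p
  for the best model;
* **per-model** p-values with explicit Bonferroni thresholds
  (`alpha / n_tests`), the mode the hierarchical scan uses.

Because distances, neighbour sets and genotype cells are phenotype-free,
they are computed once; only the vote/tally step (a few integer operations
per individual, implemented in C++) is repeated per permutation.  The CV
plan is likewise held fixed across permutations: the statistic is treated
as a function of the labels given the plan.  Re-stratifying folds per
permutation would be marginally more faithful to a from-scratch re-analysis
but would destroy the precomputation that makes $10^4$–$10^6$ permutations
feasible; at the balanced designs used here the difference is negligible.

**Adaptive early stopping.**  Deep p-values are only needed for survivors,
so permutations run in rounds of increasing cumulative count with
decreasing survival thresholds (`default_perm_schedule()`: 100/0.05,
1000/5e-3, 1e4/5e-4, 1e5/5e-5, 1e6/5e-6, 2e6/2.5e-6).  Every candidate
consumes an independent permutation sub-stream derived from the master
seed, so (a) abandoning one candidate never perturbs another's stream, and
(b) a survivor's p-value is *exactly* the single-shot p-value at the same
cumulative count — early stopping is exact for survivors, a property the
test suite asserts.

## The hierarchical large-panel scan

For panels too large to window directly, `hierarchical_scan()` runs the
three-stage protocol: (1) keep one marker every `stride` (default 15),
window the retained markers, test all window pairs, keep pairs passing
Bonferroni; (2) recover the hidden markers inside surviving regions and
rescan each recovered set with finer windows; (3) run classic MDR on all
SNP pairs within surviving refined window pairs and report pairs passing
Bonferroni.  Marker selection by fixed stride is the default; smarter
(e.g. MAF-aware) pre-selection can be plugged in upstream.  Note a
structural interaction between the stride and block-like LD: with stride
$N$ and LD blocks shorter than $N$, some blocks contain no retained proxy
marker at all, and a causal variant in such a block is invisible to round 1
regardless of effect size.  Matching the stride to the local LD extent is
therefore part of the design, not a tuning nicety.

## The simulator

`simulate_dataset()` emulates the evaluation protocol used for windowed
interaction detectors:

1. a synthetic founder panel (default 197 founders × 2000 markers) with
   per-marker MAF drawn in $[0.3, 0.5]$ and block-like LD from a latent
   AR(1) Gaussian with autocorrelation `rho` (default 0.5), thresholded at
   each marker's allele frequency.  Markers whose *realized* MAF falls
   below the floor are re-thresholded on the same latent column (LD is
   preserved) with bounded retries;
2. cohort individuals assembled by sampling, independently per 10-marker
   block, one founder's block genotype — conserving within-block LD while
   allowing $197^{200}$ distinct genotypes;
3. $G$ causal SNPs (default drawn uniformly; they may or may not be in
   LD), given a penetrance table with **exactly zero marginal effects**:
   for every causal locus $i$ and genotype $k$,
   $\sum_{\text{others}} MP \cdot f = P(A \mid G_i = k) = P$ (prevalence
   $P = 0.5$ for the balanced design).  The table is built by drawing a
   random table and projecting out, under the frequency-weighted tensor
   decomposition, the grand mean and all single-locus components; what
   remains spans exactly the null space of all $3G$ marginalization
   constraints (for $G = 1$ that space is empty: only the constant table
   exists).  The residual is scaled so its largest deviation equals
   `effect_size`;
4. phenotypes by comparing one uniform deviate per individual to its
   multi-locus penetrance; cases and controls accumulated until the exact
   quotas (default 500/500) are met;
5. optionally, one marker of every consecutive pair is discarded at random
   ("the causative variant may not have been genotyped"), halving the
   panel and leaving 5-marker LD chunks from 10-marker blocks.

**Interaction patterns.**  The direction of the penetrance deviation can
be drawn at random in the constraint null space (`pattern = "random"`,
the default — each draw carries its own, possibly weak, detectable
interaction energy, which is what a "random epistasis model" means) or
set to the deterministic canonical product pattern
(`pattern = "product"`: the tensor product of per-locus
frequency-centred heterozygote-vs-homozygote contrasts, an XOR-like
checkerboard for $G = 2$).  The product pattern is the natural *planted
signal* for pipeline-recovery tests: it is the strongest pure
interaction available at a given `effect_size`, and its detectability
does not depend on a lottery over random directions.

**Parameter choices.**  The marginal constraint uses the founders'
empirical genotype frequencies at the causal loci (`freq_mode = "panel"`),
because that is the sampling distribution of the simulated cohort — the
marginal null then holds exactly in expectation for causal loci in
different blocks; HWE frequencies are available as an idealization.  The
`effect_size` knob (largest penetrance deviation from the prevalence) has
no stated reference value in the protocol this emulates; the default 0.5
is the maximal admissible contrast at prevalence 0.5 — penetrances reach
0 and 1, the multi-locus analogue of a fully penetrant epistatic model.
Power results should always be read relative to a stated effect size.

**What a green test does not establish.**  The synthetic panel reproduces
block-wise LD and the MAF spectrum, not the long-range LD texture,
haplotype diversity or genotyping errors of a real chromosome; power
numbers from this generator approximate, but do not reproduce, results
obtained on a real reference panel.  Two caveats are inherited from the
design itself: causal loci falling in the *same* block violate the
independence assumption behind the marginal constraint (a small residual
marginal effect can appear), and when thinning removes every causal SNP
the coverage criterion becomes vacuous (flagged in the output).

## The evaluation harness

`evaluate_replicate()` runs the scan with the family-wise null and scores
*detection* (family-wise $p < \alpha$) and *coverage* (by default the
strict "all" rule: every causal SNP surviving thinning lies inside the best
model's windows; an "any" rule is available).  `summarize_experiment()`
aggregates to power (detection rate), corrected power (detection with
coverage — structurally never larger than power) and, for $G = 0$ designs,
the false-positive rate.  `run_experiment()` adds per-replicate seeds
(`seed_base + replicate`), on-disk artifacts and crash-safe resumption.

## Numerical and degenerate-input conventions

* Permutation exceedance uses plain `>=` on doubles: observed and permuted
  statistics come from the identical code path, so equal statistics are
  bitwise equal.
* Distance additivity holds to ~1e-12; the test tolerance is 1e-10.
* Equal-BA candidates rank lexicographically on the sorted window ids.
* `K` must not exceed the smallest training-fold size (checked).
* Singular in-window correlation (Mahalanobis) is an error that names the
  ridge option rather than silently regularizing.
* All simulator components draw from sub-streams derived from the master
  seed, so identical configurations are byte-identical and sub-components
  are individually reproducible.

## Known limitations

* Dichotomous phenotypes only; no covariate adjustment (the GMDR/MB-MDR
  directions are out of scope).
* No LD-adaptive automatic window sizing; window boundaries are supplied
  by the user (`make_windows_from_boundaries()` supports variable sizes).
* The Mahalanobis form is per-window; cross-window correlations are
  ignored by construction.
* The marker-weighting hook has no default beyond uniform weights.
* Binary PLINK (.bed), VCF and imputation are intentionally unsupported;
  inputs are PLINK-text .ped/.map or the TSV dialect.
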