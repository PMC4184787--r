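---
title: "Methods: specificity screens, pattern clustering, and regulatory inference for neutrophil activation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specificity screens, pattern clustering, and regulatory inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutract)
```

## The data model

`neutract` analyzes population-level expression profiles: a genes × samples
matrix of normalized, **linear-scale** intensities together with a map from
each sample to a population (and, for neutrophil populations, a condition:
BM, BL, SF, UA, TG). Linear intensities are the stored currency throughout;
log2 is applied only where a method calls for it (the ANOVA filter, fold
correlation/slope, heat-map display). The package assumes normalized values
bounded well above zero — on the arrays this pipeline targets, even silent
genes report intensities of order 10 — so no pseudocount is used and a
non-positive value is treated as a data error, not censoring.

The analysis currency is the per-gene, per-population **mean over
replicates** (`population_means()`). The presence threshold of 120 intensity
units marks the level empirically associated with ~95% probability of
detectable protein on this platform; "expressed" always means *mean > 120*,
strictly.

## Specificity screens

Two complementary over-expression criteria define lineage-specific genes:

* **presence**: mean > 120 in every neutrophil population and ≤ 120 in
  every comparator population;
* **fold**: min(neutrophil means) ≥ 2 × max(comparator means).

The under-expression screen mirrors them with the roles swapped, except that
the fold direction is **strict** (`>` 2-fold rather than `≥`) — the two
screens are asymmetric by one boundary case, deliberately, because that is
how each criterion is stated. Reported fold ratios (min NF / max non-NF) are
rounded half-away-from-zero to the nearest integer; that convention
reproduces both published anchors (11.87 → 12 for *Stfa2l1*, 3.27 → 3 for
*Mrgpra2a*). Probe-level flags collapse to gene level by logical OR
(`collapse_probes()`).

A packaged 31-gene summary table (`specificity_summary_table()`) carries the
published per-population means, the comparator count-above-120 column, and
the comparator maxima, so both criteria can be re-applied without the full
compendium; `specificity_from_summary()` does exactly that and recovers the
13 / 23 / 5 criterion counts. One published median (*Clec5a*, printed 1980)
differs by one unit from the median of its own printed per-population values
(1979), presumably because the per-population values were rounded before the
median was taken; the package reports what it computes.

## The activation-gene filter

Cross-condition analyses are restricted to genes passing all four of:

| criterion | scale | default |
|---|---|---|
| presence: max condition mean | linear | > 120 |
| one-way ANOVA across conditions | log2 replicates | *P* < 0.01 |
| max pairwise fold of condition means | linear | ≥ 2 |
| within-condition CV of replicates | linear | < 0.5, every condition |

The ANOVA is computed on log2 values because measurement noise on this
platform is multiplicative; the log stabilizes variance so the equal-variance
F-test is appropriate. The implementation is a vectorized row-wise F
statistic (the per-gene loop is checked against `stats::oneway.test` in the
test suite). Identical replicates everywhere yield *p* = 1 (no evidence of
variation) rather than 0/0. The CV criterion defaults to *every* condition
(`cv_scope = "all"`), reading the replicate-consistency requirement as
applying across the neutrophil populations; `"any"` is available. Raw
*P* < 0.01 is used in the composite filter; a BH-adjusted mode
(`anova_mode = "q"`, *Q* < 0.05) is exposed for focused gene-set analyses.
All unordered condition pairs enter the pairwise-fold criterion.

Fold-change comparisons between conditions (`condition_correlation()`)
report the Pearson *r* of log2 fold changes and the OLS slope with a 95%
confidence interval. Venn counts of shared regulation support a strict mode
(fold > 2 in each member condition) and a relaxed mode in which a gene is
shared when one condition exceeds 2-fold and the others exceed 1.5-fold; in
both modes a gene contributes only if it passes the strict cutoff somewhere,
so region counts sum to the strict-anywhere gene count. Down-regulation uses
fold < 1/cutoff, symmetric with up.

## Pattern clustering and its validity control

Filtered genes are clustered on their replicate-level profiles across BL,
SF, UA, and TG. Each profile is mean-centered across samples (no variance
scaling), then Lloyd K-means with Euclidean distance runs to convergence,
with *k* = 32 by default. Numerical choices:

* initialization: *k* distinct genes sampled without replacement under the
  seed; 10 restarts, best objective kept; identical seed ⇒ identical result;
* empty clusters are re-seeded from the point farthest from its assigned
  center;
* the per-cluster **coefficient** is the mean Pearson correlation between
  member profiles and the cluster mean profile (the minimum is reported as a
  diagnostic); singletons get 1 by convention; a zero-variance profile, or a
  flat cluster mean (e.g. two perfectly anti-correlated members),
  contributes 0 and flags the cluster degenerate.

Because centering is additive while expression magnitudes are
multiplicative, K-means splits a shared *pattern* into magnitude bands.
`merge_clusters()` recombines them explicitly: the pair of clusters whose
standardized mean profiles correlate highest (≥ 0.9) is merged greedily, and
a merge is rolled back if either original cluster's coefficient drops by
more than 0.03 — the merge step is an explicit algorithm with the observed
maximum tolerable drop as its guardrail, replacing what is usually done by
inspection.

The **randomization control** permutes the values of each sample (column)
across genes — preserving every sample's value distribution exactly —
re-clusters, and records the null coefficients. Singleton clusters are
excluded from the null (their coefficient is 1 by definition and says
nothing about chance coherence). On structured data the real coefficients
should all exceed the null maximum; on the default synthetic design the
contrast is ~0.97 versus ~0.87.

## Regulatory inference

The regulatory model assigns each target gene to exactly one coarse module
and associates each module with candidate regulators, with regression-derived
weights. Weights are comparable only within a module; the package carries
them for reporting and never uses them in a test statistic — an association
is any record with a weight.

**Module-bin enrichment.** For a gene list, X is the number of unique listed
genes that are model targets (others are dropped and counted). Each of
10,000 permutations draws X genes *without replacement* from all targets —
a hypergeometric null, chosen because a fixed set of distinct genes is being
distributed over bins — and per-module counts are tabulated. The smoothed
upper-tail p-value `(1 + B)/(n + 1)` avoids zeros; BH across modules,
*Q* < 0.05. The result also carries `p_fuzzy`, a randomized ("fuzzy")
p-value `(#{> obs} + U·(1 + #{= obs}))/(n + 1)`: the count statistic is
discrete, so the inferential *p* is super-uniform by construction and can
never look uniform in a calibration check; the fuzzy variant is exactly
Uniform(0,1) under the null and is what the calibration tests consume. It is
a diagnostic only — inference always uses `p`/`q`.

**Pair enrichment.** Each listed gene generates one regulator–target pair
per association of its module. For regulator R the 2×2 table contrasts pairs
for R versus pairs for all other regulators, in the list versus in the rest
of the model; Pearson chi-square without continuity correction (Fisher's
exact test when any expected cell < 5), BH across regulators, *Q* < 0.01.
The exact contingency construction is not prescribed anywhere, so this
definition is declared rather than reconstructed; the total pairs generated
by a list is conserved across all per-regulator tables, which the test suite
checks. The chi-square is two-sided, so the `enriched` flag additionally
requires observed > expected (over-representation).

**Selection and the P-matrix.** Clusters are pooled into up / down / complex
groups by an explicit rule on the cluster centroid's log2 fold changes
versus blood (tolerance 1.5-fold): a rise past the tolerance with no fall
means "up", the mirror image "down", anything else "complex". A regulator is
selected when it is pair-enriched in at least one pool *and* associated with
at least one significantly enriched module in some pool. The regulator ×
cluster matrix holds **raw** pair-test p-values (significance calls are made
only at the pool level), and both axes are clustered with average linkage on
−log10 *p* (floored at 1e-300), Euclidean distance; `hclust`'s deterministic
tie handling makes the orders reproducible. BH Q-values are computed within
each pool separately (joint adjustment across pools would be the
alternative; within-pool matches treating each pool as its own family).

## The synthetic-data generator

`simulation_design()` encodes a desk-scale version of the study design: five
neutrophil conditions in triplicate, 20 comparator populations in duplicate,
2,000 genes. Replicates are log-normal around population means with a
controlled linear-scale CV (default 0.1; `noise_cv = 0` gives exact means) —
multiplicative noise matches the CV-based filter semantics of array data.
Planted structure, all recorded in truth tables:

* 20 lineage-specific genes at a low comparator baseline (20–60) elevated
  10-fold in every neutrophil population;
* six activation archetypes (uniform up and down, three single-condition
  responses, one TG+UA response) at 210 genes each, applied as fold
  patterns on SF/UA/TG versus BL. 210 per archetype puts the filter-passing
  set near the ~1,300 genes that the *k* = 32 clustering stage is designed
  for, so clustering and its randomization control run in the intended
  genes-per-cluster regime;
* a 40-module, 30-regulator model in which three planted regulators own two
  home modules each, and archetype genes are routed to their planted
  regulator's home modules with probability 0.9 (`concentration = 0` gives
  the null model used for calibration tests).

Two generator choices are identifiability requirements, not realism claims.
First, planted pattern genes draw their baseline from a narrow spread
(`archetype_log2_sd = 0.25`) while background genes span the full intensity
range (sd 1.5): under Euclidean clustering of *centered linear* profiles, a
wide multiplicative spread makes small-amplitude genes of different
archetypes mutually closer than same-archetype genes of different
amplitudes, so planted clusters would be unrecoverable by the specified
algorithm at any noise level. Real co-regulated genes do span wide magnitude
ranges; recovering them would require a different distance (e.g. correlation
or log-scale), which is outside this pipeline's contract. Second, background
genes are condition-flat, so the activation filter passes (almost) only
planted genes. Consequently, passing the planted-truth tests demonstrates
that the machinery is implemented correctly — not that the pipeline would
achieve comparable recall on real data, where cluster boundaries are not
crisp, magnitudes vary within patterns, and module assignments are noisy.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the
default 2,000-gene design (about 1,260 filtered genes, *k* = 32, 10,000
module permutations), the calibration checks on a 400-gene null model with
1,000 gene lists at 300 permutations each, and oracle comparisons on models
small enough for exact hypergeometric tails. Every stochastic step takes an
explicit integer seed, threaded through `withr::with_seed`, so identical
inputs and seeds give identical outputs, including the pipeline manifest's
file checksums.

## Known limitations

* The generator does not emulate probe-level artifacts, batch effects,
  correlated noise, or realistic module-size distributions.
* The merge step assumes magnitude bands share a *shape*; antagonistic
  patterns with high |correlation| are never merged (the threshold applies
  to the signed correlation).
* Chi-square p-values in the pair test are asymptotic; the Fisher fallback
  guards small expected counts but mixed families (some chi-square, some
  Fisher) are BH-adjusted together.
* The under-expression presence criterion requires expression in *all*
  comparator populations, which is sensitive to a single silent comparator;
  that is inherent to the criterion, not a tunable.
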