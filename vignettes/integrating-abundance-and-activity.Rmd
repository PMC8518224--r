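---
title: "Methods: scoring, filtering and integrating multiplexed variant abundance and activity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, filtering and integrating multiplexed variant abundance and activity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maveintegrate)
```

This vignette is the package's own account of the models and procedures it
implements, the choices we made where the design was genuinely open, and
what the synthetic-data tests do and do not establish about real data.

## The measurement model

In a VAMP-seq style experiment, each cell expresses one protein variant
fused to a fluorophore, so a cell's fluorescence (relative to an internal
expression control) is proportional to the variant's steady-state
abundance. Cells are sorted by FACS into four bins drawn at the quartiles
of the pooled fluorescence distribution, each bin is deep-sequenced, and a
variant's distribution of reads across bins carries its abundance signal.

The simulator mirrors exactly this structure. For variant $v$ with true
abundance $a_v \in [0,1]$, each of its cells receives a fluorescence value

$$x = a_v + \varepsilon, \qquad \varepsilon \sim N(0, \sigma),$$

gates are placed at the 25/50/75th percentiles of the pooled cell
population, and reads are drawn multinomially within each bin to a fixed
per-bin depth. This unit-interval location model is the simplest one that
preserves the monotone abundance-to-bin relationship the assay relies on;
no quantitative FACS model is implied by the assay description, so we did
not attempt one. Variant dropout is Bernoulli per variant and replicate,
which reproduces the replicate-count heterogeneity that motivates the
replicate filter.

Generator defaults (chosen once, as a desk-scale mimic of a real sorting
experiment): 500 variants, 8 replicates, 50,000 reads per bin, 1,000 cells
per variant per sort, fluorescence noise sd 0.10, dropout 0.15, and
designated control sets of 20 synonymous (abundance 0.9–1.0) and 20
nonsense variants (abundance 0–0.05). Abundant classes draw their true
abundance uniformly from [0.7, 1.0], destabilized classes from [0, 0.3].

## Per-replicate abundance scores

Within one replicate, a variant's counts $c_b$ are depth-normalized and
renormalized over bins,

$$f_b = \frac{c_b/N_b}{\sum_{b'} c_{b'}/N_{b'}},$$

and collapsed with the canonical sort-seq bin-weighted average

$$s = \textstyle\sum_b w_b f_b, \qquad w = (0, \tfrac13, \tfrac23, 1).$$

The original analyses of this assay family delegated scoring to an
external enrichment-scoring tool without printing a closed-form estimator;
the weighted average above is the standard VAMP-seq estimator, keeps the
0–1 scale, and is fully transparent, which is why we specify it
explicitly. Scores are then anchored per replicate,

$$s' = \frac{s - \mathrm{med}(s_\text{nonsense})}
            {\mathrm{med}(s_\text{synonymous}) -
             \mathrm{med}(s_\text{nonsense})},$$

so nonsense controls sit near 0 and synonymous controls near 1. Medians
are the default anchor because they are robust to a few misbehaving
controls; means are available via `scoring_config(anchor = "mean")`.
Variants with fewer than `min_reads_per_variant = 5` reads in a replicate
are *missing*, never zero — some read filter is implied by any notion of a
confidently scored variant, and 5 is deliberately permissive and
configurable. Codon-level entries encoding the same amino-acid change are
averaged (unweighted) within a replicate before anchoring, because
amino-acid variants are the unit of record.

## The replicate filter

Scores of variants seen in few replicates are noisier, and with enough of
them the composite dataset degrades. The filter asks, for each candidate
threshold $k$: after keeping only variants scored in $\ge k$ replicates,
does the upper bound of the 95% confidence interval of the mean nonsense
composite score stay below the lowest 5% of synonymous composite scores?

Three constructions needed fixing where the procedure was open:

* **CI construction.** "The CI of the nonsense score" is read as the
  normal-approximation CI of the *mean* nonsense composite score
  (mean $\pm z_{0.975}\,\mathrm{sd}/\sqrt{n}$ across nonsense variants).
  A bootstrap percentile CI is available via `filter_config(ci =
  "percentile")`.
* **Decision statistic.** The pass fraction that drives selection comes
  from an ordinary paired bootstrap: control variants are resampled with
  replacement *keeping each variant's replicate count*, the filter is
  re-applied, and the separation test re-run (`n_boot = 100` by default).
  A variant of the procedure that shuffles the replicate-count labels
  across the pooled controls — destroying the association between score
  quality and replicate count — is implemented as the explicit null
  control (`permute_null = TRUE`). The permuted version cannot serve as
  the decision statistic: when low-replicate variants really are noise,
  permutation contaminates the filtered set at *every* $k$, so no filter
  would ever qualify; its role is calibration, and the package's tests
  verify both its size under exchangeable controls and that it erases the
  filter's advantage on adversarial data.
* **Selection rule.** $k^\ast$ is the smallest $k$ whose bootstrap pass
  fraction reaches 0.95. The rule matches the "minimal number of
  replicates" intent; the 0.95 is configurable.

Composite scores are the plain mean of a variant's per-replicate anchored
scores, with sd, $se = sd/\sqrt{n}$, and a coefficient of variation that
is withheld when the composite score is $\le 0.05$ (division blows up near
the nonsense anchor; such records carry `cv_undefined = TRUE`).

Confidence classes use the control composites: with $q_\text{syn}$ the 5th
percentile of synonymous and $q_\text{non}$ the 95th percentile of
nonsense composite scores, a variant is confidently wild-type-like when
$s - 2se > q_\text{non}$ and $s + 2se \ge q_\text{syn}$, confidently low
when the mirrored condition holds, and unclassified otherwise. All
empirical percentiles use linear interpolation between order statistics
(R's default quantile type 7).

When two independently scored libraries are merged,
`compare_score_sets()` fits ordinary least squares over the shared
variants; `score_sets_combinable()` gates the merge at
$|\text{slope}-1| \le 0.15$ and $|\text{intercept}| \le 0.15$ by default,
after which scores are pooled without further normalization.

## Activity integration and the four-way classification

Activity scores arrive on their raw (log-spread) scale from the yeast
rescue assay, and the classification cutoffs are applied on that raw
scale: wild-type-like above $10^{-1.11}$, loss below $10^{-2.13}$ (the
published percentile-derived cutoffs of the source activity dataset);
anything between is indeterminate. Rescaling to a reporting scale — mean
nonsense activity to 0, wild type to 1 — happens after classification and
only for presentation. The wild-type anchor is the activity table's
designated `WT` row when present, else the mean of synonymous variants
(`classification_config(wt_anchor = ...)`).

The joint classes combine the two axes: wild-type-like, loss of abundance
only, loss of activity only (abundant but catalytically dead — the
dominant-negative candidate pool), and loss of both. Any indeterminate or
missing axis yields `unclassified`, and `unclassified_reason`
distinguishes variants missing from one assay from variants measured but
indeterminate, since the two deserve different treatment downstream.

## The SNV null spectrum and enrichment

To ask whether a functional class is over-represented in a variant
catalog, the baseline is the set of protein variants reachable by single
nucleotide substitution: each sense codon has nine single-nucleotide
neighbors; synonymous events are dropped; and each unique protein variant
is weighted by its codon degeneracy (the number of distinct events
producing it). The initiator codon and terminal stop are excluded by
default, so a 403-residue ORF yields $402 \times 9 = 3618$ events.
Degeneracy is why, for instance, a TGT cysteine codon reaches serine
twice (AGT, TCT) while a CGA arginine codon reaches glycine and glutamine
once each. Transition/transversion weighting is uniform by default — the
source analyses found cancer-specific rates made little difference — but
the enumeration keeps the hook for a rate matrix.

Fold enrichment of a category is its observed class fraction (per
observation for somatic catalogs, per unique variant for clinical sets
without frequencies) divided by the degeneracy-weighted baseline fraction,
both computed over classified variants only. This forces the identity
$\sum_c \text{fold}_c \cdot \text{baseline}_c = 1$ within every category,
which the tests assert to $10^{-12}$.

The synthetic catalog generator inverts this analysis. Its contract:
classes whose fold target differs from 1 receive exactly
$\text{fold} \times \text{baseline}$ of the observations
(largest-remainder rounding of class counts), unit-fold classes absorb the
complementary probability proportionally to their baselines, and variant
identities within a class are sampled by degeneracy weight. Two
consequences are worth stating plainly. First, allocating class counts by
rounding rather than multinomially means closure tests measure the
analysis code, not sampling noise. Second, the identity above makes a
*joint* recovery of arbitrary fold targets impossible: enriching one class
must depress the others, by a factor $(1 - F b)/(1 - b)$ for an enriched
class with baseline share $b$ and fold $F$. A closure test that wants all
four recovered folds near their targets must therefore give the enriched
class a small baseline share; the package's closure tests use a 6%
loss-of-both baseline with a 3-fold target, leaving the unit-fold classes
depressed by ~13%, inside the test band.

## Tolerance profiles and clustering

A position's profile is the vector of composite scores of its scored
missense substitutions (stops excluded by default); positions with at
least 17 scored missense variants count as high coverage. Profile
distance is Euclidean over the substitutions scored at *both* positions,
rescaled by $\sqrt{19/n_\text{shared}}$ so sparse overlaps are comparable
with complete ones; pairs sharing fewer than 5 substitutions are not
comparable, and positions incomparable with everything are excluded with
a warning. Clustering is agglomerative with average linkage. None of
linkage, metric, or missing-data handling is forced by the source
analyses, so all are configurable; rows are sorted by position before
clustering, which makes the output invariant to input order. Flat
tolerance groups use the positional median score: tolerant at $\ge 0.75$,
intolerant at $\le 0.35$, partial between. These boundaries are package
defaults calibrated on synthetic mimic data (they reproduce planted
tolerant / partial / intolerant structure), not claims about any
published boundary.

## Pipeline, seeds, and problem sizes

`run_pipeline()` chains the stages from one config and one global seed;
each stage hashes its name into a child seed, so adding a stage never
perturbs another stage's randomness, and a rerun with the same config
reproduces identical output checksums. `run_demo()` concentrates the
simulated library on the first 25 positions of the packaged CDS so the
clustering stage has high-coverage positions at desk scale.

The packaged CDS (`pten_synthetic_cds()`) is a *synthetic* 403-residue
stand-in for the PTEN reference cDNA: only its length and the codons at
the three dominant-negative-relevant positions (TGT at 124, GGA at 129,
CGA at 130) match the reference, which is exactly the information the
event-count and degeneracy results depend on. It is not the biological
sequence and is labelled accordingly.

Test problem sizes were chosen as the smallest that make the statistical
assertions stable: the default 500-variant/8-replicate simulation for
score recovery and classification closure, 1,000 bootstrap replicates for
filter calibration, 20 seeded runs for the adversarial filter property,
50 random toy CDSs (10–50 codons) for the brute-force spectrum oracle,
and 5,000 observations for the enrichment closure.

## What the synthetic data does not show

The generator emulates the statistical skeleton of a sorting experiment —
monotone abundance-to-fluorescence mapping, quartile gating, multinomial
sequencing, per-replicate dropout, control anchoring — and none of its
biology or its artifacts: no barcode sequencing errors or PCR jackpots,
no multi-codon variants mapping to one barcode, no cell-cycle or
expression-level heterogeneity beyond a single Gaussian, no correlation
between abundance and activity errors, and dropout that is independent
across replicates rather than clustered by library batch. Passing the
closure tests therefore demonstrates that the analysis code implements
its stated model faithfully and recovers truth *under that model*; it
does not certify performance on real libraries, where the replicate
filter value, the confidence-class yield, and the clustering structure
must be re-examined on the controls actually present. Known limitations
worth repeating: the scoring estimator is not a regression over time
points and will differ from enrichment-regression scores on real counts;
the activity cutoffs are dataset-specific constants; and enrichment
against heavily filtered class maps (low classification coverage)
inherits the composition biases of whatever was classifiable.
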