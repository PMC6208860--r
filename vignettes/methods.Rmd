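---
title: "Methods: signature construction, concordance scoring, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature construction, concordance scoring, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`neuroconcord`, the parameters that matter, the synthetic study design
the generators emulate, and the design decisions taken where the
methodology was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## 1. Preprocessing

**Background filter.** Microarray probes are kept when their
linear-scale signal exceeds `factor` (default 1.4) times the local
background *in every sample* of a dataset. The all-sample rule is the
strict reading of an exclusive selection criterion; a
fraction-of-samples variant can be had by pre-masking. The filter is
monotone: a larger factor always retains a subset.

**Quantile normalization** delegates to
`limma::normalizeQuantiles(ties = TRUE)`: after normalization every
column shares the row-wise mean of the sorted columns, and tied values
within a column receive the mean of their tied quantile values. On
continuous (tie-free) data the transform makes all column
distributions exactly identical and is exactly idempotent; with ties
the tied-mean convention trades a small distributional discrepancy for
rank stability.

**Batch standardization.** Each gene is z-scored within each batch and
rescaled to its pooled mean and SD. Genes with zero within-batch
variance are shifted to the pooled mean without scaling (no
divide-by-zero); a single-batch input passes through unchanged. This
location/scale standardization is a deliberate simplification of
empirical-Bayes batch correction (which shrinks batch effects across
genes): it removes first- and second-moment batch differences, does
not pool information across genes, and can be switched off simply by
not calling it. It is not an empirical-Bayes method and does not claim
its small-batch robustness.

**Covariate adjustment** fits, per gene, expression on age and a sex
indicator by iteratively reweighted least squares with Huber weights
(tuning constant 1.345, at most 50 iterations, tolerance 1e-6 — the
`MASS::rlm` defaults for the psi function, with the iteration cap made
explicit). Genes fitting exactly fall back to ordinary least squares,
whose solution coincides in that case. Residuals are returned with the
gene's intercept added so the output stays on the log2 intensity
scale.

**Age diagnostics.** Control samples are ordered by age; each sample
is summarized by its mean Pearson correlation with all other samples,
smoothed by a centered moving average (window in samples, odd; edge
windows shrink). A pooled-variance Student's t statistic compares
samples below versus at-or-above the 65-year cutoff (old minus young);
it is flagged unavailable with fewer than 3 samples on either side or
degenerate variance. The 65-year cutoff is the conventional late-onset
threshold and is applied before disease-gene selection.

## 2. Signature construction

**Two-class statistic.** `d_g = (mean_case − mean_control)/(s_g + s0)`
with `s_g` the pooled two-sample standard error and the fudge factor
`s0` set to the median of all gene-wise `s_g`. The median-`s0` choice
stabilizes small-variance genes without the original spline search; it
is exposed as a parameter.

**Permutation FDR.** Class labels are shuffled; when the exact
assignment space `choose(n, n_case)` is no larger than `n_perm`
(default 1000) it is enumerated exhaustively, making small-sample
results deterministic. For a gene with observed `|d*|`,
`q = median_b #{|d_b| ≥ |d*|} / #{|d_obs| ≥ |d*|}`, clipped to [0, 1]
and made monotone non-increasing in `|d|` by a running maximum from
the largest `|d|` down. No null-proportion (pi0) correction is
applied, which makes the q-values conservative; power analyses should
account for this.

**Quantitative statistic.** The regression slope on the covariate
divided by (slope standard error + `s0`), with the covariate shuffled
for the null (all `n!` permutations when feasible).

**Commonality.** A gene enters a direction when selected at `q < fdr`
with the matching sign in at least `min_datasets` (default 2) cohorts
and never in the opposite direction anywhere — a conservative rule
that discards cross-cohort sign conflicts entirely. The source
protocol is ambiguous between "at least two" and "more than two"
cohorts; we take ≥ 2 for both gene families and expose the quota.
Stricter per-cohort thresholds (0.001 instead of 0.01) can be supplied
per dataset, matching the practice of tightening the two largest
cohorts.

**Refinement.** Final up = initial up minus all age-associated genes
(either direction); likewise down. The accounting reports
`common/(common+final)` per direction both exactly and truncated to
one decimal — truncation, not rounding, is the convention under which
the published count pairs 282/748 and 795/844 print as 27.3% and
48.5%. The published initial totals (980/1550) are inconsistent with
those pairs' sums (1030/1639); the package reports both quantities and
does not attempt to reconcile them.

## 3. Pathway activity

`A = Σ w_g r_g / |P ∩ universe|` with `w_g = −1` for annotated
repressors, `r_g` the log2 ratio to the control-group mean. The
normalizer is the *measured* member count (not the nominal pathway
size), keeping `|A|` bounded by the observed ratios and comparable
across platforms; a `nominal_size` flag restores the nominal-size
convention. Significance draws `B` random gene sets of the same
measured size from the measured universe (without replacement within a
draw) and recomputes the score with default activator roles — the
gene-set null mirrors the wording used for model evaluation, and
random sets carry no role annotation by construction. p-values are
plain proportions; an add-one option exists for downstream
multiplicity work. Differential pathways between groups use a label-
shuffling two-sided permutation p on the group-mean activity
difference, with direction from the sign.

## 4. Network topology

Distances are unweighted shortest paths (`igraph::distances`) over all
cross pairs of mapped genes; unreachable pairs are excluded from the
mean and counted (a diameter+1 imputation is optional). A set enters
only when strictly more than 50% of its genes map into the network
(the strict reading of "> 50%"). Degree-proportion profiles walk
degree values in increasing order, accumulating genes until a bin
holds at least `min_count = 10` network genes (sparse degrees merge
into the next value); the trailing bin may be smaller. The trend is a
bin-count-weighted linear GLM of the proportion on the representative
degree — the direct regression of proportion on degree; a logit-scale
variant was rejected because sparse high-degree bins dominate its
leverage. Signature-adjacent pathways are selected from a distance row
either by percentile (keep the closest fraction, default 0.9) or by an
absolute similarity cut with similarity = −distance. The published
"similarity score > 3.35 / top 90%" pairing is recorded but its
similarity formula is undefined in the source; we do not guess it, and
default to the percentile mode.

## 5. Promoter analysis

PWM columns receive a 0.01 pseudo-count and are normalized to
probabilities; a window's raw score is the sum of log probabilities of
its bases (`N` scores as the column minimum), rescaled to
`(raw − min)/(max − min)` in [0, 1] (a fully uniform matrix scores 1
with a warning). Matches are windows at relative score ≥ 0.9, counted
one base at a time on both strands (overlaps all count; strand
handling is not specified upstream, and both-strand scanning is the
symmetric default). Binding profiles are binarized before Jaccard
similarity — presence/absence minimizes the influence of absent sites —
with both-empty pairs defined as identical (J = 1); genes are
clustered by average linkage on 1 − J. The cluster-versus-direction
association uses the Yates-corrected chi-squared test on the 2×2
table, flagged undefined on zero margins.

## 6. Model evaluation

A model profile is the per-gene mean log2 ratio to its matched
control, mapped to human symbols through the orthology table (unmapped
genes dropped and counted; duplicate orthologs collapse by mean). The
null resamples `B = 1000` equal-sized gene (or pathway) sets from the
model's measured universe. One-sided p-values follow the expected
direction per sign: `p_up` is the fraction of null means at least the
observed up-mean, `p_down` the fraction at most the observed
down-mean (the source states only the upward phrasing; the downward
mirror is the natural completion). Classification is strong when both
`p ≤ 0.01`, weak when both `p ≤ 0.05`, else none. DEGs use an
inclusive 2-fold boundary (`|log2 ratio| ≥ 1`) or SAM at FDR 0.1 (the
protocol text's value; a figure caption says 0.01, so the threshold is
an override). Pooled-RNA arrays are treated as single replicates of
condition means; pooling-induced variance reduction is not modeled.

## 7. The synthetic study design

The generators emulate the structure of the multi-cohort case/control
study, not its biology:

- **Cohorts** (`gen_human_datasets`): log2 value = gene baseline
  N(8, 1) + disease effect + age effect + batch offset + N(0, σ = 1)
  noise. Planted disease genes (default 50 up + 50 down of 2000) get
  effect δ = 1.5 within-group SD in cases, each active in a random
  subset of at least 2 cohorts; planted age genes get ±0.02 log2
  units/year around age 70 (≈ 0.8 log2 units over the 40-year span).
  Ages are uniform on 55–95 so the 65-year cutoff is exercised; sexes
  alternate; batch offsets are N(0, 0.5) per gene × cohort; 5% of
  genes are planted to fail the 1.4-fold background filter. Default
  cohort size is 30 cases / 30 controls — a several-fold scale-down of
  the public cohorts emulated (hundreds of samples each), chosen so
  the permutation FDR retains realistic power while keeping runtimes
  at desk scale.
- **Models** (`gen_animal_model`): ratio = ρ·effect +
  √(1−ρ²)·N(0, σ_m = 0.3) over a 1500-gene measured universe (planted
  genes always measured), emitted under rodent-style symbols through
  the generated orthology map. ρ = 1 reproduces the human effects,
  ρ = 0 is an unrelated model, ρ = −1 an anticorrelated one.
- **Network** (`gen_network`): preferential attachment (m = 2), which
  yields the heavy-tailed degree distribution of real interactomes;
  with `hub_bias` the planted up-genes are relabeled onto nodes with
  probability ∝ degree², reproducing hub enrichment of upregulated
  signaling genes.
- **Pathways** (`gen_pathways`): random member draws of size 10–40,
  with designated pathways seeded so at least half their members are
  planted disease genes, and repressor roles assigned at a configurable
  fraction.
- **Promoters** (`gen_promoters`): uniform-base sequences of 2501 bp
  (the (−2000, +500] TSS window) with three class-specific 8-mer
  consensus motifs planted three times each, non-overlapping. 8-mers
  make a one-mismatch window score 0.875 < 0.9, so only exact copies
  match at the default threshold; longer motifs would tie exactly at
  the threshold (1 − 1/L ≥ 0.9 for L ≥ 10) and blur the classes.

What the generators deliberately omit: probe-level noise models (dye
bias, spatial artifacts), correlated gene modules beyond the planted
sets, non-linear age trajectories, and realistic pathway overlap
structure. Passing tests therefore demonstrate correctness of the
statistical machinery under the declared generative model, not
performance on real cohort data.

## 8. Numerical and reproducibility choices

- All randomness flows from one master seed through named substreams
  (`substream_seed`), so adding a stage never perturbs another's
  draws; rerunning a configuration reproduces every output table byte
  for byte.
- Permutation spaces are enumerated exhaustively when smaller than the
  requested draw count; otherwise draws are uniform random shuffles.
- Proportion p-values are reported without add-one correction by
  default, following the plain-proportion definition; at B = 1000 the
  granularity is 0.001.
- Degenerate guards: zero-variance genes in batches (no scaling),
  exact-fit genes in robust regression (OLS fallback), uniform PWMs
  (score 1 with warning), zero-margin contingency tables and
  degenerate-variance t tests (flagged, not errored), unreachable node
  pairs (excluded and counted), empty refined signatures (warning).
- Problem sizes in the test suite (2000-gene universes, 200 null-model
  replicates, 50 oracle graphs, 20 promoter seeds, B = 1000) were
  chosen as the smallest sizes at which the studied properties are
  stable across seeds.

## 9. Known limitations

- The batch stage removes only location/scale differences; strong
  batch-by-gene interactions survive it.
- SAM q-values lack a pi0 estimate and are conservative near the
  threshold in small cohorts.
- The pathway-activity null randomizes gene sets, not sample labels;
  it answers "is this score extreme for a set of this size", not "is
  this score extreme under no group structure" (the differential-
  pathway test answers the latter).
- Network distances treat the interactome as a fixed, unweighted,
  undirected graph; edge confidence and direction are ignored beyond
  the low-throughput filter.
- Orthology is symbol-level and many-to-one; paralog expansions are
  collapsed by mean.
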