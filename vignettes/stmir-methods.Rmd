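---
title: "stmir: model, assumptions, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stmir: model, assumptions, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmir)
```

## The problem and the modelling idea

Spatial transcriptomics assays capture polyadenylated mRNA; mature miRNAs
are not measured. But miRNA and mRNA abundances are jointly constrained by
the regulatory state of a tissue, so a map from mRNA profiles to miRNA
expression can be *learned* where both are measured — paired bulk cohorts —
and *applied* where only mRNA is measured — ST spots, each of which
aggregates tens of cells and therefore resembles a small bulk sample. The
transferred quantity is deliberately called predicted miRNA **activity**:
it is a model readout of the local regulatory state, not a physical
measurement of miRNA copies.

Three assumptions underpin the transfer:

1. the mRNA→miRNA relationship learned in bulk holds at the spot level
   (spots behave like small bulks);
2. rank-based encodings make expression comparable across platforms, so a
   model trained on rank-normalized bulk data can consume rank-normalized
   spot data;
3. miRNA–mRNA dependence may be nonlinear, which motivates boosted
   regression trees over linear models.

## Cross-cohort integration

Two cohorts (in the motivating application: a tumor-tissue compendium and
a cell-line panel) are harmonized in four deterministic steps:

1. **Feature harmonization.** miRNA arm suffixes (`-3p`/`-5p`, case
   insensitive, end of name) are stripped, names are lower-cased, and rows
   sharing a harmonized name are collapsed to their element-wise median.
   Features absent from either cohort, or zero in more than
   `max_zero_frac` (default 0.9) of samples in *either* cohort, are
   dropped from both — a feature unusable in one cohort cannot support a
   shared model.
2. **log2(x+1)** on the non-negative raw values.
3. **Intra-sample percentile ranking**: within each sample the n feature
   values become r/(n+1) with average-tie ranks. This erases per-sample
   distributional differences (depth, dynamic range).
4. **Cross-sample inverse normal transform (INT)**: per feature, values
   across samples are re-ranked, converted to quantiles r/(n+1), and
   mapped through Φ⁻¹. Every feature then follows a standard normal shape
   in every cohort, so the cohorts can be concatenated sample-wise.

The quantile convention r/(n+1) is used at both ranking steps because it
never produces 0 or 1 (Φ⁻¹ stays finite) and is symmetric, making each
tie-free INT row exactly mean-zero. Because steps 3–4 consume only ranks,
any strictly increasing per-sample distortion of the raw data leaves the
result **bit-identical** — this is the package's batch-effect removal, and
it is tested as such. A corollary worth knowing: percentile values are
discrete (n levels), so across samples *ties* in step 4 are normal and
slightly shrink the INT row variance; the mean-zero/closed-form-sd
properties are exact only on tie-free input, which is how they are tested.

Before training, features and targets are min-max scaled to [0,1] per
feature (per-feature rather than global, so every gene spans the full
input range; the choice is configurable in spirit but fixed here). A
constant feature maps to all zeros with a warning — it carries no signal
either way. The min/max parameters are frozen into the model; at
application time out-of-range values are clipped.

One upstream description of the source data mentions a separate outlier
and Z-score step before rank integration; the detailed pipeline above
subsumes both (ranking is insensitive to outliers and INT fixes the
marginal), so no separate winsorization is implemented.

## The regressor

One gradient-boosted tree ensemble is trained per miRNA (multi-output
architectures would couple targets and blur the per-miRNA accuracy
accounting). The learner is a native implementation (src/gbtree.cpp):
squared-error boosting where round t fits a depth-limited CART to the
current residuals using the split gain

  G_L²/(n_L+λ) + G_R²/(n_R+λ) − G²/(n+λ)

and leaf values G/(n+λ), with learning-rate shrinkage η. Splits are exact
greedy over pre-sorted features with deterministic tie-breaking (first
feature, lowest threshold), so training is bit-reproducible given the
seed; row subsampling, if enabled, uses a private counter-based RNG and
never touches R's global RNG state. Defaults: η=0.1, depth 3, 200 rounds,
min 10 samples to split, min 5 per leaf, λ=1. The grid-search helper
evaluates η∈{0.05,0.1,0.3} × depth∈{3,5,7} × rounds∈{100,300,500} by
k-fold CV and minimizes mean CV MSE, breaking ties toward the smaller
model (fewer rounds, then shallower, then slower learning).

Why implement boosting natively? No gradient-boosting, CART, random-forest
or neural-network package is available in the target environment, and the
boosted regressor is the core of the method — it is built, documented and
tested here rather than wrapped.

**Evaluation.** Per-miRNA Spearman ρ is computed across samples (the
per-sample alternative exists in principle but per-miRNA is what the
accuracy claims refer to); MSE/MAE/R² are computed over all entries with
SS_tot about the observed grand mean, per held-out fold, then averaged
over the k=5 folds. A constant observed column has undefined ρ: it is
reported as `NA`, counted, and excluded from medians — never coerced to 0.
The same convention applies when a *predictor* collapses to a constant
(e.g. an intercept-only ridge fit): its skill is undefined, not zero.

**Baselines.** Ridge and lasso (glmnet, λ by deterministic inner CV), a
bagged random forest (100 trees, mtry=p/3, reusing the native tree
builder), and a feed-forward network (two hidden ReLU layers, Adam, early
stopping on a 10% validation split; hidden sizes default (32,16) — sized
for desk-scale benchmarks rather than the (128,32) one would use on
full-cohort data) are run under identical seeded fold splits.

## Spatial transfer

QC follows the published recipe: spots with total counts above
`max_total_counts` (default 38,000) are removed first, then optional
per-spot minima, then genes detected in fewer than `min_cells_per_gene`
(default 10) of the *surviving* spots are dropped; the QC report records
each removal and the evaluation order. Counts are scaled to a common
per-spot total (10,000) and log10(x+1)-transformed. Highly variable genes
are the top 2,000 by variance of the log-normalized values — the simplest
dispersion statistic; fancier mean-variance-trend flavors exist but would
add a fitted curve without changing what the tests can establish.

How should spot expression be placed on the bulk model's input scale? The
source description is silent. The package's decision (`rank-int`, the
default encoding) is to re-apply the training encoding *within the ST
dataset*: intra-spot percentile ranks over the model's frozen feature
genes, per-gene INT across spots, per-gene min-max. Rationale: rank
encoding is precisely the mechanism that made the two bulk cohorts
comparable, and the same argument applies to a third platform. The
alternative (`lognorm-scale`: min-max of the log-normalized values
directly) is exposed for comparison. Note a real limitation either way:
the across-spot distribution of a gene in a mixed tissue is not the
across-sample distribution of the training cohorts, so transfer quality
degrades for targets whose dependence on mRNA is strongly non-monotone
(see Limitations).

## Attribution and downstream statistics

Deconvolution abundances are normalized per spot; the dominant type is the
argmax, with two conservative rules: an exact tie between the top two
shares leaves the spot unassigned (no lexicographic winner), and an
optional `min_purity` threshold (default 0 = pure argmax, since the
motivating study names a threshold without stating its value) unassigns
low-purity spots. Attribution never reads activity values — the join with
activity happens strictly afterwards.

"Consistently high activity" in a cell type is quantified by two emitted
statistics rather than one opaque cutoff: the median activity over
dominated spots (with a dense rank, 1 = highest) and the *consistency* —
the fraction of dominated spots where the miRNA exceeds that spot's own
median activity. Cell types dominating fewer than `min_spots` (default 10)
spots are excluded: medians over a handful of spots are unstable.
Pan-context conservation intersects the per-context top-k rankings
(default k=40, mean activity, ties alphabetical); the conserved set is
monotone in k by construction.

Differential activity uses the two-sided Wilcoxon rank-sum test: exact via
the U distribution when the smaller group has ≤8 spots and the data are
tie-free (exactness is cheap there), otherwise the normal approximation
with tie correction and continuity correction; all-tied data give p=1.
BH-FDR is applied across the tested miRNAs (the published threshold is
q<0.1). miRNA–target correlations use Pearson r over shared spots with
Bonferroni adjustment over all pairs tested in the call — the family is
the call, recorded in the result attributes, since the source does not
define it — and the dual threshold |r|>0.3, adjusted p<0.05; positive
significant pairs are labelled `promoting`, negative `suppressing`.
Gene-set enrichment is the upper-tail hypergeometric test against a
user-supplied universe with BH adjustment across sets. The deliberate
asymmetry — BH at 0.1 for differential activity, Bonferroni at 0.05 for
correlations — mirrors the published analysis and both are configurable.

## The synthetic world

Every test runs on generated data, so what the generator does and does not
emulate bounds what a green test means.

`make_regulatory_truth` fixes a gene universe (default 300 genes), miRNAs
(default 30) each with 3–6 target genes, signed weights in ±[0.6,1.2],
and a functional form; `generate_bulk_cohort` draws log-normal gene
expression (`exp(μ_g + z)`, z iid standard normal), evaluates each miRNA's
form on its targets' z, standardizes, adds N(0, σ) noise (default
σ=0.1), and maps through a fixed increasing function to a positive scale.
The default form mix is 80% linear and 20% threshold (step functions of
the latent z) — the stated nonlinearity level of the package's recovery
claims. A third form, pure product interactions z₁·z₂, is implemented but
*not* part of the default mix: a pure product has zero marginal
correlation with either input, and at σ=0.1 neither linear models nor
depth-3 boosting extract meaningful signal from it (held-out ρ≈0.1); it
exists to stress-test interaction learning, with `product_frac > 0`.
Batch distortion (`affine-power`: x → a·x^b per sample, a∈[0.5,2],
b∈[0.8,1.25]) is strictly monotone, which is exactly the class of effects
the rank pipeline removes.

`generate_spatial_tissue` builds cell-type profiles by perturbing the gene
means per type (shift sd 0.8 on the log scale), mixes them per spot —
70% of spots get a planted dominant type with purity uniform in
[0.6,0.95], the rest are symmetric mixtures — and draws Poisson counts at
an expected depth of 5,000 per spot. True per-spot activity applies the
truth's forms to the per-gene standardized mixed log-expression. The
emitted abundance matrix is the *true* mixing weights: attribution
recovery is tested against a noiseless deconvolution, deliberately
isolating the assignment logic from deconvolution error.

Deliberate simplifications: Poisson counts (no zero inflation or
overdispersion), no spatial autocorrelation of cell types, no
ligand–receptor structure, miRNA truth generated *from* mRNA (the
prediction task's direction, not the causal one). A green recovery test
therefore establishes that the pipeline recovers the statistical structure
it assumes — not that real tissue satisfies those assumptions.

Generation is purely functional in the seed: every generator wraps its
RNG use so the caller's RNG state is untouched, and same-seed reruns are
byte-identical.

## Numerical conventions and degenerate inputs

- Stage labels (`raw`→`log`→`percentile`→`z`→`scaled01`) are checked on
  entry and stamped on exit; applying a step out of order is an error,
  never a silent recompute.
- Ranking a single feature is refused (it would be the constant 0.5).
- Min-max of a constant feature is 0 (warned); external scaler params clip
  to [0,1]; scaling inverts to 1e-12.
- Prediction requires the exact frozen feature-gene vector, in order;
  mismatches error with the first 10 offenders, no imputation.
- Fold assignment is a seeded shuffle with round-robin labels; identical
  seed ⇒ identical folds across runs and across model families in the
  baseline benchmark.
- Model files are a versioned container; an unknown version errors rather
  than being reinterpreted.
- The pipeline runner hashes each stage's configuration together with its
  upstream hashes (MD5 of the serialized config); unchanged stages are
  served from cache, and changing a threshold invalidates exactly the
  stages downstream of it.

## Known limitations

- **Nonlinear transfer shift.** The ST encoding aligns each gene's
  *marginal* distribution with training, but the joint distribution over
  genes in a mixed tissue (low-rank, driven by cell-type composition)
  differs from bulk. For monotone-dominated dependencies this costs little
  (planted-truth recovery ρ≈0.64 at defaults); for pure interactions it
  can flip signs. Conclusions about interaction-driven miRNAs should not
  rest on transferred predictions alone.
- **Dominant-type attribution** ignores sub-dominant cell types by design;
  activity in spots with no dominant type is never attributed.
- **Deconvolution quality is inherited.** Abundances are consumed as
  given; attribution tests use noiseless abundances and so bound only the
  assignment logic.
- **Activity is relative.** Values live on the cohort-calibrated [0,1]
  scale; comparisons are meaningful within a model's outputs, not across
  differently trained models.
- IO is plain text (TSV/CSV/MTX/GMT/JSON) plus versioned RDS model files;
  HDF5 containers are not read or written.
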