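# stmir — spatially resolved miRNA activity inference from mRNA profiles

MicroRNAs are not captured by standard poly(A)-based spatial
transcriptomics (ST) assays, so their spatial organization inside tumors is
invisible to platforms like 10x Visium. `stmir` addresses this by *learning*
the mapping from mRNA expression to miRNA expression on large paired bulk
cohorts (where both modalities are measured on the same samples) and
transferring the trained regressors to ST spots — each spot being, in
effect, a miniature bulk sample. The output is a **predicted miRNA
activity** value in \[0,1\] for every (spot, miRNA) pair, which can then be
attributed to cell types and tested for differential activity and target
co-expression.

The package is aimed at computational biologists who have (a) two paired
bulk mRNA/miRNA cohorts (e.g. a tumor-tissue cohort and a cell-line
cohort), (b) a Visium-style spot-by-gene count matrix, and (c) a spot-level
cell-type abundance matrix from an external deconvolution tool.

## Method in brief

**Cross-cohort integration.** Each cohort is log2(x+1)-transformed, then
each sample's values are replaced by intra-sample percentile ranks
r/(n+1), and each feature's ranks are mapped through the standard normal
quantile function Φ⁻¹ (a rank-based inverse normal transform, INT). Because
only ranks survive, any strictly monotone per-sample distortion — platform,
lab, or library-size effects — is removed *exactly*; the two cohorts are
then concatenated and min-max scaled to \[0,1\]. Features with zero
expression in more than 90% of samples in either cohort are dropped; miRNA
arm suffixes (-3p/-5p) are stripped and duplicate names collapsed to their
element-wise median.

**Per-miRNA regression.** One gradient-boosted regression-tree ensemble per
miRNA (learning rate η, tree depth d, M rounds; default η=0.1, d=3, M=200,
grid-searchable over η∈{0.05,0.1,0.3} × d∈{3,5,7} × M∈{100,300,500})
predicts that miRNA's scaled expression from the scaled mRNA features.
Boosting minimizes squared error; each round fits a depth-limited tree to
the current residuals with gain
G_L²/(n_L+λ) + G_R²/(n_R+λ) − G²/(n+λ). The tree learner is implemented
natively (Rcpp) — no external boosting library is required. Accuracy is
reported as per-miRNA Spearman ρ plus MSE/MAE/R², averaged over 5
cross-validation folds, alongside ridge, lasso, random-forest and
feed-forward-network baselines.

**Spatial transfer.** Visium matrices are QC-filtered (spots above a total
count ceiling, default 38,000; genes detected in fewer than 10 spots),
total-count normalized, log10-transformed, and reduced to the top 2,000
highly variable genes. The model's frozen feature genes are re-encoded
inside the ST dataset with the same rank→INT→min-max recipe used in
training, and the per-miRNA regressors are applied per spot.

**Attribution and statistics.** Each spot's dominant cell type is the
argmax of its normalized deconvolution abundances (optionally thresholded;
exact ties stay unassigned). Per cell type, candidate miRNAs are ranked by
median activity over dominated spots with a consistency score. Differential
activity between spot groups uses two-sided Wilcoxon rank-sum tests (exact
for small tie-free groups) with Benjamini–Hochberg FDR; miRNA–target
correlations use Pearson r with |r|>0.3 and Bonferroni-adjusted p<0.05;
target-gene sets are tested by upper-tail hypergeometric enrichment.

## Worked example

Everything below is generated — no downloads. The synthetic generator
plants a known regulatory truth (per-miRNA target genes, signed weights,
linear or threshold functional forms) shared by two bulk cohorts and a
spotted tissue, so recovery can be checked against ground truth.

```r
library(stmir)

truth  <- make_regulatory_truth(n_genes = 300, n_mirnas = 30, seed = 7)
bulk_a <- generate_bulk_cohort(truth, n_samples = 250,
                               cohort_label = "tissueCohort", seed = 8)
bulk_b <- generate_bulk_cohort(truth, n_samples = 250,
                               cohort_label = "lineCohort",
                               batch_distortion = "affine-power", seed = 9)

ts <- run_integration(bulk_a$mrna, bulk_a$mirna, bulk_b$mrna, bulk_b$mirna)
#> TrainingSet: 500 samples, 300 feature genes, 30 target miRNAs

model <- train_model(ts, hyperparams(0.1, 3, 200), seed = 7)
#> ModelBundle: 30 miRNA regressors on 300 feature genes (lr=0.1, depth=3, trees=200)

st  <- generate_spatial_tissue(truth, n_spots = 200, seed = 10)
sdq <- qc_filter(st$spots, max_total_counts = 38000, min_cells_per_gene = 10)
act <- predict_spot_activity(model, normalize_st(sdq))
#> ActivityMatrix: 200 spots x 30 miRNAs

da <- assign_dominant(st$abundance, min_purity = 0.5)
table(da$dominant_type)
#>  celltype1  celltype2  celltype3  celltype4  celltype5 UNASSIGNED
#>         24         33         34         29         39         41

prof <- celltype_mirna_profile(act, da, min_spots = 10)
head(prof[order(prof$celltype, prof$rank), ], 3)
#>   celltype       mirna median_activity consistency rank
#>  celltype1 hsa-mir-016       0.8591765   1.0000000    1
#>  celltype1 hsa-mir-008       0.6638583   0.8333333    2
#>  celltype1 hsa-mir-029       0.6330011   0.7916667    3
```

The median activity column says that in the 24 spots dominated by
celltype1, hsa-mir-016's predicted activity is 0.86 (on the \[0,1\]
training scale) and exceeds each spot's own median miRNA activity in 100%
of those spots — a candidate celltype1-specific miRNA. Differential
testing between celltype1-dominated spots and all other assigned spots:

```r
keep <- da$dominant_type != "UNASSIGNED"
lab  <- ifelse(da$dominant_type[keep] == "celltype1", "celltype1", "other")
res  <- differential_activity(
  stmir:::new_activity_matrix(act$values[keep, ]), lab)
head(res[order(res$q), c("mirna", "effect", "p", "q")], 3)
#>        mirna     effect            p            q
#>  hsa-mir-007 -0.9438272 1.923631e-13 5.226201e-12
#>  hsa-mir-016  0.9296296 4.377493e-13 5.226201e-12
#>  hsa-mir-023 -0.9265432 5.226201e-13 5.226201e-12
```

(effect is the rank-biserial 2U/(n₁n₂)−1; positive means higher in
celltype1.) Against the planted truth, predicted spot activity reaches a
median Spearman ρ of **0.640** over the 30 miRNAs at these settings.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli","stmir.R",package="stmir"))') \
    simulate --out fixtures --seed 7
# then: integrate / train / predict-st / attribute / diff / corr / enrich,
# or a full cached pipeline from a key:value config file:
#   ... run --config run.cfg
```

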