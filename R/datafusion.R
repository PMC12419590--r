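#' @useDynLib stmir, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats qnorm median cor rnorm rlnorm runif rpois pt phyper
#'   p.adjust sd quantile pwilcox predict var
NULL

#' Harmonize miRNA names by stripping arm suffixes and collapsing duplicates
#'
#' Mature-arm designators (`-3p` / `-5p`, case-insensitive, at the end of the
#' name) are removed, names differing only in letter case are unified to the
#' lower-cased stem, and rows that end up sharing a name are collapsed to
#' their element-wise median. Output rows are ordered by first occurrence of
#' each harmonized name.
#'
#' @param m an [ExprMatrix] of modality `"miRNA"`.
#' @return an [ExprMatrix] with unique harmonized miRNA names.
#' @export
harmonize_mirna_names <- function(m) {
  stopifnot(inherits(m, "ExprMatrix"))
  if (m$modality != "miRNA") stop("harmonize_mirna_names() requires modality miRNA")
  if (nrow(m$values) == 0L) stop("no miRNA features")
  stripped <- sub("-(3p|5p)$", "", feature_ids(m), ignore.case = TRUE)
  canon <- tolower(stripped)
  groups <- split(seq_along(canon), factor(canon, levels = unique(canon)))
  out <- matrix(NA_real_, length(groups), ncol(m$values),
                dimnames = list(names(groups), sample_ids(m)))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    out[g, ] <- if (length(idx) == 1L) m$values[idx, ]
                else apply(m$values[idx, , drop = FALSE], 2, median)
  }
  em_update(m, values = out)
}

#' Restrict two cohorts to shared, non-sparse features
#'
#' Keeps only features present in both cohorts (in sorted order), then drops
#' any feature whose zero fraction exceeds `max_zero_frac` in *either*
#' cohort: a feature unusable in one cohort cannot support integration.
#'
#' @param a,b [ExprMatrix] objects of the same modality.
#' @param max_zero_frac features with a zero fraction strictly greater than
#'   this in either cohort are removed (default 0.9).
#' @return a list with elements `a` and `b`, restricted to the surviving
#'   features in identical order.
#' @export
filter_common_features <- function(a, b, max_zero_frac = 0.9) {
  stopifnot(inherits(a, "ExprMatrix"), inherits(b, "ExprMatrix"))
  if (a$modality != b$modality) stop("cohorts must share a modality")
  if (max_zero_frac < 0 || max_zero_frac > 1)
    stop("max_zero_frac must be in [0,1]")
  common <- sort(intersect(feature_ids(a), feature_ids(b)))
  if (length(common) == 0L) stop("no shared features")
  va <- a$values[common, , drop = FALSE]
  vb <- b$values[common, , drop = FALSE]
  keep <- rowMeans(va == 0) <= max_zero_frac & rowMeans(vb == 0) <= max_zero_frac
  if (!any(keep)) stop("no shared features")
  list(a = em_update(a, values = va[keep, , drop = FALSE]),
       b = em_update(b, values = vb[keep, , drop = FALSE]))
}

#' Log-transform raw expression values
#'
#' Applies `log_base(x + 1)` element-wise.
#'
#' @param m an [ExprMatrix] at stage `"raw"` with non-negative values.
#' @param base logarithm base, 2 or 10.
#' @return an [ExprMatrix] at stage `"log"`.
#' @export
log_transform <- function(m, base = 2) {
  expect_stage(m, "raw", "log_transform")
  if (!base %in% c(2, 10)) stop("base must be 2 or 10")
  neg <- which(m$values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 rownames(m$values)[neg[1, 1]], colnames(m$values)[neg[1, 2]]))
  }
  em_update(m, values = log(m$values + 1, base = base), stage = "log")
}

#' Intra-sample percentile ranking
#'
#' Within each sample (column) the feature values are replaced by their
#' percentile rank r/(n+1), with average ranks on ties, mapping every
#' sample's expression distribution onto (0,1) and discarding sample-level
#' distributional differences.
#'
#' @param m an [ExprMatrix] at stage `"log"`.
#' @return an [ExprMatrix] at stage `"percentile"`.
#' @export
intra_sample_percentile_rank <- function(m) {
  expect_stage(m, "log", "intra_sample_percentile_rank")
  n <- nrow(m$values)
  if (n < 2L) stop("ranking undefined for n=1")
  ranks <- apply(m$values, 2, rank, ties.method = "average")
  em_update(m, values = ranks / (n + 1), stage = "percentile")
}

#' Cross-sample rank-based inverse normal transform
#'
#' For each feature (row), its values across samples are ranked (average
#' ties), mapped to quantiles r/(n+1), and pushed through the standard normal
#' quantile function, so each feature follows a standard normal shape across
#' samples regardless of platform. Monotone per-sample batch distortions of
#' the raw data leave this output unchanged.
#'
#' @param m an [ExprMatrix] at stage `"percentile"`.
#' @return an [ExprMatrix] at stage `"z"`.
#' @export
inverse_normal_transform <- function(m) {
  expect_stage(m, "percentile", "inverse_normal_transform")
  n <- ncol(m$values)
  if (n < 2L) stop("inverse normal transform requires at least 2 samples")
  z <- t(apply(m$values, 1, function(x)
    qnorm(rank(x, ties.method = "average") / (n + 1))))
  dimnames(z) <- dimnames(m$values)
  em_update(m, values = z, stage = "z")
}

#' Concatenate two rank-normalized cohorts by samples
#'
#' @param a,b [ExprMatrix] objects at stage `"z"` with identical ordered
#'   features and disjoint sample ids.
#' @return a single [ExprMatrix] at stage `"z"` whose `sample_cohort` field
#'   records the originating cohort of every sample.
#' @export
integrate_cohorts <- function(a, b) {
  expect_stage(a, "z", "integrate_cohorts")
  expect_stage(b, "z", "integrate_cohorts")
  if (!identical(feature_ids(a), feature_ids(b)))
    stop("feature order mismatch between cohorts")
  if (length(intersect(sample_ids(a), sample_ids(b))) > 0)
    stop("duplicate sample_id across cohorts")
  em_update(a,
            values = cbind(a$values, b$values),
            cohort = paste(a$cohort, b$cohort, sep = "+"),
            sample_cohort = c(a$sample_cohort, b$sample_cohort))
}

#' Per-feature min-max scaling to \[0,1\]
#'
#' During training the per-feature min/max are computed from the data and
#' returned so they can be frozen in the model; at application time frozen
#' `params` are supplied and out-of-range values are clipped to \[0,1\].
#' A constant feature maps to all zeros (with a warning).
#'
#' @param m an [ExprMatrix] (typically stage `"z"`).
#' @param params optional list with numeric vectors `min` and `max` named by
#'   feature (as returned by a previous call).
#' @return list with elements `matrix` (an [ExprMatrix] at stage
#'   `"scaled01"`) and `params`.
#' @export
minmax_scale <- function(m, params = NULL) {
  stopifnot(inherits(m, "ExprMatrix"))
  v <- m$values
  external <- !is.null(params)
  if (external) {
    missing <- setdiff(names(params$min), rownames(v))
    if (length(missing) > 0)
      stop(sprintf("scaler params given for features absent from matrix: %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
    mn <- params$min[rownames(v)]
    mx <- params$max[rownames(v)]
    if (anyNA(mn) || anyNA(mx))
      stop("matrix contains features without scaler params")
  } else {
    mn <- apply(v, 1, min)
    mx <- apply(v, 1, max)
    params <- list(min = mn, max = mx)
  }
  rng <- mx - mn
  const <- rng == 0
  if (any(const) && !external)
    warning(sprintf("%d constant feature(s) mapped to 0", sum(const)))
  rng[const] <- 1
  out <- (v - mn) / rng
  out[const, ] <- 0
  if (external) out <- pmin(pmax(out, 0), 1)
  list(matrix = em_update(m, values = out, stage = "scaled01"),
       params = params)
}

#' Assemble the sample-aligned training set
#'
#' Aligns a scaled mRNA matrix (features) and a scaled miRNA matrix
#' (targets) on their shared samples and transposes them to the
#' sample x feature orientation used by the regression module.
#'
#' @param mrna,mirna [ExprMatrix] objects at stage `"scaled01"`.
#' @param feature_restrict optional character vector of genes (e.g. spatial
#'   highly variable genes) to which the feature space is restricted; genes
#'   absent from the data are dropped with a warning.
#' @param scaler_params optional list with `x` and `y` min-max parameter sets
#'   to freeze into the training set.
#' @return a `TrainingSet` with fields `X` (sample x gene), `Y`
#'   (sample x miRNA), `feature_genes`, `target_mirnas`, `scaler_params`,
#'   `cohort_of_sample`.
#' @export
build_training_set <- function(mrna, mirna, feature_restrict = NULL,
                               scaler_params = NULL) {
  expect_stage(mrna, "scaled01", "build_training_set")
  expect_stage(mirna, "scaled01", "build_training_set")
  shared <- intersect(sample_ids(mrna), sample_ids(mirna))
  if (length(shared) < 10L) stop("insufficient paired samples")
  genes <- feature_ids(mrna)
  if (!is.null(feature_restrict)) {
    missing <- setdiff(feature_restrict, genes)
    if (length(missing) > 0)
      warning(sprintf("%d requested feature gene(s) absent from data: %s",
                      length(missing),
                      paste(utils::head(missing, 10), collapse = ", ")))
    genes <- intersect(feature_restrict, genes)
    if (length(genes) == 0L) stop("feature_restrict leaves no genes")
  }
  X <- t(mrna$values[genes, shared, drop = FALSE])
  Y <- t(mirna$values[, shared, drop = FALSE])
  cohorts <- mrna$sample_cohort[match(shared, sample_ids(mrna))]
  structure(
    list(X = X, Y = Y,
         feature_genes = genes,
         target_mirnas = colnames(Y),
         scaler_params = scaler_params,
         cohort_of_sample = stats::setNames(cohorts, shared)),
    class = "TrainingSet")
}

#' @export
print.TrainingSet <- function(x, ...) {
  cat(sprintf("TrainingSet: %d samples, %d feature genes, %d target miRNAs\n",
              nrow(x$X), length(x$feature_genes), length(x$target_mirnas)))
  invisible(x)
}

#' Run the full two-cohort integration pipeline
#'
#' Convenience wrapper chaining miRNA name harmonization, shared-feature
#' filtering, log2(x+1), intra-sample percentile ranking, cross-sample
#' inverse-normal transformation, sample-wise concatenation, per-feature
#' min-max scaling, and training-set assembly.
#'
#' @param mrna_a,mirna_a raw [ExprMatrix] pair for cohort A.
#' @param mrna_b,mirna_b raw [ExprMatrix] pair for cohort B.
#' @param max_zero_frac passed to [filter_common_features()].
#' @param feature_restrict passed to [build_training_set()].
#' @return a `TrainingSet` (see [build_training_set()]); its
#'   `scaler_params` field holds the frozen min-max parameters.
#' @export
run_integration <- function(mrna_a, mirna_a, mrna_b, mirna_b,
                            max_zero_frac = 0.9, feature_restrict = NULL) {
  mirna_a <- harmonize_mirna_names(mirna_a)
  mirna_b <- harmonize_mirna_names(mirna_b)
  g <- filter_common_features(mrna_a, mrna_b, max_zero_frac)
  m <- filter_common_features(mirna_a, mirna_b, max_zero_frac)
  rank_z <- function(x) inverse_normal_transform(
    intra_sample_percentile_rank(log_transform(x, base = 2)))
  mrna_z <- integrate_cohorts(rank_z(g$a), rank_z(g$b))
  mirna_z <- integrate_cohorts(rank_z(m$a), rank_z(m$b))
  sx <- minmax_scale(mrna_z)
  sy <- minmax_scale(mirna_z)
  build_training_set(sx$matrix, sy$matrix,
                     feature_restrict = feature_restrict,
                     scaler_params = list(x = sx$params, y = sy$params))
}
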