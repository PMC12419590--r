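#' Feature-by-sample expression matrix with pipeline stage tracking
#'
#' `ExprMatrix` is the working container of the bulk-integration pipeline: a
#' numeric feature x sample matrix together with its modality (`"mRNA"` or
#' `"miRNA"`), a cohort label, and the normalization `stage` the values are
#' at. Every pipeline operation checks the stage of its input and stamps the
#' stage of its output, so applying a step to data at the wrong stage is an
#' error rather than a silent recomputation.
#'
#' Stages, in pipeline order: `"raw"` (non-negative expression, e.g. TPM),
#' `"log"` (log(x+1)), `"percentile"` (intra-sample percentile ranks, all
#' values in (0,1)), `"z"` (per-feature inverse-normal scores), `"scaled01"`
#' (per-feature min-max scaled to \[0,1\]).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   have unique, non-empty rownames (feature ids) and colnames (sample ids).
#' @param modality `"mRNA"` or `"miRNA"`.
#' @param cohort cohort label (free string).
#' @param stage one of `"raw"`, `"log"`, `"percentile"`, `"z"`, `"scaled01"`.
#' @param sample_cohort optional per-sample cohort label vector (used after
#'   cohort integration); defaults to `cohort` recycled.
#'
#' @return an object of class `ExprMatrix`.
#' @export
ExprMatrix <- function(values, modality = c("mRNA", "miRNA"),
                       cohort = "cohort", stage = "raw",
                       sample_cohort = NULL) {
  modality <- match.arg(modality)
  stage <- match.arg(stage, c("raw", "log", "percentile", "z", "scaled01"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_ids")
  if (is.null(sample_cohort))
    sample_cohort <- rep(cohort, ncol(values))
  if (length(sample_cohort) != ncol(values))
    stop("`sample_cohort` must have one entry per sample")
  obj <- structure(
    list(values = values, modality = modality, cohort = cohort,
         stage = stage, sample_cohort = sample_cohort),
    class = "ExprMatrix")
  validate_expr_matrix(obj)
  obj
}

validate_expr_matrix <- function(m) {
  v <- m$values
  if (m$stage == "percentile" && (any(v <= 0) || any(v >= 1)))
    stop("stage=percentile requires all values strictly in (0,1)")
  if (m$stage == "scaled01" && (any(v < 0) || any(v > 1)))
    stop("stage=scaled01 requires all values in [0,1]")
  invisible(m)
}

#' @export
print.ExprMatrix <- function(x, ...) {
  cat(sprintf("ExprMatrix [%s, stage=%s, cohort=%s]: %d features x %d samples\n",
              x$modality, x$stage, x$cohort, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExprMatrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

expect_stage <- function(m, stage, op) {
  if (!inherits(m, "ExprMatrix")) stop(sprintf("%s() expects an ExprMatrix", op))
  if (!m$stage %in% stage)
    stop(sprintf("%s() requires stage %s but input is at stage '%s'",
                 op, paste(sQuote(stage), collapse = " or "), m$stage))
  invisible(m)
}

# rebuild with new values/fields, revalidating
em_update <- function(m, values = m$values, stage = m$stage,
                      cohort = m$cohort, sample_cohort = m$sample_cohort) {
  obj <- structure(
    list(values = values, modality = m$modality, cohort = cohort,
         stage = stage, sample_cohort = sample_cohort),
    class = "ExprMatrix")
  validate_expr_matrix(obj)
  obj
}

#' Read an expression matrix from delimited text
#'
#' Features in rows, samples in columns, first column = feature ids, header
#' row = sample ids. Separator is inferred from the file extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param path file path.
#' @inheritParams ExprMatrix
#' @return an [ExprMatrix].
#' @export
read_expr_matrix <- function(path, modality = c("mRNA", "miRNA"),
                             cohort = "cohort", stage = "raw") {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "")
  ExprMatrix(as.matrix(df), modality = modality, cohort = cohort,
             stage = stage)
}

#' Write an expression matrix as TSV (features x samples)
#'
#' @param m an [ExprMatrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(m, path) {
  stopifnot(inherits(m, "ExprMatrix"))
  df <- data.frame(feature = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
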