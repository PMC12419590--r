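# Shared in-code fixtures. Everything is generated, seeded, and small.

# feature x sample ExprMatrix from a plain matrix, inventing dimnames
em <- function(values, modality = "mRNA", cohort = "test", stage = "raw",
               features = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- features %||%
    sprintf("%s%03d", if (modality == "mRNA") "G" else "hsa-mir-",
            seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("S%03d", seq_len(ncol(values)))
  ExprMatrix(values, modality = modality, cohort = cohort, stage = stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small TrainingSet with X in [0,1] and Y an arbitrary function of X
make_ts <- function(n = 60, p = 8, q = 3, seed = 1,
                    yfun = function(X) pmin(pmax(X[, 1], 0), 1),
                    noise_sd = 0) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("G%03d", 1:p)))
  Y <- vapply(seq_len(q), function(j) {
    y <- yfun(X) + rnorm(n, sd = noise_sd)
    pmin(pmax(y, 0), 1)
  }, numeric(n))
  colnames(Y) <- sprintf("hsa-mir-%03d", seq_len(q))
  rownames(Y) <- rownames(X)
  structure(list(X = X, Y = Y, feature_genes = colnames(X),
                 target_mirnas = colnames(Y), scaler_params = NULL,
                 cohort_of_sample = stats::setNames(rep("test", n),
                                                    rownames(X))),
            class = "TrainingSet")
}

# spot x miRNA ActivityMatrix from a plain matrix in [0,1]
am <- function(values, barcodes = NULL, mirnas = NULL) {
  values <- as.matrix(values)
  rownames(values) <- barcodes %||% sprintf("SPOT%03d", seq_len(nrow(values)))
  colnames(values) <- mirnas %||% sprintf("hsa-mir-%03d", seq_len(ncol(values)))
  stmir:::new_activity_matrix(values)
}

# SpotDataset from a dense count matrix (spots x genes)
sd_from_counts <- function(counts, coords = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("SPOT%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%03d", seq_len(ncol(counts)))
  stmir:::new_spot_dataset(
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    coords)
}
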