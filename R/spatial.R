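#' Load a Visium-style spot matrix from an MTX triplet directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (optionally
#' `.gz`) in `path`, plus an optional `tissue_positions.csv` /
#' `tissue_positions_list.csv` with barcode, in-tissue flag and array
#' row/column. The on-disk gene x barcode orientation is normalized to
#' spot x gene; rows sharing a gene symbol are summed.
#'
#' @param path directory containing the triplet.
#' @return a `SpotDataset`: sparse `counts` (spot x gene), `barcodes`,
#'   `gene_ids`, `coords` (data.frame or NULL), and per-spot `qc` totals.
#' @export
load_visium <- function(path) {
  find1 <- function(stem) {
    for (f in c(file.path(path, stem), file.path(path, paste0(stem, ".gz"))))
      if (file.exists(f)) return(f)
    NULL
  }
  mtx <- find1("matrix.mtx")
  bcf <- find1("barcodes.tsv")
  ftf <- find1("features.tsv") %||% find1("genes.tsv")
  if (is.null(mtx) || is.null(bcf) || is.null(ftf))
    stop(sprintf("'%s' is not an MTX triplet directory", path))
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(bcf)
  feat <- utils::read.table(ftf, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop(sprintf(
      "matrix is %d x %d but features/barcodes have %d/%d entries",
      nrow(m), ncol(m), length(genes), length(barcodes)))
  counts <- Matrix::t(m)            # -> spot x gene
  counts <- methods::as(counts, "CsparseMatrix")
  rownames(counts) <- barcodes
  # collapse duplicate gene symbols by summation (standard 10x practice)
  if (anyDuplicated(genes)) {
    uq <- unique(genes)
    map <- Matrix::sparseMatrix(i = seq_along(genes),
                                j = match(genes, uq),
                                x = 1,
                                dims = c(length(genes), length(uq)))
    counts <- counts %*% map
    colnames(counts) <- uq
  } else {
    colnames(counts) <- genes
  }
  coords <- NULL
  posf <- find1("tissue_positions.csv") %||% find1("tissue_positions_list.csv")
  if (!is.null(posf)) {
    pos <- utils::read.csv(posf, header = grepl("tissue_positions\\.csv",
                                                basename(posf)),
                           stringsAsFactors = FALSE)
    colnames(pos)[1] <- "barcode"
    pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]
    nc <- ncol(pos)
    coords <- data.frame(barcode = barcodes,
                         col = pos[[nc - 1]], row = pos[[nc]])
  } else {
    warning("no tissue position table found; coordinates absent")
  }
  new_spot_dataset(counts, coords)
}

new_spot_dataset <- function(counts, coords = NULL) {
  if (anyDuplicated(rownames(counts))) stop("duplicate spot barcodes")
  structure(
    list(counts = counts,
         barcodes = rownames(counts),
         gene_ids = colnames(counts),
         coords = coords,
         qc = data.frame(
           barcode = rownames(counts),
           total_counts = Matrix::rowSums(counts),
           genes_detected = Matrix::rowSums(counts > 0),
           row.names = NULL)),
    class = "SpotDataset")
}

#' @export
print.SpotDataset <- function(x, ...) {
  cat(sprintf("SpotDataset: %d spots x %d genes (median %d counts/spot)\n",
              nrow(x$counts), ncol(x$counts),
              as.integer(median(x$qc$total_counts))))
  invisible(x)
}

#' Spot and gene quality-control filtering
#'
#' Applies, in order: (1) removal of outlier spots whose total counts exceed
#' `max_total_counts`; (2) spot-level minimum total counts and detected
#' genes; (3) removal of genes detected (count > 0) in fewer than
#' `min_cells_per_gene` spots, evaluated on the spot-filtered matrix.
#' Unset thresholds (`NULL`) are disabled. The attached QC report records
#' every removal with its reason.
#'
#' @param sd a `SpotDataset`.
#' @param max_total_counts spot outlier ceiling (e.g. 38000); `NULL` = off.
#' @param min_cells_per_gene gene detection floor (default 10); `NULL` = off.
#' @param min_counts_per_spot,min_genes_per_spot spot minima; `NULL` = off.
#' @return the filtered `SpotDataset`, with the QC report in
#'   `attr(, "qc_report")`.
#' @export
qc_filter <- function(sd, max_total_counts = NULL, min_cells_per_gene = 10L,
                      min_counts_per_spot = NULL, min_genes_per_spot = NULL) {
  stopifnot(inherits(sd, "SpotDataset"))
  thr <- c(max_total_counts, min_cells_per_gene,
           min_counts_per_spot, min_genes_per_spot)
  if (any(thr < 0)) stop("QC thresholds must be non-negative")
  totals <- Matrix::rowSums(sd$counts)
  detected <- Matrix::rowSums(sd$counts > 0)
  keep_spot <- rep(TRUE, nrow(sd$counts))
  report <- list(input_spots = nrow(sd$counts), input_genes = ncol(sd$counts))
  if (!is.null(max_total_counts)) {
    drop <- totals > max_total_counts
    report$spots_over_max_counts <- sum(drop & keep_spot)
    keep_spot <- keep_spot & !drop
  }
  if (!is.null(min_counts_per_spot)) {
    drop <- totals < min_counts_per_spot
    report$spots_under_min_counts <- sum(drop & keep_spot)
    keep_spot <- keep_spot & !drop
  }
  if (!is.null(min_genes_per_spot)) {
    drop <- detected < min_genes_per_spot
    report$spots_under_min_genes <- sum(drop & keep_spot)
    keep_spot <- keep_spot & !drop
  }
  if (!any(keep_spot)) stop("QC eliminated all spots")
  counts <- sd$counts[keep_spot, , drop = FALSE]
  keep_gene <- rep(TRUE, ncol(counts))
  if (!is.null(min_cells_per_gene)) {
    ncells <- Matrix::colSums(counts > 0)
    keep_gene <- ncells >= min_cells_per_gene
    report$genes_under_min_cells <- sum(!keep_gene)
  }
  counts <- counts[, keep_gene, drop = FALSE]
  report$output_spots <- nrow(counts)
  report$output_genes <- ncol(counts)
  report$gene_filter_order <- "genes filtered after spot filtering"
  coords <- sd$coords
  if (!is.null(coords))
    coords <- coords[match(rownames(counts), coords$barcode), , drop = FALSE]
  out <- new_spot_dataset(counts, coords)
  attr(out, "qc_report") <- report
  out
}

#' Total-count normalization and log10 transform
#'
#' Each spot is scaled so its counts sum to `target_sum`, then values are
#' log10(x + 1) transformed, yielding an [ExprMatrix] at stage `"log"`
#' (genes x spots) ready for feature selection and model encoding.
#'
#' @param sd a QC-filtered `SpotDataset`.
#' @param target_sum per-spot total after scaling (default 10000).
#' @return an [ExprMatrix] (modality `"mRNA"`, cohort `"ST"`, stage `"log"`).
#' @export
normalize_st <- function(sd, target_sum = 1e4) {
  stopifnot(inherits(sd, "SpotDataset"))
  totals <- Matrix::rowSums(sd$counts)
  if (any(totals == 0))
    stop("zero-count spot present; apply qc_filter() first")
  scaled <- as.matrix(sd$counts / totals * target_sum)
  ExprMatrix(t(log10(scaled + 1)), modality = "mRNA", cohort = "ST",
             stage = "log")
}

#' Select highly variable genes
#'
#' Genes are ranked by the variance of their log-normalized expression
#' across spots (ties broken alphabetically for determinism) and the top-n
#' returned in rank order.
#'
#' @param m an [ExprMatrix] at stage `"log"` (genes x spots).
#' @param n number of genes to keep (default 2000); if fewer exist, all are
#'   returned.
#' @return character vector of gene names in decreasing-dispersion order.
#' @export
select_hvg <- function(m, n = 2000L) {
  expect_stage(m, "log", "select_hvg")
  if (ncol(m$values) < 2L) stop("select_hvg() needs at least 2 spots")
  v <- apply(m$values, 1, var)
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(min(n, length(v)))]
}

#' Encode a spatial expression matrix onto the model's input scale
#'
#' Restricts the log-normalized spot matrix to the model's frozen feature
#' genes (in model order) and re-applies the training encoding within the
#' spatial dataset: intra-spot percentile ranking over the restricted genes,
#' per-gene inverse-normal transformation across spots, and per-gene min-max
#' scaling to \[0,1\] (`"rank-int"`, the default). The alternative
#' `"lognorm-scale"` encoding min-max scales the log values directly.
#'
#' @param m an [ExprMatrix] at stage `"log"` (genes x spots).
#' @param model a `ModelBundle`.
#' @param encoding `"rank-int"` (default) or `"lognorm-scale"`.
#' @return numeric spot x gene matrix at the model input scale.
#' @export
prepare_features_for_model <- function(m, model,
                                       encoding = c("rank-int",
                                                    "lognorm-scale")) {
  expect_stage(m, "log", "prepare_features_for_model")
  encoding <- match.arg(encoding)
  stopifnot(inherits(model, "ModelBundle"))
  absent <- setdiff(model$feature_genes, feature_ids(m))
  if (length(absent) > 0)
    stop(sprintf(
      paste0("%d model feature gene(s) absent from the spatial matrix ",
             "(e.g. %s); retrain with feature_restrict set to the spatial ",
             "gene space"),
      length(absent), paste(utils::head(absent, 10), collapse = ", ")))
  sub <- em_update(m, values = m$values[model$feature_genes, , drop = FALSE])
  if (encoding == "rank-int") {
    enc <- minmax_scale(inverse_normal_transform(
      intra_sample_percentile_rank(sub)))$matrix
  } else {
    enc <- minmax_scale(em_update(sub, stage = "z"))$matrix
  }
  t(enc$values)
}

#' Predict spot-level miRNA activity
#'
#' Encodes the spatial matrix for the trained bundle and runs the per-miRNA
#' regressors, producing one predicted activity value per (spot, miRNA).
#'
#' @param model a `ModelBundle`.
#' @param m an [ExprMatrix] at stage `"log"` from [normalize_st()].
#' @param encoding passed to [prepare_features_for_model()].
#' @return an `ActivityMatrix`: `values` (spot x miRNA, in \[0,1\]),
#'   `barcodes`, `mirna_ids`, `model_id`, `encoding`.
#' @export
predict_spot_activity <- function(model, m, encoding = "rank-int") {
  X <- prepare_features_for_model(m, model, encoding)
  act <- predict(model, X)
  rownames(act) <- colnames(m$values)
  new_activity_matrix(act,
                      model_id = model$training_meta$timestamp %||% "model",
                      encoding = encoding)
}

new_activity_matrix <- function(values, model_id = "model",
                                encoding = "rank-int") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0 | values > 1)) stop("activity values must lie in [0,1]")
  structure(list(values = values,
                 barcodes = rownames(values),
                 mirna_ids = colnames(values),
                 model_id = model_id,
                 encoding = encoding),
            class = "ActivityMatrix")
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf("ActivityMatrix: %d spots x %d miRNAs (model %s)\n",
              nrow(x$values), ncol(x$values), x$model_id))
  invisible(x)
}

#' Write / read an activity matrix as TSV (spots x miRNAs)
#'
#' @param act an `ActivityMatrix`.
#' @param path file path.
#' @return `path` / an `ActivityMatrix`.
#' @export
write_activity <- function(act, path) {
  stopifnot(inherits(act, "ActivityMatrix"))
  df <- data.frame(barcode = act$barcodes, act$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "")
  new_activity_matrix(as.matrix(df))
}
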