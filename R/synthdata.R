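# Seeded generators that emulate the statistical structure the pipeline
# assumes: two paired bulk cohorts whose raw scales differ by per-sample
# monotone distortions, miRNA values that are (non)linear functions of a few
# target genes plus Gaussian noise, and spot mixtures of cell-type profiles
# with Poisson counts. miRNA "truth" is generated as a function of mRNA --
# the prediction task's direction, not the biologically causal one.

#' Regulatory ground truth shared by the bulk and spatial generators
#'
#' Defines the gene universe, per-miRNA target sets with signed weights and
#' a functional form (`linear`, `threshold`, `product`), and per-cell-type
#' mean expression profiles.
#'
#' @param n_genes number of genes (default 300).
#' @param n_mirnas number of miRNAs (default 30).
#' @param n_celltypes number of cell types for the spatial generator
#'   (default 5).
#' @param threshold_frac,product_frac fractions of miRNAs with step-function
#'   and product-interaction dependence on their targets (defaults 0.2 and
#'   0; the remainder are linear). Pure product interactions carry no
#'   marginal signal and are not part of the default mix; set
#'   `product_frac > 0` to stress-test interaction learning.
#' @param seed integer seed.
#' @return a `RegulatoryTruth` list.
#' @export
make_regulatory_truth <- function(n_genes = 300L, n_mirnas = 30L,
                                  n_celltypes = 5L, threshold_frac = 0.2,
                                  product_frac = 0, seed = 1L) {
  if (n_mirnas > n_genes) stop("n_mirnas must not exceed n_genes")
  with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    mirnas <- sprintf("hsa-mir-%03d", seq_len(n_mirnas))
    gene_meanlog <- stats::setNames(rnorm(n_genes, mean = 2, sd = 1), genes)
    n_thr <- round(threshold_frac * n_mirnas)
    n_prod <- round(product_frac * n_mirnas)
    forms <- c(rep("threshold", n_thr), rep("product", n_prod),
               rep("linear", n_mirnas - n_thr - n_prod))
    forms <- sample(forms)
    regulators <- lapply(seq_len(n_mirnas), function(j) {
      nt <- if (forms[j] == "product") 2L else sample(3:6, 1)
      targets <- sample(genes, nt)
      list(targets = targets,
           weights = stats::setNames(
             runif(nt, 0.6, 1.2) * sample(c(-1, 1), nt, replace = TRUE),
             targets),
           form = forms[j])
    })
    names(regulators) <- mirnas
    celltypes <- sprintf("celltype%d", seq_len(n_celltypes))
    celltype_shift <- matrix(rnorm(n_celltypes * n_genes, sd = 0.8),
                             n_celltypes, n_genes,
                             dimnames = list(celltypes, genes))
    structure(list(genes = genes, mirnas = mirnas,
                   gene_meanlog = gene_meanlog,
                   regulators = regulators,
                   celltypes = celltypes,
                   celltype_shift = celltype_shift,
                   seed = seed),
              class = "RegulatoryTruth")
  })
}

# evaluate each miRNA's functional form on a gene x sample latent z matrix;
# returns miRNA x sample matrix, each row standardized across samples
mirna_latent <- function(truth, z) {
  out <- matrix(0, length(truth$mirnas), ncol(z),
                dimnames = list(truth$mirnas, colnames(z)))
  for (j in seq_along(truth$regulators)) {
    reg <- truth$regulators[[j]]
    zt <- z[reg$targets, , drop = FALSE]
    f <- switch(reg$form,
      linear = colSums(zt * reg$weights),
      threshold = colSums((zt > 0) * reg$weights),
      product = reg$weights[1] * zt[1, ] * zt[2, ])
    s <- sd(f)
    out[j, ] <- if (s == 0) f - mean(f) else (f - mean(f)) / s
  }
  out
}

#' Generate one paired bulk cohort
#'
#' Gene expression is log-normal (`exp(meanlog_g + z)`, `z ~ N(0,1)` per
#' gene and sample); each miRNA's latent activity is its functional form
#' evaluated on its target genes' `z`, standardized, plus `N(0, noise_sd)`
#' noise; raw miRNA values are a fixed increasing map of that latent. An
#' optional per-sample strictly monotone distortion (`x -> a_s * x^(b_s)`)
#' mimics cross-platform scale differences and is removed exactly by the
#' rank pipeline.
#'
#' @param truth a `RegulatoryTruth` (shared across cohorts); `NULL` creates
#'   one from `n_genes`/`n_mirnas` and `seed`.
#' @param n_samples samples to draw (default 500, minimum 10).
#' @param noise_sd miRNA noise standard deviation on the standardized latent
#'   scale (default 0.1).
#' @param cohort_label cohort name used in sample ids.
#' @param batch_distortion `NULL` (none), `"affine-power"`, or a
#'   `function(x, sample_index)` applied per sample to raw values.
#' @param seed integer seed.
#' @param n_genes,n_mirnas used only when `truth` is `NULL`.
#' @return list with `mrna` and `mirna` (raw [ExprMatrix] objects),
#'   `activity` (true latent miRNA x sample matrix) and `truth`.
#' @export
generate_bulk_cohort <- function(truth = NULL, n_samples = 500L,
                                 noise_sd = 0.1, cohort_label = "cohortA",
                                 batch_distortion = NULL, seed = 1L,
                                 n_genes = 300L, n_mirnas = 30L) {
  if (n_samples < 10L) stop("n_samples must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(truth))
    truth <- make_regulatory_truth(n_genes, n_mirnas, seed = seed)
  with_seed(seed * 7L + 13L, {
    samples <- sprintf("%s_S%04d", cohort_label, seq_len(n_samples))
    z <- matrix(rnorm(length(truth$genes) * n_samples),
                length(truth$genes), n_samples,
                dimnames = list(truth$genes, samples))
    mrna_raw <- exp(truth$gene_meanlog + z)
    act <- mirna_latent(truth, z)
    act_noisy <- act + matrix(rnorm(length(act), sd = noise_sd),
                              nrow(act), ncol(act))
    mirna_raw <- exp(1 + 0.8 * act_noisy)
    if (!is.null(batch_distortion)) {
      distort <- batch_distortion
      if (is.character(distort) && distort == "affine-power") {
        a <- runif(n_samples, 0.5, 2)
        b <- runif(n_samples, 0.8, 1.25)
        distort <- function(x, s) a[s] * x^b[s]
      }
      for (s in seq_len(n_samples)) {
        mrna_raw[, s] <- distort(mrna_raw[, s], s)
        mirna_raw[, s] <- distort(mirna_raw[, s], s)
      }
    }
    list(mrna = ExprMatrix(mrna_raw, "mRNA", cohort_label, "raw"),
         mirna = ExprMatrix(mirna_raw, "miRNA", cohort_label, "raw"),
         activity = act,
         truth = truth)
  })
}

#' Generate a synthetic spatial tissue
#'
#' Each spot's expected expression is a convex combination of cell-type
#' profiles derived from the truth's gene means and cell-type shifts;
#' counts are Poisson at `depth_mean` expected total per spot. A
#' `dominant_fraction` of spots receive a planted dominant cell type with
#' purity drawn uniformly from `purity_range`; the rest are balanced
#' mixtures. True per-spot miRNA activity applies the truth's functional
#' forms to the per-gene standardized mixed log-expression and is mapped to
#' (0,1) through the normal CDF.
#'
#' @param truth a `RegulatoryTruth`.
#' @param n_spots number of spots (default 200).
#' @param dominant_fraction fraction of spots with a planted dominant type
#'   (default 0.7).
#' @param purity_range dominant-share range, within (0,1\] (default
#'   c(0.6, 0.95)).
#' @param depth_mean expected total counts per spot (default 5000).
#' @param seed integer seed.
#' @return list with `spots` (`SpotDataset` with grid coordinates),
#'   `abundance` (spot x cell-type true proportions), `activity_true`
#'   (spot x miRNA matrix in (0,1)), `dominant` (planted type per spot or
#'   NA), `truth`.
#' @export
generate_spatial_tissue <- function(truth, n_spots = 200L,
                                    dominant_fraction = 0.7,
                                    purity_range = c(0.6, 0.95),
                                    depth_mean = 5000, seed = 1L) {
  stopifnot(inherits(truth, "RegulatoryTruth"))
  if (length(truth$celltypes) == 0) stop("truth has no cell types")
  if (purity_range[1] <= 0 || purity_range[2] > 1 ||
      purity_range[1] > purity_range[2])
    stop("purity_range must lie within (0,1]")
  with_seed(seed * 11L + 5L, {
    K <- length(truth$celltypes)
    G <- length(truth$genes)
    barcodes <- sprintf("SPOT%04d", seq_len(n_spots))
    # cell-type expected expression on the linear scale
    prof <- exp(sweep(truth$celltype_shift, 2, truth$gene_meanlog, `+`))
    w <- matrix(0, n_spots, K, dimnames = list(barcodes, truth$celltypes))
    dominant <- rep(NA_character_, n_spots)
    n_dom <- round(dominant_fraction * n_spots)
    dom_idx <- if (n_dom > 0) seq_len(n_dom) else integer(0)
    for (s in seq_len(n_spots)) {
      if (s %in% dom_idx) {
        d <- sample.int(K, 1)
        u <- runif(1, purity_range[1], purity_range[2])
        rest <- rexp(K - 1)
        w[s, -d] <- (1 - u) * rest / sum(rest)
        w[s, d] <- u
        dominant[s] <- truth$celltypes[d]
      } else {
        g <- rexp(K)
        w[s, ] <- g / sum(g)
      }
    }
    mix <- w %*% prof                       # spot x gene expected expression
    rel <- mix / rowSums(mix)
    counts <- matrix(rpois(n_spots * G, depth_mean * rel), n_spots, G,
                     dimnames = list(barcodes, truth$genes))
    side <- ceiling(sqrt(n_spots))
    coords <- data.frame(barcode = barcodes,
                         col = (seq_len(n_spots) - 1) %% side,
                         row = (seq_len(n_spots) - 1) %/% side)
    zmix <- t(scale(log(mix)))              # gene x spot standardized
    act <- pnorm(mirna_latent(truth, zmix)) # spot ranks preserved per miRNA
    sd_obj <- new_spot_dataset(
      methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      coords)
    list(spots = sd_obj,
         abundance = w,
         activity_true = t(act),
         dominant = dominant,
         truth = truth)
  })
}

#' Write a complete small fixture suite to disk
#'
#' Emits every input surface the command-line interface consumes: paired
#' cohort TSVs for two batch-distorted cohorts sharing one regulatory
#' truth, a Visium-style MTX triplet with tissue positions, a cell-type
#' abundance CSV, a miRNA-target pair TSV, and a three-set GMT. Fully
#' deterministic: regeneration with the same seed is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_genes,n_mirnas,n_samples,n_spots sizes (small defaults).
#' @return invisible character vector of the written paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, n_genes = 60L,
                               n_mirnas = 10L, n_samples = 40L,
                               n_spots = 36L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- make_regulatory_truth(n_genes, n_mirnas, n_celltypes = 3L,
                                 seed = seed)
  a <- generate_bulk_cohort(truth, n_samples, cohort_label = "cohortA",
                            seed = seed + 1L)
  b <- generate_bulk_cohort(truth, n_samples, cohort_label = "cohortB",
                            batch_distortion = "affine-power",
                            seed = seed + 2L)
  st <- generate_spatial_tissue(truth, n_spots = n_spots,
                                depth_mean = 2000, seed = seed + 3L)
  paths <- character(0)
  wtsv <- function(m, name) {
    p <- file.path(out_dir, name)
    write_expr_matrix(m, p)
    p
  }
  paths <- c(paths,
             wtsv(a$mrna, "cohortA_mrna.tsv"), wtsv(a$mirna, "cohortA_mirna.tsv"),
             wtsv(b$mrna, "cohortB_mrna.tsv"), wtsv(b$mirna, "cohortB_mirna.tsv"))
  vis_dir <- file.path(out_dir, "visium")
  dir.create(vis_dir, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(st$spots$counts), file.path(vis_dir, "matrix.mtx"))
  writeLines(st$spots$barcodes, file.path(vis_dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = st$spots$gene_ids, symbol = st$spots$gene_ids,
               type = "Gene Expression"),
    file.path(vis_dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(barcode = st$spots$coords$barcode, in_tissue = 1,
               array_row = st$spots$coords$row,
               array_col = st$spots$coords$col,
               col = st$spots$coords$col, row = st$spots$coords$row),
    file.path(vis_dir, "tissue_positions.csv"),
    sep = ",", quote = FALSE, row.names = FALSE)
  paths <- c(paths, file.path(vis_dir, c("matrix.mtx", "barcodes.tsv",
                                         "features.tsv",
                                         "tissue_positions.csv")))
  abp <- file.path(out_dir, "abundance.csv")
  utils::write.table(
    data.frame(barcode = rownames(st$abundance), st$abundance,
               check.names = FALSE),
    abp, sep = ",", quote = FALSE, row.names = FALSE)
  pairp <- file.path(out_dir, "target_pairs.tsv")
  pairs <- do.call(rbind, lapply(names(truth$regulators), function(mir)
    data.frame(mirna = tolower(mir),
               gene = truth$regulators[[mir]]$targets)))
  utils::write.table(pairs, pairp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmtp <- file.path(out_dir, "genesets.gmt")
  with_seed(seed + 4L, {
    sets <- lapply(1:3, function(i)
      sample(truth$genes, min(8L, length(truth$genes))))
    writeLines(vapply(1:3, function(i)
      paste(c(sprintf("SET%d", i), "synthetic gene set", sets[[i]]),
            collapse = "\t"), character(1)), gmtp)
  })
  paths <- c(paths, abp, pairp, gmtp)
  invisible(paths)
}
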