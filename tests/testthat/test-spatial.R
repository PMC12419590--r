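write_mtx_triplet <- function(dir, counts_gene_by_spot, genes, barcodes,
                              positions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts_gene_by_spot, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(genes, genes, "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(positions))
    utils::write.table(positions, file.path(dir, "tissue_positions.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  dir
}

test_that("load_visium reads an MTX triplet and normalizes orientation", {
  m <- matrix(c(0, 1, 2, 0, 3,
                4, 0, 0, 1, 0,
                0, 0, 5, 0, 6,
                7, 0, 0, 0, 0), nrow = 5, ncol = 4) # gene x spot on disk
  dir <- write_mtx_triplet(tempfile(), m, sprintf("G%d", 1:5),
                           sprintf("BC%d", 1:4))
  expect_warning(sd <- load_visium(dir), "position")
  expect_equal(dim(sd$counts), c(4, 5))
  expect_identical(sd$barcodes, sprintf("BC%d", 1:4))
  expect_identical(sd$gene_ids, sprintf("G%d", 1:5))
  expect_equal(as.matrix(sd$counts), t(m), ignore_attr = TRUE)
})

test_that("duplicate gene symbols are summed at load", {
  # two rows for the same symbol, [1,2] and [3,0], collapse to [4,2]
  m <- matrix(c(1, 2,
                3, 0), nrow = 2, byrow = TRUE) # genes x 2 spots
  dir <- write_mtx_triplet(tempfile(), m, c("DUP", "DUP"), c("BC1", "BC2"))
  suppressWarnings(sd <- load_visium(dir))
  expect_identical(sd$gene_ids, "DUP")
  expect_equal(as.numeric(sd$counts[, 1]), c(4, 2))
})

test_that("load_visium rejects dimension mismatches", {
  m <- matrix(1, 3, 2)
  dir <- write_mtx_triplet(tempfile(), m, sprintf("G%d", 1:3),
                           c("BC1", "BC2", "BC3")) # 3 barcodes vs 2 cols
  expect_error(load_visium(dir), "features/barcodes")
  expect_error(load_visium(tempfile()), "MTX triplet")
})

test_that("fixture-suite MTX round-trips through load_visium", {
  out <- tempfile()
  make_fixture_suite(out, seed = 3, n_genes = 30, n_mirnas = 5,
                     n_samples = 20, n_spots = 16)
  sd <- load_visium(file.path(out, "visium"))
  expect_equal(dim(sd$counts), c(16, 30))
  expect_false(is.null(sd$coords))
  expect_identical(sd$coords$barcode, sd$barcodes)
})

test_that("qc_filter applies the count ceiling and detection floor", {
  set.seed(30)
  counts <- matrix(rpois(10 * 6, 20), 10, 6)
  sd <- sd_from_counts(counts)
  out <- qc_filter(sd, max_total_counts = 38000, min_cells_per_gene = NULL)
  expect_equal(nrow(out$counts), 10) # nobody above 38000 yet
  counts[2, 1] <- 39000; counts[7, 1] <- 39000
  out2 <- qc_filter(sd_from_counts(counts), max_total_counts = 38000,
                    min_cells_per_gene = NULL)
  expect_equal(nrow(out2$counts), 8)
  rep <- attr(out2, "qc_report")
  expect_equal(rep$spots_over_max_counts, 2)
  expect_equal(rep$input_spots - rep$output_spots, 2)

  # gene detected in 9 of 200 spots removed, 10 of 200 kept
  big <- matrix(0, 200, 3)
  big[, 1] <- 5
  big[1:9, 2] <- 1
  big[1:10, 3] <- 1
  outg <- qc_filter(sd_from_counts(big), min_cells_per_gene = 10)
  expect_identical(outg$gene_ids, c("G001", "G003"))

  # disabled thresholds are the identity
  ident <- qc_filter(sd, min_cells_per_gene = NULL)
  expect_equal(dim(ident$counts), dim(sd$counts))
  expect_error(qc_filter(sd_from_counts(matrix(50, 4, 2)),
                         max_total_counts = 10,
                         min_cells_per_gene = NULL),
               "eliminated all spots")
})

test_that("qc report removal counts reconcile with dimensions", {
  set.seed(31)
  counts <- matrix(rpois(50 * 20, 3), 50, 20)
  counts[1:3, ] <- 0 # zero spots
  sd <- sd_from_counts(counts)
  out <- qc_filter(sd, min_counts_per_spot = 1, min_cells_per_gene = 5)
  rep <- attr(out, "qc_report")
  expect_equal(rep$input_spots - rep$output_spots,
               rep$spots_under_min_counts)
  expect_equal(rep$input_genes - rep$output_genes,
               rep$genes_under_min_cells)
})

test_that("normalize_st rescales to the target total then log10", {
  sd <- sd_from_counts(rbind(c(1, 3)))
  m <- normalize_st(sd, target_sum = 4)
  expect_equal(unname(m$values[, 1]), c(log10(2), log10(4)))
  expect_identical(m$stage, "log")

  # proportional spots give identical normalized vectors
  sd2 <- sd_from_counts(rbind(c(2, 6, 2), c(6, 18, 6)))
  m2 <- normalize_st(sd2)
  expect_equal(m2$values[, 1], m2$values[, 2])

  # conservation: per-spot total equals target before the log
  set.seed(32)
  counts <- matrix(rpois(20 * 15, 8) + 1, 20, 15)
  m3 <- normalize_st(sd_from_counts(counts), target_sum = 1e4)
  totals <- colSums(10^m3$values - 1)
  expect_true(all(abs(totals - 1e4) < 1e-9 * 1e4))

  sdz <- sd_from_counts(rbind(c(0, 0), c(1, 2)))
  expect_error(normalize_st(sdz), "zero-count spot")
})

test_that("select_hvg ranks genes by log-expression variance", {
  set.seed(33)
  sds <- c(3, 2, 1, 0.5, 0)
  v <- t(vapply(sds, function(s) rnorm(12, sd = s), numeric(12)))
  v[5, ] <- 1 # constant gene
  m <- em(v, stage = "log")
  hv <- select_hvg(m, n = 2000)
  expect_equal(length(hv), 5) # clamp to available genes
  expect_identical(hv[5], "G005") # constant gene ranks last
  vars <- apply(m$values, 1, var)
  oracle <- rownames(m$values)[order(-vars, rownames(m$values))]
  expect_identical(hv, oracle)
  expect_identical(select_hvg(m, 2), oracle[1:2])
})

test_that("prepare_features_for_model restricts, orders, and bounds", {
  ts <- make_ts(n = 30, p = 4, q = 1, seed = 34)
  model <- train_model(ts, hyperparams(n_estimators = 5), seed = 1)
  set.seed(35)
  v <- matrix(abs(rnorm(6 * 25)), 6, 25,
              dimnames = list(c("G003", "G001", "EXTRA1", "G004", "G002",
                                "EXTRA2"),
                              sprintf("SP%02d", 1:25)))
  m <- ExprMatrix(v, "mRNA", "ST", "log")
  X <- prepare_features_for_model(m, model)
  expect_identical(colnames(X), model$feature_genes)
  expect_equal(nrow(X), 25)
  expect_true(all(X >= 0 & X <= 1))

  # shuffling gene rows changes nothing
  perm <- sample(6)
  m2 <- ExprMatrix(v[perm, ], "mRNA", "ST", "log")
  expect_equal(prepare_features_for_model(m2, model), X)

  m3 <- ExprMatrix(v[-1, ], "mRNA", "ST", "log")
  expect_error(prepare_features_for_model(m3, model),
               "G003.*feature_restrict")
})

test_that("encoded features stay in [0,1] across random inputs", {
  ts <- make_ts(n = 30, p = 5, q = 1, seed = 36)
  model <- train_model(ts, hyperparams(n_estimators = 5), seed = 1)
  set.seed(37)
  for (i in 1:100) {
    v <- matrix(exp(rnorm(5 * 8, sd = 2)), 5, 8,
                dimnames = list(sprintf("G%03d", 1:5), sprintf("s%d", 1:8)))
    m <- ExprMatrix(v, "mRNA", "ST", "log")
    X <- suppressWarnings(prepare_features_for_model(m, model))
    expect_true(all(X >= 0 & X <= 1))
  }
})

test_that("predict_spot_activity maps spots row-wise", {
  truth <- make_regulatory_truth(40, 6, seed = 40)
  a <- generate_bulk_cohort(truth, 30, cohort_label = "A", seed = 41)
  b <- generate_bulk_cohort(truth, 30, cohort_label = "B", seed = 42)
  ts <- run_integration(a$mrna, a$mirna, b$mrna, b$mirna)
  model <- train_model(ts, hyperparams(n_estimators = 20), seed = 4)
  st <- generate_spatial_tissue(truth, n_spots = 50, depth_mean = 2000,
                                seed = 43)
  m <- normalize_st(st$spots)
  act <- predict_spot_activity(model, m)
  expect_s3_class(act, "ActivityMatrix")
  expect_equal(dim(act$values), c(50, 6))
  expect_true(all(act$values >= 0 & act$values <= 1))

  # duplicated spots yield duplicated activity rows
  counts2 <- rbind(st$spots$counts, st$spots$counts[1, , drop = FALSE])
  rownames(counts2) <- c(st$spots$barcodes, "SPOTDUP")
  m2 <- normalize_st(stmir:::new_spot_dataset(counts2))
  act2 <- predict_spot_activity(model, m2)
  expect_equal(unname(act2$values["SPOTDUP", ]),
               unname(act2$values[st$spots$barcodes[1], ]))

  # end-to-end invariance to gene and spot input order
  perm_g <- sample(ncol(st$spots$counts))
  perm_s <- sample(nrow(st$spots$counts))
  counts3 <- st$spots$counts[perm_s, perm_g]
  m3 <- normalize_st(stmir:::new_spot_dataset(counts3))
  act3 <- predict_spot_activity(model, m3)
  expect_equal(act3$values[act$barcodes, ], act$values)
})

test_that("spot predictions recover planted activity at generator defaults", {
  # bulk-trained model transferred to synthetic tissue: median rank
  # correlation with the planted per-spot activity must reach 0.6
  truth <- make_regulatory_truth(300, 30, seed = 7)
  a <- generate_bulk_cohort(truth, 250, cohort_label = "A", seed = 8)
  b <- generate_bulk_cohort(truth, 250, cohort_label = "B",
                            batch_distortion = "affine-power", seed = 9)
  ts <- run_integration(a$mrna, a$mirna, b$mrna, b$mirna)
  model <- train_model(ts, hyperparams(0.1, 3, 200), seed = 7)
  st <- generate_spatial_tissue(truth, n_spots = 200, seed = 10)
  sdq <- qc_filter(st$spots, max_total_counts = 38000,
                   min_cells_per_gene = 10)
  act <- predict_spot_activity(model, normalize_st(sdq))
  rho <- vapply(colnames(act$values), function(j)
    spearman_rho(act$values[, j], st$activity_true[act$barcodes, j]),
    numeric(1))
  expect_gte(median(rho), 0.6)
})

test_that("activity TSV round-trips", {
  a <- am(matrix(runif(12), 4, 3))
  p <- tempfile(fileext = ".tsv")
  write_activity(a, p)
  b <- read_activity(p)
  expect_equal(b$values, a$values, tolerance = 1e-12)
})
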