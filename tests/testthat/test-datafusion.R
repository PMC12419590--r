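test_that("harmonize_mirna_names strips arm suffixes and collapses by median", {
  m <- em(rbind(c(2, 6), c(4, 2)), modality = "miRNA",
          features = c("hsa-miR-21-3p", "hsa-miR-21-5p"))
  out <- harmonize_mirna_names(m)
  expect_identical(rownames(out$values), "hsa-mir-21")
  expect_equal(unname(out$values[1, ]), c(3, 4))

  single <- em(rbind(c(1, 1)), modality = "miRNA", features = "hsa-let-7a")
  out2 <- harmonize_mirna_names(single)
  expect_identical(rownames(out2$values), "hsa-let-7a")
  expect_equal(unname(out2$values[1, ]), c(1, 1))

  empty <- em(matrix(1, 1, 2), modality = "miRNA")
  empty$values <- empty$values[0, , drop = FALSE]
  expect_error(harmonize_mirna_names(empty), "no miRNA features")
})

test_that("harmonize collapse matches a brute-force median oracle", {
  set.seed(11)
  vals <- matrix(runif(5 * 4), 5, 4)
  m <- em(vals, modality = "miRNA",
          features = c("hsa-miR-9-5p", "hsa-miR-9-3p", "hsa-miR-9",
                       "hsa-miR-10a", "HSA-MIR-10A"))
  out <- harmonize_mirna_names(m)
  expect_identical(rownames(out$values), c("hsa-mir-9", "hsa-mir-10a"))
  expect_equal(unname(out$values["hsa-mir-9", ]),
               apply(vals[1:3, ], 2, median))
  expect_equal(unname(out$values["hsa-mir-10a", ]),
               apply(vals[4:5, ], 2, median))
})

test_that("filter_common_features applies either-cohort zero-fraction rule", {
  a <- em(matrix(1, 3, 20), features = c("G1", "G2", "G3"))
  b <- em(matrix(1, 3, 20), features = c("G1", "G2", "G3"))
  out <- filter_common_features(a, b)
  expect_identical(feature_sorted <- rownames(out$a$values), c("G1", "G2", "G3"))
  expect_identical(rownames(out$b$values), rownames(out$a$values))

  # zero in 19/20 (95% > 90%) dropped from both; 17/20 (85%) kept
  va <- matrix(1, 2, 20, dimnames = list(c("G1", "G2"), sprintf("S%d", 1:20)))
  va["G1", 1:19] <- 0
  va["G2", 1:17] <- 0
  a2 <- ExprMatrix(va, "mRNA", "a", "raw")
  out2 <- filter_common_features(a2, b <- em(matrix(1, 2, 20),
                                             features = c("G1", "G2")))
  expect_identical(rownames(out2$a$values), "G2")
  expect_identical(rownames(out2$b$values), "G2")

  expect_error(filter_common_features(
    em(matrix(1, 1, 2), features = "GX"),
    em(matrix(1, 1, 2), features = "GY")), "no shared features")
})

test_that("filter_common_features agrees with a brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    va <- matrix(rbinom(10 * 8, 1, 0.4) * runif(80), 10, 8,
                 dimnames = list(sprintf("G%02d", sample(1:14, 10)),
                                 sprintf("A%d", 1:8)))
    vb <- matrix(rbinom(12 * 8, 1, 0.4) * runif(96), 12, 8,
                 dimnames = list(sprintf("G%02d", sample(1:14, 12)),
                                 sprintf("B%d", 1:8)))
    frac <- 0.5
    shared <- intersect(rownames(va), rownames(vb))
    ok <- length(shared) > 0
    expected <- character(0)
    for (g in sort(shared)) {
      za <- mean(va[g, ] == 0); zb <- mean(vb[g, ] == 0)
      if (za <= frac && zb <= frac) expected <- c(expected, g)
    }
    if (!ok || length(expected) == 0) next
    out <- filter_common_features(ExprMatrix(va, "mRNA", "a"),
                                  ExprMatrix(vb, "mRNA", "b"), frac)
    expect_identical(rownames(out$a$values), expected)
  }
})

test_that("log_transform computes log(x+1) and rejects bad input", {
  m <- em(rbind(c(0, 3), c(99, 1)))
  out2 <- log_transform(m, base = 2)
  expect_equal(out2$values[1, 1], 0)
  expect_equal(out2$values[1, 2], 2)
  expect_equal(log_transform(m, base = 10)$values[2, 1], 2)
  expect_identical(out2$stage, "log")

  bad <- em(rbind(c(1, -2)))
  expect_error(log_transform(bad), "G001.*S002")
  expect_error(log_transform(out2), "stage")
})

test_that("intra-sample percentile rank follows r/(n+1) with average ties", {
  m <- em(matrix(c(5, 1, 3), 3, 1), stage = "log")
  expect_equal(unname(intra_sample_percentile_rank(m)$values[, 1]),
               c(0.75, 0.25, 0.5))
  tied <- em(matrix(c(2, 2, 2), 3, 1), stage = "log")
  expect_equal(unname(intra_sample_percentile_rank(tied)$values[, 1]),
               rep(0.5, 3))
  expect_error(intra_sample_percentile_rank(
    em(matrix(1, 1, 3), stage = "log")), "n=1")
})

test_that("percentile ranks are invariant to monotone column transforms", {
  set.seed(31)
  v <- matrix(rnorm(50), 10, 5)
  m1 <- em(v, stage = "log")
  m2 <- em(exp(v) * 10, stage = "log")
  expect_equal(intra_sample_percentile_rank(m1)$values,
               intra_sample_percentile_rank(m2)$values)
})

test_that("inverse normal transform maps ranks through qnorm", {
  set.seed(41)
  # tie-free percentile-stage matrix (INT re-ranks rows itself)
  m <- em(matrix(runif(9 * 5), 9, 5), stage = "percentile")
  z <- inverse_normal_transform(m)
  expect_identical(z$stage, "z")
  # median of a row maps to 0 for odd n
  for (i in seq_len(nrow(z$values))) {
    med_pos <- which(rank(m$values[i, ]) == 3) # median of 5 samples
    expect_equal(unname(z$values[i, med_pos]), 0)
  }
  # antisymmetry: sorted z values are symmetric about 0 (tie-free)
  for (i in seq_len(nrow(z$values))) {
    s <- sort(z$values[i, ])
    expect_equal(s, -rev(s), ignore_attr = TRUE)
  }
  # the quantile map itself
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
  expect_error(inverse_normal_transform(
    em(matrix(0.5, 2, 1), stage = "log")), "stage")
})

test_that("post-INT rows have mean ~0 and closed-form sd", {
  set.seed(51)
  n <- 80
  m <- em(matrix(runif(20 * n), 20, n), stage = "percentile") # tie-free
  z <- inverse_normal_transform(m)
  expect_true(all(abs(rowMeans(z$values)) < 1e-9))
  closed_form_sd <- sd(qnorm((1:n) / (n + 1)))
  sds <- apply(z$values, 1, sd)
  expect_true(all(abs(sds / closed_form_sd - 1) < 0.05))
})

test_that("integrate_cohorts concatenates columns and validates", {
  set.seed(61)
  mk <- function(ns, cohort, prefix) {
    m <- em(matrix(rnorm(4 * ns), 4, ns), cohort = cohort, stage = "log",
            samples = sprintf("%s%02d", prefix, seq_len(ns)))
    inverse_normal_transform(intra_sample_percentile_rank(m))
  }
  a <- mk(3, "A", "a"); b <- mk(2, "B", "b")
  out <- integrate_cohorts(a, b)
  expect_equal(ncol(out$values), 5)
  expect_identical(rownames(out$values), rownames(a$values))
  expect_identical(out$sample_cohort, c(rep("A", 3), rep("B", 2)))

  b_re <- b
  rownames(b_re$values) <- rev(rownames(b_re$values))
  expect_error(integrate_cohorts(a, b_re), "feature order")
  expect_error(integrate_cohorts(a, a), "duplicate sample_id")

  # self-integration under renamed samples duplicates each value multiset
  a2 <- a
  colnames(a2$values) <- paste0("dup_", colnames(a2$values))
  both <- integrate_cohorts(a, a2)
  for (i in seq_len(nrow(both$values)))
    expect_equal(sort(both$values[i, ]), sort(rep(a$values[i, ], 2)),
                 ignore_attr = TRUE)
})

test_that("minmax_scale maps endpoints, constants, and inverts", {
  m <- em(rbind(c(-1, 0, 3)), stage = "raw")
  out <- minmax_scale(m)
  expect_equal(unname(out$matrix$values[1, ]), c(0, 0.25, 1))
  expect_identical(out$matrix$stage, "scaled01")

  expect_warning(cm <- minmax_scale(em(rbind(c(2, 2)), stage = "raw")),
                 "constant")
  expect_equal(unname(cm$matrix$values[1, ]), c(0, 0))

  set.seed(71)
  v <- matrix(rnorm(40), 8, 5)
  m2 <- em(v, stage = "raw")
  sc <- minmax_scale(m2)
  undone <- sc$matrix$values * (sc$params$max - sc$params$min) + sc$params$min
  expect_equal(unname(undone), unname(v), tolerance = 1e-12)

  expect_error(minmax_scale(em(matrix(1:4, 2, 2), stage = "raw"),
                            params = list(min = c(ZZZ = 0), max = c(ZZZ = 1))),
               "absent")
  # external params clip out-of-range values into [0,1]
  p <- list(min = c(G001 = 0), max = c(G001 = 1))
  clipped <- minmax_scale(em(rbind(c(-0.5, 2)), stage = "raw"), params = p)
  expect_equal(unname(clipped$matrix$values[1, ]), c(0, 1))
})

test_that("build_training_set aligns samples and restricts features", {
  set.seed(81)
  x <- em(matrix(runif(4 * 6), 4, 6), stage = "raw",
          samples = sprintf("S%d", 1:6))
  y <- em(matrix(runif(2 * 7), 2, 7), modality = "miRNA", stage = "raw",
          samples = sprintf("S%d", 2:8))
  sx <- minmax_scale(x)$matrix; sy <- minmax_scale(y)$matrix
  expect_error(build_training_set(sx, sy), "insufficient paired samples")

  x2 <- em(matrix(runif(4 * 12), 4, 12), stage = "raw",
           samples = sprintf("S%d", 1:12))
  y2 <- em(matrix(runif(2 * 12), 2, 12), modality = "miRNA", stage = "raw",
           samples = sprintf("S%d", 1:12))
  sx2 <- minmax_scale(x2)$matrix; sy2 <- minmax_scale(y2)$matrix
  ts <- build_training_set(sx2, sy2)
  expect_equal(nrow(ts$X), 12)
  expect_identical(rownames(ts$X), rownames(ts$Y))

  expect_warning(
    ts2 <- build_training_set(sx2, sy2,
                              feature_restrict = c("G001", "G003", "GZZZ")),
    "GZZZ")
  expect_identical(colnames(ts2$X), c("G001", "G003"))
})

test_that("training-set assembly is invariant to input column order", {
  set.seed(91)
  x <- em(matrix(runif(5 * 15), 5, 15), stage = "raw")
  y <- em(matrix(runif(3 * 15), 3, 15), modality = "miRNA", stage = "raw")
  sx <- minmax_scale(x)$matrix; sy <- minmax_scale(y)$matrix
  perm <- sample(15)
  sy_perm <- sy
  sy_perm$values <- sy_perm$values[, perm]
  sy_perm$sample_cohort <- sy_perm$sample_cohort[perm]
  expect_equal(build_training_set(sx, sy), build_training_set(sx, sy_perm))
})

test_that("full rank pipeline removes per-sample monotone distortions", {
  truth <- make_regulatory_truth(40, 6, seed = 5)
  a <- generate_bulk_cohort(truth, 25, cohort_label = "A", seed = 6)
  b <- generate_bulk_cohort(truth, 25, cohort_label = "B", seed = 7)
  bd <- generate_bulk_cohort(truth, 25, cohort_label = "B",
                             batch_distortion = "affine-power", seed = 7)
  ts_plain <- run_integration(a$mrna, a$mirna, b$mrna, b$mirna)
  ts_dist <- run_integration(a$mrna, a$mirna, bd$mrna, bd$mirna)
  expect_identical(ts_plain$X, ts_dist$X)
  expect_identical(ts_plain$Y, ts_dist$Y)
})

test_that("stage bookkeeping rejects out-of-order operations", {
  m <- em(matrix(1:6, 3, 2))
  expect_error(intra_sample_percentile_rank(m), "stage")
  expect_error(inverse_normal_transform(m), "stage")
  logm <- log_transform(m)
  expect_error(log_transform(logm), "stage")
})
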