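#' Build or read a pipeline run configuration
#'
#' A `RunConfig` collects all file paths and thresholds of the
#' integrate -> train -> predict -> attribute chain. Every threshold
#' defaults to its published value: zero-fraction filter 0.9, spot-count
#' ceiling 38000, gene detection floor 10, 2000 highly variable genes,
#' correlation threshold 0.3 with alpha 0.05, FDR 0.1, conservation top-40.
#' The configuration is serialized next to every output for provenance.
#'
#' `read_run_config()` reads a flat declarative `key: value` text file
#' (Debian-control layout, one field per line); unknown keys are an error.
#'
#' @param ... named overrides of the defaults listed above plus the input
#'   paths `mrna_a`, `mirna_a`, `mrna_b`, `mirna_b`, `visium_dir`,
#'   `abundance`, `pairs`, `gmt`, and `out_dir`, `seed`, `learning_rate`,
#'   `max_depth`, `n_estimators`, `hvg_n`, `min_purity`, `min_spots`,
#'   `st_encoding`, `diff_group_type`.
#' @return a `RunConfig` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    mrna_a = NULL, mirna_a = NULL, mrna_b = NULL, mirna_b = NULL,
    visium_dir = NULL, abundance = NULL, pairs = NULL, gmt = NULL,
    out_dir = "stmir_out", seed = 1L,
    max_zero_frac = 0.9, max_total_counts = 38000,
    min_cells_per_gene = 10L, hvg_n = 2000L,
    min_purity = 0, min_spots = 10L,
    r_min = 0.3, alpha = 0.05, fdr = 0.1, top_k = 40L,
    learning_rate = 0.1, max_depth = 3L, n_estimators = 200L,
    st_encoding = "rank-int", diff_group_type = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "RunConfig")
}

#' @param path path to a `key: value` config file.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  dcf <- read.dcf(path)
  vals <- as.list(dcf[1, ])
  numeric_keys <- c("seed", "max_zero_frac", "max_total_counts",
                    "min_cells_per_gene", "hvg_n", "min_purity",
                    "min_spots", "r_min", "alpha", "fdr", "top_k",
                    "learning_rate", "max_depth", "n_estimators")
  for (k in intersect(names(vals), numeric_keys))
    vals[[k]] <- as.numeric(vals[[k]])
  do.call(run_config, vals)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

# run `fun()` or reuse the cached result keyed by this stage's config hash
stage_cached <- function(name, key, cache_dir, fun, log) {
  hash <- config_hash(key)
  path <- file.path(cache_dir, sprintf("%s-%s.rds", name, hash))
  if (file.exists(path)) {
    log(sprintf("stage %-10s cache hit (%s)", name, substr(hash, 1, 8)))
    return(list(value = readRDS(path), hash = hash, cached = TRUE))
  }
  log(sprintf("stage %-10s running   (%s)", name, substr(hash, 1, 8)))
  value <- tryCatch(fun(), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  saveRDS(value, path)
  list(value = value, hash = hash, cached = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Executes, in order: spatial QC and normalization, two-cohort bulk
#' integration restricted to the spatial highly variable genes, per-miRNA
#' model training, spot activity prediction, dominant-cell-type
#' attribution, and (when the config provides the inputs) differential
#' activity, miRNA-target correlation and gene-set enrichment. Stage
#' results are cached under `out_dir/cache` keyed by the hash of the stage
#' config plus its upstream hashes, so an unchanged rerun reuses them and a
#' threshold change invalidates exactly the downstream stages.
#'
#' @param cfg a `RunConfig` from [run_config()] or [read_run_config()].
#' @param quiet suppress progress logging (default FALSE).
#' @return the run report (also written to `out_dir/run_report.json`):
#'   stages with hashes and cache status, output paths, the full config,
#'   and the package version.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  needed <- c("mrna_a", "mirna_a", "mrna_b", "mirna_b", "visium_dir",
              "abundance")
  missing <- needed[vapply(cfg[needed], is.null, TRUE)]
  if (length(missing) > 0)
    stop("config is missing required input(s): ",
         paste(missing, collapse = ", "))
  dir.create(file.path(cfg$out_dir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  cache_dir <- file.path(cfg$out_dir, "cache")
  log <- if (quiet) function(...) invisible() else
    function(msg) message("[stmir] ", msg)
  stages <- list()
  version <- as.character(utils::packageVersion("stmir"))

  sp_key <- list(v = version, visium = cfg$visium_dir,
                 max_total_counts = cfg$max_total_counts,
                 min_cells_per_gene = cfg$min_cells_per_gene,
                 hvg_n = cfg$hvg_n)
  sp <- stage_cached("spatial_qc", sp_key, cache_dir, function() {
    sd <- load_visium(cfg$visium_dir)
    sd <- qc_filter(sd, max_total_counts = cfg$max_total_counts,
                    min_cells_per_gene = cfg$min_cells_per_gene)
    m <- normalize_st(sd)
    list(expr = m, hvg = select_hvg(m, cfg$hvg_n),
         qc_report = attr(sd, "qc_report"))
  }, log)
  stages$spatial_qc <- sp

  int_key <- list(v = version, up = sp$hash,
                  inputs = cfg[c("mrna_a", "mirna_a", "mrna_b", "mirna_b")],
                  max_zero_frac = cfg$max_zero_frac)
  int <- stage_cached("integrate", int_key, cache_dir, function() {
    run_integration(
      read_expr_matrix(cfg$mrna_a, "mRNA", "cohortA"),
      read_expr_matrix(cfg$mirna_a, "miRNA", "cohortA"),
      read_expr_matrix(cfg$mrna_b, "mRNA", "cohortB"),
      read_expr_matrix(cfg$mirna_b, "miRNA", "cohortB"),
      max_zero_frac = cfg$max_zero_frac,
      feature_restrict = sp$value$hvg)
  }, log)
  stages$integrate <- int

  tr_key <- list(v = version, up = int$hash, seed = cfg$seed,
                 hp = cfg[c("learning_rate", "max_depth", "n_estimators")])
  tr <- stage_cached("train", tr_key, cache_dir, function() {
    train_model(int$value,
                hyperparams(cfg$learning_rate, cfg$max_depth,
                            cfg$n_estimators),
                seed = as.integer(cfg$seed))
  }, log)
  stages$train <- tr

  pr_key <- list(v = version, up = c(sp$hash, tr$hash),
                 encoding = cfg$st_encoding)
  pr <- stage_cached("predict", pr_key, cache_dir, function() {
    predict_spot_activity(tr$value, sp$value$expr,
                          encoding = cfg$st_encoding)
  }, log)
  stages$predict <- pr

  at_key <- list(v = version, up = pr$hash, abundance = cfg$abundance,
                 min_purity = cfg$min_purity, min_spots = cfg$min_spots,
                 top_k = cfg$top_k)
  at <- stage_cached("attribute", at_key, cache_dir, function() {
    ab <- read_abundance(cfg$abundance)
    da <- assign_dominant(ab, min_purity = cfg$min_purity)
    prof <- celltype_mirna_profile(pr$value, da,
                                   min_spots = cfg$min_spots)
    list(assignment = da, profile = prof,
         ranking = rank_mirnas_per_context(pr$value))
  }, log)
  stages$attribute <- at

  outputs <- list()
  model_path <- file.path(cfg$out_dir, "model.stmir")
  save_model(tr$value, model_path)
  outputs$model <- model_path
  act_path <- file.path(cfg$out_dir, "activity.tsv")
  write_activity(pr$value, act_path)
  outputs$activity <- act_path
  assign_path <- file.path(cfg$out_dir, "dominant_assignment.tsv")
  utils::write.table(at$value$assignment, assign_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outputs$assignment <- assign_path
  prof_path <- file.path(cfg$out_dir, "celltype_profiles.tsv")
  utils::write.table(at$value$profile, prof_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outputs$profiles <- prof_path

  if (!is.null(cfg$diff_group_type)) {
    da <- at$value$assignment
    keep <- da$dominant_type != "UNASSIGNED"
    labels <- ifelse(da$dominant_type[keep] == cfg$diff_group_type,
                     cfg$diff_group_type, "other")
    act_sub <- new_activity_matrix(
      pr$value$values[da$barcode[keep], , drop = FALSE],
      model_id = pr$value$model_id)
    diff <- differential_activity(act_sub, labels)
    diff_path <- file.path(cfg$out_dir, "differential_activity.tsv")
    utils::write.table(diff, diff_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs$differential <- diff_path
  }
  if (!is.null(cfg$pairs)) {
    pairs <- read_target_pairs(cfg$pairs)
    pairs <- pairs[pairs$mirna %in% pr$value$mirna_ids &
                     pairs$gene %in% feature_ids(sp$value$expr), ,
                   drop = FALSE]
    if (nrow(pairs) > 0) {
      corr <- mirna_target_correlation(
        pr$value, t(sp$value$expr$values), pairs,
        r_min = cfg$r_min, alpha = cfg$alpha)
      corr_path <- file.path(cfg$out_dir, "target_correlation.tsv")
      utils::write.table(corr, corr_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs$correlation <- corr_path
      if (!is.null(cfg$gmt)) {
        sig <- unique(corr$gene[corr$classification != "not_significant"])
        if (length(sig) > 0) {
          enr <- enrich(sig, read_gmt(cfg$gmt),
                        universe = feature_ids(sp$value$expr))
          enr_path <- file.path(cfg$out_dir, "enrichment.tsv")
          utils::write.table(enr, enr_path, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          outputs$enrichment <- enr_path
        }
      }
    }
  }

  report <- list(
    package = "stmir", version = version,
    stages = lapply(stages, function(s)
      list(hash = s$hash, cached = s$cached)),
    qc_report = sp$value$qc_report,
    outputs = outputs,
    config = cfg[!vapply(cfg, is.null, TRUE)])
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
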