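#' Hyperparameters for the boosted-tree regressor
#'
#' @param learning_rate shrinkage applied to each tree's contribution
#'   (default 0.1).
#' @param max_depth maximum tree depth (default 3).
#' @param n_estimators number of boosting rounds (default 200).
#' @param ... extra engine parameters (`min_split`, `min_leaf`, `lambda`,
#'   `subsample`).
#' @return a `Hyperparams` list.
#' @export
hyperparams <- function(learning_rate = 0.1, max_depth = 3L,
                        n_estimators = 200L, ...) {
  stopifnot(learning_rate > 0, max_depth >= 1, n_estimators >= 1)
  structure(list(learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 extras = list(...)),
            class = "Hyperparams")
}

#' The default hyperparameter search grid
#'
#' Learning rate \{0.05, 0.1, 0.3\} x tree depth \{3, 5, 7\} x number of
#' boosting rounds \{100, 300, 500\}.
#'
#' @return a list of [hyperparams()] objects (27 grid points).
#' @export
default_grid <- function() {
  grid <- expand.grid(learning_rate = c(0.05, 0.1, 0.3),
                      max_depth = c(3L, 5L, 7L),
                      n_estimators = c(100L, 300L, 500L))
  lapply(seq_len(nrow(grid)), function(i)
    hyperparams(grid$learning_rate[i], grid$max_depth[i], grid$n_estimators[i]))
}

#' Train one boosted-tree regressor per miRNA target
#'
#' Fits an independent gradient-boosted tree ensemble to each miRNA column
#' of the training set, using the scaled mRNA matrix as features. Constant
#' target columns are still fitted (the ensemble reduces to a constant) but
#' flagged as degenerate in the training metadata.
#'
#' @param ts a `TrainingSet` from [build_training_set()].
#' @param hp a [hyperparams()] object.
#' @param seed integer seed; training is fully deterministic given the seed.
#' @return a `ModelBundle` with one fitted regressor per miRNA, the frozen
#'   feature gene list, the hyperparameters, the min-max scaler parameters
#'   and training metadata.
#' @export
train_model <- function(ts, hp = hyperparams(), seed = 1L) {
  stopifnot(inherits(ts, "TrainingSet"), inherits(hp, "Hyperparams"))
  ex <- hp$extras
  degenerate <- character(0)
  models <- vector("list", length(ts$target_mirnas))
  names(models) <- ts$target_mirnas
  for (j in seq_along(ts$target_mirnas)) {
    y <- ts$Y[, j]
    if (stats::var(y) == 0) degenerate <- c(degenerate, ts$target_mirnas[j])
    models[[j]] <- gbt_fit(
      ts$X, y,
      learning_rate = hp$learning_rate, max_depth = hp$max_depth,
      n_estimators = hp$n_estimators,
      min_split = ex$min_split %||% 10L,
      min_leaf = ex$min_leaf %||% 5L,
      lambda = ex$lambda %||% 1.0,
      subsample = ex$subsample %||% 1.0,
      seed = seed + j)
  }
  structure(
    list(per_target_models = models,
         feature_genes = colnames(ts$X),
         target_mirnas = ts$target_mirnas,
         hyperparams = hp,
         scaler_params = ts$scaler_params,
         training_meta = list(
           cohorts = unique(unname(ts$cohort_of_sample)),
           n_samples = nrow(ts$X),
           seed = seed,
           degenerate_targets = degenerate,
           version = as.character(utils::packageVersion("stmir")),
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "ModelBundle")
}

#' @export
print.ModelBundle <- function(x, ...) {
  cat(sprintf(
    "ModelBundle: %d miRNA regressors on %d feature genes (lr=%g, depth=%d, trees=%d)\n",
    length(x$target_mirnas), length(x$feature_genes),
    x$hyperparams$learning_rate, x$hyperparams$max_depth,
    x$hyperparams$n_estimators))
  invisible(x)
}

#' Predict miRNA activity for new samples
#'
#' @param object a `ModelBundle`.
#' @param newdata numeric sample x gene matrix on the \[0,1\] training scale;
#'   its columns must match the bundle's `feature_genes` exactly, in order.
#'   No silent reordering or imputation is performed.
#' @param ... unused.
#' @return sample x miRNA matrix of predicted activities, clipped to \[0,1\].
#' @export
predict.ModelBundle <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!identical(colnames(newdata), object$feature_genes)) {
    nd <- colnames(newdata) %||% character(0)
    bad <- c(setdiff(object$feature_genes, nd), setdiff(nd, object$feature_genes))
    if (length(bad) == 0) bad <- "(same set, different order)"
    stop(sprintf("feature mismatch between newdata and model: %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  out <- vapply(object$per_target_models,
                function(m) predict(m, newdata), numeric(nrow(newdata)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(newdata),
                                       dimnames = list(NULL, object$target_mirnas))
  rownames(out) <- rownames(newdata)
  pmin(pmax(out, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman rank correlation
#'
#' Average-tie ranks followed by Pearson correlation. Returns `NA` when
#' either vector is constant.
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Prediction-accuracy metrics
#'
#' Computes per-miRNA Spearman's rho down each column (across samples), and
#' global MSE, MAE and R-squared over all entries; R-squared is
#' 1 - SS_res/SS_tot with SS_tot taken about the observed grand mean.
#' Columns with constant observed values have undefined rho and are reported
#' as `NA` and excluded from (but counted against) the rho summary.
#'
#' @param pred,obs numeric matrices of identical shape and dimnames order.
#' @return a `MetricsReport` list with `per_mirna_spearman`, `mse`, `mae`,
#'   `r2`, `median_spearman`, `n_undefined_spearman`.
#' @export
evaluate_predictions <- function(pred, obs) {
  stopifnot(is.matrix(pred), is.matrix(obs), identical(dim(pred), dim(obs)))
  if (!is.null(colnames(pred)) && !is.null(colnames(obs)))
    stopifnot(identical(colnames(pred), colnames(obs)))
  rho <- vapply(seq_len(ncol(obs)),
                function(j) spearman_rho(pred[, j], obs[, j]), numeric(1))
  names(rho) <- colnames(obs)
  err <- pred - obs
  ss_tot <- sum((obs - mean(obs))^2)
  structure(
    list(per_mirna_spearman = rho,
         mse = mean(err^2),
         mae = mean(abs(err)),
         r2 = 1 - sum(err^2) / ss_tot,
         median_spearman = median(rho, na.rm = TRUE),
         n_undefined_spearman = sum(is.na(rho))),
    class = "MetricsReport")
}

make_folds <- function(n, k, seed) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer samples than folds")
  idx <- with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[idx] <- rep(seq_len(k), length.out = n) # round-robin over the shuffle

  split(seq_len(n), fold_of)
}

fit_predict_fold <- function(engine, Xtr, Ytr, Xte, hp, seed) {
  ntest <- nrow(Xte)
  out <- matrix(NA_real_, ntest, ncol(Ytr), dimnames = list(NULL, colnames(Ytr)))
  for (j in seq_len(ncol(Ytr))) {
    fit <- engine(Xtr, Ytr[, j], hp, seed + j)
    out[, j] <- predict(fit, Xte)
  }
  out
}

engine_gbt <- function(X, y, hp, seed) {
  ex <- hp$extras
  gbt_fit(X, y, learning_rate = hp$learning_rate, max_depth = hp$max_depth,
          n_estimators = hp$n_estimators,
          min_split = ex$min_split %||% 10L, min_leaf = ex$min_leaf %||% 5L,
          lambda = ex$lambda %||% 1.0, subsample = ex$subsample %||% 1.0,
          seed = seed)
}

#' K-fold cross-validation of the boosted-tree regressors
#'
#' Samples are shuffled with the given seed and partitioned into `k`
#' disjoint folds; each fold serves once as the held-out test set. Metrics
#' are computed on held-out predictions per fold and averaged.
#'
#' @param ts a `TrainingSet`.
#' @param hp a [hyperparams()] object.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold shuffle and training.
#' @param engine internal: fitting engine (used by the baseline benchmark).
#' @return a `CVReport` list: `per_fold` (list of `MetricsReport`),
#'   `summary` (fold-averaged mse/mae/r2/median_spearman),
#'   `per_mirna_spearman` (fold-averaged rho per target), `folds`.
#' @export
cross_validate <- function(ts, hp = hyperparams(), k = 5L, seed = 1L,
                           engine = engine_gbt) {
  stopifnot(inherits(ts, "TrainingSet"))
  folds <- make_folds(nrow(ts$X), k, seed)
  per_fold <- vector("list", length(folds))
  rho_mat <- matrix(NA_real_, length(folds), ncol(ts$Y),
                    dimnames = list(NULL, colnames(ts$Y)))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    pred <- fit_predict_fold(engine, ts$X[-te, , drop = FALSE],
                             ts$Y[-te, , drop = FALSE],
                             ts$X[te, , drop = FALSE], hp, seed * 1000L + f)
    per_fold[[f]] <- evaluate_predictions(pred, ts$Y[te, , drop = FALSE])
    rho_mat[f, ] <- per_fold[[f]]$per_mirna_spearman
  }
  summ <- c(mse = mean(vapply(per_fold, `[[`, 0, "mse")),
            mae = mean(vapply(per_fold, `[[`, 0, "mae")),
            r2 = mean(vapply(per_fold, `[[`, 0, "r2")),
            median_spearman = mean(vapply(per_fold, `[[`, 0, "median_spearman")))
  structure(list(per_fold = per_fold, summary = summ,
                 per_mirna_spearman = colMeans(rho_mat, na.rm = TRUE),
                 folds = folds),
            class = "CVReport")
}

#' Exhaustive grid search over boosted-tree hyperparameters
#'
#' Every grid point is evaluated by the same seeded k-fold split; the point
#' with the lowest fold-averaged MSE wins, ties broken by lower
#' `n_estimators`, then lower `max_depth`, then lower `learning_rate`.
#'
#' @param ts a `TrainingSet`.
#' @param grid list of [hyperparams()] objects (default [default_grid()]);
#'   duplicated points are evaluated once.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @return list with `best` (the winning `Hyperparams`), `best_report`
#'   (its `CVReport`) and `table` (per-point metrics data.frame).
#' @export
grid_search <- function(ts, grid = default_grid(), k = 5L, seed = 1L) {
  if (length(grid) == 0) stop("empty hyperparameter grid")
  key <- vapply(grid, function(h)
    paste(h$learning_rate, h$max_depth, h$n_estimators,
          paste(deparse(h$extras), collapse = ""), sep = "|"), character(1))
  grid <- grid[!duplicated(key)]
  reports <- lapply(grid, function(h) cross_validate(ts, h, k = k, seed = seed))
  tab <- data.frame(
    learning_rate = vapply(grid, `[[`, 0, "learning_rate"),
    max_depth = vapply(grid, `[[`, 0L, "max_depth"),
    n_estimators = vapply(grid, `[[`, 0L, "n_estimators"),
    mse = vapply(reports, function(r) unname(r$summary["mse"]), 0),
    mae = vapply(reports, function(r) unname(r$summary["mae"]), 0),
    r2 = vapply(reports, function(r) unname(r$summary["r2"]), 0),
    median_spearman = vapply(reports, function(r)
      unname(r$summary["median_spearman"]), 0))
  ord <- order(tab$mse, tab$n_estimators, tab$max_depth, tab$learning_rate)
  best <- ord[1]
  list(best = grid[[best]], best_report = reports[[best]], table = tab)
}

#' Benchmark the boosted-tree model against standard baselines
#'
#' Ridge and Lasso regression (glmnet, per-target, inner deterministic CV
#' for lambda), a bagged random forest, a two-hidden-layer feed-forward
#' network, and gradient boosting are each evaluated with identical seeded
#' k-fold splits.
#'
#' @param ts a `TrainingSet`.
#' @param k folds (default 5).
#' @param seed integer seed shared across models.
#' @param hp boosted-tree hyperparameters (default [hyperparams()]).
#' @param models character subset of
#'   `c("Ridge","Lasso","RandomForest","NeuralNetwork","GradientBoosting")`.
#' @return list with `table` (Model/MSE/MAE/R2/MedianSpearman data.frame)
#'   and `reports` (named list of `CVReport`s).
#' @export
benchmark_baselines <- function(ts, k = 5L, seed = 1L, hp = hyperparams(),
                                models = c("Ridge", "Lasso", "RandomForest",
                                           "NeuralNetwork",
                                           "GradientBoosting")) {
  models <- match.arg(models, several.ok = TRUE)
  engines <- list(
    Ridge = function(X, y, hp, seed) glmnet_engine(X, y, alpha = 0, seed),
    Lasso = function(X, y, hp, seed) glmnet_engine(X, y, alpha = 1, seed),
    RandomForest = function(X, y, hp, seed)
      rf_fit(X, y, n_trees = 100L, seed = seed),
    NeuralNetwork = function(X, y, hp, seed) mlp_fit(X, y, seed = seed),
    GradientBoosting = engine_gbt)
  reports <- lapply(models, function(mod)
    cross_validate(ts, hp, k = k, seed = seed, engine = engines[[mod]]))
  names(reports) <- models
  tab <- data.frame(
    Model = models,
    MSE = vapply(reports, function(r) unname(r$summary["mse"]), 0),
    MAE = vapply(reports, function(r) unname(r$summary["mae"]), 0),
    R2 = vapply(reports, function(r) unname(r$summary["r2"]), 0),
    MedianSpearman = vapply(reports, function(r)
      unname(r$summary["median_spearman"]), 0),
    row.names = NULL)
  list(table = tab, reports = reports)
}

glmnet_engine <- function(X, y, alpha, seed) {
  foldid <- rep_len(1:5, nrow(X))[with_seed(seed, sample.int(nrow(X)))]
  fit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                           standardize = TRUE)
  structure(list(fit = fit), class = "glmnet_reg")
}

#' @export
predict.glmnet_reg <- function(object, newdata, ...) {
  as.numeric(predict(object$fit, newx = newdata, s = "lambda.min"))
}

#' Save / load a fitted model bundle
#'
#' The on-disk format is a versioned RDS archive; loading a file written by
#' an incompatible format version is an explicit error, never a silent
#' reinterpretation.
#'
#' @param model a `ModelBundle`.
#' @param path file path (conventionally `*.stmir`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `ModelBundle`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ModelBundle"))
  saveRDS(list(format = "stmir-model", format_version = 1L, bundle = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read model file '%s': %s", path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, "stmir-model"))
    stop("not a stmir model file")
  if (!identical(obj$format_version, 1L))
    stop(sprintf("unsupported model format version: %s", obj$format_version))
  obj$bundle
}
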