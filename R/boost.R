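# R-side wrappers around the native tree learners. The boosted ensemble is
# the production regressor; the single tree and the bagged forest exist for
# the baseline comparison protocol.

gbt_fit <- function(X, y, learning_rate = 0.1, max_depth = 3L,
                    n_estimators = 200L, min_split = 10L, min_leaf = 5L,
                    lambda = 1.0, subsample = 1.0, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  fit <- .gbt_fit_cpp(X, as.numeric(y), as.integer(n_estimators),
                      as.integer(max_depth), learning_rate,
                      as.integer(min_split), as.integer(min_leaf),
                      lambda, subsample, as.integer(seed))
  fit$feature_names <- colnames(X)
  class(fit) <- "gbt"
  fit
}

#' @export
predict.gbt <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  as.numeric(.gbt_predict_cpp(object, newdata))
}

# Bagged regression trees with per-tree feature subsampling (random forest
# baseline). Deterministic given seed; RNG is confined by on.exit restore.
rf_fit <- function(X, y, n_trees = 100L, max_depth = 8L, mtry = NULL,
                   min_split = 5L, min_leaf = 2L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      rows <- sample.int(nrow(X), replace = TRUE)
      cols <- sort(sample.int(p, mtry))
      tree <- .tree_fit_cpp(X[rows, cols, drop = FALSE], y[rows],
                            as.integer(max_depth), as.integer(min_split),
                            as.integer(min_leaf), 1.0)
      # remap local feature indices back to the full design matrix
      split_rows <- tree[, "feature"] >= 0
      tree[split_rows, "feature"] <- cols[tree[split_rows, "feature"] + 1] - 1
      trees[[t]] <- tree
    }
  })
  structure(list(trees = trees, feature_names = colnames(X)), class = "rf")
}

#' @export
predict.rf <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  preds <- vapply(object$trees,
                  function(tr) as.numeric(.tree_predict_cpp(tr, newdata)),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(newdata))
  rowMeans(preds)
}

# Evaluate expr with a private RNG state seeded at `seed`; the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
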