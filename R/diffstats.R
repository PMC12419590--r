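#' Differential miRNA activity between two spot groups
#'
#' Per miRNA, a two-sided Wilcoxon rank-sum (Mann-Whitney) test compares the
#' activity distributions of groups A and B. The exact null distribution is
#' used when the smaller group has at most `exact_max` spots and the data
#' are tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used. P-values are Benjamini-Hochberg adjusted
#' across all tested miRNAs, and the rank-biserial effect size
#' 2U/(n1*n2) - 1 is reported (positive = higher in group A).
#'
#' @param act an `ActivityMatrix` (or plain spot x miRNA matrix).
#' @param labels factor/character vector with exactly two levels, one entry
#'   per spot, in the order of the activity rows.
#' @param exact_max exact-test group-size ceiling (default 8).
#' @return data.frame: `mirna`, `n1`, `n2`, `U`, `effect`, `direction`,
#'   `p`, `q`.
#' @export
differential_activity <- function(act, labels, exact_max = 8L) {
  v <- if (inherits(act, "ActivityMatrix")) act$values else act
  stopifnot(is.matrix(v))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two groups")
  if (length(labels) != nrow(v))
    stop("one label per spot is required")
  n1 <- sum(labels == levels(labels)[1])
  n2 <- sum(labels == levels(labels)[2])
  if (min(n1, n2) < 3L) stop("both groups need at least 3 spots")
  gA <- labels == levels(labels)[1]
  res <- t(apply(v, 2, function(x) {
    wilcox_ranksum(x[gA], x[!gA], exact_max = exact_max)
  }))
  out <- data.frame(
    mirna = colnames(v),
    n1 = n1, n2 = n2,
    U = res[, "U"],
    effect = res[, "effect"],
    direction = ifelse(res[, "effect"] > 0, levels(labels)[1],
                       ifelse(res[, "effect"] < 0, levels(labels)[2], "none")),
    p = res[, "p"],
    row.names = NULL, stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

# Two-sided Wilcoxon rank-sum on two samples. Exact via the U distribution
# (pwilcox) for small tie-free groups; tie-corrected normal approximation
# with continuity correction otherwise. sigma == 0 (all values tied) => p=1.
wilcox_ranksum <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && min(n1, n2) <= exact_max) {
    p <- if (U > n1 * n2 / 2) {
      2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else if (U < n1 * n2 / 2) {
      2 * pwilcox(U, n1, n2)
    } else 1
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  c(U = U, p = p, effect = 2 * U / (n1 * n2) - 1)
}

#' Benjamini-Hochberg and Bonferroni adjustment
#'
#' Thin, explicit wrappers so the adjustment used by each analysis is
#' visible at call sites.
#'
#' @param p numeric vector of raw p-values.
#' @param m family size for Bonferroni (default `length(p)`).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' @rdname bh_adjust
#' @export
bonferroni_adjust <- function(p, m = length(p)) pmin(1, p * m)

#' miRNA-target correlation classification
#'
#' For each (miRNA, target gene) pair, Pearson correlation between the
#' miRNA's predicted activity and the gene's expression over spots, with
#' Bonferroni adjustment over all pairs tested in the call. A pair is
#' classified `promoting` when r > `r_min` and adjusted p < `alpha`,
#' `suppressing` when r < -`r_min` and adjusted p < `alpha`, otherwise
#' `not_significant`. Pairs with a constant vector get `r = NA` and a
#' `degenerate` flag.
#'
#' @param act an `ActivityMatrix`.
#' @param expr spot x gene expression matrix (barcodes as rownames).
#' @param pairs data.frame with columns `mirna` and `gene`.
#' @param r_min absolute-correlation threshold (default 0.3).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame: `mirna`, `gene`, `r`, `p`, `p_adj`,
#'   `classification`, `degenerate`; the Bonferroni family size is recorded
#'   in `attr(, "n_pairs_tested")`.
#' @export
mirna_target_correlation <- function(act, expr, pairs, r_min = 0.3,
                                     alpha = 0.05) {
  stopifnot(inherits(act, "ActivityMatrix"), is.matrix(expr))
  if (!all(c("mirna", "gene") %in% colnames(pairs)))
    stop("pairs needs columns 'mirna' and 'gene'")
  shared <- intersect(act$barcodes, rownames(expr))
  if (length(shared) < 3L) stop("need at least 3 shared spots")
  bad_m <- setdiff(pairs$mirna, act$mirna_ids)
  bad_g <- setdiff(pairs$gene, colnames(expr))
  if (length(bad_m) > 0 || length(bad_g) > 0)
    stop(sprintf("unknown pair members: %s",
                 paste(utils::head(c(bad_m, bad_g), 10), collapse = ", ")))
  a <- act$values[shared, , drop = FALSE]
  e <- expr[shared, , drop = FALSE]
  n <- length(shared)
  m_tests <- nrow(pairs)
  stats_one <- function(mir, gene) {
    x <- a[, mir]; y <- e[, gene]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(r = NA_real_, p = NA_real_, degenerate = 1))
    r <- cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
    c(r = r, p = p, degenerate = 0)
  }
  res <- t(mapply(stats_one, pairs$mirna, pairs$gene))
  p_adj <- bonferroni_adjust(res[, "p"], m_tests)
  classify <- ifelse(
    is.na(res[, "r"]), "not_significant",
    ifelse(res[, "r"] > r_min & p_adj < alpha, "promoting",
           ifelse(res[, "r"] < -r_min & p_adj < alpha, "suppressing",
                  "not_significant")))
  out <- data.frame(
    mirna = pairs$mirna, gene = pairs$gene,
    r = res[, "r"], p = res[, "p"], p_adj = p_adj,
    classification = classify,
    degenerate = res[, "degenerate"] == 1,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_pairs_tested") <- m_tests
  out
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query and the set within the
#' universe; BH adjustment across sets. Sets are intersected with the
#' universe first.
#'
#' @param query_genes character vector; must be a subset of `universe`.
#' @param genesets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all considered genes.
#' @return data.frame: `set`, `overlap` (k), `set_size` (K), `query_size`
#'   (n), `universe_size` (N), `p`, `p_adj`.
#' @export
enrich <- function(query_genes, genesets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0)
    stop(sprintf("query genes outside the universe: %s",
                 paste(utils::head(outside, 10), collapse = ", ")))
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(genesets), function(nm) {
    set <- intersect(unique(genesets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Read a two-column miRNA-target pair list
#'
#' @param path TSV with columns `mirna` and `gene` (header optional if the
#'   columns come in that order).
#' @return data.frame with columns `mirna` and `gene`.
#' @export
read_target_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("mirna", "gene") %in% colnames(df))) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    colnames(df)[1:2] <- c("mirna", "gene")
  }
  df[, c("mirna", "gene")]
}
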