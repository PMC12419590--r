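#' Assign each spot its dominant cell type
#'
#' Abundances within each spot are normalized to sum to one; the cell type
#' with the largest share is dominant. A spot is `UNASSIGNED` when its top
#' share is below `min_purity`, when the top two shares tie exactly, or when
#' all abundances are zero. Dominance uses abundances only; activity values
#' are never consulted.
#'
#' @param ab spot x cell-type abundance matrix (non-negative; rows need not
#'   sum to one), with barcodes as rownames and cell types as colnames, or a
#'   data.frame of the same layout.
#' @param min_purity minimum dominant share (default 0, pure argmax).
#' @return a `DominantAssignment` data.frame: `barcode`, `dominant_type`
#'   (`"UNASSIGNED"` where the rule fails), `purity` (the max normalized
#'   share, `NA` for all-zero spots).
#' @export
assign_dominant <- function(ab, min_purity = 0) {
  if (is.data.frame(ab)) ab <- as.matrix(ab)
  stopifnot(is.matrix(ab), !is.null(rownames(ab)), !is.null(colnames(ab)))
  if (any(ab < 0)) stop("abundances must be non-negative")
  if (min_purity < 0 || min_purity > 1) stop("min_purity must be in [0,1]")
  totals <- rowSums(ab)
  zero <- totals == 0
  if (any(zero))
    warning(sprintf("%d spot(s) with all-zero abundance left UNASSIGNED",
                    sum(zero)))
  share <- ab / ifelse(totals == 0, 1, totals)
  top_idx <- max.col(share, ties.method = "first")
  top <- share[cbind(seq_len(nrow(share)), top_idx)]
  n_at_top <- rowSums(share == top)
  tied <- n_at_top > 1
  assigned <- !zero & !tied & top >= min_purity
  out <- data.frame(
    barcode = rownames(ab),
    dominant_type = ifelse(assigned, colnames(ab)[top_idx], "UNASSIGNED"),
    purity = ifelse(zero, NA_real_, top),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DominantAssignment", "data.frame")
  out
}

#' Candidate cell-type-specific miRNA profiles
#'
#' For every cell type dominating at least `min_spots` spots, computes per
#' miRNA: the median predicted activity over its dominated spots, the
#' consistency (fraction of those spots in which the miRNA's activity
#' exceeds that spot's own median activity across miRNAs), and the dense
#' rank of the median within the cell type (1 = highest). Cell types under
#' `min_spots` are excluded and listed in `attr(, "excluded_celltypes")`.
#'
#' @param act an `ActivityMatrix`.
#' @param da a `DominantAssignment` sharing barcodes with `act`.
#' @param min_spots minimum dominated spots per profiled cell type
#'   (default 10).
#' @return a long data.frame: `celltype`, `mirna`, `median_activity`,
#'   `consistency`, `rank`.
#' @export
celltype_mirna_profile <- function(act, da, min_spots = 10L) {
  stopifnot(inherits(act, "ActivityMatrix"),
            inherits(da, "DominantAssignment"))
  shared <- intersect(act$barcodes, da$barcode)
  if (length(shared) == 0) stop("no shared barcodes")
  v <- act$values[shared, , drop = FALSE]
  dom <- da$dominant_type[match(shared, da$barcode)]
  spot_median <- apply(v, 1, median)
  counts <- table(dom[dom != "UNASSIGNED"])
  eligible <- names(counts)[counts >= min_spots]
  excluded <- setdiff(names(counts), eligible)
  if (length(eligible) == 0)
    stop(sprintf("no cell type dominates >= %d spots", min_spots))
  rows <- lapply(eligible, function(ct) {
    sel <- dom == ct
    med <- apply(v[sel, , drop = FALSE], 2, median)
    consist <- colMeans(v[sel, , drop = FALSE] > spot_median[sel])
    data.frame(celltype = ct, mirna = colnames(v),
               median_activity = unname(med),
               consistency = unname(consist),
               rank = match(-med, sort(unique(-med))),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded_celltypes") <- excluded
  out
}

#' Rank miRNAs by mean activity within one context
#'
#' @param act an `ActivityMatrix` (one context, e.g. one cancer type).
#' @return character vector of miRNA ids, highest mean activity first; ties
#'   broken alphabetically.
#' @export
rank_mirnas_per_context <- function(act) {
  stopifnot(inherits(act, "ActivityMatrix"))
  mu <- colMeans(act$values)
  names(mu)[order(-mu, names(mu))]
}

#' Pan-context conserved miRNAs
#'
#' Intersects the top-`top_k` miRNA rankings of every context; also returns
#' the full per-miRNA rank table across contexts for heatmap-style
#' inspection.
#'
#' @param rankings named list of ranked miRNA character vectors (one per
#'   context, from [rank_mirnas_per_context()]).
#' @param top_k rank cutoff (default 40).
#' @return list with `conserved` (sorted character vector) and `rank_table`
#'   (miRNA x context integer matrix of ranks, NA if absent).
#' @export
conserved_mirnas <- function(rankings, top_k = 40L) {
  if (!is.list(rankings) || length(rankings) < 2L)
    stop("need rankings for at least 2 contexts")
  if (any(vapply(rankings, length, 0L) == 0L)) stop("empty ranking list")
  tops <- lapply(rankings, utils::head, top_k)
  conserved <- sort(Reduce(intersect, tops))
  all_mirnas <- sort(unique(unlist(rankings)))
  rank_table <- vapply(rankings, function(r)
    match(all_mirnas, r), integer(length(all_mirnas)))
  rownames(rank_table) <- all_mirnas
  list(conserved = conserved, rank_table = rank_table)
}

#' Read a spot x cell-type abundance table
#'
#' Accepts the CSV/TSV export of common deconvolution tools: spots in rows
#' (first column = barcode), cell types in columns.
#'
#' @param path file path.
#' @return numeric matrix with barcode rownames.
#' @export
read_abundance <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "")
  as.matrix(df)
}
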