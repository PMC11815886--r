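# Single-cell localization of the gene-pair reversal: dotplot-style
# percent-expressing / median-expression summaries stratified by cell type
# and condition, and a testable reversal verdict per cell type.

#' Dotplot-style summary: percent expressing and median expression
#'
#' For each (gene, cell type, condition) stratum: the percentage of cells
#' with count > 0 and the median expression over all cells of the stratum
#' (zeros included). Raw counts are used by default -- the comparison of
#' interest is between two genes across the same cells, so per-cell depth
#' scaling is optional and off.
#'
#' @param dataset [single_cell_dataset()].
#' @param genes genes to summarize (must be present).
#' @param cell_type_col,condition_col metadata column names.
#' @param scale_depth if TRUE, counts are scaled per cell to a common total
#'   before medians are computed (percentages are unaffected: scaling
#'   preserves zero status).
#' @return data.frame of class `dotplot_summary` with columns `gene`,
#'   `cell_type`, `condition`, `n_cells`, `pct_expressing` (0-100),
#'   `median_expr`. Strata with zero cells are absent, not zero-filled.
#' @export
dotplot_summary <- function(dataset, genes, cell_type_col = "cell_type",
                            condition_col = "condition",
                            scale_depth = FALSE) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  miss <- setdiff(genes, dataset$gene_ids)
  if (length(miss)) stop("gene(s) not in dataset: ",
                         paste(miss, collapse = ", "))
  meta <- dataset$cell_meta
  for (col in c(cell_type_col, condition_col))
    if (!col %in% names(meta)) stop("metadata column missing: ", col)
  counts <- dataset$counts[, genes, drop = FALSE]
  if (scale_depth) {
    tot <- Matrix::rowSums(dataset$counts)
    fac <- ifelse(tot > 0, stats::median(tot[tot > 0]) / tot, 0)
    counts <- counts * fac
  }
  strata <- interaction(meta[[cell_type_col]], meta[[condition_col]],
                        sep = "\r", drop = TRUE)
  out <- list()
  for (st in levels(strata)) {
    idx <- which(strata == st)
    parts <- strsplit(st, "\r", fixed = TRUE)[[1]]
    sub <- counts[idx, , drop = FALSE]
    out[[st]] <- data.frame(
      gene = genes,
      cell_type = parts[1], condition = parts[2],
      n_cells = length(idx),
      pct_expressing = 100 * Matrix::colSums(sub > 0) / length(idx),
      median_expr = apply(as.matrix(sub), 2, stats::median),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("dotplot_summary", "data.frame")
  res
}

#' Check whether a gene pair's ordering reverses between condition groups
#'
#' Per cell type, the two genes are ordered by median expression within each
#' condition group. The cell type is `supported` iff, in both groups, the
#' higher-median gene is expressed in at least `min_pct` percent of cells,
#' and `reversed` iff both orderings are non-ties, opposite, and supported.
#' Only cell types summarized in both groups for both genes are assessed.
#'
#' @param summary a [dotplot_summary()].
#' @param pair length-2 character `(gene_a, gene_b)`.
#' @param groups length-2 character, the two condition labels to contrast.
#' @param min_pct percent-expressing support floor (default 10).
#' @return data.frame of class `pair_pattern_verdict` with columns
#'   `cell_type`, `ordering_a`, `ordering_b` (each `"a<b"`, `"a>b"` or
#'   `"tie"`), `supported`, `reversed`; the number of reversed cell types is
#'   in attribute `"n_reversed"`.
#' @export
pair_pattern_check <- function(summary, pair, groups, min_pct = 10) {
  stopifnot(length(pair) == 2, length(groups) == 2)
  s <- summary[summary$gene %in% pair & summary$condition %in% groups, ]
  if (!nrow(s)) stop("pair/groups not found in summary")
  types <- unique(s$cell_type)
  rows <- list()
  for (ct in types) {
    cell <- function(g, grp) s[s$cell_type == ct & s$gene == g &
                                 s$condition == grp, , drop = FALSE]
    a1 <- cell(pair[1], groups[1]); b1 <- cell(pair[2], groups[1])
    a2 <- cell(pair[1], groups[2]); b2 <- cell(pair[2], groups[2])
    if (!all(nrow(a1), nrow(b1), nrow(a2), nrow(b2))) next
    ord <- function(a, b) {
      if (a$median_expr < b$median_expr) "a<b"
      else if (a$median_expr > b$median_expr) "a>b"
      else "tie"
    }
    o1 <- ord(a1, b1); o2 <- ord(a2, b2)
    # support: the higher-median gene must clear min_pct in each group
    sup1 <- if (o1 == "a<b") b1$pct_expressing else
      if (o1 == "a>b") a1$pct_expressing else
        max(a1$pct_expressing, b1$pct_expressing)
    sup2 <- if (o2 == "a<b") b2$pct_expressing else
      if (o2 == "a>b") a2$pct_expressing else
        max(a2$pct_expressing, b2$pct_expressing)
    supported <- sup1 >= min_pct && sup2 >= min_pct
    reversed <- supported && o1 != "tie" && o2 != "tie" && o1 != o2
    rows[[ct]] <- data.frame(cell_type = ct, ordering_a = o1,
                             ordering_b = o2, supported = supported,
                             reversed = reversed, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no cell type summarized in both groups")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "n_reversed") <- sum(res$reversed)
  class(res) <- c("pair_pattern_verdict", "data.frame")
  res
}
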