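# Tabular / sparse I-O and the domain containers.
#
# Conventions (documented in README):
#   * bulk expression: TSV, genes in rows, samples in columns, first column
#     holds gene symbols, header row holds sample ids; values non-negative and
#     comparable within each sample (arbitrary units);
#   * single cell: matrix-market triple with CELLS IN ROWS, genes in columns,
#     plus a plain gene list and a TSV of per-cell metadata.
# Missing values are never imputed: any NA in a numeric table is an error.

#' Validate an expression matrix
#'
#' An expression matrix is a base numeric matrix with genes in rows (unique
#' rownames), samples in columns (unique colnames), all values finite and
#' non-negative, at least 2 genes and 1 sample.
#'
#' @param x numeric matrix, genes x samples.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (genes x samples)")
  if (nrow(x) < 2L || ncol(x) < 1L)
    stop("expression matrix needs >= 2 genes and >= 1 sample")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  if (any(x < 0))
    stop("expression matrix contains negative values")
  invisible(x)
}

#' Construct a cluster labeling
#'
#' @param assignments named character vector, names = sample ids, values =
#'   cluster labels.
#' @param label_set optional ordered character vector of labels; defaults to
#'   the sorted distinct assigned labels.
#' @return an object of class `cluster_labels` with fields `assignments` and
#'   `label_set`.
#' @export
cluster_labels <- function(assignments, label_set = NULL) {
  assignments <- unlist(assignments)
  if (is.null(names(assignments)) || anyDuplicated(names(assignments)))
    stop("assignments must be uniquely named by sample id")
  assignments <- stats::setNames(as.character(assignments), names(assignments))
  if (is.null(label_set)) {
    label_set <- sort(unique(assignments))
  } else {
    label_set <- as.character(label_set)
    bad <- setdiff(assignments, label_set)
    if (length(bad))
      stop("assigned label(s) not in label_set: ", paste(bad, collapse = ", "))
  }
  if (length(unique(assignments)) < 2L)
    stop("need at least 2 distinct cluster labels")
  structure(list(assignments = assignments, label_set = label_set),
            class = "cluster_labels")
}

#' Construct a gene-pair feature set
#'
#' A feature set is an ordered per-cluster list of oriented gene pairs, stored
#' as a data frame with columns `cluster`, `gene_a`, `gene_b` (file layout
#' `ClusterLabel GeneA GeneB`). Within a cluster no gene may appear in two
#' pairs and `gene_a != gene_b` in every pair.
#'
#' @param pairs data.frame with columns `cluster`, `gene_a`, `gene_b`.
#' @param provenance named list recording selection settings (thresholds,
#'   datasets consulted, seed).
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(pairs, provenance = list()) {
  need <- c("cluster", "gene_a", "gene_b")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns cluster, gene_a, gene_b")
  pairs <- data.frame(cluster = as.character(pairs$cluster),
                      gene_a = as.character(pairs$gene_a),
                      gene_b = as.character(pairs$gene_b),
                      stringsAsFactors = FALSE)
  if (any(pairs$gene_a == pairs$gene_b))
    stop("gene_a must differ from gene_b in every pair")
  for (cl in unique(pairs$cluster)) {
    g <- with(pairs[pairs$cluster == cl, ], c(gene_a, gene_b))
    if (anyDuplicated(g))
      stop("gene appears in two pairs of cluster ", cl, ": ",
           paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  structure(list(pairs = pairs, provenance = provenance), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>", nrow(x$pairs), "pairs over",
      length(unique(x$pairs$cluster)), "clusters\n")
  print(utils::head(x$pairs, 10))
  invisible(x)
}

# ---- alias maps -------------------------------------------------------------

#' Read a gene-alias table
#'
#' Two-column TSV (`alias`, `canonical`) mapping alias symbols to canonical
#' symbols (many-to-one). An alias mapping to the literal canonical symbol
#' `"unknown"` marks rows to be dropped by [read_expression()]. Multi-symbol
#' strings (e.g. `"A///B"` or its mangled `"A.....B"` form) are treated as
#' opaque symbols and never split.
#'
#' @param path TSV file path.
#' @return named character vector: `names` = aliases, values = canonical.
#' @export
read_alias_map <- function(path) {
  df <- read_tsv_checked(path, c("alias", "canonical"))
  if (anyDuplicated(df$alias))
    stop("alias map: alias mapped to more than one canonical symbol: ",
         paste(unique(df$alias[duplicated(df$alias)]), collapse = ", "))
  if (any(!nzchar(df$canonical)))
    stop("alias map: empty canonical symbol")
  stats::setNames(as.character(df$canonical), as.character(df$alias))
}

#' Apply an alias map to a vector of gene symbols
#'
#' Idempotent: symbols already canonical (or absent from the map) pass
#' through unchanged.
#'
#' @param genes character vector of symbols.
#' @param alias_map named character vector from [read_alias_map()], or NULL.
#' @return character vector of canonical symbols.
#' @export
apply_alias_map <- function(genes, alias_map = NULL) {
  if (is.null(alias_map)) return(genes)
  hit <- genes %in% names(alias_map)
  genes[hit] <- unname(alias_map[genes[hit]])
  genes
}

# ---- bulk expression --------------------------------------------------------

#' Read a genes-x-samples expression TSV
#'
#' First column = gene symbols, remaining columns = samples (header row =
#' sample ids). Optionally harmonizes symbols through an alias map: rows whose
#' canonical symbol is `"unknown"` are dropped (count reported via `message`);
#' duplicate symbols after mapping are resolved by keeping the row with the
#' highest mean expression (reported).
#'
#' @param path TSV file path.
#' @param alias_map optional named character vector (alias -> canonical).
#' @return validated expression matrix (genes x samples).
#' @export
read_expression <- function(path, alias_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("malformed expression header: need a gene column plus >= 1 sample")
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s' (row %d, column %d)",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 bad[1, 1], bad[1, 2] + 1L))
  }
  dimnames(num) <- list(genes, colnames(vals))
  num <- harmonize_genes(num, alias_map)
  validate_expression(num)
  num
}

harmonize_genes <- function(mat, alias_map) {
  canon <- apply_alias_map(rownames(mat), alias_map)
  drop <- canon == "unknown"
  if (any(drop)) {
    message(sum(drop), " row(s) with unknown gene symbol dropped")
    mat <- mat[!drop, , drop = FALSE]
    canon <- canon[!drop]
  }
  rownames(mat) <- canon
  if (anyDuplicated(canon)) {
    means <- rowMeans(mat)
    keep <- !logical(nrow(mat))
    for (g in unique(canon[duplicated(canon)])) {
      idx <- which(canon == g)
      keep[idx] <- FALSE
      keep[idx[which.max(means[idx])]] <- TRUE
      message("duplicate symbol '", g, "': kept row with highest mean")
    }
    mat <- mat[keep, , drop = FALSE]
  }
  mat
}

#' Write a genes-x-samples expression TSV
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- labels -----------------------------------------------------------------

#' Read a cluster-label TSV (columns `sample_id`, `cluster`)
#'
#' @param path TSV file path.
#' @param label_order optional ordered label set; labels outside it error.
#' @return [cluster_labels()] object.
#' @export
read_labels <- function(path, label_order = NULL) {
  df <- read_tsv_checked(path, c("sample_id", "cluster"))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in label table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  cluster_labels(stats::setNames(df$cluster, df$sample_id), label_order)
}

#' Write a cluster-label TSV
#' @param labels [cluster_labels()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels$assignments),
                   cluster = unname(labels$assignments))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- survival ---------------------------------------------------------------

#' Read a survival TSV (columns `sample_id`, `time`, `event`, optional `group`)
#'
#' `time` is survival in days (strictly positive); `event` is 1 for an
#' observed event (death) and 0 for censoring -- this coding is fixed.
#'
#' @param path TSV file path.
#' @return data.frame with columns sample_id, time, event (and group if present).
#' @export
read_survival <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "time", "event"))
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  validate_survival(df)
  df
}

validate_survival <- function(df) {
  if (!all(c("sample_id", "time", "event") %in% names(df)))
    stop("survival table needs columns sample_id, time, event")
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("survival times must be strictly positive and finite")
  if (!all(df$event %in% c(0L, 1L)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  invisible(df)
}

#' Write a survival TSV
#' @param df survival data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(df, path) {
  validate_survival(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pair feature files -----------------------------------------------------

#' Read a gene-pair feature TSV (columns `cluster`, `gene_a`, `gene_b`)
#'
#' Lines starting with `#` before the header are parsed as `# key: value`
#' provenance comments.
#'
#' @param path TSV file path.
#' @return [feature_set()] object.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  prov <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) prov[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                          quote = "", colClasses = "character")
  if (!all(c("cluster", "gene_a", "gene_b") %in% names(df)))
    stop("pair file needs columns cluster, gene_a, gene_b")
  feature_set(df, prov)
}

#' Write a gene-pair feature TSV with provenance header comments
#' @param fs [feature_set()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(fs$provenance))
    writeLines(sprintf("# %s: %s", k, fs$provenance[[k]]), con)
  utils::write.table(fs$pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- single cell ------------------------------------------------------------

#' Construct a single-cell dataset
#'
#' @param counts sparse non-negative matrix, CELLS in rows, genes in columns.
#' @param gene_ids character vector matching `ncol(counts)`.
#' @param cell_meta data.frame with one row per cell; must contain the columns
#'   later used for grouping (typically `cell_type` and `condition`).
#' @return object of class `single_cell_dataset`.
#' @export
single_cell_dataset <- function(counts, gene_ids, cell_meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (ncol(counts) != length(gene_ids))
    stop("counts columns must match gene_ids")
  if (nrow(counts) != nrow(cell_meta))
    stop("counts rows must match cell_meta rows")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  colnames(counts) <- gene_ids
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 cell_meta = as.data.frame(cell_meta)),
            class = "single_cell_dataset")
}

#' Read a single-cell triple (matrix-market counts + gene list + cell metadata)
#'
#' @param matrix_path matrix-market (.mtx) file, cells in rows.
#' @param genes_path plain text file, one gene symbol per line.
#' @param meta_path TSV of per-cell metadata, same row order as the matrix.
#' @return [single_cell_dataset()] object.
#' @export
read_single_cell <- function(matrix_path, genes_path, meta_path) {
  counts <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  meta <- utils::read.delim(meta_path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
  single_cell_dataset(counts, genes, meta)
}

#' Write a single-cell triple
#' @param x [single_cell_dataset()] object.
#' @param matrix_path,genes_path,meta_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_single_cell <- function(x, matrix_path, genes_path, meta_path) {
  stopifnot(inherits(x, "single_cell_dataset"))
  Matrix::writeMM(x$counts, matrix_path)
  writeLines(x$gene_ids, genes_path)
  utils::write.table(x$cell_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

# ---- shared helpers ---------------------------------------------------------

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
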