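# Dot-plot summarization of an annotated single-cell expression matrix: per
# gene and cell type, the mean normalized-log expression, its gene-wise Z
# across types, and the fraction of cells expressing (> 0).  Used to assign
# candidate plasma biomarkers to their likely cellular source.

#' Read an annotated single-cell expression matrix
#'
#' Accepts either a MatrixMarket triplet (`.mtx` with sibling gene and cell
#' index files) or a dense CSV (genes in rows, cells in columns), plus a
#' tab-separated annotation mapping cell barcode to cell type.  Cells
#' without an annotation are dropped with a message; a barcode mismatch
#' above 50% aborts (likely mispaired files).
#'
#' @param matrix_path `.mtx` or `.csv` expression file.  For MTX, gene and
#'   cell names are read from `<prefix>_genes.tsv` / `<prefix>_barcodes.tsv`
#'   next to it (or `features.tsv` / `barcodes.tsv` in the same directory).
#' @param annotation_path TSV with columns `barcode`, `cell_type` (header
#'   optional if exactly two columns).
#' @return list with `expression` (genes x cells) and `cell_types`.
#' @export
read_annotated_expression <- function(matrix_path, annotation_path) {
  if (grepl("\\.mtx$", matrix_path)) {
    expr <- as.matrix(Matrix::readMM(matrix_path))
    prefix <- sub("\\.mtx$", "", matrix_path)
    gene_file <- first_existing(c(paste0(prefix, "_genes.tsv"),
                                  file.path(dirname(matrix_path), "features.tsv"),
                                  file.path(dirname(matrix_path), "genes.tsv")))
    cell_file <- first_existing(c(paste0(prefix, "_barcodes.tsv"),
                                  file.path(dirname(matrix_path), "barcodes.tsv")))
    rownames(expr) <- utils::read.table(gene_file, stringsAsFactors = FALSE)[[1]]
    colnames(expr) <- utils::read.table(cell_file, stringsAsFactors = FALSE)[[1]]
  } else {
    df <- utils::read.csv(matrix_path, row.names = 1, check.names = FALSE)
    expr <- as.matrix(df)
  }
  ann <- utils::read.table(annotation_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("barcode", "cell_type") %in% names(ann))) {
    if (ncol(ann) == 2) names(ann) <- c("barcode", "cell_type")
    else stop("annotation needs columns 'barcode' and 'cell_type'")
  }
  hit <- colnames(expr) %in% ann$barcode
  if (mean(hit) < 0.5) {
    stop("more than 50% of cell barcodes lack annotation; ",
         "are the files correctly paired?")
  }
  if (any(!hit)) {
    message(sum(!hit), " unannotated cell(s) dropped")
    expr <- expr[, hit, drop = FALSE]
  }
  types <- ann$cell_type[match(colnames(expr), ann$barcode)]
  list(expression = expr, cell_types = types)
}

first_existing <- function(paths) {
  for (p in paths) if (file.exists(p)) return(p)
  stop("no index file found among: ", paste(paths, collapse = ", "))
}

#' Dot-plot statistics per gene and cell type
#'
#' For each requested gene and each cell type: the mean expression over the
#' type's cells, the fraction of cells with expression strictly greater than
#' zero, and the gene-wise Z of the mean vector across types (population-SD
#' standardization; a gene with identical means in every type gets Z = 0
#' everywhere).
#'
#' @param expression genes x cells numeric matrix (normalized log scale).
#' @param labels cell-type label per column.
#' @param genes genes to summarize; default all rows.
#' @return object of class `celltype_summary` with matrices `mean_expression`,
#'   `z_mean`, `pct_expressing` (genes x cell types) and `cell_counts`.
#' @export
celltype_dot_stats <- function(expression, labels, genes = rownames(expression)) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expression))
  missing_g <- setdiff(genes, rownames(expression))
  if (length(missing_g)) {
    stop("gene(s) not in matrix: ", paste(missing_g, collapse = ", "))
  }
  types <- unique(labels)
  counts <- vapply(types, function(tp) sum(labels == tp), integer(1))
  if (any(counts < 1)) stop("every cell type needs at least one cell")
  x <- expression[genes, , drop = FALSE]
  mean_mat <- vapply(types, function(tp)
    rowMeans(x[, labels == tp, drop = FALSE]), numeric(length(genes)))
  pct_mat <- vapply(types, function(tp)
    rowMeans(x[, labels == tp, drop = FALSE] > 0), numeric(length(genes)))
  if (length(genes) == 1L) {
    mean_mat <- matrix(mean_mat, nrow = 1, dimnames = list(genes, types))
    pct_mat <- matrix(pct_mat, nrow = 1, dimnames = list(genes, types))
  }
  mu <- rowMeans(mean_mat)
  sdev <- sqrt(rowMeans((mean_mat - mu)^2))  # population SD across types
  z_mat <- (mean_mat - mu) / ifelse(sdev == 0, Inf, sdev)
  structure(
    list(mean_expression = mean_mat, z_mean = z_mat, pct_expressing = pct_mat,
         cell_counts = counts, sd_convention = "population"),
    class = "celltype_summary")
}

#' @export
print.celltype_summary <- function(x, ...) {
  cat("celltype_summary: ", nrow(x$mean_expression), " genes x ",
      ncol(x$mean_expression), " cell types (",
      sum(x$cell_counts), " cells)\n", sep = "")
  invisible(x)
}

#' Order genes by mean expression in one cell type
#'
#' Descending by mean expression in `cell_type`; ties broken alphabetically.
#'
#' @param summary a `celltype_summary`.
#' @param cell_type one of its cell types.
#' @return character vector, a permutation of the summarized genes.
#' @export
rank_genes_by_celltype <- function(summary, cell_type) {
  m <- summary$mean_expression
  if (!cell_type %in% colnames(m)) stop("unknown cell type: ", cell_type)
  g <- rownames(m)
  g[order(-m[, cell_type], g)]
}

#' Flatten a cell-type summary to a long table
#'
#' @param summary a `celltype_summary`.
#' @return data.frame with columns `gene`, `cell_type`, `mean_expression`,
#'   `z_mean`, `pct_expressing`.
#' @export
celltype_summary_table <- function(summary) {
  m <- summary$mean_expression
  data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    cell_type = rep(colnames(m), each = nrow(m)),
    mean_expression = as.vector(m),
    z_mean = as.vector(summary$z_mean),
    pct_expressing = as.vector(summary$pct_expressing),
    stringsAsFactors = FALSE)
}
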