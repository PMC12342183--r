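#' Construct a cell-by-gene count matrix container
#'
#' Light S3 container used throughout the package. Cells are rows and genes
#' are columns everywhere in memory, whatever the on-disk orientation of the
#' source file.
#'
#' @param values numeric matrix (dense `matrix` or sparse `Matrix`), cells in
#'   rows, genes in columns, all entries non-negative. The `raw` layer must be
#'   integer-valued counts.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_ids character vector of unique gene identifiers, one per column.
#' @param layer one of `"raw"`, `"lognorm"`, `"hvg"` marking the processing
#'   stage the values are at.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(values, cell_ids, gene_ids,
                         layer = c("raw", "lognorm", "hvg")) {
  layer <- match.arg(layer)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(cell_ids))
    stop("count_matrix: ", nrow(values), " rows but ", length(cell_ids),
         " cell ids")
  if (ncol(values) != length(gene_ids))
    stop("count_matrix: ", ncol(values), " columns but ", length(gene_ids),
         " gene ids")
  if (anyDuplicated(cell_ids))
    stop("count_matrix: duplicate cell ids (e.g. '",
         cell_ids[duplicated(cell_ids)][1], "')")
  if (anyDuplicated(gene_ids))
    stop("count_matrix: duplicate gene ids (e.g. '",
         gene_ids[duplicated(gene_ids)][1], "')")
  if (any(!is.finite(values)) || any(values < 0))
    stop("count_matrix: entries must be finite and non-negative")
  if (layer == "raw" && any(values != round(values)))
    stop("count_matrix: raw layer must contain integer counts")
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(list(values = values,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids),
                 layer = layer),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes [layer: %s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Construct a cell-graph container
#'
#' Sparse symmetric binary adjacency over cells, as produced by
#' [build_knn_graph()]. The diagonal is zero; self-loops are added only
#' inside the attention mechanism, never stored here.
#'
#' @param adjacency square sparse or dense 0/1 matrix, symmetric with zero
#'   diagonal.
#' @param k number of neighbors requested when the graph was built.
#' @param metric distance used; only `"cosine"` is supported.
#' @return an object of class `cell_graph`.
#' @export
cell_graph <- function(adjacency, k = NA_integer_, metric = "cosine") {
  adjacency <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix")
  adjacency <- 1 * (adjacency != 0)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop("cell_graph: adjacency must be square")
  if (any(Matrix::diag(adjacency) != 0))
    stop("cell_graph: adjacency must have a zero diagonal")
  if (!Matrix::isSymmetric(adjacency, tol = 0))
    stop("cell_graph: adjacency must be symmetric")
  structure(list(adjacency = adjacency, k = as.integer(k), metric = metric),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("cell_graph: %d cells, %d undirected edges (k = %s, %s)\n",
              nrow(x$adjacency), Matrix::nnzero(x$adjacency) / 2,
              x$k, x$metric))
  invisible(x)
}

# dense base-matrix view of an adjacency, accepting cell_graph / Matrix / matrix
as_dense_adj <- function(a) {
  if (inherits(a, "cell_graph")) a <- a$adjacency
  if (inherits(a, "Matrix")) a <- as.matrix(a)
  storage.mode(a) <- "double"
  a
}
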