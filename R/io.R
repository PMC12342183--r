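#' Read a count matrix from disk
#'
#' Supported formats: delimited text (`csv`/`tsv`, header row of gene ids,
#' first column of cell ids, cells in rows), the 10x Matrix-Market triple
#' (`matrix.mtx` + `features.tsv`/`genes.tsv` + `barcodes.tsv`, stored genes
#' x cells on disk and transposed on read, `.gz` variants accepted), and
#' `h5ad`. Whatever the on-disk orientation, the returned matrix always has
#' cells as rows.
#'
#' h5ad files are converted through the `python` interpreter on `PATH`
#' (requires the `anndata` and `scipy` Python packages); the main matrix is
#' read unless `layer` names an AnnData layer.
#'
#' @param path file path, or for `mtx_10x` either the matrix file or the
#'   directory holding the triple.
#' @param format one of `"csv"`, `"tsv"`, `"mtx_10x"`, `"h5ad"`.
#' @param layer for h5ad only: optional name of the AnnData layer to read.
#' @return a raw-layer [count_matrix()].
#' @export
read_counts <- function(path, format = c("csv", "tsv", "mtx_10x", "h5ad"),
                        layer = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("read_counts: no such file or directory: ", path)
  switch(format,
         csv = read_counts_delim(path, ","),
         tsv = read_counts_delim(path, "\t"),
         mtx_10x = read_counts_mtx(path),
         h5ad = read_counts_h5ad(path, layer))
}

read_counts_delim <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("read_counts: non-numeric entries in ", path)
  count_matrix(m, rownames(df), colnames(df), layer = "raw")
}

find_10x_file <- function(dir, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop("read_counts: none of [", paste(stems, collapse = ", "),
       "] found next to the matrix in ", dir)
}

read_counts_mtx <- function(path) {
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx <- if (dir.exists(path)) find_10x_file(dir, c("matrix.mtx")) else path
  m <- Matrix::readMM(mtx)                       # genes x cells on disk
  feat <- find_10x_file(dir, c("features.tsv", "genes.tsv"))
  bc <- find_10x_file(dir, c("barcodes.tsv"))
  features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
    stop("read_counts: matrix is ", nrow(m), " x ", ncol(m),
         " but features/barcodes have ", nrow(features), "/",
         length(barcodes), " entries")
  gene_ids <- features[[min(2L, ncol(features))]]
  if (anyDuplicated(gene_ids)) gene_ids <- features[[1]]
  count_matrix(Matrix::t(m), barcodes, gene_ids, layer = "raw")
}

read_counts_h5ad <- function(path, layer = NULL) {
  py <- Sys.which("python")
  if (py == "") stop("read_counts: h5ad input needs a 'python' interpreter ",
                     "with the anndata package on PATH")
  out <- tempfile("h5ad2mtx")
  dir.create(out)
  script <- sprintf('
import sys
import anndata, scipy.sparse, scipy.io
ad = anndata.read_h5ad(sys.argv[1])
x = ad.layers[sys.argv[3]] if len(sys.argv) > 3 else ad.X
x = scipy.sparse.csr_matrix(x)
scipy.io.mmwrite(sys.argv[2] + "/matrix.mtx", x.T)
open(sys.argv[2] + "/barcodes.tsv", "w").write("\\n".join(map(str, ad.obs_names)) + "\\n")
open(sys.argv[2] + "/genes.tsv", "w").write("\\n".join(map(str, ad.var_names)) + "\\n")
')
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  args <- c(sf, path, out, layer)
  res <- suppressWarnings(system2(py, shQuote(args), stdout = TRUE,
                                  stderr = TRUE))
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
    stop("read_counts: h5ad conversion failed for ", path, ":\n",
         paste(res, collapse = "\n"))
  read_counts_mtx(out)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()] for the text formats; raw integer counts
#' round-trip exactly.
#'
#' @param m a [count_matrix()].
#' @param path output file (csv/tsv) or directory (mtx_10x).
#' @param format one of `"csv"`, `"tsv"`, `"mtx_10x"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("csv", "tsv", "mtx_10x")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "count_matrix"))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = m$cell_ids, m$values, check.names = FALSE)
    colnames(df) <- c("cell_id", m$gene_ids)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    sp <- methods::as(Matrix::Matrix(t(m$values), sparse = TRUE), "CsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))   # genes x cells
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    utils::write.table(data.frame(m$gene_ids, m$gene_ids),
                       file.path(path, "genes.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
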