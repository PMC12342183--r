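#' Quality-control filtering of cells and genes
#'
#' Removes cells expressing fewer than `min_genes_per_cell` genes and genes
#' expressed (count > 0) in fewer than `min_cells_per_gene` cells. Both
#' filters are evaluated on the input matrix and applied jointly in a single
#' pass (not iterated to a fixed point).
#'
#' @param m raw-layer [count_matrix()].
#' @param min_genes_per_cell minimum number of expressed genes a cell must
#'   have to be kept.
#' @param min_cells_per_gene minimum number of cells a gene must be expressed
#'   in to be kept.
#' @return the filtered raw-layer [count_matrix()].
#' @export
quality_control <- function(m, min_genes_per_cell = 5L,
                            min_cells_per_gene = 5L) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw")
    stop("quality_control: expected a raw-layer matrix, got '", m$layer, "'")
  nz <- m$values > 0
  keep_cells <- rowSums(nz) >= min_genes_per_cell
  keep_genes <- colSums(nz) >= min_cells_per_gene
  if (!any(keep_cells) || !any(keep_genes))
    stop("quality_control: all ", if (!any(keep_cells)) "cells" else "genes",
         " removed; lower the thresholds")
  count_matrix(m$values[keep_cells, keep_genes, drop = FALSE],
               m$cell_ids[keep_cells], m$gene_ids[keep_genes], layer = "raw")
}

#' Median-library-size normalization and log transform
#'
#' Each cell's counts are scaled so its total equals the median pre-scaling
#' cell total, then `log(1 + x)` is applied elementwise.
#'
#' @param m raw-layer [count_matrix()].
#' @return a lognorm-layer [count_matrix()].
#' @export
normalize_log <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "raw")
    stop("normalize_log: expected a raw-layer matrix, got '", m$layer, "'")
  totals <- rowSums(m$values)
  if (any(totals == 0))
    stop("normalize_log: cell(s) with zero total count (run quality_control",
         " first): ", paste(m$cell_ids[totals == 0][1:min(3, sum(totals == 0))],
                            collapse = ", "))
  target <- stats::median(totals)
  v <- log1p(m$values * (target / totals))
  out <- count_matrix(v, m$cell_ids, m$gene_ids, layer = "lognorm")
  out
}

#' Select highly variable genes
#'
#' Dispersion-based ranking on log-normalized data: per-gene dispersion is
#' variance over mean; genes are cut into 20 equal-frequency bins by mean
#' expression and the dispersion is z-scored within each bin, so that highly
#' variable genes are called relative to genes of similar abundance. The
#' `n_top` genes with the highest normalized dispersion are kept (ties broken
#' by lower gene index); input gene order is preserved among the survivors.
#'
#' @param m lognorm-layer [count_matrix()].
#' @param n_top number of genes to keep; if at least the number of genes
#'   present, the input is returned unchanged (relabeled `hvg`).
#' @param n_bins number of mean-expression bins for dispersion normalization.
#' @return an hvg-layer [count_matrix()].
#' @export
select_hvg <- function(m, n_top = 3000L, n_bins = 20L) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "lognorm")
    stop("select_hvg: expected a lognorm-layer matrix, got '", m$layer, "'")
  if (n_top < 1) stop("select_hvg: n_top must be >= 1")
  p <- ncol(m$values)
  if (n_top >= p)
    return(count_matrix(m$values, m$cell_ids, m$gene_ids, layer = "hvg"))
  mu <- colMeans(m$values)
  v <- apply(m$values, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency binning by mean; bins hold >= 20 genes so the within-bin
  # z-score is stable; constant bins get z-score 0
  nb <- max(1L, min(n_bins, p %/% 20L))
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = nb, labels = FALSE, include.lowest = TRUE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    mdb <- mean(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mdb) / s
  }
  ord <- order(-z, seq_len(p))
  keep <- sort(ord[seq_len(n_top)])
  count_matrix(m$values[, keep, drop = FALSE], m$cell_ids, m$gene_ids[keep],
               layer = "hvg")
}

#' Convenience preprocessing pipeline
#'
#' Runs [quality_control()], [normalize_log()] and [select_hvg()] in that
#' order.
#'
#' @param m raw-layer [count_matrix()].
#' @param min_genes_per_cell,min_cells_per_gene QC thresholds.
#' @param n_top number of highly variable genes to keep.
#' @return an hvg-layer [count_matrix()].
#' @export
preprocess_counts <- function(m, min_genes_per_cell = 5L,
                              min_cells_per_gene = 5L, n_top = 3000L) {
  select_hvg(normalize_log(quality_control(m, min_genes_per_cell,
                                           min_cells_per_gene)),
             n_top = n_top)
}

#' Build the cosine K-nearest-neighbor cell graph
#'
#' Each cell gets directed edges to its `k` nearest other cells by cosine
#' distance (1 - cosine similarity); distance ties are broken by lower cell
#' index. The adjacency is then symmetrized by union (`A | t(A)`), so every
#' cell's chosen neighbors remain neighbors both ways; the diagonal is zero.
#'
#' @param m hvg-layer [count_matrix()] (any layer accepted; hvg intended).
#' @param k number of neighbors, `1 <= k < n`.
#' @return a [cell_graph()].
#' @export
build_knn_graph <- function(m, k = 15L) {
  x <- if (inherits(m, "count_matrix")) m$values else as.matrix(m)
  n <- nrow(x)
  if (k < 1 || k >= n)
    stop("build_knn_graph: need 1 <= k < n (k = ", k, ", n = ", n, ")")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0))
    stop("build_knn_graph: zero-norm expression vector for cell(s): ",
         paste(which(nrm == 0)[1:min(3, sum(nrm == 0))], collapse = ", "))
  u <- x / nrm
  sim <- tcrossprod(u)
  diag(sim) <- -Inf                      # never pick self
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(-sim[i, ], seq_len(n))[seq_len(k)]
    ii <- c(ii, rep.int(i, k)); jj <- c(jj, nb)
  }
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  a <- 1 * ((a + Matrix::t(a)) != 0)
  cell_graph(a, k = k, metric = "cosine")
}
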