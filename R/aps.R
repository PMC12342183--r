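#' Smooth soft labels over the cell graph
#'
#' Averages the two views' soft labels and propagates them one step over the
#' graph. With `normalize = "rw"` (default) the propagation matrix is the
#' row-stochastic random-walk normalization of `A + I`, so the smoothed rows
#' stay on the probability simplex and the argmax is a meaningful cluster
#' assignment; `normalize = "none"` applies the bare adjacency sum, which
#' scales each row by its node degree.
#'
#' @param Y1,Y2 n x M soft-label matrices.
#' @param graph [cell_graph()] (or 0/1 adjacency) over the n cells.
#' @param normalize `"rw"` or `"none"`.
#' @return n x M matrix `g` of smoothed soft labels.
#' @export
smooth_soft_labels <- function(Y1, Y2, graph, normalize = c("rw", "none")) {
  normalize <- match.arg(normalize)
  a <- as_dense_adj(graph)
  ybar <- (Y1 + Y2) / 2
  if (nrow(a) != nrow(ybar))
    stop("smooth_soft_labels: graph has ", nrow(a), " cells but Y has ",
         nrow(ybar), " rows")
  if (normalize == "rw") {
    diag(a) <- diag(a) + 1
    a <- a / rowSums(a)
  }
  a %*% ybar
}

#' Soft-label similarity adjacency
#'
#' `A_hat[i, j] = 1` iff the cosine similarity of the smoothed soft-label
#' rows of cells i and j is at least `lambda`. Symmetric by symmetry of the
#' cosine; the diagonal is 1 at any `lambda <= 1` (kept, since the final
#' adjacency is intersected with a zero-diagonal graph).
#'
#' @param g n x M matrix of smoothed soft labels with nonzero rows.
#' @param lambda similarity threshold.
#' @return dense 0/1 matrix n x n.
#' @export
soft_label_adjacency <- function(g, lambda = 0.9) {
  g <- as.matrix(g)
  nrm <- sqrt(rowSums(g^2))
  if (any(nrm == 0))
    stop("soft_label_adjacency: zero soft-label row for cell(s): ",
         paste(which(nrm == 0)[1:min(3, sum(nrm == 0))], collapse = ", "))
  u <- g / nrm
  1 * (tcrossprod(u) >= lambda)
}

#' Final adjacency for adaptive positive sampling
#'
#' Elementwise product of the expression-KNN adjacency and the soft-label
#' adjacency: an edge survives only if the cells are both expression
#' neighbors and carry similar soft labels. Always a subgraph of `A`, with
#' zero diagonal.
#'
#' @param graph [cell_graph()] or 0/1 adjacency `A`.
#' @param a_hat 0/1 matrix from [soft_label_adjacency()].
#' @return sparse symmetric 0/1 `Matrix`.
#' @export
final_adjacency <- function(graph, a_hat) {
  a <- as_dense_adj(graph)
  ah <- as_dense_adj(a_hat)
  if (any(dim(a) != dim(ah)))
    stop("final_adjacency: shape mismatch ", nrow(a), " vs ", nrow(ah))
  methods::as(Matrix::Matrix(a * ah, sparse = TRUE), "CsparseMatrix")
}

#' PPV / NPV of the adaptive positive-sampling decision
#'
#' Evaluates, over the universe of KNN-candidate pairs `{(i,j): A[i,j] = 1,
#' i < j}`, how well the filtered adjacency separates same-type from
#' different-type pairs: PPV is the fraction of kept pairs whose cells share
#' the true label, NPV the fraction of dropped pairs whose cells differ.
#' Requires ground-truth labels, so this is an evaluation-only quantity.
#'
#' @param a_final filtered adjacency (subgraph of `graph`).
#' @param graph the KNN [cell_graph()] defining the candidate pairs.
#' @param true_labels integer vector of ground-truth labels.
#' @return list with `ppv`, `npv` (either is `NA` when its denominator is
#'   empty), and the pair counts `n_pos`, `n_neg`.
#' @export
pair_sampling_quality <- function(a_final, graph, true_labels) {
  a <- as_dense_adj(graph)
  af <- as_dense_adj(a_final)
  n <- nrow(a)
  if (length(true_labels) != n)
    stop("pair_sampling_quality: ", length(true_labels), " labels for ",
         n, " cells")
  ut <- upper.tri(a)
  cand <- which(ut & a != 0)
  same <- outer(true_labels, true_labels, "==")
  kept <- af[cand] != 0
  n_pos <- sum(kept); n_neg <- sum(!kept)
  ppv <- if (n_pos > 0) mean(same[cand][kept]) else NA_real_
  npv <- if (n_neg > 0) mean(!same[cand][!kept]) else NA_real_
  list(ppv = ppv, npv = npv, n_pos = n_pos, n_neg = n_neg)
}
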