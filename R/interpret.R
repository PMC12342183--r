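#' Integrated-gradients attribution of cluster assignments
#'
#' For each cell, attributes the pre-softmax cluster-head score of its
#' assigned cluster to the input genes by integrating the gradient along the
#' straight path from a baseline expression vector to the observed one
#' (right-endpoint Riemann sum with `n_steps` steps). Only the focal cell's
#' expression row is interpolated; all other cells keep their observed
#' values, and the graph is held fixed, so neighborhood context is part of
#' the explained function. Cells whose rows may interact through attention
#' are processed in separate batches (greedy graph coloring), which makes the
#' per-cell gradients exact while sharing forward passes.
#'
#' @param fit a fitted `scgcl_fit` model.
#' @param x the hvg-layer [count_matrix()] (or matrix) the model was fitted
#'   on.
#' @param graph the [cell_graph()] used in fitting.
#' @param target_labels cluster index (1..M) explained per cell; defaults to
#'   the fitted hard labels.
#' @param n_steps number of Riemann steps (>= 1); the completeness residual
#'   shrinks as `1/n_steps`.
#' @param baseline `"zeros"` (an absent cell) or `"mean"` (the average
#'   cell).
#' @param cells optional integer subset of cells to attribute (rows of the
#'   result for other cells are zero).
#' @return n x p matrix of attributions.
#' @export
integrated_gradients <- function(fit, x, graph,
                                 target_labels = fit$hard_labels,
                                 n_steps = 50L,
                                 baseline = c("zeros", "mean"),
                                 cells = NULL) {
  baseline <- match.arg(baseline)
  if (n_steps < 1) stop("integrated_gradients: n_steps must be >= 1")
  xv <- if (inherits(x, "count_matrix")) x$values else as.matrix(x)
  n <- nrow(xv); p <- ncol(xv)
  a <- as_dense_adj(graph)
  mask <- a != 0; diag(mask) <- TRUE
  if (is.null(cells)) cells <- seq_len(n)
  b <- if (baseline == "zeros") matrix(0, n, p) else
    matrix(colMeans(xv), n, p, byrow = TRUE)

  # cells in one batch must not influence each other's outputs: for L
  # layers, that is graph distance > L; color the L-step reachability graph
  reach <- mask
  if (fit$cfg$n_layers > 1)
    for (l in seq_len(fit$cfg$n_layers - 1))
      reach <- (reach %*% mask) > 0
  colors <- greedy_coloring(reach, cells)

  grads_sum <- matrix(0, n, p)
  for (cls in unique(colors)) {
    s <- cells[colors == cls]
    dlogits <- matrix(0, n, fit$cfg$n_clusters)
    dlogits[cbind(s, target_labels[s])] <- 1
    for (t in seq_len(n_steps)) {
      xt <- xv
      xt[s, ] <- b[s, , drop = FALSE] +
        (t / n_steps) * (xv[s, , drop = FALSE] - b[s, , drop = FALSE])
      fwd <- model_fwd(xt, mask, fit$params, fit$cfg, view = 1L)
      bwd <- model_bwd(fwd, fit$params, fit$cfg, zero_grads(fit$params),
                       dlogits = dlogits)
      grads_sum[s, ] <- grads_sum[s, ] + bwd$dx[s, , drop = FALSE]
    }
  }
  ig <- (xv - b) * grads_sum / n_steps
  ig[setdiff(seq_len(n), cells), ] <- 0
  dimnames(ig) <- dimnames(xv)
  ig
}

# greedy coloring of the subgraph induced on `cells` (indices into reach)
greedy_coloring <- function(reach, cells) {
  colors <- integer(length(cells))
  for (i in seq_along(cells)) {
    nb <- cells[which(reach[cells[i], cells] & colors > 0)]
    used <- colors[match(nb, cells)]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    colors[i] <- c0
  }
  colors
}

#' Completeness check of an attribution row
#'
#' Returns the attributed total `sum(IG[i, ])`, the exact score difference
#' `F_c(x) - F_c(x with row i at baseline)`, and their relative gap. The gap
#' goes to zero as `n_steps` grows (integrated-gradients completeness
#' axiom).
#'
#' @inheritParams integrated_gradients
#' @param cell single cell index to check.
#' @return list with `attribution_sum`, `score_delta`, `relative_gap`.
#' @export
ig_completeness <- function(fit, x, graph, cell, n_steps = 200L,
                            baseline = c("zeros", "mean"),
                            target_labels = fit$hard_labels) {
  baseline <- match.arg(baseline)
  xv <- if (inherits(x, "count_matrix")) x$values else as.matrix(x)
  a <- as_dense_adj(graph)
  mask <- a != 0; diag(mask) <- TRUE
  ig <- integrated_gradients(fit, xv, graph, target_labels = target_labels,
                             n_steps = n_steps, baseline = baseline,
                             cells = cell)
  tgt <- target_labels[cell]
  f1 <- model_fwd(xv, mask, fit$params, fit$cfg)$logits[cell, tgt]
  x0 <- xv
  x0[cell, ] <- if (baseline == "zeros") 0 else colMeans(xv)
  f0 <- model_fwd(x0, mask, fit$params, fit$cfg)$logits[cell, tgt]
  s <- sum(ig[cell, ])
  list(attribution_sum = s, score_delta = f1 - f0,
       relative_gap = abs(s - (f1 - f0)) / max(abs(f1 - f0), 1e-12))
}

# right-endpoint Riemann path integral for a single input vector and a
# differentiable scalar function; used to validate the IG quadrature against
# closed forms
riemann_ig <- function(grad_fn, x, b, n_steps) {
  g <- 0
  for (t in seq_len(n_steps)) g <- g + grad_fn(b + (t / n_steps) * (x - b))
  (x - b) * g / n_steps
}

#' Rank genes by per-cluster mean attribution
#'
#' Averages attributions over the member cells of each predicted cluster and
#' ranks genes by decreasing mean attribution (ties broken by lower gene
#' index).
#'
#' @param att n x p attribution matrix from [integrated_gradients()].
#' @param hard_labels predicted cluster per cell (1..M).
#' @param gene_ids gene identifiers (defaults to `att` column names).
#' @param top_k list length per cluster.
#' @return list with `scores` (M x p matrix of mean attributions) and `top`
#'   (list of character vectors of gene ids, one per cluster; empty with a
#'   warning for empty clusters).
#' @export
rank_attributed_genes <- function(att, hard_labels, gene_ids = colnames(att),
                                  top_k = 200L) {
  m <- max(hard_labels)
  p <- ncol(att)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(p))
  scores <- matrix(0, m, p, dimnames = list(paste0("cluster", 1:m), gene_ids))
  top <- vector("list", m)
  names(top) <- rownames(scores)
  for (cl in seq_len(m)) {
    idx <- which(hard_labels == cl)
    if (length(idx) == 0) {
      warning("rank_attributed_genes: predicted cluster ", cl, " is empty")
      top[[cl]] <- character(0)
      next
    }
    scores[cl, ] <- colMeans(att[idx, , drop = FALSE])
    ord <- order(-scores[cl, ], seq_len(p))
    top[[cl]] <- gene_ids[ord[seq_len(min(top_k, p))]]
  }
  list(scores = scores, top = top)
}

#' Wilcoxon one-vs-rest marker genes
#'
#' For each group, tests every gene with a two-sided Wilcoxon rank-sum test
#' of the group's cells against all others, adjusts p-values by
#' Benjamini-Hochberg within the group, keeps genes with `q <= fdr` and log
#' fold-change (difference of group means on the log scale) `>= min_lfc`,
#' and ranks survivors by decreasing log fold-change. A stand-in for
#' Seurat-style marker detection: same test family, not numerically
#' identical output.
#'
#' @param m lognorm-layer [count_matrix()] (or matrix of log expression).
#' @param groups group label per cell (e.g. predicted or true clusters).
#' @param fdr maximum BH-adjusted q-value.
#' @param min_lfc minimum log fold-change.
#' @param top_k maximum genes reported per group.
#' @return list with `table` (data frame: group, gene, lfc, p, q) and `top`
#'   (list of character vectors per group). Groups with fewer than 2 cells
#'   are skipped with a warning.
#' @export
wilcoxon_markers <- function(m, groups, fdr = 0.01, min_lfc = 1,
                             top_k = 200L) {
  xv <- if (inherits(m, "count_matrix")) m$values else as.matrix(m)
  gene_ids <- colnames(xv)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(ncol(xv)))
  if (length(groups) != nrow(xv))
    stop("wilcoxon_markers: ", length(groups), " labels for ", nrow(xv),
         " cells")
  gl <- sort(unique(groups))
  rows <- list(); top <- list()
  for (g in gl) {
    idx <- which(groups == g)
    if (length(idx) < 2 || length(idx) > nrow(xv) - 2) {
      warning("wilcoxon_markers: group ", g, " has too few cells; skipped")
      top[[as.character(g)]] <- character(0)
      next
    }
    lfc <- colMeans(xv[idx, , drop = FALSE]) -
      colMeans(xv[-idx, , drop = FALSE])
    pv <- vapply(seq_len(ncol(xv)), function(j)
      suppressWarnings(stats::wilcox.test(xv[idx, j], xv[-idx, j],
                                          exact = FALSE)$p.value),
      numeric(1))
    pv[is.na(pv)] <- 1                  # constant genes: no evidence
    qv <- stats::p.adjust(pv, method = "BH")
    keep <- which(qv <= fdr & lfc >= min_lfc)
    keep <- keep[order(-lfc[keep], keep)]
    keep <- keep[seq_len(min(top_k, length(keep)))]
    rows[[as.character(g)]] <- data.frame(group = g, gene = gene_ids,
                                          lfc = lfc, p = pv, q = qv,
                                          row.names = NULL)
    top[[as.character(g)]] <- gene_ids[keep]
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       top = top)
}

#' Overlap counts between two families of gene lists
#'
#' Entry `(c, t)` is the number of genes shared by attribution list `c` and
#' marker list `t` — the quantity shown in overlap heatmaps comparing
#' model-attributed genes with differential-expression markers.
#'
#' @param ig_lists list of character vectors (e.g. per predicted cluster).
#' @param deg_lists list of character vectors (e.g. per true cell type).
#' @return integer matrix `length(ig_lists)` x `length(deg_lists)`.
#' @export
overlap_counts <- function(ig_lists, deg_lists) {
  out <- matrix(0L, length(ig_lists), length(deg_lists),
                dimnames = list(names(ig_lists), names(deg_lists)))
  for (i in seq_along(ig_lists))
    for (j in seq_along(deg_lists))
      out[i, j] <- length(intersect(ig_lists[[i]], deg_lists[[j]]))
  out
}
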