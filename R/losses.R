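#' Instance-level neighbor contrastive loss
#'
#' For each anchor cell in each view, the positives are its own augmentation
#' in the other view plus every graph neighbor in both views; the
#' denominator ranges over all cells of both views, including the anchor's
#' same-view self term (cosine similarity 1) unless `exclude_self = TRUE`.
#' The loss is the mean over the 2n anchors of
#' `-log(numerator / denominator)` with similarities `exp(cos / tau)`.
#' No normalization by the number of positives is applied.
#'
#' @param z1,z2 n x q instance-head embeddings of the two views.
#' @param adjacency symmetric 0/1 matrix with zero diagonal ([cell_graph()]
#'   or plain matrix); defines which cells count as positives.
#' @param tau temperature, > 0.
#' @param exclude_self drop the same-view anchor term from the denominator
#'   (the conventional variant).
#' @return scalar loss value.
#' @export
neighbor_contrastive_loss <- function(z1, z2, adjacency, tau = 0.5,
                                      exclude_self = FALSE) {
  neighbor_contrastive(z1, z2, adjacency, tau, exclude_self,
                       grad = FALSE)$value
}

# value and (optionally) gradients wrt z1, z2
neighbor_contrastive <- function(z1, z2, adjacency, tau = 0.5,
                                 exclude_self = FALSE, grad = TRUE) {
  if (tau <= 0) stop("neighbor_contrastive_loss: tau must be > 0")
  a <- as_dense_adj(adjacency)
  n <- nrow(z1)
  if (any(dim(a) != n)) stop("neighbor_contrastive_loss: adjacency is ",
                             nrow(a), "x", ncol(a), " but z has ", n, " rows")
  nrm1 <- sqrt(rowSums(z1^2)); nrm2 <- sqrt(rowSums(z2^2))
  if (any(nrm1 == 0) || any(nrm2 == 0))
    stop("neighbor_contrastive_loss: zero-norm embedding row")
  u1 <- z1 / nrm1; u2 <- z2 / nrm2
  e11 <- exp(tcrossprod(u1) / tau)       # cosines bounded: no overflow
  e22 <- exp(tcrossprod(u2) / tau)
  e12 <- exp(tcrossprod(u1, u2) / tau)
  e21 <- t(e12)
  self_w <- if (exclude_self) 0 else 1
  d11 <- diag(e11) * self_w
  d22 <- diag(e22) * self_w
  num1 <- diag(e12) + rowSums(a * (e11 + e12))
  den1 <- rowSums(e11) - diag(e11) + d11 + rowSums(e12)
  num2 <- diag(e21) + rowSums(a * (e22 + e21))
  den2 <- rowSums(e22) - diag(e22) + d22 + rowSums(e21)
  value <- mean(c(-log(num1 / den1), -log(num2 / den2)))
  if (!grad) return(list(value = value))

  c0 <- 1 / (2 * n * tau)
  # anchor view 1: d l1_i / d e11[i,j], e12[i,j]
  g11 <- c0 * (-(a / num1) * e11 + (e11 / den1))
  if (exclude_self) diag(g11) <- 0
  g12 <- c0 * (-(a + diag(n)) / num1 * e12 + e12 / den1)
  # anchor view 2
  g22 <- c0 * (-(a / num2) * e22 + (e22 / den2))
  if (exclude_self) diag(g22) <- 0
  g21 <- c0 * (-(a + diag(n)) / num2 * e21 + e21 / den2)
  # chain through the exp and the cosine products
  du1 <- (g11 + t(g11)) %*% u1 + g12 %*% u2 + crossprod(g21, u2)
  du2 <- (g22 + t(g22)) %*% u2 + g21 %*% u1 + crossprod(g12, u1)
  dz1 <- (du1 - u1 * rowSums(du1 * u1)) / nrm1
  dz2 <- (du2 - u2 * rowSums(du2 * u2)) / nrm2
  list(value = value, dz1 = dz1, dz2 = dz2)
}

#' Cluster-level assignment contrastive loss
#'
#' Contrasts the M cluster representations, taken as the columns of the
#' soft-label matrices: for cluster m the positive pair is its own column in
#' the other view, the denominator sums over all M columns of both views
#' (including the same-view self term unless `exclude_self = TRUE`). The
#' value is the mean of `-log` ratios over the 2M cluster anchors; the
#' entropy regularizer is added separately by [combine_losses()].
#'
#' @param Y1,Y2 n x M soft-label matrices (rows on the simplex).
#' @param tau temperature, > 0.
#' @param exclude_self drop the same-view self column from the denominator.
#' @return scalar loss value.
#' @export
cluster_contrastive_loss <- function(Y1, Y2, tau = 0.5,
                                     exclude_self = FALSE) {
  cluster_contrastive(Y1, Y2, tau, exclude_self, grad = FALSE)$value
}

cluster_contrastive <- function(Y1, Y2, tau = 0.5, exclude_self = FALSE,
                                grad = TRUE) {
  if (tau <= 0) stop("cluster_contrastive_loss: tau must be > 0")
  m <- ncol(Y1)
  cn1 <- sqrt(colSums(Y1^2)); cn2 <- sqrt(colSums(Y2^2))
  if (any(cn1 == 0) || any(cn2 == 0))
    stop("cluster_contrastive_loss: empty cluster column; the entropy ",
         "regularizer should prevent this")
  v1 <- sweep(Y1, 2, cn1, "/"); v2 <- sweep(Y2, 2, cn2, "/")
  e11 <- exp(crossprod(v1) / tau)        # M x M over column vectors
  e22 <- exp(crossprod(v2) / tau)
  e12 <- exp(crossprod(v1, v2) / tau)
  e21 <- t(e12)
  self_w <- if (exclude_self) 0 else 1
  num1 <- diag(e12)
  den1 <- rowSums(e11) - diag(e11) + diag(e11) * self_w + rowSums(e12)
  num2 <- diag(e21)
  den2 <- rowSums(e22) - diag(e22) + diag(e22) * self_w + rowSums(e21)
  value <- mean(c(-log(num1 / den1), -log(num2 / den2)))
  if (!grad) return(list(value = value))

  c0 <- 1 / (2 * m * tau)
  g11 <- c0 * e11 / den1
  if (exclude_self) diag(g11) <- 0
  g12 <- c0 * (e12 / den1); diag(g12) <- diag(g12) - c0 * diag(e12) / num1
  g22 <- c0 * e22 / den2
  if (exclude_self) diag(g22) <- 0
  g21 <- c0 * (e21 / den2); diag(g21) <- diag(g21) - c0 * diag(e21) / num2
  dv1 <- v1 %*% (g11 + t(g11)) + v2 %*% t(g12) + v2 %*% g21
  dv2 <- v2 %*% (g22 + t(g22)) + v1 %*% t(g21) + v1 %*% g12
  dY1 <- sweep(dv1 - sweep(v1, 2, colSums(dv1 * v1), "*"), 2, cn1, "/")
  dY2 <- sweep(dv2 - sweep(v2, 2, colSums(dv2 * v2), "*"), 2, cn2, "/")
  list(value = value, dY1 = dY1, dY2 = dY2)
}

#' Cluster-balance entropy regularizer
#'
#' Penalizes degenerate solutions that put most cells into one cluster.
#' Under the default per-view convention the M cluster masses (column sums)
#' of each view are normalized within the view, the entropy of each view's
#' mass distribution is averaged across views, and the value is
#' `log(M) - H`: zero at perfectly uniform masses, `log(M)` when all mass
#' sits in a single cluster. With `joint_views = TRUE` the literal variant
#' normalizing the 2M masses of both views jointly is used (its value can
#' go negative at uniformity since the entropy is then bounded by
#' `log(2M)`).
#'
#' @param Y1,Y2 n x M soft-label matrices.
#' @param joint_views use the joint-2M normalization variant.
#' @return scalar regularizer value (in `[0, log M]` for the default
#'   convention).
#' @export
cluster_entropy_reg <- function(Y1, Y2, joint_views = FALSE) {
  cluster_entropy(Y1, Y2, joint_views, grad = FALSE)$value
}

cluster_entropy <- function(Y1, Y2, joint_views = FALSE, grad = TRUE) {
  m <- ncol(Y1)
  if (any(Y1 < 0) || any(Y2 < 0))
    stop("cluster_entropy_reg: soft labels must be non-negative")
  if (sum(Y1) == 0 || sum(Y2) == 0)
    stop("cluster_entropy_reg: all-zero soft-label matrix")
  plogp <- function(p) ifelse(p > 0, p * log(p), 0)
  if (joint_views) {
    s <- c(colSums(Y1), colSums(Y2))
    p <- s / sum(s)
    value <- log(m) + sum(plogp(p))
    if (!grad) return(list(value = value))
    dH_ds <- (-(ifelse(p > 0, log(p), 0) + 1) -
                sum(-(ifelse(p > 0, log(p), 0) + 1) * p)) / sum(s)
    dreg <- -dH_ds
    dY1 <- matrix(dreg[seq_len(m)], nrow(Y1), m, byrow = TRUE)
    dY2 <- matrix(dreg[m + seq_len(m)], nrow(Y2), m, byrow = TRUE)
  } else {
    val <- 0; dY1 <- NULL; dY2 <- NULL
    for (vw in 1:2) {
      Y <- if (vw == 1) Y1 else Y2
      s <- colSums(Y)
      tot <- sum(s)
      p <- s / tot
      val <- val + (log(m) + sum(plogp(p))) / 2
      if (grad) {
        lp <- ifelse(p > 0, log(p), 0)
        # d(-H)/ds_j where H = -sum p log p, p = s/tot
        dreg_ds <- ((lp + 1) - sum((lp + 1) * p)) / tot / 2
        dY <- matrix(dreg_ds, nrow(Y), m, byrow = TRUE)
        if (vw == 1) dY1 <- dY else dY2 <- dY
      }
    }
    value <- val
    if (!grad) return(list(value = value))
  }
  list(value = value, dY1 = dY1, dY2 = dY2)
}

#' Combine the loss components
#'
#' The cluster-level loss is the assignment contrastive term plus the
#' entropy regularizer; the total is the convex combination
#' `alpha * L_ins + (1 - alpha) * L_cls`.
#'
#' @param l_ins instance-level loss value.
#' @param l_cls_contrast cluster-level contrastive term.
#' @param l_reg entropy regularizer value.
#' @param alpha weight in `[0, 1]` on the instance-level term.
#' @return list with `l_ins`, `l_cls`, `l_reg`, `l_total`, `alpha`.
#' @export
combine_losses <- function(l_ins, l_cls_contrast, l_reg, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("combine_losses: alpha must be in [0, 1]")
  l_cls <- l_cls_contrast + l_reg
  list(l_ins = l_ins, l_cls = l_cls, l_reg = l_reg,
       l_total = alpha * l_ins + (1 - alpha) * l_cls, alpha = alpha)
}
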