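#' Adjusted Rand index
#'
#' Permutation-model-adjusted Rand index computed from the contingency
#' table; 1 for identical partitions (up to relabeling), about 0 for
#' independent ones.
#'
#' @param truth,pred label vectors of equal length (any integer or factor
#'   coding; no contiguity assumed).
#' @return scalar in `[-1, 1]`.
#' @export
ari <- function(truth, pred) {
  ct <- check_label_pair(truth, pred)
  n <- sum(ct)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(ct))
  sum_a <- sum(choose2(rowSums(ct)))
  sum_b <- sum(choose2(colSums(ct)))
  exp_idx <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)       # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Normalized mutual information
#'
#' Mutual information of the two partitions normalized by the arithmetic
#' mean of their entropies (default) or the geometric mean.
#'
#' @inheritParams ari
#' @param normalization `"arithmetic"` or `"geometric"` mean of the two
#'   entropies.
#' @return scalar in `[0, 1]`; 0 (with a warning) when either partition has
#'   a single cluster.
#' @export
nmi <- function(truth, pred, normalization = c("arithmetic", "geometric")) {
  normalization <- match.arg(normalization)
  ct <- check_label_pair(truth, pred)
  n <- sum(ct)
  p <- ct / n
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hy <- -sum(ifelse(py > 0, py * log(py), 0))
  if (hx == 0 || hy == 0) {
    warning("nmi: a partition has a single cluster; returning 0")
    return(0)
  }
  outer_p <- outer(px, py)
  mi <- sum(ifelse(p > 0, p * log(p / outer_p), 0))
  norm <- if (normalization == "arithmetic") (hx + hy) / 2 else sqrt(hx * hy)
  mi / norm
}

#' Clustering accuracy under optimal cluster matching
#'
#' Maximum fraction of agreeing labels over all one-to-one mappings between
#' predicted and true cluster ids, solved by Hungarian assignment on the
#' contingency table (padded with zeros when the cluster counts differ).
#'
#' @inheritParams ari
#' @return scalar in `(0, 1]`.
#' @export
acc <- function(truth, pred) {
  ct <- check_label_pair(truth, pred)
  k <- max(dim(ct))
  padded <- matrix(0, k, k)
  padded[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  assignment <- hungarian_max(padded)
  sum(padded[cbind(seq_len(k), assignment)]) / sum(ct)
}

#' All three agreement metrics at once
#'
#' @inheritParams ari
#' @return list with `ari`, `nmi`, `acc`.
#' @export
cluster_metrics <- function(truth, pred) {
  list(ari = ari(truth, pred), nmi = nmi(truth, pred),
       acc = acc(truth, pred))
}

check_label_pair <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors differ in length: ", length(truth), " vs ",
         length(pred))
  if (length(truth) < 2) stop("need at least 2 observations")
  table(factor(truth), factor(pred))
}

# Maximum-weight perfect matching on a square non-negative matrix via the
# Jonker-Volgenant shortest augmenting path algorithm (O(k^3)) on the
# minimization form. Returns for each row the assigned column.
hungarian_max <- function(w) {
  k <- nrow(w)
  cost <- max(w) - w                     # maximize -> minimize
  u <- numeric(k + 1); v <- numeric(k + 1)
  p <- integer(k + 1)                    # p[j]: row matched to column j
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(k) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(k + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_col <- integer(k)
  for (j in seq_len(k) + 1L) if (p[j] > 0) match_col[p[j]] <- j - 1L
  match_col
}
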