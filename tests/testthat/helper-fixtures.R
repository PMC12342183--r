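# Shared fixtures and independent oracles. Expensive objects are memoized so
# several test files can reuse one small trained model.

.scgcl_test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .scgcl_test_cache))
    assign(key, expr, envir = .scgcl_test_cache)
  get(key, envir = .scgcl_test_cache)
}

small_sim <- function() memo("small_sim",
  simulate_counts(n_cells = 150, n_genes = 120, n_clusters = 3,
                  markers_per_cluster = 12, lfc = 2.5, dropout_rate = 0.2,
                  seed = 11))

small_pp <- function() memo("small_pp", preprocess_counts(small_sim()$counts))

small_graph <- function() memo("small_graph",
                               build_knn_graph(small_pp(), k = 10))

small_fit <- function() memo("small_fit",
  fit_scgcl(small_pp(), small_graph(), 3,
            opts = scgcl_config(max_epochs = 80), seed = 1))

# random symmetric 0/1 adjacency with zero diagonal
rand_adj <- function(n, p = 0.3) {
  a <- matrix(stats::rbinom(n * n, 1, p), n, n)
  a <- 1 * ((a + t(a)) > 0)
  diag(a) <- 0
  a
}

# Literal double-loop transcription of the neighbor contrastive loss:
# independent of the vectorized implementation.
oracle_neighbor_loss <- function(z1, z2, a, tau) {
  n <- nrow(z1)
  cs <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  total <- 0
  for (view in 1:2) {
    za <- if (view == 1) z1 else z2
    zb <- if (view == 1) z2 else z1
    for (i in 1:n) {
      num <- exp(cs(za[i, ], zb[i, ]) / tau)
      for (j in 1:n) if (a[i, j] == 1)
        num <- num + exp(cs(za[i, ], za[j, ]) / tau) +
          exp(cs(za[i, ], zb[j, ]) / tau)
      den <- 0
      for (k in 1:n)
        den <- den + exp(cs(za[i, ], za[k, ]) / tau) +
          exp(cs(za[i, ], zb[k, ]) / tau)
      total <- total - log(num / den)
    }
  }
  total / (2 * n)
}

# Literal transcription of the assignment contrastive loss over columns.
oracle_cluster_loss <- function(Y1, Y2, tau) {
  m <- ncol(Y1)
  cs <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  total <- 0
  for (view in 1:2) {
    ya <- if (view == 1) Y1 else Y2
    yb <- if (view == 1) Y2 else Y1
    for (i in 1:m) {
      num <- exp(cs(ya[, i], yb[, i]) / tau)
      den <- 0
      for (j in 1:m)
        den <- den + exp(cs(ya[, i], ya[, j]) / tau) +
          exp(cs(ya[, i], yb[, j]) / tau)
      total <- total - log(num / den)
    }
  }
  total / (2 * m)
}

# Per-view entropy-gap transcription (the package's default convention).
oracle_entropy_reg <- function(Y1, Y2) {
  m <- ncol(Y1)
  h <- function(Y) {
    p <- colSums(Y) / sum(Y)
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  log(m) - (h(Y1) + h(Y2)) / 2
}

# Pair-counting Rand index oracle, O(n^2).
oracle_ari_pairs <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c <- d <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1 else if (st && !sp) c <- c + 1
    else if (!st && sp) d <- d + 1 else b <- b + 1
  }
  tot <- a + b + c + d
  exp_a <- (a + c) * (a + d) / tot
  max_a <- ((a + c) + (a + d)) / 2
  (a - exp_a) / (max_a - exp_a)
}

# Exhaustive assignment oracle for clustering accuracy (small label sets).
oracle_acc_perm <- function(truth, pred) {
  tl <- sort(unique(truth)); pl <- sort(unique(pred))
  k <- max(length(tl), length(pl))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (pm in perms(seq_len(k))) {
    hits <- 0
    for (i in seq_along(truth)) {
      pi <- match(pred[i], pl)
      ti <- match(truth[i], tl)
      if (!is.na(ti) && pm[pi] == ti) hits <- hits + 1
    }
    best <- max(best, hits)
  }
  best / length(truth)
}

fd_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
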