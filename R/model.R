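#' Encoder configuration
#'
#' Architecture of the graph-transformer encoder and its two projection
#' heads. Defaults follow the method's standard regime: a single attention
#' layer with four heads, 32-dimensional embeddings, feed-forward hidden
#' width `2 * embed_dim`.
#'
#' @param input_dim number of genes fed to the encoder.
#' @param n_clusters number of clusters M (output width of the cluster head).
#' @param embed_dim encoder embedding width d; must be divisible by
#'   `n_heads`.
#' @param n_heads number of attention heads.
#' @param n_layers number of graph-transformer layers.
#' @param instance_dim output width of the instance-level head.
#' @param tied_encoders if `TRUE` (default) the two views share one encoder
#'   (Siamese); if `FALSE` each view gets an independent parameter copy.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(input_dim, n_clusters, embed_dim = 32L,
                           n_heads = 4L, n_layers = 1L, instance_dim = 32L,
                           tied_encoders = TRUE) {
  if (embed_dim %% n_heads != 0)
    stop("encoder_config: embed_dim must be divisible by n_heads")
  if (n_clusters < 2) stop("encoder_config: n_clusters must be >= 2")
  if (min(input_dim, embed_dim, n_heads, n_layers, instance_dim) < 1)
    stop("encoder_config: all dimensions must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 n_clusters = as.integer(n_clusters),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 instance_dim = as.integer(instance_dim),
                 head_dim = as.integer(embed_dim / n_heads),
                 ffn_hidden = as.integer(2L * embed_dim),
                 tied_encoders = isTRUE(tied_encoders)),
            class = "encoder_config")
}

# fan-in uniform init for a fan_in x fan_out weight matrix
init_w <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

encoder_param_block <- function(cfg, prefix) {
  d <- cfg$embed_dim; f <- cfg$ffn_hidden
  pr <- list()
  pr[[paste0(prefix, "w_in")]] <- init_w(cfg$input_dim, d)
  pr[[paste0(prefix, "b_in")]] <- numeric(d)
  for (l in seq_len(cfg$n_layers)) {
    lp <- paste0(prefix, "l", l, "_")
    pr[[paste0(lp, "wq")]] <- init_w(d, d)
    pr[[paste0(lp, "wk")]] <- init_w(d, d)
    pr[[paste0(lp, "wv")]] <- init_w(d, d)
    pr[[paste0(lp, "wo")]] <- init_w(d, d)
    pr[[paste0(lp, "ln1_g")]] <- rep(1, d)
    pr[[paste0(lp, "ln1_b")]] <- numeric(d)
    pr[[paste0(lp, "w1")]] <- init_w(d, f)
    pr[[paste0(lp, "bf1")]] <- numeric(f)
    pr[[paste0(lp, "w2")]] <- init_w(f, d)
    pr[[paste0(lp, "bf2")]] <- numeric(d)
    pr[[paste0(lp, "ln2_g")]] <- rep(1, d)
    pr[[paste0(lp, "ln2_b")]] <- numeric(d)
  }
  pr
}

#' Initialize model parameters
#'
#' Fan-in uniform initialization for all weight matrices, zeros for biases,
#' unit gain / zero shift for the layer norms; deterministic given `seed`.
#'
#' @param cfg an [encoder_config()].
#' @param seed integer seed.
#' @return flat named list of parameter arrays.
#' @export
init_params <- function(cfg, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  d <- cfg$embed_dim
  pr <- encoder_param_block(cfg, "enc_")
  if (!cfg$tied_encoders) pr <- c(pr, encoder_param_block(cfg, "enc2_"))
  pr[["ins_w1"]] <- init_w(d, d);   pr[["ins_b1"]] <- numeric(d)
  pr[["ins_w2"]] <- init_w(d, cfg$instance_dim)
  pr[["ins_b2"]] <- numeric(cfg$instance_dim)
  pr[["cls_w1"]] <- init_w(d, d);   pr[["cls_b1"]] <- numeric(d)
  pr[["cls_w2"]] <- init_w(d, cfg$n_clusters)
  pr[["cls_b2"]] <- numeric(cfg$n_clusters)
  pr
}

row_softmax <- function(s) {
  mx <- apply(s, 1, max)
  e <- exp(s - mx)
  e / rowSums(e)
}

add_rowvec <- function(x, b) sweep(x, 2, b, "+")

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = add_rowvec(sweep(xhat, 2, g, "*"), b), xhat = xhat, inv = inv,
       g = g)
}

layernorm_bwd <- function(cache, dy) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, cache$g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# attention mask with self-loops: dense logical n x n
attn_mask <- function(adjacency) {
  a <- as_dense_adj(adjacency) != 0
  diag(a) <- TRUE
  a
}

# Forward pass of one graph-transformer layer. pr is the flat param list,
# lp the "enc_l1_" style prefix, mask the dense self-looped logical
# adjacency. Returns output and everything needed for the backward pass.
gt_layer_fwd <- function(h, mask, pr, lp, cfg) {
  d <- cfg$embed_dim; dk <- cfg$head_dim; H <- cfg$n_heads
  q <- h %*% pr[[paste0(lp, "wq")]]
  k <- h %*% pr[[paste0(lp, "wk")]]
  v <- h %*% pr[[paste0(lp, "wv")]]
  conc <- matrix(0, nrow(h), d)
  wlist <- vector("list", H)
  for (hd in seq_len(H)) {
    idx <- ((hd - 1) * dk + 1):(hd * dk)
    s <- tcrossprod(q[, idx, drop = FALSE], k[, idx, drop = FALSE]) / sqrt(dk)
    s[!mask] <- -Inf
    w <- row_softmax(s)
    wlist[[hd]] <- w
    conc[, idx] <- w %*% v[, idx, drop = FALSE]
  }
  hhat <- conc %*% pr[[paste0(lp, "wo")]]
  ln1 <- layernorm_fwd(h + hhat, pr[[paste0(lp, "ln1_g")]],
                       pr[[paste0(lp, "ln1_b")]])
  a <- add_rowvec(ln1$y %*% pr[[paste0(lp, "w1")]], pr[[paste0(lp, "bf1")]])
  r <- pmax(a, 0)
  hbar <- add_rowvec(r %*% pr[[paste0(lp, "w2")]], pr[[paste0(lp, "bf2")]])
  ln2 <- layernorm_fwd(ln1$y + hbar, pr[[paste0(lp, "ln2_g")]],
                       pr[[paste0(lp, "ln2_b")]])
  list(y = ln2$y, h = h, q = q, k = k, v = v, conc = conc, wlist = wlist,
       ln1 = ln1, a = a, r = r, ln2 = ln2)
}

gt_layer_bwd <- function(cache, dy, pr, lp, cfg, grads) {
  d <- cfg$embed_dim; dk <- cfg$head_dim; H <- cfg$n_heads
  b2 <- layernorm_bwd(cache$ln2, dy)
  grads[[paste0(lp, "ln2_g")]] <- grads[[paste0(lp, "ln2_g")]] + b2$dg
  grads[[paste0(lp, "ln2_b")]] <- grads[[paste0(lp, "ln2_b")]] + b2$db
  dhbar <- b2$dx
  dhtilde <- b2$dx
  grads[[paste0(lp, "w2")]] <- grads[[paste0(lp, "w2")]] +
    crossprod(cache$r, dhbar)
  grads[[paste0(lp, "bf2")]] <- grads[[paste0(lp, "bf2")]] + colSums(dhbar)
  dr <- tcrossprod(dhbar, pr[[paste0(lp, "w2")]])
  da <- dr * (cache$a > 0)
  grads[[paste0(lp, "w1")]] <- grads[[paste0(lp, "w1")]] +
    crossprod(cache$ln1$y, da)
  grads[[paste0(lp, "bf1")]] <- grads[[paste0(lp, "bf1")]] + colSums(da)
  dhtilde <- dhtilde + tcrossprod(da, pr[[paste0(lp, "w1")]])
  b1 <- layernorm_bwd(cache$ln1, dhtilde)
  grads[[paste0(lp, "ln1_g")]] <- grads[[paste0(lp, "ln1_g")]] + b1$dg
  grads[[paste0(lp, "ln1_b")]] <- grads[[paste0(lp, "ln1_b")]] + b1$db
  dh <- b1$dx                       # residual into h
  dhhat <- b1$dx
  grads[[paste0(lp, "wo")]] <- grads[[paste0(lp, "wo")]] +
    crossprod(cache$conc, dhhat)
  dconc <- tcrossprod(dhhat, pr[[paste0(lp, "wo")]])
  dq <- matrix(0, nrow(dy), d); dk_ <- matrix(0, nrow(dy), d)
  dv <- matrix(0, nrow(dy), d)
  for (hd in seq_len(H)) {
    idx <- ((hd - 1) * dk + 1):(hd * dk)
    w <- cache$wlist[[hd]]
    dhead <- dconc[, idx, drop = FALSE]
    dw <- tcrossprod(dhead, cache$v[, idx, drop = FALSE])
    dv[, idx] <- crossprod(w, dhead)
    ds <- w * (dw - rowSums(dw * w))
    dq[, idx] <- (ds %*% cache$k[, idx, drop = FALSE]) / sqrt(dk)
    dk_[, idx] <- (crossprod(ds, cache$q[, idx, drop = FALSE])) / sqrt(dk)
  }
  grads[[paste0(lp, "wq")]] <- grads[[paste0(lp, "wq")]] +
    crossprod(cache$h, dq)
  grads[[paste0(lp, "wk")]] <- grads[[paste0(lp, "wk")]] +
    crossprod(cache$h, dk_)
  grads[[paste0(lp, "wv")]] <- grads[[paste0(lp, "wv")]] +
    crossprod(cache$h, dv)
  dh <- dh + tcrossprod(dq, pr[[paste0(lp, "wq")]]) +
    tcrossprod(dk_, pr[[paste0(lp, "wk")]]) +
    tcrossprod(dv, pr[[paste0(lp, "wv")]])
  list(dh = dh, grads = grads)
}

encoder_fwd <- function(x, mask, pr, cfg, prefix = "enc_") {
  h <- add_rowvec(x %*% pr[[paste0(prefix, "w_in")]],
                  pr[[paste0(prefix, "b_in")]])
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    caches[[l]] <- gt_layer_fwd(h, mask, pr, paste0(prefix, "l", l, "_"), cfg)
    h <- caches[[l]]$y
  }
  list(h = h, caches = caches, x = x, prefix = prefix)
}

encoder_bwd <- function(fwd, dh, pr, cfg, grads) {
  prefix <- fwd$prefix
  for (l in rev(seq_len(cfg$n_layers))) {
    r <- gt_layer_bwd(fwd$caches[[l]], dh, pr, paste0(prefix, "l", l, "_"),
                      cfg, grads)
    dh <- r$dh; grads <- r$grads
  }
  grads[[paste0(prefix, "w_in")]] <- grads[[paste0(prefix, "w_in")]] +
    crossprod(fwd$x, dh)
  grads[[paste0(prefix, "b_in")]] <- grads[[paste0(prefix, "b_in")]] +
    colSums(dh)
  dx <- tcrossprod(dh, pr[[paste0(prefix, "w_in")]])
  list(dx = dx, grads = grads)
}

mlp_head_fwd <- function(h, pr, prefix, softmax = FALSE) {
  a <- add_rowvec(h %*% pr[[paste0(prefix, "w1")]], pr[[paste0(prefix, "b1")]])
  r <- pmax(a, 0)
  out <- add_rowvec(r %*% pr[[paste0(prefix, "w2")]],
                    pr[[paste0(prefix, "b2")]])
  y <- if (softmax) row_softmax(out) else out
  list(y = y, logits = out, a = a, r = r, h = h)
}

# dy: grad wrt post-softmax output (or NULL); dlogits: grad wrt pre-softmax
mlp_head_bwd <- function(cache, dy, pr, prefix, grads, softmax = FALSE,
                         dlogits = NULL) {
  if (softmax && !is.null(dy)) {
    y <- cache$y
    dl <- y * (dy - rowSums(dy * y))
  } else dl <- if (is.null(dy)) 0 else dy
  if (!is.null(dlogits)) dl <- dl + dlogits
  grads[[paste0(prefix, "w2")]] <- grads[[paste0(prefix, "w2")]] +
    crossprod(cache$r, dl)
  grads[[paste0(prefix, "b2")]] <- grads[[paste0(prefix, "b2")]] + colSums(dl)
  dr <- tcrossprod(dl, pr[[paste0(prefix, "w2")]])
  da <- dr * (cache$a > 0)
  grads[[paste0(prefix, "w1")]] <- grads[[paste0(prefix, "w1")]] +
    crossprod(cache$h, da)
  grads[[paste0(prefix, "b1")]] <- grads[[paste0(prefix, "b1")]] + colSums(da)
  list(dh = tcrossprod(da, pr[[paste0(prefix, "w1")]]), grads = grads)
}

# full forward for one view; view 2 uses the second encoder copy when untied
model_fwd <- function(x, mask, pr, cfg, view = 1L) {
  prefix <- if (view == 2L && !cfg$tied_encoders) "enc2_" else "enc_"
  enc <- encoder_fwd(x, mask, pr, cfg, prefix)
  ins <- mlp_head_fwd(enc$h, pr, "ins_")
  cls <- mlp_head_fwd(enc$h, pr, "cls_", softmax = TRUE)
  list(h = enc$h, z = ins$y, Y = cls$y, logits = cls$logits,
       enc = enc, ins = ins, cls = cls)
}

zero_grads <- function(pr) lapply(pr, function(p) p * 0)

# backward for one view, accumulating into grads; returns grads and dx
model_bwd <- function(fwd, pr, cfg, grads, dz = NULL, dY = NULL,
                      dlogits = NULL) {
  dh <- 0
  if (!is.null(dz)) {
    r <- mlp_head_bwd(fwd$ins, dz, pr, "ins_", grads)
    dh <- dh + r$dh; grads <- r$grads
  }
  if (!is.null(dY) || !is.null(dlogits)) {
    r <- mlp_head_bwd(fwd$cls, dY, pr, "cls_", grads, softmax = TRUE,
                      dlogits = dlogits)
    dh <- dh + r$dh; grads <- r$grads
  }
  if (is.matrix(dh)) {
    r <- encoder_bwd(fwd$enc, dh, pr, cfg, grads)
    list(dx = r$dx, grads = r$grads)
  } else list(dx = NULL, grads = grads)
}

#' Apply one graph-transformer layer
#'
#' Multi-head scaled-dot-product attention over each node's graph
#' neighborhood plus itself (self-loops are added internally so the softmax
#' is defined for every node), followed by residual + layer norm, a
#' position-wise feed-forward block, and a second residual + layer norm.
#'
#' @param h numeric matrix n x d of node embeddings.
#' @param graph a [cell_graph()] (or 0/1 adjacency) over the n nodes.
#' @param params flat named parameter list containing the `l<layer>_`-
#'   prefixed tensors, e.g. from [init_params()].
#' @param cfg an [encoder_config()].
#' @param layer which layer's parameters to use.
#' @param prefix parameter name prefix (default the shared encoder).
#' @return numeric matrix n x d.
#' @export
graph_attention_layer <- function(h, graph, params, cfg, layer = 1L,
                                  prefix = "enc_") {
  mask <- attn_mask(graph)
  gt_layer_fwd(h, mask, params, paste0(prefix, "l", layer, "_"), cfg)$y
}

#' Per-head attention weight matrices
#'
#' Returns the row-stochastic attention weights of one layer, one n x n
#' matrix per head; rows sum to one over each node's neighborhood plus
#' itself.
#'
#' @inheritParams graph_attention_layer
#' @return list of `n_heads` matrices.
#' @export
attention_weights <- function(h, graph, params, cfg, layer = 1L,
                              prefix = "enc_") {
  mask <- attn_mask(graph)
  gt_layer_fwd(h, mask, params, paste0(prefix, "l", layer, "_"),
               cfg)$wlist
}

#' Encode two augmented views
#'
#' Runs both views through the encoder(s) and the two heads, returning the
#' dual embeddings: encoder outputs `h1`, `h2`, instance-head projections
#' `z1`, `z2`, and cluster-head soft labels `Y1`, `Y2` (rows on the
#' probability simplex).
#'
#' @param views list with `view1`, `view2` as from [make_views()].
#' @param graph a [cell_graph()] over the cells.
#' @param cfg an [encoder_config()].
#' @param params parameters from [init_params()] or a fitted model.
#' @return list with `h1`, `h2`, `z1`, `z2`, `Y1`, `Y2`.
#' @export
encode <- function(views, graph, cfg, params) {
  mask <- attn_mask(graph)
  if (nrow(views$view1) != nrow(mask))
    stop("encode: views have ", nrow(views$view1), " rows but graph has ",
         nrow(mask), " cells")
  f1 <- model_fwd(views$view1, mask, params, cfg, view = 1L)
  f2 <- model_fwd(views$view2, mask, params, cfg, view = 2L)
  list(h1 = f1$h, h2 = f2$h, z1 = f1$z, z2 = f2$z, Y1 = f1$Y, Y2 = f2$Y)
}

adam_init <- function(pr) {
  list(m = lapply(pr, function(p) p * 0),
       v = lapply(pr, function(p) p * 0), t = 0L)
}

adam_step <- function(pr, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(pr)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    pr[[nm]] <- pr[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = pr, state = st)
}
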