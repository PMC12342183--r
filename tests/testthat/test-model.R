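tiny_setup <- function(n = 6, p = 8, d = 8, heads = 2, m = 3, seed = 3) {
  set.seed(seed)
  x <- matrix(abs(rnorm(n * p)), n)
  a <- rand_adj(n, 0.4)
  cfg <- encoder_config(p, n_clusters = m, embed_dim = d, n_heads = heads,
                        instance_dim = 5)
  list(x = x, a = a, g = cell_graph(a), cfg = cfg,
       pr = init_params(cfg, seed = seed))
}

test_that("attention weights are row-stochastic over neighborhood + self", {
  s <- tiny_setup(n = 10)
  h <- matrix(rnorm(10 * 8), 10)
  wl <- attention_weights(h, s$g, s$pr, s$cfg)
  expect_length(wl, 2)
  for (w in wl) {
    expect_equal(rowSums(w), rep(1, 10), tolerance = 1e-6)
    # support is exactly the neighborhood plus self
    supp <- s$a; diag(supp) <- 1
    expect_true(all(w[supp == 0] == 0))
  }
})

test_that("zero query/key weights give uniform attention", {
  s <- tiny_setup()
  s$pr$enc_l1_wq[] <- 0
  s$pr$enc_l1_wk[] <- 0
  h <- matrix(rnorm(6 * 8), 6)
  w <- attention_weights(h, s$g, s$pr, s$cfg)[[1]]
  deg <- rowSums(s$a) + 1
  for (i in 1:6) {
    nz <- w[i, w[i, ] > 0]
    expect_equal(nz, rep(1 / deg[i], deg[i]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a single self-looped node reproduces the hand-computed layer", {
  # one node, d = 4, one head: attention weight is 1, so the layer is
  # Norm(h + (V h) O) -> FFN -> Norm(residual + FFN), computable by hand
  cfg <- encoder_config(4, n_clusters = 2, embed_dim = 4, n_heads = 1)
  pr <- init_params(cfg, seed = 1)
  pr$enc_l1_wo <- diag(4)
  pr$enc_l1_w1[] <- 0; pr$enc_l1_w2[] <- 0      # zeroed FFN
  h <- matrix(c(0.5, -1, 2, 0.25), 1, 4)
  g <- cell_graph(matrix(0, 1, 1))
  out <- graph_attention_layer(h, g, pr, cfg)
  t1 <- h + h %*% pr$enc_l1_wv                  # w = 1, O = I
  ln <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  expect_equal(as.vector(out), ln(ln(as.vector(t1))), tolerance = 1e-10)
})

test_that("encode is permutation-equivariant and simplex-valued", {
  s <- tiny_setup(n = 8, seed = 5)
  views <- make_views(s$x, 0, seed = 1)
  e <- encode(views, s$g, s$cfg, s$pr)
  expect_equal(rowSums(e$Y1), rep(1, 8), tolerance = 1e-9)
  expect_identical(e$h1, e$h2)                  # mask 0 + tied weights
  perm <- sample(8)
  gp <- cell_graph(s$a[perm, perm])
  vp <- make_views(s$x[perm, ], 0, seed = 1)
  ep <- encode(vp, gp, s$cfg, s$pr)
  expect_equal(ep$h1, e$h1[perm, ], tolerance = 1e-10)
  expect_equal(ep$Y1, e$Y1[perm, ], tolerance = 1e-10)
  expect_error(encode(make_views(s$x[1:3, ], 0, 1), s$g, s$cfg, s$pr),
               "rows")
})

test_that("a one-layer encoder only sees one-hop neighborhoods", {
  s <- tiny_setup(n = 7, seed = 7)
  # build a path graph 1-2-3-4-5-6-7: node 1 is at distance >= 2 from 3..7
  a <- matrix(0, 7, 7)
  for (i in 1:6) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
  g <- cell_graph(a)
  v <- make_views(s$x, 0, seed = 1)
  e1 <- encode(v, g, s$cfg, s$pr)
  x2 <- s$x; x2[5, ] <- x2[5, ] * 3 + 1          # perturb a far node
  e2 <- encode(make_views(x2, 0, seed = 1), g, s$cfg, s$pr)
  expect_equal(e1$h1[1:3, ], e2$h1[1:3, ], tolerance = 1e-12)
  expect_gt(max(abs(e1$h1[5, ] - e2$h1[5, ])), 1e-6)
})

test_that("analytic gradients match finite differences for all tensors", {
  s <- tiny_setup()
  mask <- scgcl:::attn_mask(s$g)
  x2 <- s$x * 1.1
  lossfun <- function(pr) {
    f1 <- scgcl:::model_fwd(s$x, mask, pr, s$cfg, 1L)
    f2 <- scgcl:::model_fwd(x2, mask, pr, s$cfg, 2L)
    ins <- scgcl:::neighbor_contrastive(f1$z, f2$z, s$a, 0.5,
                                        grad = FALSE)$value
    clc <- scgcl:::cluster_contrastive(f1$Y, f2$Y, 0.5, grad = FALSE)$value
    reg <- scgcl:::cluster_entropy(f1$Y, f2$Y, grad = FALSE)$value
    0.5 * ins + 0.5 * (clc + reg)
  }
  f1 <- scgcl:::model_fwd(s$x, mask, s$pr, s$cfg, 1L)
  f2 <- scgcl:::model_fwd(x2, mask, s$pr, s$cfg, 2L)
  ins <- scgcl:::neighbor_contrastive(f1$z, f2$z, s$a, 0.5)
  clc <- scgcl:::cluster_contrastive(f1$Y, f2$Y, 0.5)
  reg <- scgcl:::cluster_entropy(f1$Y, f2$Y)
  gr <- scgcl:::zero_grads(s$pr)
  gr <- scgcl:::model_bwd(f1, s$pr, s$cfg, gr, dz = 0.5 * ins$dz1,
                          dY = 0.5 * (clc$dY1 + reg$dY1))$grads
  gr <- scgcl:::model_bwd(f2, s$pr, s$cfg, gr, dz = 0.5 * ins$dz2,
                          dY = 0.5 * (clc$dY2 + reg$dY2))$grads
  set.seed(99)
  for (nm in names(s$pr)) {
    expect_gt(max(abs(gr[[nm]])), 0)             # no dead tensors at init
    for (i in sample(length(s$pr[[nm]]), min(3, length(s$pr[[nm]])))) {
      eps <- 1e-5
      pp <- s$pr; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- s$pr; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) / max(abs(num), 1e-4), 1e-4)
    }
  }
})

test_that("untied encoders give the second view its own parameters", {
  cfg <- encoder_config(8, n_clusters = 3, embed_dim = 8, n_heads = 2,
                        tied_encoders = FALSE)
  pr <- init_params(cfg, seed = 2)
  expect_true("enc2_w_in" %in% names(pr))
  set.seed(1)
  x <- matrix(abs(rnorm(48)), 6)
  g <- cell_graph(rand_adj(6))
  e <- encode(make_views(x, 0, 1), g, cfg, pr)
  expect_gt(max(abs(e$h1 - e$h2)), 1e-6)         # same input, different maps
})
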