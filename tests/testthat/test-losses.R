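test_that("neighbor contrastive loss matches the literal double-loop oracle", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(4:12, 1); q <- sample(3:6, 1)
    z1 <- matrix(rnorm(n * q), n); z2 <- matrix(rnorm(n * q), n)
    a <- rand_adj(n)
    tau <- runif(1, 0.2, 1)
    expect_equal(neighbor_contrastive_loss(z1, z2, a, tau),
                 oracle_neighbor_loss(z1, z2, a, tau), tolerance = 1e-6)
  }
})

test_that("identical embeddings with no neighbors give log 4 at any tau", {
  z <- matrix(rep(c(1, 2, 3), each = 2), 2, 3)
  a0 <- matrix(0, 2, 2)
  for (tau in c(0.1, 0.5, 2))
    expect_equal(neighbor_contrastive_loss(z, z, a0, tau), log(4),
                 tolerance = 1e-10)
})

test_that("neighbor loss properties: positivity, scale invariance", {
  set.seed(42)
  n <- 8
  z1 <- matrix(rnorm(n * 4), n); z2 <- matrix(rnorm(n * 4), n)
  a <- rand_adj(n)
  l <- neighbor_contrastive_loss(z1, z2, a, 0.5)
  expect_gte(l, 0)
  # cosine similarity ignores positive per-row rescaling
  sc <- runif(n, 0.2, 5)
  expect_equal(neighbor_contrastive_loss(z1 * sc, z2, a, 0.5), l,
               tolerance = 1e-10)
  expect_error(neighbor_contrastive_loss(z1, z2, a, -1), "tau")
  z1[3, ] <- 0
  expect_error(neighbor_contrastive_loss(z1, z2, a, 0.5), "zero-norm")
})

test_that("cluster contrastive loss matches its oracle and closed form", {
  set.seed(43)
  for (rep in 1:6) {
    n <- sample(6:14, 1); m <- sample(2:6, 1)
    y1 <- matrix(runif(n * m), n); y1 <- y1 / rowSums(y1)
    y2 <- matrix(runif(n * m), n); y2 <- y2 / rowSums(y2)
    tau <- runif(1, 0.2, 1)
    expect_equal(cluster_contrastive_loss(y1, y2, tau),
                 oracle_cluster_loss(y1, y2, tau), tolerance = 1e-6)
  }
  # M = 2, Y1 == Y2, orthogonal columns, tau = 0.5:
  # each anchor: -log(e^2 / (e^2 + 1 + e^2 + 1)) = log(2 + 2 e^-2)
  y <- rbind(c(1, 0), c(1, 0), c(0, 1))
  closed <- log(2 + 2 * exp(-2))
  expect_equal(cluster_contrastive_loss(y, y, 0.5), closed,
               tolerance = 1e-10)
  expect_equal(oracle_cluster_loss(y, y, 0.5), closed, tolerance = 1e-10)
  # invariant to a common cluster-index permutation
  set.seed(44)
  y1 <- matrix(runif(20), 5); y1 <- y1 / rowSums(y1)
  y2 <- matrix(runif(20), 5); y2 <- y2 / rowSums(y2)
  pm <- sample(4)
  expect_equal(cluster_contrastive_loss(y1[, pm], y2[, pm], 0.5),
               cluster_contrastive_loss(y1, y2, 0.5), tolerance = 1e-12)
  expect_error(cluster_contrastive_loss(cbind(y1, 0), cbind(y2, 0), 0.5),
               "empty cluster")
})

test_that("entropy regularizer spans [0, log M] under the per-view rule", {
  m <- 4; n <- 12
  yu <- matrix(1 / m, n, m)                      # uniform masses
  expect_equal(cluster_entropy_reg(yu, yu), 0, tolerance = 1e-12)
  yd <- matrix(0, n, m); yd[, 2] <- 1            # all mass in one cluster
  expect_equal(cluster_entropy_reg(yd, yd), log(m), tolerance = 1e-12)
  set.seed(45)
  for (rep in 1:5) {
    y1 <- matrix(runif(n * m), n); y1 <- y1 / rowSums(y1)
    y2 <- matrix(runif(n * m), n); y2 <- y2 / rowSums(y2)
    r <- cluster_entropy_reg(y1, y2)
    expect_equal(r, oracle_entropy_reg(y1, y2), tolerance = 1e-10)
    expect_gte(r, 0); expect_lte(r, log(m))
  }
  # the literal joint-2M variant is negative at per-view uniformity
  expect_lt(cluster_entropy_reg(yu, yu, joint_views = TRUE), 0)
})

test_that("loss combination follows the convex form", {
  expect_equal(combine_losses(2, 3, 1, alpha = 1)$l_total, 2)
  expect_equal(combine_losses(2, 3, 1, alpha = 0)$l_total, 4)
  lc <- combine_losses(2, 3, 1, alpha = 0.5)
  expect_equal(lc$l_cls, 4)
  expect_equal(lc$l_total, 3)
  expect_error(combine_losses(1, 1, 1, alpha = 2), "alpha")
})

test_that("loss gradients agree with finite differences on a 6-cell case", {
  set.seed(46)
  n <- 6; q <- 4; m <- 3
  z1 <- matrix(rnorm(n * q), n); z2 <- matrix(rnorm(n * q), n)
  a <- rand_adj(n)
  r <- scgcl:::neighbor_contrastive(z1, z2, a, 0.5)
  g1 <- fd_grad(function(z) neighbor_contrastive_loss(z, z2, a, 0.5), z1)
  expect_lt(max(abs(g1 - r$dz1)) / max(abs(g1)), 1e-4)
  g2 <- fd_grad(function(z) neighbor_contrastive_loss(z1, z, a, 0.5), z2)
  expect_lt(max(abs(g2 - r$dz2)) / max(abs(g2)), 1e-4)
  y1 <- matrix(runif(n * m), n); y1 <- y1 / rowSums(y1)
  y2 <- matrix(runif(n * m), n); y2 <- y2 / rowSums(y2)
  rc <- scgcl:::cluster_contrastive(y1, y2, 0.5)
  gc1 <- fd_grad(function(y) cluster_contrastive_loss(y, y2, 0.5), y1)
  expect_lt(max(abs(gc1 - rc$dY1)) / max(abs(gc1)), 1e-4)
  re <- scgcl:::cluster_entropy(y1, y2)
  ge <- fd_grad(function(y) cluster_entropy_reg(y, y2), y1)
  expect_lt(max(abs(ge - re$dY1)) / max(abs(ge), 1e-8), 1e-4)
  rj <- scgcl:::cluster_entropy(y1, y2, joint_views = TRUE)
  gj <- fd_grad(function(y) cluster_entropy_reg(y, y2, joint_views = TRUE),
                y1)
  expect_lt(max(abs(gj - rj$dY1)) / max(abs(gj), 1e-8), 1e-4)
})

test_that("the conventional exclude-self variant shrinks the denominator", {
  set.seed(47)
  n <- 6
  z1 <- matrix(rnorm(n * 4), n); z2 <- matrix(rnorm(n * 4), n)
  a <- rand_adj(n)
  expect_lt(neighbor_contrastive_loss(z1, z2, a, 0.5, exclude_self = TRUE),
            neighbor_contrastive_loss(z1, z2, a, 0.5))
})
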