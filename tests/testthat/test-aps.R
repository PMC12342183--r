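test_that("soft-label smoothing averages over the closed neighborhood", {
  # 3-node path 1-2-3 with one-hot labels; random-walk (A+I) by hand
  a <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  y <- rbind(c(1, 0), c(0, 1), c(1, 0))
  g <- smooth_soft_labels(y, y, a)
  hand <- rbind(c(1, 1) / 2, c(2, 1) / 3, c(1, 1) / 2)
  expect_equal(as.matrix(g), hand, ignore_attr = TRUE)
  expect_equal(rowSums(as.matrix(g)), rep(1, 3))  # stays on the simplex
  # isolated node keeps its own (averaged) label
  a0 <- matrix(0, 2, 2)
  y1 <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  y2 <- rbind(c(0.5, 0.5), c(0.4, 0.6))
  expect_equal(as.matrix(smooth_soft_labels(y1, y2, a0)), (y1 + y2) / 2,
               ignore_attr = TRUE)
  # constant labels are a fixed point
  yc <- matrix(rep(c(0.25, 0.75), each = 3), 3)
  expect_equal(as.matrix(smooth_soft_labels(yc, yc, a)), yc,
               ignore_attr = TRUE)
  # unnormalized variant scales rows by closed-neighborhood mass
  gu <- smooth_soft_labels(y, y, a, normalize = "none")
  expect_equal(as.matrix(gu), a %*% y, ignore_attr = TRUE)
})

test_that("soft-label adjacency respects the cosine bounds", {
  set.seed(51)
  g <- matrix(runif(6 * 3), 6); g <- g / rowSums(g)
  expect_true(all(soft_label_adjacency(g, -1) == 1))
  expect_true(all(soft_label_adjacency(g, 1 + 1e-9) == 0))
  oh <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(soft_label_adjacency(oh, 0.5)[1, 2], 0)  # orthogonal rows
  ah <- soft_label_adjacency(g, 0.9)
  expect_identical(ah, t(ah))
  g[2, ] <- 0
  expect_error(soft_label_adjacency(g, 0.9), "zero")
})

test_that("final adjacency is the elementwise AND with the KNN graph", {
  set.seed(52)
  a <- rand_adj(10)
  ah <- rand_adj(10); diag(ah) <- 1
  af <- as.matrix(final_adjacency(a, ah))
  for (i in 1:10) for (j in 1:10)
    expect_equal(af[i, j], a[i, j] * ah[i, j])
  expect_true(all(af <= a))
  expect_true(all(diag(af) == 0))
  expect_equal(as.matrix(final_adjacency(a, matrix(1, 10, 10))), a,
               ignore_attr = TRUE)
  expect_true(all(final_adjacency(a, matrix(0, 10, 10)) == 0))
})

test_that("edge filtering is monotone in lambda and vacuous at -1", {
  set.seed(53)
  g <- matrix(runif(20 * 4), 20); g <- g / rowSums(g)
  a <- rand_adj(20)
  lambdas <- c(-1, 0, 0.5, 0.9, 0.99)
  edges <- vapply(lambdas, function(l)
    sum(final_adjacency(a, soft_label_adjacency(g, l))), numeric(1))
  expect_true(all(diff(edges) <= 0))
  expect_equal(as.matrix(final_adjacency(a, soft_label_adjacency(g, -1))),
               a, ignore_attr = TRUE)
  # edgewise subset, not just counts
  f1 <- as.matrix(final_adjacency(a, soft_label_adjacency(g, 0.5)))
  f2 <- as.matrix(final_adjacency(a, soft_label_adjacency(g, 0.9)))
  expect_true(all(f2 <= f1))
})

test_that("PPV and NPV match a hand-counted pair table", {
  # 6 cells, 2 types; candidate edges (i<j) and the kept subset are planted
  truth <- c(1, 1, 1, 2, 2, 2)
  a <- matrix(0, 6, 6)
  cand <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6),  # 5 same-type
                c(1, 4), c(2, 5), c(3, 6))                    # 3 cross-type
  for (r in seq_len(nrow(cand))) {
    a[cand[r, 1], cand[r, 2]] <- 1; a[cand[r, 2], cand[r, 1]] <- 1
  }
  keep <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(1, 4))  # 4 same + 1 cross
  af <- matrix(0, 6, 6)
  for (r in seq_len(nrow(keep))) {
    af[keep[r, 1], keep[r, 2]] <- 1; af[keep[r, 2], keep[r, 1]] <- 1
  }
  q <- pair_sampling_quality(af, a, truth)
  expect_equal(q$ppv, 4 / 5)   # dropped: (4,6) same; (2,5),(3,6) cross
  expect_equal(q$npv, 2 / 3)
  # permutation invariance of the pair statistics
  pm <- c(3, 1, 6, 2, 5, 4)
  qp <- pair_sampling_quality(af[pm, pm], a[pm, pm], truth[pm])
  expect_equal(qp$ppv, q$ppv); expect_equal(qp$npv, q$npv)
  # degenerate: everything kept, one type -> NPV undefined
  q2 <- pair_sampling_quality(a, a, rep(1, 6))
  expect_equal(q2$ppv, 1)
  expect_true(is.na(q2$npv))
  expect_error(pair_sampling_quality(af, a, c(1, 2)), "labels")
})
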