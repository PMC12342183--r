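#' Training and model options
#'
#' Collects every tunable of the pipeline with its default. Standard-regime
#' defaults: mask rate 0.5, four attention heads, one layer, embedding
#' width 32, 500 epochs, Adam at learning rate 0.001, temperature and
#' loss weight 0.5, size-dependent batch size.
#'
#' @param embed_dim,n_heads,n_layers,instance_dim,tied_encoders encoder
#'   architecture; see [encoder_config()].
#' @param max_epochs,lr,batch_size optimization schedule. `batch_size = NULL`
#'   selects by dataset size: 64 below 1000 cells, 256 up to 2000, 512 up to
#'   10000, 1024 beyond.
#' @param tau contrastive temperature (> 0).
#' @param alpha weight of the instance-level loss in the total, in `[0, 1]`.
#' @param exclude_self drop the printed same-view self terms from both
#'   contrastive denominators (conventional variant).
#' @param joint_view_entropy use the joint-2M entropy normalization.
#' @param mask_rate,rescale augmentation; see [make_views()].
#' @param aps_lambda soft-label cosine threshold for adaptive positive
#'   sampling.
#' @param aps_warmup_frac fraction of `max_epochs` during which the
#'   unfiltered KNN adjacency is used before APS activates.
#' @param aps_refresh_every refresh period (epochs) of the filtered
#'   adjacency.
#' @param aps_normalize soft-label smoothing normalization, `"rw"` or
#'   `"none"`.
#' @param use_aps,use_neighbors,use_cluster_head ablation switches: disable
#'   the APS filter, the KNN-neighbor positives (single positive pair per
#'   anchor), or the whole cluster-level head and loss.
#' @return an options list of class `scgcl_opts`.
#' @export
scgcl_config <- function(embed_dim = 32L, n_heads = 4L, n_layers = 1L,
                         instance_dim = 32L, tied_encoders = TRUE,
                         max_epochs = 500L, lr = 1e-3, batch_size = NULL,
                         tau = 0.5, alpha = 0.5, exclude_self = FALSE,
                         joint_view_entropy = FALSE,
                         mask_rate = 0.5, rescale = TRUE,
                         aps_lambda = 0.9, aps_warmup_frac = 0.2,
                         aps_refresh_every = 1L, aps_normalize = "rw",
                         use_aps = TRUE, use_neighbors = TRUE,
                         use_cluster_head = TRUE) {
  if (max_epochs < 1 || lr <= 0) stop("scgcl_config: max_epochs >= 1, lr > 0")
  if (!is.null(batch_size) && batch_size < 2)
    stop("scgcl_config: batch_size must be >= 2")
  structure(as.list(environment()), class = "scgcl_opts")
}

default_batch_size <- function(n) {
  if (n < 1000) 64L else if (n <= 2000) 256L
  else if (n <= 10000) 512L else 1024L
}

#' Partition cells into mini-batches
#'
#' A seeded random permutation of the nodes is cut into contiguous chunks of
#' `batch_size`; a trailing chunk of size 1 is merged into the previous
#' batch. Each batch is trained on the induced subgraph of its nodes, and
#' all contrastive denominators range over the batch only.
#'
#' @param n number of cells, or a [cell_graph()].
#' @param batch_size target batch size, >= 2.
#' @param seed integer seed.
#' @return list of disjoint integer index vectors covering `1:n`.
#' @export
make_batches <- function(n, batch_size, seed = 1L) {
  if (inherits(n, "cell_graph")) n <- nrow(n$adjacency)
  if (batch_size < 2) stop("make_batches: batch_size must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) perm[s:min(s + batch_size - 1, n)])
  nb <- length(batches)
  if (nb > 1 && length(batches[[nb]]) < 2) {
    batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

# mask-free full-graph forward of both views (identical inputs)
full_forward <- function(x, mask, pr, cfg) {
  f1 <- model_fwd(x, mask, pr, cfg, view = 1L)
  if (cfg$tied_encoders) list(f1 = f1, f2 = f1)
  else list(f1 = f1, f2 = model_fwd(x, mask, pr, cfg, view = 2L))
}

#' Fit the graph contrastive clustering model
#'
#' End-to-end training: per epoch, the filtered adjacency is refreshed on
#' schedule from a mask-free full-graph forward pass, then each mini-batch
#' draws fresh masked views, encodes them, evaluates the combined
#' contrastive loss on the batch-induced subgraph and takes an Adam step.
#' After training, a mask-free forward pass produces the smoothed soft
#' labels whose row-wise argmax is the hard cluster assignment.
#'
#' @param x hvg-layer [count_matrix()] (or plain cells x genes matrix).
#' @param graph [cell_graph()] over the same cells.
#' @param n_clusters number of clusters M (>= 2).
#' @param opts options from [scgcl_config()].
#' @param seed root seed; every random draw (initialization, batching,
#'   masking) derives from it, so a fit is reproducible bit-for-bit.
#' @param verbose print the epoch loss every 50 epochs.
#' @return an object of class `scgcl_fit`: `hard_labels` (1..M),
#'   `soft_labels` (smoothed, n x M), `h`, `z`, `Y` (final mask-free
#'   embeddings), `loss_history` (data frame per epoch), `a_final` and
#'   `a_final_first` (filtered adjacency at the last epoch and at the end of
#'   warm-up), `params`, `cfg`, `opts`, `seed`.
#' @export
fit_scgcl <- function(x, graph, n_clusters, opts = scgcl_config(),
                      seed = 1L, verbose = FALSE) {
  xv <- if (inherits(x, "count_matrix")) x$values else as.matrix(x)
  n <- nrow(xv)
  if (n_clusters > n) stop("fit_scgcl: n_clusters (", n_clusters,
                           ") exceeds number of cells (", n, ")")
  cfg <- encoder_config(input_dim = ncol(xv), n_clusters = n_clusters,
                        embed_dim = opts$embed_dim, n_heads = opts$n_heads,
                        n_layers = opts$n_layers,
                        instance_dim = opts$instance_dim,
                        tied_encoders = opts$tied_encoders)
  a_full <- as_dense_adj(graph)
  if (nrow(a_full) != n) stop("fit_scgcl: graph has ", nrow(a_full),
                              " cells but x has ", n)
  mask_full <- a_full != 0; diag(mask_full) <- TRUE
  bs <- if (is.null(opts$batch_size)) default_batch_size(n) else
    as.integer(opts$batch_size)
  pr <- init_params(cfg, seed = derive_seed(seed, 1L))
  st <- adam_init(pr)
  warmup_epochs <- ceiling(opts$aps_warmup_frac * opts$max_epochs)
  a_train <- if (opts$use_neighbors) a_full else a_full * 0
  a_final <- a_train
  a_final_first <- NULL
  alpha <- if (opts$use_cluster_head) opts$alpha else 1
  hist <- vector("list", opts$max_epochs)

  for (epoch in seq_len(opts$max_epochs)) {
    if (opts$use_aps && opts$use_neighbors && epoch > warmup_epochs &&
        (epoch - warmup_epochs - 1) %% opts$aps_refresh_every == 0 &&
        opts$use_cluster_head) {
      ff <- full_forward(xv, mask_full, pr, cfg)
      g <- smooth_soft_labels(ff$f1$Y, ff$f2$Y, a_full,
                              normalize = opts$aps_normalize)
      a_final <- a_train * soft_label_adjacency(g, opts$aps_lambda)
      if (is.null(a_final_first)) a_final_first <- a_final
    }
    batches <- make_batches(n, bs, derive_seed(seed, epoch, 0L, 1L))
    ep <- c(l_ins = 0, l_cls = 0, l_reg = 0, l_total = 0)
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      vw <- make_views(xv[idx, , drop = FALSE], opts$mask_rate,
                       seed = derive_seed(seed, epoch, b, 2L),
                       rescale = opts$rescale)
      mb <- mask_full[idx, idx, drop = FALSE]
      f1 <- model_fwd(vw$view1, mb, pr, cfg, view = 1L)
      f2 <- model_fwd(vw$view2, mb, pr, cfg, view = 2L)
      ins <- neighbor_contrastive(f1$z, f2$z, a_final[idx, idx],
                                  tau = opts$tau,
                                  exclude_self = opts$exclude_self)
      if (opts$use_cluster_head) {
        clc <- cluster_contrastive(f1$Y, f2$Y, tau = opts$tau,
                                   exclude_self = opts$exclude_self)
        reg <- cluster_entropy(f1$Y, f2$Y,
                               joint_views = opts$joint_view_entropy)
      } else {
        clc <- list(value = 0); reg <- list(value = 0)
      }
      lc <- combine_losses(ins$value, clc$value, reg$value, alpha)
      if (!is.finite(lc$l_total))
        stop("fit_scgcl: non-finite loss at epoch ", epoch, " (l_ins = ",
             signif(ins$value, 4), ", l_cls = ", signif(lc$l_cls, 4), ")")
      grads <- zero_grads(pr)
      dY1 <- dY2 <- NULL
      if (opts$use_cluster_head) {
        dY1 <- (1 - alpha) * (clc$dY1 + reg$dY1)
        dY2 <- (1 - alpha) * (clc$dY2 + reg$dY2)
      }
      grads <- model_bwd(f1, pr, cfg, grads, dz = alpha * ins$dz1,
                         dY = dY1)$grads
      grads <- model_bwd(f2, pr, cfg, grads, dz = alpha * ins$dz2,
                         dY = dY2)$grads
      stp <- adam_step(pr, grads, st, lr = opts$lr)
      pr <- stp$params; st <- stp$state
      w <- length(idx) / n
      ep <- ep + w * c(ins$value, lc$l_cls, reg$value, lc$l_total)
    }
    hist[[epoch]] <- ep
    if (verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d: total %.4f (ins %.4f, cls %.4f)",
                      epoch, ep["l_total"], ep["l_ins"], ep["l_cls"]))
  }

  ff <- full_forward(xv, mask_full, pr, cfg)
  g <- smooth_soft_labels(ff$f1$Y, ff$f2$Y, a_full,
                          normalize = opts$aps_normalize)
  hard <- max.col(g, ties.method = "first")
  if (opts$use_aps && opts$use_neighbors && opts$use_cluster_head &&
      opts$max_epochs > warmup_epochs)
    a_final <- a_train * soft_label_adjacency(g, opts$aps_lambda)
  lh <- as.data.frame(do.call(rbind, hist))
  lh$epoch <- seq_len(nrow(lh))
  structure(list(hard_labels = hard, soft_labels = g,
                 h = ff$f1$h, z = ff$f1$z, Y = ff$f1$Y,
                 loss_history = lh[, c("epoch", "l_ins", "l_cls", "l_reg",
                                       "l_total")],
                 a_final = methods::as(Matrix::Matrix(a_final, sparse = TRUE),
                                       "CsparseMatrix"),
                 a_final_first = if (is.null(a_final_first)) NULL else
                   methods::as(Matrix::Matrix(a_final_first, sparse = TRUE),
                               "CsparseMatrix"),
                 params = pr, cfg = cfg, opts = opts, seed = seed,
                 cell_ids = if (inherits(x, "count_matrix")) x$cell_ids else
                   as.character(seq_len(n)),
                 gene_ids = if (inherits(x, "count_matrix")) x$gene_ids else
                   as.character(seq_len(ncol(xv)))),
            class = "scgcl_fit")
}

#' @export
print.scgcl_fit <- function(x, ...) {
  cat(sprintf(paste0("scgcl_fit: %d cells, %d clusters, %d epochs ",
                     "(final loss %.4f)\n"),
              length(x$hard_labels), x$cfg$n_clusters, nrow(x$loss_history),
              x$loss_history$l_total[nrow(x$loss_history)]))
  invisible(x)
}

#' Choose the number of clusters by silhouette
#'
#' Trains a short-budget model per candidate M and scores the hard labels
#' with the mean silhouette coefficient on the chosen representation
#' (Euclidean distance); returns the candidate with the highest mean
#' silhouette, preferring the smaller M on ties.
#'
#' @param x hvg-layer [count_matrix()] or matrix.
#' @param graph [cell_graph()].
#' @param candidates integer vector of candidate cluster numbers (>= 2).
#' @param opts options from [scgcl_config()]; `max_epochs` here is the
#'   short training budget per candidate.
#' @param seed root seed shared by all candidate fits.
#' @param space representation scored: encoder embeddings `"h"` (default),
#'   instance projections `"z"`, or smoothed soft labels `"g"`.
#' @return the selected number of clusters, with the per-candidate mean
#'   silhouettes in attribute `"silhouette"`.
#' @export
select_n_clusters <- function(x, graph, candidates, opts = scgcl_config(
                                max_epochs = 100L),
                              seed = 1L, space = c("h", "z", "g")) {
  space <- match.arg(space)
  if (length(candidates) == 0) stop("select_n_clusters: no candidates")
  if (any(candidates < 2)) stop("select_n_clusters: candidates must be >= 2")
  n <- if (inherits(x, "count_matrix")) nrow(x$values) else nrow(x)
  ok <- candidates <= n
  if (!all(ok)) {
    warning("select_n_clusters: skipping candidates > n: ",
            paste(candidates[!ok], collapse = ", "))
    candidates <- candidates[ok]
  }
  if (length(candidates) == 1) return(candidates)
  sil <- vapply(candidates, function(m) {
    fit <- fit_scgcl(x, graph, m, opts = opts, seed = seed)
    emb <- switch(space, h = fit$h, z = fit$z, g = fit$soft_labels)
    lab <- fit$hard_labels
    if (length(unique(lab)) < 2) return(-1)
    mean(cluster::silhouette(lab, stats::dist(emb))[, "sil_width"])
  }, numeric(1))
  best <- candidates[order(-sil, candidates)][1]
  attr(best, "silhouette") <- stats::setNames(sil, candidates)
  best
}

#' Choose the KNN neighborhood size by final training loss
#'
#' Unsupervised selector: for each candidate `k` the cell graph is rebuilt,
#' a short-budget model is trained, and the candidate minimizing the final
#' epoch's total contrastive loss is returned (smaller `k` on ties). Note
#' that the instance-level loss is not normalized by the number of
#' positives, so comparisons across very different `k` should be read with
#' care.
#'
#' @param x hvg-layer [count_matrix()] or matrix.
#' @param candidates integer vector of candidate neighbor counts.
#' @param n_clusters number of clusters used for the probe fits.
#' @param opts short-budget options, as in [select_n_clusters()].
#' @param seed root seed shared by all candidate fits.
#' @return the selected `k`, with per-candidate final losses in attribute
#'   `"loss"`.
#' @export
select_k <- function(x, candidates, n_clusters,
                     opts = scgcl_config(max_epochs = 100L), seed = 1L) {
  if (length(candidates) == 0) stop("select_k: no candidates")
  loss <- vapply(candidates, function(k) {
    graph <- build_knn_graph(x, k = k)
    fit <- fit_scgcl(x, graph, n_clusters, opts = opts, seed = seed)
    fit$loss_history$l_total[nrow(fit$loss_history)]
  }, numeric(1))
  best <- candidates[order(loss, candidates)][1]
  attr(best, "loss") <- stats::setNames(loss, candidates)
  best
}

#' Write the artifacts of a fitted model
#'
#' Writes predicted labels, smoothed soft labels, encoder embeddings, the
#' loss history and a JSON run manifest (options, seed, package version)
#' into a directory.
#'
#' @param fit an `scgcl_fit`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_fit_outputs <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(data.frame(cell_id = fit$cell_ids,
                              predicted_cluster = fit$hard_labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = fit$cell_ids, fit$soft_labels,
                              check.names = FALSE),
                   file.path(dir, "soft_labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = fit$cell_ids, fit$h,
                              check.names = FALSE),
                   file.path(dir, "embeddings.csv"), row.names = FALSE)
  utils::write.csv(fit$loss_history, file.path(dir, "loss_history.csv"),
                   row.names = FALSE)
  manifest <- list(options = fit$opts[setdiff(names(fit$opts), "")],
                   n_clusters = fit$cfg$n_clusters, seed = fit$seed,
                   package_version = as.character(utils::packageVersion("scgcl")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  saveRDS(list(params = fit$params, cfg = fit$cfg, opts = fit$opts,
               seed = fit$seed), file.path(dir, "checkpoint.rds"))
  invisible(dir)
}
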