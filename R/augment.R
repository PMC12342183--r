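#' Generate two masked augmented views of an expression matrix
#'
#' Each view zeroes entries with an independent elementwise
#' Bernoulli(`mask_rate`) mask. With `rescale = TRUE` (dropout semantics)
#' survivors are scaled by `1/(1 - mask_rate)` so the expected value of every
#' entry is preserved; with `rescale = FALSE` plain zero-masking is applied.
#' The two views use independent masks. The cell graph is never perturbed by
#' augmentation.
#'
#' @param x numeric matrix (cells x genes).
#' @param mask_rate masking probability in `[0, 1)`; the default masks half
#'   of the entries.
#' @param seed integer seed; views are deterministic given it. Callers that
#'   need fresh masks every epoch should pass a per-(epoch, batch) seed.
#' @param rescale rescale survivors by `1/(1 - mask_rate)`.
#' @return list with `view1`, `view2` (same shape as `x`), `mask_rate`,
#'   `seed`.
#' @export
make_views <- function(x, mask_rate = 0.5, seed = 1L, rescale = TRUE) {
  if (mask_rate < 0 || mask_rate >= 1)
    stop("make_views: mask_rate must lie in [0, 1)")
  x <- as.matrix(x)
  if (mask_rate == 0)
    return(list(view1 = x, view2 = x, mask_rate = 0, seed = seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  scale <- if (rescale) 1 / (1 - mask_rate) else 1
  m1 <- matrix(stats::runif(length(x)) >= mask_rate, nrow(x), ncol(x))
  m2 <- matrix(stats::runif(length(x)) >= mask_rate, nrow(x), ncol(x))
  list(view1 = x * m1 * scale, view2 = x * m2 * scale,
       mask_rate = mask_rate, seed = seed)
}

# derive a bounded, deterministic sub-seed for (epoch, batch, purpose)
# streams from one root seed; stays below 2^31
derive_seed <- function(root, a = 0L, b = 0L, c = 0L) {
  s <- (as.double(root) * 48271 + a * 1664525 + b * 22695477 + c * 69069) %%
    2147483629
  as.integer(s) + 1L
}
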