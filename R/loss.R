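# Training objective: exponentially down-weighted per-block reconstruction
# losses, L = sum_i decay^(n-i) d(pred_i, target) + alpha * perceptual, with
# d one of l1, MSE, or l1 on Laplacian-pyramid bands.

#' Loss configuration
#'
#' @param distance per-block distance: `"laplacian_l1"` (l1 on Laplacian
#'   pyramid bands, the default), `"l1"`, or `"mse"`.
#' @param alpha weight of the optional perceptual feature term (0 or 0.5 in
#'   practice; 0 disables it and requires no feature extractor).
#' @param decay_base exponential down-weighting base for earlier blocks
#'   (default 0.8; the final block always has weight 1).
#' @param n_blocks number of supervised block predictions (default 9).
#' @param pyramid_levels Laplacian pyramid depth (default 3).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(distance = c("laplacian_l1", "l1", "mse"),
                        alpha = 0, decay_base = 0.8, n_blocks = 9L,
                        pyramid_levels = 3L) {
  distance <- match.arg(distance)
  stopifnot(decay_base > 0, decay_base <= 1, alpha >= 0, n_blocks >= 1,
            pyramid_levels >= 1)
  structure(list(distance = distance, alpha = alpha,
                 decay_base = decay_base, n_blocks = as.integer(n_blocks),
                 pyramid_levels = as.integer(pyramid_levels)),
            class = "loss_config")
}

# 5-tap binomial blur kernel, outer product, as a fixed (5,5,1,1) conv weight
.lap_kernel <- local({
  k1 <- c(1, 4, 6, 4, 1) / 16
  k <- outer(k1, k1)
  array(k, dim = c(5L, 5L, 1L, 1L))
})

# tensor-level pyramid on a (H, W, 1, N) tensor
.lap_pyramid_t <- function(x, levels) {
  kw <- hf_tensor(.lap_kernel)
  kb <- hf_tensor(0)
  bands <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels - 1L)) {
    d <- dim(cur$value)
    down <- op_conv2d(cur, kw, kb, stride = 2L, pad = 2L)
    up <- op_resize(down, d[1], d[2])
    bands[[l]] <- op_sub(cur, up)
    cur <- down
  }
  bands[[levels]] <- cur
  bands
}

#' Laplacian pyramid decomposition
#'
#' Gaussian levels are formed by 5-tap binomial blur and factor-2
#' downsampling; each difference band is `level_k - upsample(level_{k+1})`
#' and the last element is the coarsest Gaussian level. Reconstruction by
#' iterated upsample-and-add recovers the input exactly.
#'
#' @param image a numeric matrix.
#' @param levels pyramid depth (>= 1); the image side must be at least
#'   `2^(levels - 1)`.
#' @return list of `levels` band matrices, finest first.
#' @export
laplacian_pyramid <- function(image, levels = 3L) {
  stopifnot(is.matrix(image))
  levels <- as.integer(levels)
  if (levels < 1L) stop("laplacian_pyramid: levels must be >= 1")
  if (min(dim(image)) < 2^(levels - 1L))
    stop("laplacian_pyramid: image too small for ", levels, " levels")
  bands <- .lap_pyramid_t(hf_tensor(hf_as4d(image)), levels)
  lapply(bands, function(t) matrix(t$value, dim(t$value)[1], dim(t$value)[2]))
}

#' Reconstruct an image from its Laplacian pyramid
#'
#' @param bands list of band matrices as returned by [laplacian_pyramid()].
#' @return the reconstructed matrix.
#' @export
laplacian_reconstruct <- function(bands) {
  cur <- bands[[length(bands)]]
  for (l in rev(seq_len(length(bands) - 1L))) {
    up <- cpp_resize_fwd(hf_as4d(cur), nrow(bands[[l]]), ncol(bands[[l]]))
    cur <- bands[[l]] + matrix(up, nrow(bands[[l]]))
  }
  cur
}

# scalar distance tensor between two (H,W,1,N) tensors
.distance_t <- function(a, b, cfg) {
  switch(cfg$distance,
    l1 = op_l1(a, b),
    mse = op_mse(a, b),
    laplacian_l1 = {
      pa <- .lap_pyramid_t(a, cfg$pyramid_levels)
      pb <- .lap_pyramid_t(b, cfg$pyramid_levels)
      terms <- mapply(op_l1, pa, pb, SIMPLIFY = FALSE)
      op_weighted_sum(terms, rep(1, length(terms)))
    })
}

# tensor-level Eq-8 style objective used by the training loop
.block_loss_t <- function(per_block, target, cfg, extractor = NULL) {
  n <- cfg$n_blocks
  if (length(per_block) != n)
    stop("block_weighted_loss: expected ", n, " block predictions, got ",
         length(per_block))
  weights <- cfg$decay_base^(n - seq_len(n))
  terms <- lapply(per_block, .distance_t, b = target, cfg = cfg)
  loss <- op_weighted_sum(terms, weights)
  if (cfg$alpha > 0) {
    if (is.null(extractor))
      stop("block_weighted_loss: alpha > 0 requires a feature extractor; ",
           "set alpha = 0 or supply one")
    feats_p <- extractor(per_block[[n]])
    feats_t <- extractor(target)
    pterms <- mapply(op_mse, feats_p, feats_t, SIMPLIFY = FALSE)
    pl <- op_weighted_sum(pterms, rep(1 / length(pterms), length(pterms)))
    loss <- op_weighted_sum(list(loss, pl), c(1, cfg$alpha))
  }
  loss
}

#' Block-weighted training loss
#'
#' The prediction of block `i` contributes with weight
#' `decay_base^(n_blocks - i)`, so late blocks dominate and the final block
#' has weight one. With `alpha > 0` a perceptual feature distance on the
#' final prediction is added.
#'
#' @param per_block_preds list of `n_blocks` predicted frames (matrices).
#' @param target the observed next frame (matrix).
#' @param cfg a [loss_config()].
#' @param extractor optional feature extractor for the perceptual term: a
#'   function mapping a 3-channel image (`w x w x 3` array) to a list of
#'   numeric feature arrays. Single-channel frames are replicated to 3
#'   channels before extraction.
#' @return the scalar loss.
#' @export
block_weighted_loss <- function(per_block_preds, target, cfg = loss_config(),
                                extractor = NULL) {
  stopifnot(is.list(per_block_preds), is.matrix(target))
  per_t <- lapply(per_block_preds, function(p) {
    if (!identical(dim(p), dim(target)))
      stop("block_weighted_loss: block prediction shape mismatch")
    hf_tensor(hf_as4d(p))
  })
  n <- cfg$n_blocks
  if (length(per_t) != n)
    stop("block_weighted_loss: expected ", n, " block predictions, got ",
         length(per_t))
  weights <- cfg$decay_base^(n - seq_len(n))
  tt <- hf_tensor(hf_as4d(target))
  terms <- vapply(per_t, function(a) .distance_t(a, tt, cfg)$value, numeric(1))
  loss <- sum(weights * terms)
  if (cfg$alpha > 0) {
    loss <- loss + cfg$alpha *
      perceptual_feature_loss(per_block_preds[[n]], target, extractor)
  }
  loss
}

#' Perceptual feature distance
#'
#' Mean squared distance between corresponding feature maps of the two
#' frames under a user-supplied extractor. With the identity extractor this
#' reduces to the mean squared pixel error.
#'
#' @param pred,target matrices of equal size.
#' @param extractor function mapping a `w x w x 3` array to a list of
#'   numeric feature arrays.
#' @return non-negative scalar; 0 when `pred == target`.
#' @export
perceptual_feature_loss <- function(pred, target, extractor) {
  if (is.null(extractor))
    stop("perceptual_feature_loss: no feature extractor configured; ",
         "use alpha = 0 to disable the perceptual term")
  to3 <- function(m) array(rep(m, 3L), dim = c(dim(m), 3L))
  fp <- extractor(to3(pred))
  ft <- extractor(to3(target))
  stopifnot(length(fp) == length(ft))
  mean(mapply(function(a, b) mean((a - b)^2), fp, ft))
}
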