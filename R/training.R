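# Dataset assembly, the optimization loop, and checkpoint selection.

#' Cosine-annealed learning rate
#'
#' Decays from `lr_init` at the first epoch to exactly `lr_final` at the
#' last, monotonically.
#'
#' @param epoch 1-based epoch index.
#' @param epochs total number of epochs.
#' @param lr_init,lr_final endpoints (defaults 1e-4 and 1e-5).
#' @return the learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, epochs, lr_init = 1e-4, lr_final = 1e-5) {
  stopifnot(epoch >= 1, epoch <= epochs, lr_final <= lr_init)
  if (epochs == 1L) return(lr_init)
  lr_final + (lr_init - lr_final) * 0.5 *
    (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

#' Assemble training windows from per-chromosome time series
#'
#' Every diagonal patch crossed with every 5-consecutive-frame window (two
#' input frames, three targets) becomes one sample. Chromosomes are
#' assigned to train / validation / test by label; the defaults mirror the
#' convention of validating on a small chromosome (19) and testing on
#' chromosomes 2 and 6. Frames are clip-normalized before patching.
#' All-zero input patches carry no signal and are dropped.
#'
#' @param series_by_chromosome named list of [hic_timeseries()] objects.
#' @param split which split to assemble.
#' @param val_chroms,test_chroms chromosome labels held out for validation
#'   and testing (must be disjoint).
#' @param patch_size,stride diagonal patching of the frames.
#' @param cutoff normalization cutoff.
#' @param drop_empty drop samples whose input patches are all zero.
#' @return list of samples, each with `chromosome`, `offset`,
#'   `window_start`, `inputs` (2 matrices) and `targets` (3 matrices);
#'   the patching/normalization settings are attached as attributes.
#' @export
build_dataset <- function(series_by_chromosome,
                          split = c("train", "val", "test"),
                          val_chroms = "chr19", test_chroms = c("chr2", "chr6"),
                          patch_size = 64L, stride = 60L, cutoff = 100,
                          drop_empty = TRUE) {
  split <- match.arg(split)
  stopifnot(length(series_by_chromosome) >= 1L,
            !is.null(names(series_by_chromosome)))
  overlap <- intersect(val_chroms, test_chroms)
  if (length(overlap))
    stop("build_dataset: chromosomes in both val and test: ",
         paste(overlap, collapse = ", "))
  chroms <- names(series_by_chromosome)
  pick <- switch(split,
    train = setdiff(chroms, c(val_chroms, test_chroms)),
    val = intersect(chroms, val_chroms),
    test = intersect(chroms, test_chroms))
  samples <- list()
  for (nm in pick) {
    ser <- series_by_chromosome[[nm]]
    stopifnot(inherits(ser, "HiCTimeSeries"))
    k <- length(ser$frames)
    if (k < 5L)
      stop("build_dataset: chromosome ", nm, " has only ", k,
           " timepoints; need >= 5")
    norm <- lapply(ser$frames, function(f)
      clip_normalize(f, cutoff)$values)
    ps <- lapply(norm, extract_diagonal_patches, patch_size = patch_size,
                 stride = stride)
    offsets <- ps[[1]]$offsets
    for (oi in seq_along(offsets)) {
      for (s in seq_len(k - 4L)) {
        inp <- list(ps[[s]]$patches[[oi]], ps[[s + 1L]]$patches[[oi]])
        if (drop_empty && all(inp[[1]] == 0) && all(inp[[2]] == 0)) next
        samples[[length(samples) + 1L]] <- list(
          chromosome = nm, offset = offsets[oi], window_start = s,
          inputs = inp,
          targets = list(ps[[s + 2L]]$patches[[oi]],
                         ps[[s + 3L]]$patches[[oi]],
                         ps[[s + 4L]]$patches[[oi]]))
      }
    }
  }
  attr(samples, "patch_size") <- as.integer(patch_size)
  attr(samples, "stride") <- as.integer(stride)
  attr(samples, "cutoff") <- cutoff
  samples
}

# ---- parameter (de)serialization -------------------------------------------

#' Extract / restore flat parameter values
#'
#' `params_to_values()` flattens a parameter set to a named list of plain
#' arrays (the representation stored in checkpoints);
#' `params_set_values()` writes such a list back into a
#' [voxelflow_params()] shell in place.
#'
#' @param params a [voxelflow_params()].
#' @return named list of numeric arrays.
#' @export
params_to_values <- function(params) {
  lapply(hf_flatten_params(params[c("blocks", "routing")]),
         function(t) t$value)
}

#' @rdname params_to_values
#' @param values a list as returned by `params_to_values()`.
#' @export
params_set_values <- function(params, values) {
  flat <- hf_flatten_params(params[c("blocks", "routing")])
  stopifnot(length(flat) == length(values))
  for (i in seq_along(flat)) flat[[i]]$value <- values[[i]]
  invisible(params)
}

#' Write / read model checkpoints
#'
#' Checkpoints are RDS files embedding the architecture config (scales,
#' patch size, normalization cutoff, resolution) so that prediction can
#' refuse inputs preprocessed differently from the training data.
#'
#' @param params a [voxelflow_params()].
#' @param path file path.
#' @param epoch optional epoch tag stored alongside.
#' @param optimizer optional optimizer state to resume from.
#' @export
write_checkpoint <- function(params, path, epoch = NA_integer_,
                             optimizer = NULL) {
  saveRDS(list(config = params$config, values = params_to_values(params),
               epoch = epoch, optimizer = optimizer), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @return `read_checkpoint()` returns a [voxelflow_params()] with the
#'   stored config, plus attributes `epoch` and `optimizer`.
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  params <- voxelflow_params(ck$config, seed = 0L)
  params_set_values(params, ck$values)
  attr(params, "epoch") <- ck$epoch
  attr(params, "optimizer") <- ck$optimizer
  params
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(flat) {
  list(step = 0L,
       m = lapply(flat, function(t) t$value * 0),
       v = lapply(flat, function(t) t$value * 0))
}

.adam_step <- function(flat, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (i in seq_along(flat)) {
    g <- flat[[i]]$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    flat[[i]]$value <- flat[[i]]$value -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

# stack a list of w x w matrices into (w, w, 1, N)
.stack_frames <- function(ms) {
  w <- nrow(ms[[1]])
  array(unlist(ms), dim = c(w, w, 1L, length(ms)))
}

#' Train the voxel-flow forecaster
#'
#' Each optimizer step supervises the first target frame (next-frame
#' prediction) with the block-weighted loss; the chain is gated by
#' straight-through Bernoulli routing (`routing = "sampled"`, so the
#' routing module learns) or run ungated (`routing = "full"`), and in both
#' modes every block's intermediate prediction is computed for supervision
#' regardless of its gate. The learning rate follows cosine annealing
#' between the configured endpoints. One checkpoint is recorded per epoch.
#'
#' @param samples training samples from [build_dataset()].
#' @param params initial [voxelflow_params()] (modified in place and
#'   returned).
#' @param loss_cfg a [loss_config()].
#' @param epochs number of epochs (default 100).
#' @param batch_size minibatch size (default 8).
#' @param lr_init,lr_final cosine-annealing endpoints.
#' @param seed seed controlling shuffling, routing draws and weight noise.
#' @param max_steps optional cap on total optimizer steps (for desk-scale
#'   runs); training stops once reached.
#' @param routing `"sampled"` (straight-through gates) or `"full"`.
#' @param extractor optional differentiable feature extractor used when
#'   `loss_cfg$alpha > 0`: a function mapping an `(H, W, 1, N)` tensor to a
#'   list of tensors built from this package's ops.
#' @param keep_checkpoints `"all"` or `"last"`.
#' @param verbose print a line per epoch.
#' @return list with `params` (trained), `checkpoints` (list of
#'   `list(epoch, values)`), and `log` (data frame: epoch, step, lr, loss).
#' @export
train <- function(samples, params, loss_cfg = loss_config(), epochs = 100L,
                  batch_size = 8L, lr_init = 1e-4, lr_final = 1e-5,
                  seed = 1L, max_steps = Inf,
                  routing = c("sampled", "full"), extractor = NULL,
                  keep_checkpoints = c("all", "last"), verbose = FALSE) {
  routing <- match.arg(routing)
  keep_checkpoints <- match.arg(keep_checkpoints)
  n <- length(samples)
  if (n == 0L) stop("train: empty dataset")
  if (loss_cfg$alpha > 0 && is.null(extractor))
    stop("train: alpha > 0 requires a feature extractor; set alpha = 0 ",
         "or supply one")
  set.seed(seed)
  flat <- hf_flatten_params(params[c("blocks", "routing")])
  opt <- .adam_init(flat)
  log <- list()
  checkpoints <- list()
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(epochs)) {
    lr <- cosine_lr(epoch, epochs, lr_init, lr_final)
    order <- sample.int(n)
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- order[b0:min(b0 + batch_size - 1L, n)]
      prev <- hf_tensor(.stack_frames(lapply(samples[idx],
                                             function(s) s$inputs[[1]])))
      cur <- hf_tensor(.stack_frames(lapply(samples[idx],
                                            function(s) s$inputs[[2]])))
      target <- hf_tensor(.stack_frames(lapply(samples[idx],
                                               function(s) s$targets[[1]])))
      fwd <- hf_forward(prev, cur, params,
                        mode = if (routing == "full") "full" else "sampled",
                        training = TRUE)
      loss <- .block_loss_t(fwd$per_block, target, loss_cfg, extractor)
      if (!is.finite(loss$value))
        stop(sprintf("train: non-finite loss at epoch %d step %d (lr %.2e)",
                     epoch, step + 1L, lr))
      hf_zero_grad(params[c("blocks", "routing")])
      hf_backward(loss)
      opt <- .adam_step(flat, opt, lr)
      step <- step + 1L
      log[[length(log) + 1L]] <- data.frame(epoch = epoch, step = step,
                                            lr = lr, loss = loss$value)
      if (step >= max_steps) {
        done <- TRUE
        break
      }
    }
    checkpoints[[length(checkpoints) + 1L]] <-
      list(epoch = epoch, values = params_to_values(params))
    if (keep_checkpoints == "last" && length(checkpoints) > 1L)
      checkpoints <- checkpoints[length(checkpoints)]
    if (verbose)
      message(sprintf("epoch %3d  lr %.3e  loss %.5f", epoch, lr,
                      log[[length(log)]]$loss))
    if (done) break
  }
  list(params = params, checkpoints = checkpoints,
       log = do.call(rbind, log))
}

#' Score a parameter set on validation windows
#'
#' Rolls out three steps from each validation window's two input frames
#' (deterministic thresholded routing) and averages the chosen metric per
#' horizon over the central evaluation crops.
#'
#' @param params a [voxelflow_params()].
#' @param val_samples samples from [build_dataset()].
#' @param metric metric name (default `"genomedisco"`).
#' @param crop central evaluation crop (default 60).
#' @return numeric vector of length 3: mean metric at horizons 1..3.
#' @export
validation_scores <- function(params, val_samples, metric = "genomedisco",
                              crop = 60L) {
  stopifnot(length(val_samples) >= 1L)
  acc <- matrix(NA_real_, length(val_samples), 3L)
  for (i in seq_along(val_samples)) {
    s <- val_samples[[i]]
    preds <- rollout(s$inputs[[1]], s$inputs[[2]], params, horizon = 3L,
                     routing_mode = "thresholded")
    for (h in 1:3) {
      a <- central_crop(preds[[h]], crop)
      b <- central_crop(s$targets[[h]], crop)
      v <- switch(metric,
                  genomedisco = genomedisco(b, a),
                  pcc = pcc(a, b),
                  psnr = psnr(a, b),
                  ssim = ssim(a, b))
      acc[i, h] <- as.numeric(v)
    }
  }
  colMeans(acc, na.rm = TRUE)
}

#' Select the best checkpoint by weighted validation performance
#'
#' Scores every checkpoint on the validation windows at horizons 1..3 and
#' combines them with weights favoring later timesteps (default
#' `(1, 2, 3) / 6`); ties go to the later epoch.
#'
#' @param checkpoints list of `list(epoch, values)` from [train()].
#' @param params a [voxelflow_params()] used as the architecture shell.
#' @param val_samples validation samples from [build_dataset()].
#' @param metric metric used for scoring.
#' @param weights length-3 horizon weights.
#' @return list with `params` (restored best checkpoint), `epoch`, `score`
#'   and the per-checkpoint `table`.
#' @export
select_checkpoint <- function(checkpoints, params, val_samples,
                              metric = "genomedisco",
                              weights = c(1, 2, 3) / 6) {
  if (length(checkpoints) == 0L)
    stop("select_checkpoint: empty checkpoint list")
  stopifnot(length(weights) == 3L)
  rows <- list()
  for (ck in checkpoints) {
    params_set_values(params, ck$values)
    sc <- validation_scores(params, val_samples, metric = metric)
    rows[[length(rows) + 1L]] <- data.frame(
      epoch = ck$epoch, h1 = sc[1], h2 = sc[2], h3 = sc[3],
      score = sum(weights * sc))
  }
  tab <- do.call(rbind, rows)
  best <- which(tab$score == max(tab$score))
  best <- best[which.max(tab$epoch[best])]  # tie -> later epoch
  params_set_values(params, checkpoints[[best]]$values)
  list(params = params, epoch = tab$epoch[best], score = tab$score[best],
       table = tab)
}
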