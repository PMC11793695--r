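# The user-facing fitting front-end: hicflow() trains a voxel-flow
# forecaster on per-chromosome Hi-C time series and returns a fitted-model
# object with the usual methods.

#' Fit a Hi-C contact-map forecaster
#'
#' Trains the dynamic multi-scale voxel flow network on diagonal 64x64
#' patches of the supplied time series (two input frames, next-frame
#' supervision with the block-weighted loss) and, when validation
#' chromosomes are given, selects the checkpoint with the best weighted
#' validation concordance over the three forecast horizons.
#'
#' @param series named list of [hic_timeseries()] objects, one per
#'   chromosome, each with at least 5 timepoints.
#' @param val_chroms,test_chroms chromosome names held out from training
#'   for validation-based checkpoint selection and final testing.
#' @param model a [voxelflow_config()]; its `cutoff` and `patch_size`
#'   drive preprocessing and are embedded in the fitted object.
#' @param loss a [loss_config()].
#' @param stride diagonal patching stride (default 60).
#' @param epochs,batch_size,lr_init,lr_final,max_steps optimization
#'   settings (see [train()]); defaults follow the reference protocol
#'   (batch 8, Adam, cosine annealing 1e-4 to 1e-5, 100 epochs).
#' @param routing `"sampled"` straight-through gating (default) or
#'   `"full"`.
#' @param select_metric,select_weights checkpoint-selection metric and
#'   horizon weights (later horizons weighted up).
#' @param seed integer seed for initialization, shuffling and routing.
#' @param verbose print per-epoch progress.
#' @return an object of class `hicflow`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_chrom = 2, n_bins = 128, seed = 1)
#' series <- lapply(cohort, `[[`, "series")
#' fit <- hicflow(series, epochs = 2, max_steps = 4, verbose = FALSE)
#' print(fit)
#' }
#' @export
hicflow <- function(series, val_chroms = character(),
                    test_chroms = character(),
                    model = voxelflow_config(),
                    loss = loss_config(), stride = 60L,
                    epochs = 100L, batch_size = 8L,
                    lr_init = 1e-4, lr_final = 1e-5, max_steps = Inf,
                    routing = c("sampled", "full"),
                    select_metric = "genomedisco",
                    select_weights = c(1, 2, 3) / 6,
                    seed = 1L, verbose = FALSE) {
  routing <- match.arg(routing)
  cl <- match.call()
  train_ds <- build_dataset(series, "train", val_chroms, test_chroms,
                            patch_size = model$patch_size, stride = stride,
                            cutoff = model$cutoff)
  val_ds <- if (length(val_chroms))
    build_dataset(series, "val", val_chroms, test_chroms,
                  patch_size = model$patch_size, stride = stride,
                  cutoff = model$cutoff) else list()
  params <- voxelflow_params(model, seed = seed)
  run <- train(train_ds, params, loss_cfg = loss, epochs = epochs,
               batch_size = batch_size, lr_init = lr_init,
               lr_final = lr_final, seed = seed, max_steps = max_steps,
               routing = routing,
               keep_checkpoints = if (length(val_ds)) "all" else "last",
               verbose = verbose)
  if (length(val_ds)) {
    sel <- select_checkpoint(run$checkpoints, params, val_ds,
                             metric = select_metric,
                             weights = select_weights)
    selection <- sel[c("epoch", "score", "table")]
  } else {
    selection <- list(epoch = run$checkpoints[[length(run$checkpoints)]]$epoch,
                      score = NA_real_, table = NULL)
  }
  structure(list(params = params, config = model, loss = loss,
                 stride = as.integer(stride), log = run$log,
                 selection = selection, n_train = length(train_ds),
                 n_val = length(val_ds), val_samples = val_ds,
                 seed = as.integer(seed), call = cl),
            class = "hicflow")
}

#' @export
print.hicflow <- function(x, ...) {
  cat("Hi-C voxel-flow forecaster\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cfg <- x$config
  cat(sprintf("  %d MVFB blocks (scales %s), %dx%d patches, cutoff %g\n",
              cfg$n_blocks, paste(cfg$scales, collapse = ","),
              cfg$patch_size, cfg$patch_size, cfg$cutoff))
  cat(sprintf("  trained on %d windows, %d optimizer steps; final loss %.5f\n",
              x$n_train, nrow(x$log), x$log$loss[nrow(x$log)]))
  cat(sprintf("  selected checkpoint: epoch %d%s\n", x$selection$epoch,
              if (is.na(x$selection$score)) " (last)" else
                sprintf(" (validation score %.4f)", x$selection$score)))
  invisible(x)
}

#' @export
summary.hicflow <- function(object, ...) {
  print(object)
  if (!is.null(object$selection$table)) {
    cat("\nPer-checkpoint validation (horizons 1-3 and weighted score):\n")
    print(round(object$selection$table, 4), row.names = FALSE)
  }
  ep <- stats::aggregate(loss ~ epoch, data = object$log, FUN = mean)
  cat("\nMean loss of first / last epoch: ",
      sprintf("%.5f / %.5f\n", ep$loss[1], ep$loss[nrow(ep)]))
  invisible(object)
}

#' @export
coef.hicflow <- function(object, ...) {
  params_to_values(object$params)
}

.coerce_two_frames <- function(newdata, cutoff) {
  if (inherits(newdata, "HiCTimeSeries")) {
    k <- length(newdata$frames)
    frames <- newdata$frames[c(k - 1L, k)]
  } else if (is.list(newdata) && length(newdata) == 2L) {
    frames <- lapply(newdata, function(f) {
      if (inherits(f, "ContactMatrix")) f else contact_matrix(f)
    })
  } else {
    stop("predict: newdata must be a HiCTimeSeries or a list of two ",
         "contact matrices")
  }
  if (!identical(dim(frames[[1]]$values), dim(frames[[2]]$values)))
    stop("predict: the two input frames differ in size")
  frames
}

#' Forecast future contact maps from a fitted model
#'
#' Normalizes the two most recent frames with the model's embedded cutoff,
#' cuts them into diagonal patches, rolls the forecaster out
#' autoregressively, symmetrizes each predicted patch (optional per config),
#' stitches patches back (mean over overlaps) and restores the count scale.
#'
#' @param object a fitted [hicflow()] model.
#' @param newdata a [hic_timeseries()] (its last two frames are used) or a
#'   list of two [contact_matrix()] objects / square matrices.
#' @param horizon number of future timepoints (default 3).
#' @param routing routing mode at inference; the default `"thresholded"`
#'   is deterministic.
#' @param seed seed for `"sampled"` routing.
#' @param ... unused.
#' @return list of `horizon` [contact_matrix()] objects labeled `t+1` ...
#' @export
predict.hicflow <- function(object, newdata, horizon = 3L,
                            routing = c("thresholded", "sampled", "full"),
                            seed = NULL, ...) {
  routing <- match.arg(routing)
  frames <- .coerce_two_frames(newdata, object$config$cutoff)
  cutoff <- object$config$cutoff
  w <- object$config$patch_size
  n <- nrow(frames[[1]]$values)
  if (n < w)
    stop("predict: input matrices (", n, " bins) are smaller than the ",
         "model patch size ", w)
  norm <- lapply(frames, clip_normalize, cutoff = cutoff)
  ps <- lapply(norm, function(m)
    extract_diagonal_patches(m$values, w, object$stride))
  offsets <- ps[[1]]$offsets
  preds <- vector("list", horizon)
  for (h in seq_len(horizon)) preds[[h]] <- vector("list", length(offsets))
  for (oi in seq_along(offsets)) {
    ro <- rollout(ps[[1]]$patches[[oi]], ps[[2]]$patches[[oi]],
                  object$params, horizon = horizon, routing_mode = routing,
                  seed = if (is.null(seed)) NULL else seed + 31L * oi)
    for (h in seq_len(horizon)) {
      p <- ro[[h]]
      if (object$config$symmetrize_output) p <- (p + t(p)) / 2
      preds[[h]][[oi]] <- p
    }
  }
  out <- vector("list", horizon)
  for (h in seq_len(horizon)) {
    pset <- structure(list(patch_size = w, stride = object$stride,
                           offsets = offsets, patches = preds[[h]],
                           source_n = n),
                      class = "DiagonalPatchSet")
    stitched <- stitch_patches(pset, "mean")
    stitched <- (stitched + t(stitched)) / 2
    cm <- contact_matrix(stitched, frames[[1]]$resolution,
                         frames[[1]]$chromosome, frames[[1]]$start_bin)
    out[[h]] <- denormalize(cm, cutoff)
  }
  names(out) <- paste0("t+", seq_len(horizon))
  out
}

#' Stochastic forecasts under sampled routing
#'
#' Draws `nsim` independent forecasts with Bernoulli-sampled routing
#' vectors, exposing the model's routing-induced predictive variability.
#'
#' @param object a fitted [hicflow()] model.
#' @param nsim number of forecast draws.
#' @param seed integer seed.
#' @param newdata as in [predict.hicflow()].
#' @param horizon forecast horizon.
#' @param ... unused.
#' @return list of `nsim` forecast lists (each as [predict.hicflow()]).
#' @export
simulate.hicflow <- function(object, nsim = 1L, seed = NULL, newdata,
                             horizon = 3L, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- sample.int(1e6, nsim)
  lapply(seq_len(nsim), function(i)
    predict(object, newdata, horizon = horizon, routing = "sampled",
            seed = base[i]))
}

#' @export
residuals.hicflow <- function(object, ...) {
  samples <- if (object$n_val > 0) object$val_samples else NULL
  if (is.null(samples))
    stop("residuals: no validation windows stored; fit with val_chroms")
  lapply(samples, function(s) {
    p <- predict_next(s$inputs[[1]], s$inputs[[2]], object$params,
                      routing_mode = "thresholded")$prediction
    if (object$config$symmetrize_output) p <- (p + t(p)) / 2
    p - s$targets[[1]]
  })
}

#' @export
plot.hicflow <- function(x, ...) {
  has_val <- !is.null(x$selection$table)
  op <- graphics::par(mfrow = c(1L, if (has_val) 2L else 1L))
  on.exit(graphics::par(op))
  graphics::plot(x$log$step, x$log$loss, type = "l", xlab = "optimizer step",
                 ylab = "training loss", main = "Training loss", ...)
  if (has_val) {
    tab <- x$selection$table
    graphics::matplot(tab$epoch, tab[, c("h1", "h2", "h3")], type = "b",
                      pch = 1:3, lty = 1, xlab = "epoch",
                      ylab = "validation concordance",
                      main = "Validation by horizon")
    graphics::legend("bottomright", legend = paste0("t+", 1:3), pch = 1:3,
                     col = 1:3, bty = "n")
    graphics::abline(v = x$selection$epoch, lty = 3)
  }
  invisible(x)
}
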