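# The hicflow() front-end and its S3 methods, on a desk-scale fit.

fit_once <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    series <- small_cohort_series(n_chrom = 2L, n_bins = 72L, seed = 3)
    cfg <- voxelflow_config(patch_size = 64L, n_blocks = 2L,
                            scales = c(2, 1), ch_spatial = 2L,
                            ch_motion = 4L, ch_routing = 2L, cutoff = 100)
    cache <<- hicflow(series, val_chroms = "chr2", model = cfg,
                      loss = loss_config("l1", n_blocks = 2L),
                      epochs = 2L, batch_size = 4L, lr_init = 5e-3,
                      lr_final = 5e-4, seed = 2L)
    cache
  }
})

test_that("the fitted object prints, summarizes and exposes coefficients", {
  fit <- fit_once()
  expect_s3_class(fit, "hicflow")
  expect_output(print(fit), "voxel-flow forecaster")
  expect_output(summary(fit), "validation")
  cf <- coef(fit)
  expect_true(is.list(cf) && length(cf) > 10)
  expect_true(any(grepl("head_w", names(cf))))
  expect_true(fit$selection$epoch %in% 1:2)
})

test_that("predict() returns symmetric non-negative count-scale forecasts", {
  fit <- fit_once()
  series <- small_cohort_series(n_chrom = 1L, n_bins = 72L, seed = 9)
  preds <- predict(fit, series[[1]], horizon = 3)
  expect_named(preds, c("t+1", "t+2", "t+3"))
  for (p in preds) {
    expect_s3_class(p, "ContactMatrix")
    expect_equal(p$values, t(p$values))
    expect_true(all(p$values >= 0))
    expect_lte(max(p$values), fit$config$cutoff)
  }
  # list-of-two-frames input, too
  k <- length(series[[1]]$frames)
  preds2 <- predict(fit, series[[1]]$frames[c(k - 1, k)], horizon = 1)
  expect_equal(preds2[["t+1"]]$values, preds[["t+1"]]$values)
  expect_error(predict(fit, series[[1]]$frames[[1]]), "newdata")
})

test_that("an untrained model started from identical frames stays put", {
  cfg <- voxelflow_config(patch_size = 64L, n_blocks = 2L, scales = c(2, 1),
                          ch_spatial = 2L, ch_motion = 4L, ch_routing = 2L)
  fit <- structure(list(params = voxelflow_params(cfg, seed = 1),
                        config = cfg, stride = 60L),
                   class = "hicflow")
  # zero-initialized heads: prediction of (I, I) is the 0.5/0.5 fusion = I
  m <- contact_matrix(rand_contact(72, seed = 4))
  pred <- predict(fit, list(m, m), horizon = 1)[["t+1"]]
  clipped <- denormalize(clip_normalize(m, cfg$cutoff), cfg$cutoff)
  # predictions exist only on the diagonal patch band; compare there
  covered <- matrix(FALSE, 72, 72)
  for (o in c(0L, 8L)) covered[(o + 1):(o + 64), (o + 1):(o + 64)] <- TRUE
  expect_equal(pred$values[covered], clipped$values[covered],
               tolerance = 1e-8)
  expect_true(all(pred$values[!covered] == 0))
})

test_that("simulate() draws routing-stochastic forecasts reproducibly", {
  fit <- fit_once()
  series <- small_cohort_series(n_chrom = 1L, n_bins = 72L, seed = 9)
  s1 <- simulate(fit, nsim = 2, seed = 5, newdata = series[[1]],
                 horizon = 1)
  s2 <- simulate(fit, nsim = 2, seed = 5, newdata = series[[1]],
                 horizon = 1)
  expect_length(s1, 2L)
  expect_equal(s1[[1]][["t+1"]]$values, s2[[1]][["t+1"]]$values)
})

test_that("residuals come from held-out validation windows", {
  fit <- fit_once()
  res <- residuals(fit)
  expect_gte(length(res), 1L)
  expect_true(all(vapply(res, function(r)
    all(dim(r) == fit$config$patch_size), logical(1))))
  expect_lt(max(abs(res[[1]])), 1 + 1e-9)
})

test_that("plot() renders without error", {
  fit <- fit_once()
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
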