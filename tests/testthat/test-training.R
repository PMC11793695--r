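test_that("cosine schedule hits its endpoints and never increases", {
  lrs <- vapply(1:100, cosine_lr, numeric(1), epochs = 100)
  expect_equal(lrs[1], 1e-4)
  expect_equal(lrs[100], 1e-5)
  expect_true(all(diff(lrs) < 0))
  expect_equal(cosine_lr(1, 1, 3e-3, 1e-5), 3e-3)
})

test_that("dataset assembly enumerates patch x window combinations", {
  mk_series <- function(k, n = 70, seed = 1) {
    frames <- lapply(seq_len(k), function(t)
      contact_matrix(rand_contact(n, seed + t), chromosome = "x"))
    hic_timeseries(frames)
  }
  # 6 timepoints -> 2 windows per patch; n=70, patch 64, stride 60 -> 2
  # offsets (0 and trailing 6)
  ds <- build_dataset(list(chrA = mk_series(6)), "train",
                      val_chroms = character(), test_chroms = character())
  expect_length(ds, 2L * 2L)
  expect_setequal(unique(vapply(ds, `[[`, integer(1), "offset")), c(0L, 6L))
  ds5 <- build_dataset(list(chrA = mk_series(5)), "train",
                       val_chroms = character(), test_chroms = character())
  expect_length(ds5, 2L)  # one window per patch

  expect_error(build_dataset(list(chrA = mk_series(4)), "train",
                             val_chroms = character(),
                             test_chroms = character()),
               "chrA.*timepoints")
  expect_error(build_dataset(list(chrA = mk_series(6)), "train",
                             val_chroms = "chr1", test_chroms = "chr1"),
               "both")
  # split membership
  ser <- list(chr1 = mk_series(6), chr19 = mk_series(6, seed = 7))
  tr <- build_dataset(ser, "train", val_chroms = "chr19",
                      test_chroms = character())
  va <- build_dataset(ser, "val", val_chroms = "chr19",
                      test_chroms = character())
  expect_setequal(unique(vapply(tr, `[[`, character(1), "chromosome")),
                  "chr1")
  expect_setequal(unique(vapply(va, `[[`, character(1), "chromosome")),
                  "chr19")
  # inputs are normalized
  expect_true(all(vapply(tr, function(s)
    max(s$inputs[[1]], s$inputs[[2]]) <= 1, logical(1))))
})

test_that("training runs are reproducible and losses decrease", {
  series <- small_cohort_series(n_chrom = 1L, n_bins = 72L, seed = 2)
  ds <- build_dataset(series, "train", val_chroms = character(),
                      test_chroms = character(), patch_size = 64L)
  expect_gte(length(ds), 2L)
  cfg <- voxelflow_config(patch_size = 64L, n_blocks = 2L, scales = c(2, 1),
                          ch_spatial = 2L, ch_motion = 4L, ch_routing = 2L)
  lc <- loss_config("l1", n_blocks = 2L)

  run1 <- train(ds, voxelflow_params(cfg, seed = 3), lc, epochs = 1L,
                batch_size = 2L, lr_init = 1e-2, lr_final = 1e-2, seed = 4L,
                max_steps = 1L)
  run2 <- train(ds, voxelflow_params(cfg, seed = 3), lc, epochs = 1L,
                batch_size = 2L, lr_init = 1e-2, lr_final = 1e-2, seed = 4L,
                max_steps = 1L)
  expect_identical(run1$log$loss[1], run2$log$loss[1])

  run <- train(ds, voxelflow_params(cfg, seed = 3), lc, epochs = 50L,
               batch_size = length(ds), lr_init = 5e-3, lr_final = 5e-4,
               seed = 4L, max_steps = 50L, keep_checkpoints = "last")
  # smoke: the fixed-batch loss drops substantially over 50 steps
  expect_lt(mean(tail(run$log$loss, 5)), 0.8 * mean(head(run$log$loss, 5)))
  # bookkeeping: one step per batch, one checkpoint per epoch retained
  expect_equal(nrow(run$log), 50L)
  expect_length(run$checkpoints, 1L)
  expect_error(train(list(), voxelflow_params(cfg), lc), "empty")
})

test_that("checkpoint selection weighs horizons and breaks ties late", {
  series <- small_cohort_series(n_chrom = 1L, n_bins = 72L, seed = 5)
  ds <- build_dataset(series, "train", val_chroms = character(),
                      test_chroms = character())
  cfg <- voxelflow_config(patch_size = 64L, n_blocks = 2L, scales = c(2, 1),
                          ch_spatial = 2L, ch_motion = 4L, ch_routing = 2L)
  params <- voxelflow_params(cfg, seed = 1)
  ck1 <- list(epoch = 1L, values = params_to_values(params))
  sel <- select_checkpoint(list(ck1), params, ds)
  expect_equal(sel$epoch, 1L)
  # identical parameter sets: the later epoch must win the tie
  ck2 <- list(epoch = 2L, values = ck1$values)
  sel <- select_checkpoint(list(ck1, ck2), params, ds)
  expect_equal(sel$epoch, 2L)
  # degenerate weights: only horizon 3 counts
  sel3 <- select_checkpoint(list(ck1, ck2), params, ds, weights = c(0, 0, 1))
  expect_equal(sel3$score, sel3$table$h3[2])
  expect_error(select_checkpoint(list(), params, ds), "empty")
})

test_that("checkpoints round-trip with their embedded config", {
  params <- tiny_params(seed = 12)
  f <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(params, f, epoch = 42L)
  back <- read_checkpoint(f)
  expect_equal(attr(back, "epoch"), 42L)
  expect_equal(back$config, params$config)
  expect_equal(params_to_values(back), params_to_values(params))
})
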