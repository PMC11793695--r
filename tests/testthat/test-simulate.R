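test_that("expected matrices combine decay, TAD blocks and loops", {
  cfg <- sim_config(n_bins = 64, noise = "none")
  e <- expected_matrix(cfg, 0)$values
  # pure distance decay: strictly decreasing along the first row
  expect_true(all(diff(e[1, ]) < 0))
  expect_equal(e, t(e))

  cfg2 <- sim_config(n_bins = 64, noise = "none",
                     tad_blocks = data.frame(start = 10, end = 30,
                                             intensity = 50, drift = 0))
  m0 <- expected_matrix(cfg2, 0)$values
  m4 <- expected_matrix(cfg2, 4)$values
  expect_equal(m0, m4)  # no drift -> static dynamics

  cfg3 <- sim_config(n_bins = 64, noise = "none",
                     tad_blocks = data.frame(start = 10, end = 30,
                                             intensity = 50, drift = 1))
  for (t in 0:3) {
    m <- expected_matrix(cfg3, t)$values
    base <- expected_matrix(cfg, t)$values
    lifted <- which(m[, 15 + t] - base[, 15 + t] > 49)
    expect_equal(range(lifted), c(10 + t + 1, 30 + t))  # 1-based block rows
  }
  expect_error(sim_config(n_bins = 64, tad_blocks =
    data.frame(start = 55, end = 64, intensity = 10, drift = 2)), "drifted")
})

test_that("simulated series are reproducible and match their truth", {
  cfg <- sim_config(n_bins = 48, noise = "none", n_timepoints = 5,
                    tad_blocks = data.frame(start = 5, end = 25,
                                            intensity = 40, drift = 1))
  sim <- simulate_timeseries(cfg)
  for (t in 1:5)
    expect_equal(sim$series$frames[[t]]$values,
                 sim$truth$expected[[t]]$values)

  cfgp <- sim_config(n_bins = 48, noise = "poisson", seed = 9)
  s1 <- simulate_timeseries(cfgp)
  s2 <- simulate_timeseries(cfgp)
  for (t in 1:6)
    expect_identical(s1$series$frames[[t]]$values,
                     s2$series$frames[[t]]$values)
})

test_that("Poisson sampling concentrates on the expected matrix", {
  cfg <- sim_config(n_bins = 16, noise = "poisson", n_timepoints = 5,
                    depth_scale = 50)
  lam <- expected_matrix(cfg, 0)$values
  acc <- matrix(0, 16, 16)
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    c2 <- cfg
    c2$seed <- 10000L + r
    acc <- acc + simulate_timeseries(c2)$series$frames[[1]]$values
  }
  mean_err <- abs(acc / n_rep - lam)
  expect_true(all(mean_err <= 4 * sqrt(lam / n_rep) + 1e-9))
})

test_that("all scenario frames are valid symmetric non-negative matrices", {
  scen <- benchmark_scenarios(n_bins = 96, seed = 3)
  for (cfg in scen) {
    sim <- simulate_timeseries(cfg)
    for (f in sim$series$frames) {
      expect_true(all(f$values >= 0))
      expect_equal(f$values, t(f$values))
    }
  }
})

test_that("persistence baseline separates static from drifting dynamics", {
  scen <- benchmark_scenarios(n_bins = 96, seed = 5, noise = "none")
  stat <- simulate_timeseries(scen$static)$series
  drift <- simulate_timeseries(scen$drift)$series
  for (h in 1:3) {
    # copy-last-frame forecast of t3+h compared to the truth at t3+h
    s_static <- evaluate_matrices(stat$frames[[3]], stat$frames[[3 + h]],
                                  patch_size = 48, stride = 48)
    s_drift <- evaluate_matrices(drift$frames[[3]], drift$frames[[3 + h]],
                                 patch_size = 48, stride = 48)
    expect_equal(s_static$per_matrix[["genomedisco"]], 1)
    expect_lt(s_drift$per_matrix[["genomedisco"]], 1)
  }
})

test_that("truth sidecar boundaries match an edge scan of the frames", {
  cfg <- sim_config(n_bins = 64, noise = "none",
                    tad_blocks = data.frame(start = 12, end = 40,
                                            intensity = 60, drift = 1))
  sim <- simulate_timeseries(cfg)
  for (t in c(1, 4)) {
    m <- sim$series$frames[[t]]$values
    # scan the near-diagonal for the largest intensity step
    band <- vapply(1:(64 - 2), function(i) m[i, i + 2], numeric(1))
    jumps <- abs(diff(band))
    edges <- sort(order(jumps, decreasing = TRUE)[1:2])
    tb <- sim$truth$tad_boundaries[[t]]
    expect_equal(edges[1], tb$start)       # rising edge at start (0-based)
    expect_equal(edges[2], tb$end - 2L)    # falling edge near end
  }
})

test_that("benchmark suites regenerate byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  scen <- benchmark_scenarios(n_bins = 64, seed = 7)
  scen <- lapply(scen, function(cfg) { cfg$n_timepoints <- 5L; cfg })
  make_benchmark_suite(scen, d1)
  make_benchmark_suite(scen, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(sort(files), sort(list.files(d2, recursive = TRUE)))
  expect_length(files, 3L * (5L + 1L) + 1L)  # triplets + truth + manifest
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # truth sidecar parses and has one boundary table per timepoint
  truth <- jsonlite::read_json(file.path(d1, "drift", "truth.json"))
  expect_length(truth$tad_boundaries, 5L)
})
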