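test_that("concordance attains 1 exactly on identical patches", {
  for (i in 1:20) {
    a <- rand_contact(12, seed = i)
    expect_equal(genomedisco(a, a), 1)
  }
})

test_that("concordance matches a brute-force random-walk oracle", {
  # two 4x4 patches with disjoint single off-diagonal contacts
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1
  b <- matrix(0, 4, 4); b[3, 4] <- b[4, 3] <- 1
  rownorm <- function(m) {
    rs <- rowSums(m)
    m / ifelse(rs > 0, rs, 1)
  }
  pa <- rownorm(a); pb <- rownorm(b)
  pa3 <- pa %*% pa %*% pa
  pb3 <- pb %*% pb %*% pb
  oracle <- 1 - sum(abs(pa3 - pb3)) / ((2 + 2) / 2)
  expect_equal(genomedisco(a, b), oracle, tolerance = 1e-10)
  expect_lt(genomedisco(a, b), 1)
  # symmetry of the score
  set.seed(3)
  for (i in 1:10) {
    x <- rand_contact(8, seed = i)
    y <- rand_contact(8, seed = i + 50)
    expect_equal(genomedisco(x, y), genomedisco(y, x))
  }
  # all-zero patch signals a skip
  z <- matrix(0, 4, 4)
  expect_true(is.na(genomedisco(z, a)))
  expect_equal(attr(genomedisco(z, a), "skip"), "all-zero patch")
})

test_that("concordance degrades with increasing noise on average", {
  set.seed(17)
  base <- rand_contact(20, seed = 99)
  eps <- c(0, 0.2, 0.5, 1, 2)
  scores <- vapply(eps, function(e) {
    mean(vapply(1:5, function(r) {
      noise <- matrix(rpois(400, 5), 20, 20)
      noise <- (noise + t(noise)) / 2
      genomedisco(base, base + e * noise)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-8))
  expect_equal(scores[1], 1)
})

test_that("patch PCC follows the textbook formula", {
  a <- rand_contact(10, seed = 1)
  expect_equal(pcc(a, a), 1)
  expect_equal(pcc(a, -2 * a + 7), -1)
  x <- matrix(c(1, 2, 3, 4), 2, 2)
  y <- matrix(c(1, 2, 3, 5), 2, 2)
  xv <- as.vector(x); yv <- as.vector(y)
  oracle <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  expect_equal(pcc(x, y), oracle)
  expect_true(is.na(pcc(matrix(1, 3, 3), a[1:3, 1:3])))
  # invariance to separate positive affine maps
  b <- rand_contact(10, seed = 2)
  expect_equal(pcc(3 * a + 1, 0.5 * b + 4), pcc(a, b))
})

test_that("PSNR closed forms hold and identical patches flag infinity", {
  a <- matrix(0, 4, 4)
  b <- matrix(1, 4, 4)
  expect_equal(psnr(a, b, peak = 1), 0)          # MSE = peak^2
  b2 <- matrix(c(rep(0.1, 16)), 4, 4)
  expect_equal(psnr(a, b2, peak = 1), 20)        # MSE = 0.01
  expect_true(is.infinite(psnr(a, a)))
  expect_error(psnr(a, b, peak = 0), "peak")
})

test_that("SSIM fixed points and a hand-computed toy value", {
  a <- rand_contact(8, seed = 4) / 20
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(matrix(0.3, 4, 4), matrix(0.3, 4, 4)), 1)
  x <- matrix(c(0, 1, 1, 0), 2, 2)
  y <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  mx <- mean(x); my <- mean(y)
  vx <- var(as.vector(x)); vy <- var(as.vector(y))
  cxy <- cov(as.vector(x), as.vector(y))
  c1 <- 1e-4; c2 <- 9e-4
  oracle <- (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(x, y, L = 1), oracle)
  expect_error(ssim(x, y, L = 0), "L")
})

test_that("matrix evaluation averages per-patch scores with bookkeeping", {
  m <- rand_contact(180, seed = 21)
  rep_ <- evaluate_matrices(m, m, patch_size = 60, stride = 60)
  expect_equal(rep_$n_patches_used, 3L)
  expect_equal(rep_$per_matrix[["genomedisco"]], 1)
  expect_equal(rep_$per_matrix[["pcc"]], 1)
  expect_equal(rep_$per_matrix[["ssim"]], 1)
  expect_equal(rep_$n_psnr_infinite, 3L)
  expect_true(is.na(rep_$per_matrix[["psnr"]]))
  # per-matrix mean equals the mean of the per-patch table
  n <- rand_contact(180, seed = 22)
  rep2 <- evaluate_matrices(n, m)
  expect_equal(rep2$per_matrix[["pcc"]], mean(rep2$per_patch$pcc))
  expect_equal(rep2$per_matrix[["genomedisco"]],
               mean(rep2$per_patch$genomedisco))
  expect_equal(rep2$n_patches_used + rep2$n_patches_skipped,
               length(extract_diagonal_patches(m, 60, 60)$offsets))
  # all-zero truth: every patch skipped
  z <- matrix(0, 120, 120)
  rep3 <- evaluate_matrices(rand_contact(120, 1), z)
  expect_equal(rep3$n_patches_used, 0L)
  expect_true(is.na(rep3$per_matrix[["genomedisco"]]))
  expect_error(evaluate_matrices(m, matrix(0, 10, 10)), "shape")
})

test_that("interaction recovery counts canonical bin pairs", {
  truth <- data.frame(bin_i = c(1, 5, 9, 2), bin_j = c(4, 8, 12, 7),
                      p_value = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(interaction_recovery_rate(truth, truth), 100)
  none <- data.frame(bin_i = 20, bin_j = 30, p_value = 0.001)
  expect_equal(interaction_recovery_rate(none, truth), 0)
  half <- truth[1:2, ]
  expect_equal(interaction_recovery_rate(half, truth), 50)
  # order of the pair does not matter
  flipped <- data.frame(bin_i = truth$bin_j, bin_j = truth$bin_i,
                        p_value = truth$p_value)
  expect_equal(interaction_recovery_rate(flipped, truth), 100)
  # significance filter drops p > 0.05 records
  mixed <- rbind(truth, data.frame(bin_i = 50, bin_j = 60, p_value = 0.5))
  expect_equal(interaction_recovery_rate(truth, mixed), 100)
  expect_error(interaction_recovery_rate(truth,
    data.frame(bin_i = 1, bin_j = 2, p_value = 0.9)), "undefined|filter")
  # literal reading of the filter direction is available
  expect_equal(interaction_recovery_rate(
    data.frame(bin_i = 50, bin_j = 60, p_value = 0.5), mixed,
    direction = "literal_gt"), 100)
  # fuzzy matching tolerates one-bin shifts
  shifted <- transform(truth, bin_i = bin_i + 1)
  expect_equal(interaction_recovery_rate(shifted, truth, match = "fuzzy1"),
               100)
  expect_equal(interaction_recovery_rate(shifted, truth), 0)
})

test_that("interaction sets round-trip through BEDPE-like text", {
  x <- data.frame(bin_i = c(2L, 7L), bin_j = c(9L, 11L),
                  p_value = c(0.01, 0.2))
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_interactions(x, f, resolution = 40000)
  y <- read_interactions(f, resolution = 40000)
  expect_equal(y, x)
})

test_that("timestep similarity is maximal on the diagonal and symmetric", {
  cfg <- sim_config(n_bins = 120, n_timepoints = 5,
                    tad_blocks = data.frame(start = 20, end = 60,
                                            intensity = 80, drift = 2),
                    noise = "none", seed = 2)
  ser <- simulate_timeseries(cfg)$series
  sim <- timestep_similarity_matrix(ser, ser, patch_size = 60, stride = 60)
  expect_equal(diag(sim), rep(1, 5), ignore_attr = TRUE)
  expect_equal(sim, t(sim))
  # scores decay with timestep distance (drift dynamics)
  for (lag in 1:3) {
    band <- function(l) mean(sim[cbind(1:(5 - l), (1 + l):5)])
    expect_gt(band(lag), band(lag + 1) - 1e-12)
  }
})
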