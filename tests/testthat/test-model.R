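# oracle: shift a matrix by an integer displacement with clamp-to-edge,
# matching out(y, x) = img[clamp(y + dy), clamp(x + dx)]
shift_oracle <- function(img, dx, dy) {
  n <- nrow(img)
  out <- img
  for (y in seq_len(n)) for (x in seq_len(n)) {
    sy <- min(max(y + dy, 1L), n)
    sx <- min(max(x + dx, 1L), n)
    out[y, x] <- img[sy, sx]
  }
  out
}

const_flow <- function(w, dx, dy) {
  fl <- array(0, c(w, w, 2))
  fl[, , 1] <- dx
  fl[, , 2] <- dy
  fl
}

test_that("backward warp with zero flow is the identity", {
  for (i in 1:5) {
    img <- rand_frame(16, seed = i)
    expect_identical(backward_warp(img, array(0, c(16, 16, 2))), img)
  }
})

test_that("backward warp matches the integer-shift oracle", {
  set.seed(23)
  for (i in 1:20) {
    img <- rand_frame(16, seed = 100 + i)
    dx <- sample(-17:17, 1)
    dy <- sample(-17:17, 1)
    expect_equal(backward_warp(img, const_flow(16, dx, dy)),
                 shift_oracle(img, dx, dy))
  }
})

test_that("backward warp interpolates fractional flows bilinearly", {
  # ramp r(x) = x along columns: shifting by +0.5 samples x + 0.5
  w <- 8
  img <- matrix(rep(0:(w - 1), each = w), w, w)  # img[y, x] = x - 1
  out <- backward_warp(img, const_flow(w, 0.5, 0))
  expect_equal(out[, 1:(w - 1)], img[, 1:(w - 1)] + 0.5)
  expect_error(backward_warp(img, array(0, c(4, 4, 2))), "flow")
})

test_that("mask fusion obeys its closed forms and convexity", {
  a <- rand_frame(8, 1)
  b <- rand_frame(8, 2)
  expect_equal(fuse(a, b, matrix(1, 8, 8)), a)
  expect_equal(fuse(a, b, matrix(0, 8, 8)), b)
  expect_equal(fuse(matrix(0, 8, 8), matrix(1, 8, 8), matrix(0.5, 8, 8)),
               matrix(0.5, 8, 8))
  expect_error(fuse(a, b, matrix(2, 8, 8)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:10) {
    mask <- matrix(runif(64), 8, 8)
    f <- fuse(a, b, mask)
    expect_true(all(f >= pmin(a, b) - 1e-12 & f <= pmax(a, b) + 1e-12))
  }
})

test_that("an MVFB block with zero weights averages its two inputs", {
  cfg <- tiny_config()
  params <- voxelflow_params(cfg, seed = 1)
  blk <- params$blocks[[1]]
  for (p in hicflow:::hf_flatten_params(blk)) p$value <- p$value * 0
  prev <- rand_frame(16, 1)
  cur <- rand_frame(16, 2)
  out <- mvfb_forward(prev, cur, cur, hicflow:::zero_flow_state(16), blk, 2)
  expect_equal(out$pred, 0.5 * prev + 0.5 * cur)
  expect_equal(out$flow$mask, matrix(0.5, 16, 16))
  expect_true(all(out$flow$flow_to_cur == 0))
})

test_that("MVFB output shapes are scale-invariant and deterministic", {
  params <- tiny_params(seed = 3)
  prev <- rand_frame(16, 5)
  cur <- rand_frame(16, 6)
  fs <- hicflow:::zero_flow_state(16)
  o1 <- mvfb_forward(prev, cur, cur, fs, params$blocks[[1]], 1)
  o2 <- mvfb_forward(prev, cur, cur, fs, params$blocks[[1]], 2)
  expect_identical(dim(o1$pred), dim(o2$pred))
  o1b <- mvfb_forward(prev, cur, cur, fs, params$blocks[[1]], 1)
  expect_identical(o1$pred, o1b$pred)
})

test_that("routing weights follow the sigmoid-normalized clamped rule", {
  for (v in c(-3, 0, 2))
    expect_equal(routing_weights(rep(v, 9)), rep(0.5, 9))
  w <- routing_weights(c(40, rep(-40, 8)))
  expect_equal(w[1], 1)
  set.seed(9)
  for (i in 1:20) {
    w <- routing_weights(rnorm(9, sd = 4))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("routing module emits probabilities in [0, 1]", {
  params <- tiny_params(seed = 8)
  rf <- routing_forward(rand_frame(16, 1), rand_frame(16, 2), params)
  expect_length(rf$w_tilde, 3L)
  expect_true(all(rf$w_tilde >= 0 & rf$w_tilde <= 1))
  expect_equal(rf$w_tilde, routing_weights(rf$v_tilde))
})

test_that("straight-through Bernoulli sampling is correct at the extremes", {
  expect_equal(stebs_sample(rep(1, 9), seed = 1), rep(1L, 9))
  expect_equal(stebs_sample(rep(0, 9), seed = 1), rep(0L, 9))
  expect_identical(stebs_sample(rep(0.5, 9), seed = 7),
                   stebs_sample(rep(0.5, 9), seed = 7))
  draws <- stebs_sample(rep(0.5, 10000), seed = 11)
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("predict_next honors forced routing and stays in range", {
  params <- tiny_params(seed = 2)
  prev <- rand_frame(16, 3)
  cur <- rand_frame(16, 4)
  # all blocks gated off: pure pass-through of the initialization
  out <- predict_next(prev, cur, params, routing_mode = "sampled",
                      v_force = rep(0L, 3))
  expect_equal(out$prediction, cur)
  out_full <- predict_next(prev, cur, params, routing_mode = "full")
  expect_true(all(is.finite(out_full$prediction)))
  expect_true(all(out_full$prediction >= 0 & out_full$prediction <= 1))
  expect_length(out_full$per_block, 3L)
  # determinism under a fixed routing seed
  a <- predict_next(prev, cur, params, routing_mode = "sampled", seed = 5)
  b <- predict_next(prev, cur, params, routing_mode = "sampled", seed = 5)
  expect_identical(a$prediction, b$prediction)
  expect_identical(a$routing$v, b$routing$v)
  expect_error(predict_next(rand_frame(8), rand_frame(8), params), "size")
  expect_error(predict_next(prev * 3, cur, params), "normalized")
})

test_that("rollout is autoregressive with the documented base case", {
  params <- tiny_params(seed = 6)
  prev <- rand_frame(16, 7)
  cur <- rand_frame(16, 8)
  r1 <- rollout(prev, cur, params, horizon = 1, routing_mode = "thresholded")
  p1 <- predict_next(prev, cur, params, routing_mode = "thresholded")
  expect_equal(r1[[1]], p1$prediction)
  r3 <- rollout(prev, cur, params, horizon = 3, routing_mode = "thresholded")
  expect_length(r3, 3L)
  for (f in r3) expect_true(all(f >= 0 & f <= 1))
  # a model that copies its second input (all blocks off) is a fixed point
  rz <- rollout(prev, cur, params, horizon = 3, routing_mode = "sampled",
                v_force = rep(0L, 3))
  for (f in rz) expect_equal(f, cur)
  expect_error(rollout(prev, cur, params, horizon = 0), "horizon")
})
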