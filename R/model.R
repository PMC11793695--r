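# The dynamic multi-scale voxel flow forecaster.
#
# A prediction for frame I_{t+1} is synthesized from the two preceding frames
# by estimating two backward optical flows f_{t+1->t-1}, f_{t+1->t} and a
# fusion mask m, refined through a chain of multi-scale voxel flow blocks
# (MVFB). A routing module decides, per input, which blocks participate at
# inference via Bernoulli gates with a straight-through gradient estimator.

#' Model architecture configuration
#'
#' @param patch_size side length of the square input frames (bins).
#' @param n_blocks number of MVFB blocks in the chain (default 9).
#' @param scales per-block spatial scaling factors `S_i`, coarse to fine.
#' @param ch_spatial channel width of the full-resolution spatial path.
#' @param ch_motion channel width of the downscaled motion path.
#' @param ch_routing channel width of the routing convolution.
#' @param cutoff normalization cutoff the model was / will be trained with;
#'   embedded in checkpoints so prediction can refuse mismatched inputs.
#' @param resolution bin resolution in bp, metadata carried into checkpoints.
#' @param symmetrize_output if `TRUE`, predicted patches are symmetrized as
#'   `(P + t(P)) / 2` (contact maps are symmetric; warping is not
#'   symmetry-preserving).
#' @return an object of class `voxelflow_config`.
#' @export
voxelflow_config <- function(patch_size = 64L, n_blocks = 9L,
                             scales = c(4, 4, 4, 2, 2, 2, 1, 1, 1),
                             ch_spatial = 8L, ch_motion = 16L,
                             ch_routing = 8L, cutoff = 100,
                             resolution = 40000L,
                             symmetrize_output = TRUE) {
  stopifnot(n_blocks >= 1L, length(scales) == n_blocks, all(scales >= 1),
            patch_size >= 4L, cutoff > 0)
  structure(list(patch_size = as.integer(patch_size),
                 n_blocks = as.integer(n_blocks),
                 scales = as.numeric(scales),
                 ch_spatial = as.integer(ch_spatial),
                 ch_motion = as.integer(ch_motion),
                 ch_routing = as.integer(ch_routing),
                 cutoff = cutoff,
                 resolution = as.integer(resolution),
                 symmetrize_output = isTRUE(symmetrize_output)),
            class = "voxelflow_config")
}

.conv_param <- function(kh, kw, cin, cout, gain = 1) {
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = gain * sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  list(w = hf_param(w), b = hf_param(numeric(cout)))
}

#' Initialize voxel-flow model parameters
#'
#' Convolution weights use He-scaled Gaussian initialization; PReLU slopes
#' start at 0.25; the per-block flow/mask head starts at zero so the initial
#' prediction is the mask-0.5 fusion of the two (unwarped) input frames.
#'
#' @param config a [voxelflow_config()].
#' @param seed integer seed for the weight draw.
#' @return a nested list of parameter tensors of class `voxelflow_params`.
#' @export
voxelflow_params <- function(config = voxelflow_config(), seed = 1L) {
  set.seed(seed)
  cs <- config$ch_spatial
  cm <- config$ch_motion
  cr <- config$ch_routing
  cin <- 8L  # prev + cur + pred_in + 4 flow channels + mask
  blocks <- lapply(seq_len(config$n_blocks), function(i) {
    list(
      sc1 = .conv_param(3, 3, cin, cs),
      sc2 = .conv_param(3, 3, cs, cs),
      a_s1 = hf_param(rep(0.25, cs)), a_s2 = hf_param(rep(0.25, cs)),
      mc = lapply(seq_len(6), function(j)
        .conv_param(3, 3, if (j == 1) cin else cm, cm)),
      a_m = lapply(seq_len(6), function(j) hf_param(rep(0.25, cm))),
      # transposed-convolution head -> (2 flows x 2) + mask logit; zero init
      head_w = hf_param(array(0, dim = c(3, 3, 5, cs + cm))),
      head_b = hf_param(numeric(5))
    )
  })
  routing <- list(
    conv = .conv_param(3, 3, 2L, cr),
    a_r = hf_param(rep(0.25, cr)),
    lin_w = hf_param(matrix(stats::rnorm(config$n_blocks * cr, sd = sqrt(1 / cr)),
                            nrow = config$n_blocks)),
    lin_b = hf_param(numeric(config$n_blocks))
  )
  structure(list(blocks = blocks, routing = routing, config = config),
            class = "voxelflow_params")
}

#' Backward warping of a frame by a displacement field
#'
#' `output[y, x]` is the bilinear sample of `image` at `(x + flow[y, x, 1],
#' y + flow[y, x, 2])` (0-based pixel coordinates, clamp-to-edge sampling).
#'
#' @param image a `w x w` numeric matrix.
#' @param flow a `w x w x 2` array; channel 1 is the column (x) displacement,
#'   channel 2 the row (y) displacement, in pixels.
#' @return the warped matrix.
#' @export
backward_warp <- function(image, flow) {
  stopifnot(is.matrix(image))
  if (!identical(dim(flow)[1:2], dim(image)) || dim(flow)[3] != 2L)
    stop("backward_warp: flow must be dim(image) x 2")
  out <- cpp_warp_fwd(hf_as4d(image), hf_as4d(flow))
  matrix(out, nrow = nrow(image))
}

#' Mask fusion of two single-frame estimates
#'
#' Combines the estimate warped from the earlier frame and the estimate
#' warped from the current frame: `mask * pred_from_prev +
#' (1 - mask) * pred_from_cur`, elementwise.
#'
#' @param pred_from_prev,pred_from_cur matrices of equal size.
#' @param mask matrix of the same size with entries in `[0, 1]`.
#' @return the fused matrix.
#' @export
fuse <- function(pred_from_prev, pred_from_cur, mask) {
  stopifnot(identical(dim(pred_from_prev), dim(pred_from_cur)),
            identical(dim(mask), dim(pred_from_prev)))
  if (any(mask < 0 | mask > 1)) stop("fuse: mask entries must lie in [0, 1]")
  mask * pred_from_prev + (1 - mask) * pred_from_cur
}

#' Flow-state container
#'
#' @param flow_to_prev,flow_to_cur `w x w x 2` displacement fields.
#' @param mask `w x w` fusion mask in `[0, 1]`.
#' @return a `flow_state` list.
#' @export
flow_state <- function(flow_to_prev, flow_to_cur, mask) {
  stopifnot(dim(flow_to_prev)[3] == 2L, dim(flow_to_cur)[3] == 2L)
  if (any(mask < 0 | mask > 1)) stop("flow_state: mask must lie in [0, 1]")
  structure(list(flow_to_prev = flow_to_prev, flow_to_cur = flow_to_cur,
                 mask = mask), class = "flow_state")
}

zero_flow_state <- function(w) {
  flow_state(array(0, c(w, w, 2)), array(0, c(w, w, 2)),
             matrix(0.5, w, w))
}

# ---- internal tensor-level forward pieces ----------------------------------

# One MVFB block on tensors. state: list(pred, flow (H,W,4,N), mlogit (H,W,1,N))
.mvfb_block <- function(prev, cur, state, blk, scale) {
  d <- dim(prev$value)
  H <- d[1]; W <- d[2]
  mask <- op_sigmoid(state$mlogit)
  xin <- op_concat_c(list(prev, cur, state$pred, state$flow, mask))
  # motion path: shrink by 1/S, six PReLU convolutions (first stride 2),
  # then restore to input resolution (factor 2S)
  m <- op_resize(xin, max(2L, round(H / scale)), max(2L, round(W / scale)))
  for (j in seq_len(6)) {
    m <- op_conv2d(m, blk$mc[[j]]$w, blk$mc[[j]]$b,
                   stride = if (j == 1) 2L else 1L, pad = 1L)
    m <- op_prelu(m, blk$a_m[[j]])
  }
  m <- op_resize(m, H, W)
  # spatial path at full resolution
  s <- op_prelu(op_conv2d(xin, blk$sc1$w, blk$sc1$b), blk$a_s1)
  s <- op_prelu(op_conv2d(s, blk$sc2$w, blk$sc2$b), blk$a_s2)
  # transposed-convolution head estimates residual flows and mask logit
  o <- op_deconv2d(op_concat_c(list(s, m)), blk$head_w, blk$head_b)
  flow_out <- op_add(state$flow, op_slice_c(o, 1:4))
  mlogit_out <- op_add(state$mlogit, op_slice_c(o, 5L))
  mask_out <- op_sigmoid(mlogit_out)
  wp <- op_warp(prev, op_slice_c(flow_out, 1:2))
  wc <- op_warp(cur, op_slice_c(flow_out, 3:4))
  pred <- op_add(op_cmul(mask_out, wp),
                 op_cmul(op_sub(hf_tensor(array(1, dim(mask_out$value))), mask_out), wc))
  list(pred = pred, flow = flow_out, mlogit = mlogit_out)
}

# Routing probabilities from the two input frames (tensor level).
# Returns list(logits (n x N matrix), w_tilde tensor (1,1,n,N)).
.routing_forward <- function(prev, cur, params) {
  rt <- params$routing
  n <- params$config$n_blocks
  xin <- op_concat_c(list(prev, cur))
  r <- op_prelu(op_conv2d(xin, rt$conv$w, rt$conv$b, stride = 2L), rt$a_r)
  g <- op_gap(r)
  lin <- op_linear(g, rt$lin_w, rt$lin_b)  # (1,1,n,N) pre-sigmoid logits
  w_tilde <- .op_routing_weights(lin, n)
  list(logits = matrix(lin$value, nrow = n), w_tilde = w_tilde)
}

# w_i = min((n/2) * sigmoid(v_i) / sum_j sigmoid(v_j), 1), differentiable.
.op_routing_weights <- function(lin, n) {
  d <- dim(lin$value)
  N <- d[4]
  sig <- 1 / (1 + exp(-lin$value))
  sm <- matrix(sig, nrow = n)
  S <- colSums(sm)
  raw <- sweep(sm, 2, S, "/") * (n / 2)
  w <- pmin(raw, 1)
  val <- array(w, dim = d)
  hf_tensor(val, parents = list(lin), backward = function(g) {
    gm <- matrix(g, nrow = n)
    gm[raw >= 1] <- 0  # clamped entries
    gv <- matrix(0, n, N)
    for (s in seq_len(N)) {
      sv <- sm[, s]
      sp <- sv * (1 - sv)
      # d w_i / d v_j = (n/2) * (delta_ij * sp_i * S - sv_i * sp_j) / S^2
      J <- -outer(sv, sp) / S[s]^2
      diag(J) <- diag(J) + sp / S[s]
      gv[, s] <- (n / 2) * t(J) %*% gm[, s]
    }
    list(array(gv, dim = d))
  })
}

#' Routing weights of the gating rule
#'
#' Maps pre-sigmoid routing logits to Bernoulli inclusion probabilities:
#' `w_i = min(n/2 * sigmoid(v_i) / sum_j(sigmoid(v_j)), 1)`. Equal logits
#' give every block weight 0.5; a single dominant logit saturates to 1.
#'
#' @param logits numeric vector of pre-sigmoid logits (one per block).
#' @return a vector of inclusion probabilities in `[0, 1]`.
#' @export
routing_weights <- function(logits) {
  n <- length(logits)
  s <- 1 / (1 + exp(-logits))
  pmin(n / 2 * s / sum(s), 1)
}

#' Routing module forward pass
#'
#' @param prev,cur normalized `w x w` frames.
#' @param params a [voxelflow_params()] object.
#' @return list with `v_tilde` (pre-sigmoid logits) and `w_tilde`
#'   (inclusion probabilities in `[0, 1]`).
#' @export
routing_forward <- function(prev, cur, params) {
  stopifnot(identical(dim(prev), dim(cur)))
  rf <- .routing_forward(hf_tensor(hf_as4d(prev)), hf_tensor(hf_as4d(cur)),
                         params)
  list(v_tilde = as.numeric(rf$logits), w_tilde = as.numeric(rf$w_tilde$value))
}

#' Straight-through Bernoulli sampling of a routing vector
#'
#' Draws `v_i ~ Bernoulli(w_tilde_i)` independently. Inside the training
#' graph the backward pass treats the sample as the probability
#' (straight-through), so gradients reach the routing module.
#'
#' @param w_tilde vector of probabilities in `[0, 1]`.
#' @param seed optional integer seed for a reproducible draw.
#' @return an integer 0/1 vector of the same length.
#' @export
stebs_sample <- function(w_tilde, seed = NULL) {
  stopifnot(all(w_tilde >= 0 & w_tilde <= 1))
  if (!is.null(seed)) set.seed(seed)
  as.integer(stats::rbinom(length(w_tilde), 1L, w_tilde))
}

# Full tensor-level forward pass over a batch.
# mode: "full" (all blocks, ungated), "sampled" (STEBS gates), "thresholded"
# (deterministic gates w_tilde >= 0.5). v_force: optional 0/1 matrix (n x N).
# training: if TRUE, every block is executed so that per-block supervision is
# routing-independent; if FALSE, blocks gated off for the whole batch are
# skipped (pass-through).
hf_forward <- function(prev, cur, params, mode = "sampled", seed = NULL,
                       v_force = NULL, training = FALSE) {
  cfg <- params$config
  d <- dim(prev$value)
  N <- d[4]
  n <- cfg$n_blocks
  rf <- .routing_forward(prev, cur, params)
  w_tilde <- matrix(rf$w_tilde$value, nrow = n)
  v <- if (!is.null(v_force)) {
    matrix(v_force, nrow = n, ncol = N)
  } else if (mode == "full") {
    matrix(1L, n, N)
  } else if (mode == "thresholded") {
    (w_tilde >= 0.5) * 1L
  } else {
    if (!is.null(seed)) set.seed(seed)
    matrix(stats::rbinom(n * N, 1L, pmin(pmax(w_tilde, 0), 1)), nrow = n)
  }
  state <- list(pred = cur,
                flow = hf_tensor(array(0, c(d[1], d[2], 4L, N))),
                mlogit = hf_tensor(array(0, c(d[1], d[2], 1L, N))))
  per_block <- vector("list", n)
  for (i in seq_len(n)) {
    gated_off <- all(v[i, ] == 0)
    run_block <- training || mode == "full" || !gated_off
    if (run_block) {
      out <- .mvfb_block(prev, cur, state, params$blocks[[i]], cfg$scales[i])
    } else {
      out <- state
    }
    if (mode == "full") {
      state <- out
    } else {
      w_i <- op_slice_c(rf$w_tilde, i)
      gate <- if (mode == "sampled" && training) {
        op_straight_through(w_i, array(v[i, ], c(1, 1, 1, N)))
      } else {
        hf_tensor(array(v[i, ], c(1, 1, 1, N)))
      }
      state <- list(pred = op_gate_mix(out$pred, state$pred, gate),
                    flow = op_gate_mix(out$flow, state$flow, gate),
                    mlogit = op_gate_mix(out$mlogit, state$mlogit, gate))
    }
    # intermediate supervision targets: block i applied regardless of v_i
    # for i < n; the final output is the routed chain itself
    per_block[[i]] <- if (i < n && run_block) out$pred else state$pred
  }
  list(pred = state$pred, per_block = per_block, flow = state$flow,
       mlogit = state$mlogit, routing = rf, v = v)
}

#' Predict the next frame from two consecutive frames
#'
#' Runs the chain of MVFB blocks. `routing_mode` controls block selection:
#' `"sampled"` draws the routing vector by straight-through Bernoulli
#' sampling, `"thresholded"` includes block `i` iff its routing weight is at
#' least 0.5 (deterministic), and `"full"` runs every block (used for
#' intermediate supervision during training).
#'
#' @param prev,cur normalized `w x w` frames with entries in `[0, 1]`.
#' @param params a [voxelflow_params()].
#' @param routing_mode one of `"sampled"`, `"full"`, `"thresholded"`.
#' @param seed seed for the routing draw when sampling.
#' @param v_force optional forced 0/1 routing vector (testing aid).
#' @return a list with `prediction` (clamped to `[0, 1]`), `per_block`
#'   (the intermediate per-block predictions), `routing` (`v_tilde`,
#'   `w_tilde`, sampled `v`) and `flow` (the final [flow_state()]).
#' @export
predict_next <- function(prev, cur, params,
                         routing_mode = c("sampled", "full", "thresholded"),
                         seed = NULL, v_force = NULL) {
  routing_mode <- match.arg(routing_mode)
  stopifnot(is.matrix(prev), identical(dim(prev), dim(cur)))
  if (nrow(prev) != params$config$patch_size)
    stop("predict_next: frame size ", nrow(prev),
         " does not match the model patch size ", params$config$patch_size)
  if (min(prev, cur) < -1e-8 || max(prev, cur) > 1 + 1e-8)
    stop("predict_next: frames must be normalized to [0, 1]")
  out <- hf_forward(hf_tensor(hf_as4d(prev)), hf_tensor(hf_as4d(cur)), params,
                    mode = routing_mode, seed = seed, v_force = v_force)
  w <- nrow(prev)
  fl <- out$flow$value
  list(prediction = matrix(pmin(pmax(out$pred$value, 0), 1), w, w),
       per_block = lapply(out$per_block, function(t) matrix(t$value, w, w)),
       routing = list(v_tilde = as.numeric(out$routing$logits),
                      w_tilde = as.numeric(out$routing$w_tilde$value),
                      v = as.integer(out$v)),
       flow = flow_state(array(fl[, , 1:2, 1], c(w, w, 2)),
                         array(fl[, , 3:4, 1], c(w, w, 2)),
                         matrix(1 / (1 + exp(-out$mlogit$value)), w, w)))
}

#' Autoregressive rollout
#'
#' Predicts `horizon` future frames from `(prev, cur)`, feeding each
#' prediction back as input: e.g. forecasting t4..t6 of a six-stage series
#' from t2 and t3.
#'
#' @inheritParams predict_next
#' @param horizon number of future frames (default 3).
#' @return a list of `horizon` predicted frames in temporal order.
#' @export
rollout <- function(prev, cur, params, horizon = 3L,
                    routing_mode = c("thresholded", "sampled", "full"),
                    seed = NULL, v_force = NULL) {
  routing_mode <- match.arg(routing_mode)
  if (horizon < 1L) stop("rollout: horizon must be >= 1")
  out <- vector("list", horizon)
  a <- prev; b <- cur
  for (h in seq_len(horizon)) {
    p <- predict_next(a, b, params, routing_mode = routing_mode,
                      seed = if (is.null(seed)) NULL else seed + h,
                      v_force = v_force)
    out[[h]] <- p$prediction
    a <- b; b <- p$prediction
  }
  out
}

#' One MVFB block applied to plain matrices
#'
#' Refines a flow state and next-frame estimate: the concatenated inputs go
#' through a downscaled six-convolution motion path and a full-resolution
#' spatial path, a transposed-convolution head emits residual flows and a
#' mask logit, and the refined flows re-synthesize the prediction by
#' backward warping and mask fusion.
#'
#' @param prev,cur,pred_in `w x w` matrices.
#' @param flow a [flow_state()].
#' @param block one element of `voxelflow_params()$blocks`.
#' @param scale the block's spatial scaling factor `S_i` (>= 1).
#' @return list with `pred` (matrix) and `flow` (a [flow_state()]).
#' @export
mvfb_forward <- function(prev, cur, pred_in, flow, block, scale) {
  stopifnot(identical(dim(prev), dim(cur)), identical(dim(prev), dim(pred_in)),
            scale >= 1)
  w <- nrow(prev)
  fl <- array(c(flow$flow_to_prev, flow$flow_to_cur), c(w, w, 4L, 1L))
  ml <- pmin(pmax(flow$mask, 1e-8), 1 - 1e-8)
  state <- list(pred = hf_tensor(hf_as4d(pred_in)),
                flow = hf_tensor(fl),
                mlogit = hf_tensor(hf_as4d(log(ml / (1 - ml)))))
  out <- .mvfb_block(hf_tensor(hf_as4d(prev)), hf_tensor(hf_as4d(cur)),
                     state, block, scale)
  if (any(!is.finite(out$pred$value)))
    stop("mvfb_forward: non-finite activations in block output")
  flv <- out$flow$value
  list(pred = matrix(out$pred$value, w, w),
       flow = flow_state(array(flv[, , 1:2, 1], c(w, w, 2)),
                         array(flv[, , 3:4, 1], c(w, w, 2)),
                         matrix(1 / (1 + exp(-out$mlogit$value)), w, w)))
}
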