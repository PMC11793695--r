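# Shared fixtures: tiny models and matrices built in code.

# a symmetric non-negative random contact-like matrix
rand_contact <- function(n, seed = 1, density = 0.5, max_count = 20) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  v <- rpois(sum(up), max_count * density)
  m[up] <- v
  m + t(m) - diag(diag(m))
}

# a small model for unit tests (full 9-block default unless overridden)
tiny_config <- function(patch_size = 16L, n_blocks = 3L) {
  voxelflow_config(patch_size = patch_size, n_blocks = n_blocks,
                   scales = rep(c(2, 1), length.out = n_blocks),
                   ch_spatial = 2L, ch_motion = 4L, ch_routing = 4L)
}

tiny_params <- function(seed = 1L, ...) voxelflow_params(tiny_config(...), seed)

# random normalized frame
rand_frame <- function(w, seed = 1) {
  set.seed(seed)
  matrix(runif(w * w), w, w)
}

# a fast drifting-TAD cohort for training smoke tests
small_cohort_series <- function(n_chrom = 2L, n_bins = 80L, seed = 1L) {
  cohort <- simulate_cohort(n_chrom = n_chrom, n_bins = n_bins, drift = 1,
                            noise = "poisson", seed = seed)
  lapply(cohort, `[[`, "series")
}
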