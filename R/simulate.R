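# Synthetic spatiotemporal Hi-C generator.
#
# Emulates the structure of developmental Hi-C series: symmetric
# non-negative count matrices with power-law distance decay, TAD blocks
# whose boundaries drift across timepoints, focal loops with ramping
# intensity, and Poisson count noise. Dynamics are expressible as smooth
# pixel motion / intensity change, matching the inductive bias of an
# optical-flow forecaster so end-to-end learning tests are meaningful.

#' Simulation configuration
#'
#' @param n_bins matrix size in bins (default 256).
#' @param resolution bp per bin (default 40 kb).
#' @param decay_exponent power of the `(1 + |i - j|)^-a` distance decay.
#' @param depth_scale expected count on the diagonal from the decay
#'   background alone.
#' @param tad_blocks data frame with columns `start`, `end` (0-based,
#'   half-open bins at timestep 0), `intensity` (added expected counts
#'   inside the block) and `drift` (bins of diagonal boundary drift per
#'   step).
#' @param loops data frame with columns `bin_i`, `bin_j`, `intensity`,
#'   `delta` (additive intensity change per step); each loop is a Gaussian
#'   bump of radius ~1 bin at the (drifting-intensity) anchor.
#' @param noise `"none"` for the expected matrices themselves or
#'   `"poisson"` for Poisson-sampled counts (upper triangle drawn, mirrored).
#' @param n_timepoints number of frames (>= 5 so a 2-in/3-out window fits).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_bins = 256L, resolution = 40000L,
                       decay_exponent = 1, depth_scale = 100,
                       tad_blocks = NULL, loops = NULL,
                       noise = c("poisson", "none"),
                       n_timepoints = 6L, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_bins >= 8L, n_timepoints >= 5L, decay_exponent > 0,
            depth_scale > 0)
  if (is.null(tad_blocks))
    tad_blocks <- data.frame(start = integer(), end = integer(),
                             intensity = numeric(), drift = numeric())
  if (is.null(loops))
    loops <- data.frame(bin_i = integer(), bin_j = integer(),
                        intensity = numeric(), delta = numeric())
  stopifnot(all(c("start", "end", "intensity", "drift") %in% names(tad_blocks)),
            all(c("bin_i", "bin_j", "intensity", "delta") %in% names(loops)))
  cfg <- structure(list(n_bins = as.integer(n_bins),
                        resolution = as.integer(resolution),
                        decay_exponent = decay_exponent,
                        depth_scale = depth_scale,
                        tad_blocks = tad_blocks, loops = loops,
                        noise = noise,
                        n_timepoints = as.integer(n_timepoints),
                        seed = as.integer(seed)),
                   class = "sim_config")
  for (t in seq_len(n_timepoints) - 1L) .drifted_tads(cfg, t)  # validates
  cfg
}

.drifted_tads <- function(cfg, timestep) {
  tb <- cfg$tad_blocks
  if (nrow(tb) == 0L) return(tb)
  tb$start <- tb$start + round(tb$drift * timestep)
  tb$end <- tb$end + round(tb$drift * timestep)
  if (any(tb$start < 0) || any(tb$end > cfg$n_bins) || any(tb$start >= tb$end))
    stop("sim_config: a drifted TAD leaves [0, n_bins) at timestep ", timestep)
  tb
}

#' Expected (noise-free) contact matrix at a timestep
#'
#' `E[i, j] = depth_scale * (1 + |i - j|)^(-decay_exponent)` plus the
#' intensity of every TAD block containing `(i, j)` at the drifted position
#' and a Gaussian kernel for every loop; symmetric by construction.
#'
#' @param cfg a [sim_config()].
#' @param timestep 0-based timestep, `0 <= timestep < n_timepoints`.
#' @return a [contact_matrix()].
#' @export
expected_matrix <- function(cfg, timestep) {
  stopifnot(inherits(cfg, "sim_config"),
            timestep >= 0, timestep < cfg$n_timepoints)
  n <- cfg$n_bins
  idx <- seq_len(n) - 1L
  dist <- abs(outer(idx, idx, "-"))
  e <- cfg$depth_scale * (1 + dist)^(-cfg$decay_exponent)
  tb <- .drifted_tads(cfg, timestep)
  for (k in seq_len(nrow(tb))) {
    inside <- idx >= tb$start[k] & idx < tb$end[k]
    e[inside, inside] <- e[inside, inside] + tb$intensity[k]
  }
  lp <- cfg$loops
  for (k in seq_len(nrow(lp))) {
    inten <- max(0, lp$intensity[k] + lp$delta[k] * timestep)
    if (inten == 0) next
    bump <- inten * exp(-(outer(idx - lp$bin_i[k], idx - lp$bin_j[k],
                                function(a, b) a^2 + b^2)) / 2)
    e <- e + bump + t(bump)
  }
  contact_matrix(e, cfg$resolution, chromosome = "sim")
}

#' Simulate a Hi-C time series with known truth
#'
#' @param cfg a [sim_config()].
#' @param chromosome label attached to the frames.
#' @return list with `series` (a [hic_timeseries()]) and `truth` (per-
#'   timepoint expected matrices, TAD boundary tables and loop tables).
#' @export
simulate_timeseries <- function(cfg, chromosome = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  tps <- seq_len(cfg$n_timepoints) - 1L
  expected <- lapply(tps, function(t) {
    m <- expected_matrix(cfg, t)
    m$chromosome <- chromosome
    m
  })
  frames <- expected
  if (cfg$noise == "poisson") {
    set.seed(cfg$seed)
    frames <- lapply(expected, function(m) {
      n <- nrow(m$values)
      up <- upper.tri(m$values, diag = TRUE)
      v <- matrix(0, n, n)
      v[up] <- stats::rpois(sum(up), m$values[up])
      v <- v + t(v) - diag(diag(v))
      contact_matrix(v, m$resolution, m$chromosome)
    })
  }
  truth <- list(
    expected = expected,
    tad_boundaries = lapply(tps, function(t) .drifted_tads(cfg, t)),
    loops = lapply(tps, function(t) {
      lp <- cfg$loops
      if (nrow(lp)) lp$intensity <- pmax(0, lp$intensity + lp$delta * t)
      lp
    }))
  list(series = hic_timeseries(frames), truth = truth)
}

#' Canonical benchmark scenarios
#'
#' Three desk-scale scenarios: `static` (TADs and loops, no dynamics),
#' `drift` (all TAD boundaries drift one bin per step along the diagonal)
#' and `loop_gain` (loop intensities ramp up).
#'
#' @param n_bins matrix size (default 256).
#' @param seed base seed; each scenario gets a distinct offset.
#' @param noise noise model passed to [sim_config()].
#' @return named list of [sim_config()] objects.
#' @export
benchmark_scenarios <- function(n_bins = 256L, seed = 1L,
                                noise = "poisson") {
  sc <- n_bins / 256  # canonical layout defined on 256 bins, scaled
  tads <- function(drift) data.frame(
    start = round(sc * c(20L, 70L, 130L, 190L)),
    end = round(sc * c(50L, 110L, 170L, 230L)),
    intensity = c(80, 60, 70, 90),
    drift = drift)
  loops0 <- data.frame(bin_i = round(sc * c(30L, 145L)),
                       bin_j = round(sc * c(95L, 210L)),
                       intensity = c(60, 60), delta = c(0, 0))
  loops_ramp <- transform(loops0, intensity = c(15, 15), delta = c(12, 12))
  list(
    static = sim_config(n_bins = n_bins, tad_blocks = tads(0),
                        loops = loops0, noise = noise, seed = seed),
    drift = sim_config(n_bins = n_bins, tad_blocks = tads(1),
                       noise = noise, seed = seed + 1L),
    loop_gain = sim_config(n_bins = n_bins, tad_blocks = tads(0),
                           loops = loops_ramp, noise = noise, seed = seed + 2L)
  )
}

#' Write a benchmark fixture set to disk
#'
#' For every scenario, writes one sparse-triplet file per timepoint
#' (`<name>/sim_t<k>.txt`), a JSON truth sidecar with TAD boundaries and
#' loop lists, and a top-level manifest with seeds and parameters.
#' Regenerating with the same configs yields byte-identical files.
#'
#' @param scenarios named list of [sim_config()] objects.
#' @param out_dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
make_benchmark_suite <- function(scenarios, out_dir) {
  stopifnot(length(names(scenarios)) == length(scenarios),
            !anyDuplicated(names(scenarios)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("make_benchmark_suite: cannot create ", out_dir)
  manifest <- list()
  for (nm in names(scenarios)) {
    cfg <- scenarios[[nm]]
    sdir <- file.path(out_dir, nm)
    dir.create(sdir, showWarnings = FALSE)
    sim <- simulate_timeseries(cfg)
    files <- character(cfg$n_timepoints)
    for (t in seq_len(cfg$n_timepoints)) {
      files[t] <- file.path(sdir, sprintf("sim_t%d.txt", t))
      write_contact_matrix(sim$series$frames[[t]], files[t])
    }
    truth <- list(
      tad_boundaries = lapply(sim$truth$tad_boundaries, function(d)
        d[, c("start", "end", "intensity")]),
      loops = sim$truth$loops)
    jsonlite::write_json(truth, file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest[[nm]] <- list(
      n_bins = cfg$n_bins, resolution = cfg$resolution,
      decay_exponent = cfg$decay_exponent, depth_scale = cfg$depth_scale,
      noise = cfg$noise, n_timepoints = cfg$n_timepoints, seed = cfg$seed,
      files = basename(files))
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

# A small cohort of chromosome-like units for training experiments: same
# dynamics, different TAD layouts per chromosome (seeded).
#' Simulate a cohort of chromosome-like series
#'
#' Generates `n_chrom` independent series sharing the scenario's dynamics
#' (e.g. one-bin-per-step TAD drift) but with randomized TAD layouts, for
#' train/validation/test splits in end-to-end experiments.
#'
#' @param n_chrom number of chromosome-like units.
#' @param n_bins matrix size per unit.
#' @param drift TAD boundary drift in bins per step.
#' @param noise noise model.
#' @param seed base seed (unit k uses `seed + k`).
#' @return named list of [simulate_timeseries()] results
#'   (`chr1`, `chr2`, ...).
#' @export
simulate_cohort <- function(n_chrom = 4L, n_bins = 256L, drift = 1,
                            noise = "poisson", seed = 1L) {
  out <- list()
  for (k in seq_len(n_chrom)) {
    set.seed(seed + 1000L * k)
    n_tad <- 4L
    anchors <- sort(sample(10:(n_bins - 50L), n_tad))
    width <- sample(25:40, n_tad, replace = TRUE)
    ends <- pmin(anchors + width, n_bins - 8L)
    keep <- ends - anchors >= 15L
    # prevent overlap so blocks stay distinct
    if (n_tad > 1L) for (i in 2:n_tad) anchors[i] <- max(anchors[i], ends[i - 1L] + 2L)
    ends <- pmin(anchors + width, n_bins - 8L)
    keep <- keep & (ends - anchors >= 15L) & (anchors < n_bins - 25L)
    tads <- data.frame(start = anchors[keep], end = ends[keep],
                       intensity = stats::runif(sum(keep), 60, 100),
                       drift = drift)
    cfg <- sim_config(n_bins = n_bins, tad_blocks = tads, noise = noise,
                      seed = seed + k)
    nm <- paste0("chr", k)
    sim <- simulate_timeseries(cfg, chromosome = nm)
    out[[nm]] <- sim
  }
  out
}
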