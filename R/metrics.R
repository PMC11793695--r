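# Patch-wise evaluation suite: random-walk graph concordance, Pearson
# correlation, PSNR, SSIM, interaction recovery, and pairwise
# timestep-similarity matrices. All matrix-level scores are means over
# 60x60 diagonal patches, skipping patches without signal.

#' Random-walk graph concordance between two contact patches
#'
#' Each patch is treated as the adjacency matrix of a weighted graph and
#' row-normalized into a transition matrix (all-zero rows stay zero). The
#' `t`-step transition matrices are compared by L1 distance normalized by
#' the mean number of nonzero rows, and the score is `1 - distance`, in
#' `[-1, 1]` with `score(a, a) = 1` exactly.
#'
#' @param a,b non-negative square matrices of equal size.
#' @param t random-walk step count (default 3).
#' @return the concordance score, or `NA` (with attribute `skip`) when
#'   either patch has no nonzero row.
#' @export
genomedisco <- function(a, b, t = 3L) {
  stopifnot(identical(dim(a), dim(b)), t >= 1)
  ra <- rowSums(a)
  rb <- rowSums(b)
  na <- sum(ra > 0)
  nb <- sum(rb > 0)
  if (na == 0L || nb == 0L)
    return(structure(NA_real_, skip = "all-zero patch"))
  pa <- a / ifelse(ra > 0, ra, 1)
  pb <- b / ifelse(rb > 0, rb, 1)
  pat <- pa; pbt <- pb
  for (k in seq_len(t - 1L)) {
    pat <- pat %*% pa
    pbt <- pbt %*% pb
  }
  d <- sum(abs(pat - pbt)) / ((na + nb) / 2)
  1 - d
}

#' Pearson correlation between two patches
#'
#' Computed over all entries of the flattened patches.
#'
#' @param a,b numeric matrices of equal size.
#' @return correlation in `[-1, 1]`, or `NA` (attribute `skip`) when either
#'   patch has zero variance.
#' @export
pcc <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, skip = "zero variance"))
  stats::cor(as.vector(a), as.vector(b))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)`; identical patches give `Inf`, which callers
#' exclude from averaging.
#'
#' @param a,b numeric matrices of equal size.
#' @param peak maximum possible value of the signal (1 on normalized data).
#' @return PSNR in decibels.
#' @export
psnr <- function(a, b, peak = 1) {
  stopifnot(identical(dim(a), dim(b)))
  if (peak <= 0) stop("psnr: peak must be > 0")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index (global moments)
#'
#' Single-window SSIM over the whole patch with sample means, variances and
#' covariance: `(2 mux muy + c1)(2 sxy + c2) /
#' ((mux^2 + muy^2 + c1)(sx2 + sy2 + c2))`, `c1 = (k1 L)^2`,
#' `c2 = (k2 L)^2`.
#'
#' @param x,y numeric matrices of equal size.
#' @param k1,k2 stabilization constants (standard 0.01 and 0.03).
#' @param L dynamic range of the data (1 on normalized data).
#' @return the SSIM index.
#' @export
ssim <- function(x, y, k1 = 0.01, k2 = 0.03, L = 1) {
  stopifnot(identical(dim(x), dim(y)))
  if (L <= 0) stop("ssim: dynamic range L must be > 0")
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(as.vector(x)); vy <- stats::var(as.vector(y))
  cxy <- stats::cov(as.vector(x), as.vector(y))
  (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Patch-averaged evaluation of a predicted contact matrix
#'
#' Extracts aligned diagonal patches from prediction and truth (by default
#' non-overlapping 60x60 patches), scores each included patch with
#' concordance, PCC, PSNR and SSIM, and averages. Patches that are all zero
#' in the truth are skipped and counted; per-metric undefined values
#' (zero-variance PCC, infinite PSNR) are excluded from that metric's mean
#' and counted.
#'
#' @param pred,truth [contact_matrix()] objects or plain matrices of equal
#'   size.
#' @param patch_size evaluation window (default 60).
#' @param stride diagonal stride (default 60: non-overlapping tiling).
#' @param t random-walk steps for the concordance score.
#' @param peak,L PSNR peak and SSIM dynamic range.
#' @return an object of class `MetricReport`: `per_patch` data frame,
#'   `per_matrix` named means, `n_patches_used`, `n_patches_skipped`,
#'   `n_psnr_infinite`, `patch_size`.
#' @export
evaluate_matrices <- function(pred, truth, patch_size = 60L, stride = 60L,
                              t = 3L, peak = 1, L = 1) {
  pv <- if (inherits(pred, "ContactMatrix")) pred$values else pred
  tv <- if (inherits(truth, "ContactMatrix")) truth$values else truth
  if (!identical(dim(pv), dim(tv)))
    stop("evaluate_matrices: prediction and truth shapes differ")
  pp <- extract_diagonal_patches(pv, patch_size, stride)
  tp <- extract_diagonal_patches(tv, patch_size, stride)
  rows <- list()
  skipped <- 0L
  psnr_inf <- 0L
  for (k in seq_along(pp$offsets)) {
    a <- pp$patches[[k]]
    b <- tp$patches[[k]]
    if (all(b == 0)) {
      skipped <- skipped + 1L
      next
    }
    gd <- genomedisco(b, a, t = t)
    r <- pcc(a, b)
    ps <- psnr(a, b, peak = peak)
    if (is.infinite(ps)) psnr_inf <- psnr_inf + 1L
    ss <- ssim(a, b, L = L)
    rows[[length(rows) + 1L]] <- data.frame(
      offset = pp$offsets[k], genomedisco = as.numeric(gd), pcc = as.numeric(r),
      psnr = ps, ssim = ss)
  }
  per_patch <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offset = integer(), genomedisco = numeric(), pcc = numeric(),
               psnr = numeric(), ssim = numeric())
  fin_mean <- function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  per_matrix <- c(genomedisco = fin_mean(per_patch$genomedisco),
                  pcc = fin_mean(per_patch$pcc),
                  psnr = fin_mean(per_patch$psnr),
                  ssim = fin_mean(per_patch$ssim))
  structure(list(per_patch = per_patch, per_matrix = per_matrix,
                 n_patches_used = nrow(per_patch),
                 n_patches_skipped = skipped,
                 n_psnr_infinite = psnr_inf,
                 patch_size = as.integer(patch_size)),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("MetricReport: %d patches used, %d skipped (window %d)\n",
              x$n_patches_used, x$n_patches_skipped, x$patch_size))
  print(round(x$per_matrix, 4))
  if (x$n_psnr_infinite > 0)
    cat(sprintf("  (%d patches with infinite PSNR excluded from its mean)\n",
                x$n_psnr_infinite))
  invisible(x)
}

#' Interaction recovery rate
#'
#' Both interaction sets are filtered to significant records (default
#' `p_value <= 0.05`; `direction = "literal_gt"` keeps `p > threshold`
#' instead) and the rate is `100 * |pred & truth| / |truth|` over canonical
#' `(bin_i <= bin_j)` pairs. `match = "fuzzy1"` counts a truth pair as
#' recovered if a predicted pair lies within one bin in both coordinates.
#'
#' @param pred,truth data frames with columns `bin_i`, `bin_j`, `p_value`.
#' @param p_threshold significance threshold (default 0.05).
#' @param match `"exact_bin_pair"` or `"fuzzy1"`.
#' @param direction `"significant"` (keep `p <= threshold`) or
#'   `"literal_gt"`.
#' @return the recovery rate as a percentage in `[0, 100]`.
#' @export
interaction_recovery_rate <- function(pred, truth, p_threshold = 0.05,
                                      match = c("exact_bin_pair", "fuzzy1"),
                                      direction = c("significant",
                                                    "literal_gt")) {
  match <- match.arg(match)
  direction <- match.arg(direction)
  canon <- function(d) {
    stopifnot(all(c("bin_i", "bin_j", "p_value") %in% names(d)))
    ii <- pmin(d$bin_i, d$bin_j)
    jj <- pmax(d$bin_i, d$bin_j)
    keep <- if (direction == "significant") d$p_value <= p_threshold else
      d$p_value > p_threshold
    unique(data.frame(bin_i = ii[keep], bin_j = jj[keep]))
  }
  pf <- canon(pred)
  tf <- canon(truth)
  if (nrow(tf) == 0L)
    stop("interaction_recovery_rate: no ground-truth interactions after ",
         "the p-value filter; rate undefined")
  if (match == "exact_bin_pair") {
    hits <- sum(paste(tf$bin_i, tf$bin_j) %in% paste(pf$bin_i, pf$bin_j))
  } else {
    hits <- sum(vapply(seq_len(nrow(tf)), function(k)
      any(abs(pf$bin_i - tf$bin_i[k]) <= 1 & abs(pf$bin_j - tf$bin_j[k]) <= 1),
      logical(1)))
  }
  100 * hits / nrow(tf)
}

#' Read / write interaction sets as BEDPE-like text
#'
#' Seven tab-delimited columns: chrom, start1, end1, chrom, start2, end2,
#' p_value (bp coordinates; bins are `start / resolution`).
#'
#' @param path file path.
#' @param resolution bin size in bp used to convert coordinates to bins.
#' @return data frame with `bin_i`, `bin_j`, `p_value`.
#' @export
read_interactions <- function(path, resolution = 40000L) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 7L) stop("read_interactions: expected 7 columns in ", path)
  data.frame(bin_i = as.integer(d[[2]] / resolution),
             bin_j = as.integer(d[[5]] / resolution),
             p_value = as.numeric(d[[7]]))
}

#' @rdname read_interactions
#' @param x data frame with `bin_i`, `bin_j`, `p_value`.
#' @param chromosome chromosome label for the BEDPE columns.
#' @export
write_interactions <- function(x, path, resolution = 40000L,
                               chromosome = "chr") {
  d <- data.frame(c1 = chromosome, s1 = x$bin_i * resolution,
                  e1 = (x$bin_i + 1L) * resolution,
                  c2 = chromosome, s2 = x$bin_j * resolution,
                  e2 = (x$bin_j + 1L) * resolution, p = x$p_value)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Pairwise timestep-similarity matrix
#'
#' Entry `(i, j)` is the patch-averaged similarity between frame `i` of the
#' first series and frame `j` of the second; with a series against itself
#' the diagonal is 1 and the matrix symmetric. Mirrors the ground-truth /
#' prediction cross-timestep concordance heatmaps used to check temporal
#' consistency.
#'
#' @param series_a,series_b [hic_timeseries()] objects with equal frame
#'   sizes.
#' @param metric `"genomedisco"`, `"pcc"`, `"psnr"` or `"ssim"`.
#' @param patch_size,stride evaluation patching.
#' @return a `k_a x k_b` numeric matrix with dimnames from the timepoint
#'   labels.
#' @export
timestep_similarity_matrix <- function(series_a, series_b = series_a,
                                       metric = "genomedisco",
                                       patch_size = 60L, stride = 60L) {
  stopifnot(inherits(series_a, "HiCTimeSeries"),
            inherits(series_b, "HiCTimeSeries"))
  if (nrow(series_a$frames[[1]]$values) != nrow(series_b$frames[[1]]$values))
    stop("timestep_similarity_matrix: frame shapes differ")
  ka <- length(series_a$frames)
  kb <- length(series_b$frames)
  out <- matrix(NA_real_, ka, kb,
                dimnames = list(series_a$timepoint_labels,
                                series_b$timepoint_labels))
  for (i in seq_len(ka))
    for (j in seq_len(kb)) {
      rep_ <- evaluate_matrices(series_b$frames[[j]], series_a$frames[[i]],
                                patch_size = patch_size, stride = stride)
      out[i, j] <- rep_$per_matrix[[metric]]
    }
  out
}
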