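# Contact-matrix containers and I/O.
#
# Coordinate convention throughout: 0-based, half-open bin intervals;
# genomic bp = bin * resolution.

#' Construct a Hi-C contact matrix
#'
#' @param values square numeric matrix of non-negative contacts (raw counts
#'   or normalized values). Must be symmetric within an additive tolerance
#'   of 1e-6; it is symmetrized exactly on construction.
#' @param resolution base pairs per bin (default 40 kb).
#' @param chromosome chromosome label.
#' @param start_bin 0-based genomic offset of the first row, in bins.
#' @return an object of class `ContactMatrix`.
#' @export
contact_matrix <- function(values, resolution = 40000L, chromosome = "chr",
                           start_bin = 0L) {
  if (!is.matrix(values) || nrow(values) != ncol(values) || nrow(values) < 1L)
    stop("contact_matrix: values must be a square matrix with n >= 1")
  if (any(!is.finite(values))) stop("contact_matrix: non-finite entries")
  if (any(values < 0)) stop("contact_matrix: negative contact values")
  if (max(abs(values - t(values))) > 1e-6)
    stop("contact_matrix: matrix is not symmetric within tolerance 1e-6")
  values <- (values + t(values)) / 2
  structure(list(values = values, resolution = as.integer(resolution),
                 chromosome = as.character(chromosome),
                 start_bin = as.integer(start_bin)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s: %d x %d bins @ %d bp, start bin %d\n",
              x$chromosome, nrow(x$values), ncol(x$values), x$resolution,
              x$start_bin))
  cat(sprintf("  total contacts %.4g, max %.4g, nonzero %.1f%%\n",
              sum(x$values), max(x$values),
              100 * mean(x$values != 0)))
  invisible(x)
}

#' Construct an ordered Hi-C time series
#'
#' @param frames list of [contact_matrix()] objects sharing size, resolution
#'   and chromosome; the "video" whose frames the model forecasts.
#' @param timepoint_labels optional character labels (default `t1, t2, ...`).
#' @return an object of class `HiCTimeSeries`.
#' @export
hic_timeseries <- function(frames, timepoint_labels = NULL) {
  stopifnot(length(frames) >= 2L)
  lapply(frames, function(f) stopifnot(inherits(f, "ContactMatrix")))
  n <- nrow(frames[[1]]$values)
  for (f in frames) {
    if (nrow(f$values) != n ||
        f$resolution != frames[[1]]$resolution ||
        !identical(f$chromosome, frames[[1]]$chromosome))
      stop("hic_timeseries: frames must share size, resolution and chromosome")
  }
  if (is.null(timepoint_labels))
    timepoint_labels <- paste0("t", seq_along(frames))
  stopifnot(length(timepoint_labels) == length(frames))
  structure(list(frames = frames, timepoint_labels = timepoint_labels),
            class = "HiCTimeSeries")
}

#' @export
print.HiCTimeSeries <- function(x, ...) {
  cat(sprintf("HiCTimeSeries %s: %d timepoints (%s), %d bins @ %d bp\n",
              x$frames[[1]]$chromosome, length(x$frames),
              paste(x$timepoint_labels, collapse = ", "),
              nrow(x$frames[[1]]$values), x$frames[[1]]$resolution))
  invisible(x)
}

#' Read a contact matrix from disk
#'
#' Supported dialects: `sparse_triplet` -- whitespace/tab-delimited lines
#' `bin_i bin_j count` with 0-based bin indices (counts may be real-valued;
#' asymmetric input is symmetrized by the elementwise maximum, the usual cure
#' for upper-triangle dumps); `dense_binary` -- `n_bins^2` doubles in
#' column-major order. `.cool` files are not read directly; export them to
#' triplets first (e.g. `cooler dump`).
#'
#' @param path file path.
#' @param format one of `"sparse_triplet"`, `"dense_binary"`, `"cooler"`.
#' @param chromosome chromosome label to attach.
#' @param resolution bin size in bp.
#' @param n_bins matrix size; required for `dense_binary`, otherwise inferred
#'   from the maximum bin index + 1 when omitted.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path,
                                format = c("sparse_triplet", "dense_binary",
                                           "cooler"),
                                chromosome = "chr", resolution = 40000L,
                                n_bins = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_contact_matrix: no such file: ", path)
  if (format == "cooler") {
    stop("read_contact_matrix: direct .cool reading is not supported in this ",
         "build (no HDF5 reader); dump the cooler to sparse triplets at a ",
         "single resolution and use format = 'sparse_triplet'")
  }
  if (format == "dense_binary") {
    if (is.null(n_bins)) stop("read_contact_matrix: dense_binary needs n_bins")
    vals <- readBin(path, what = "double", n = n_bins^2)
    if (length(vals) != n_bins^2)
      stop("read_contact_matrix: file holds ", length(vals),
           " doubles, expected ", n_bins^2)
    m <- matrix(vals, n_bins, n_bins)
    m <- pmax(m, t(m))
    return(contact_matrix(m, resolution, chromosome))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    if (is.null(n_bins)) stop("read_contact_matrix: empty file and no n_bins")
    return(contact_matrix(matrix(0, n_bins, n_bins), resolution, chromosome))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad))
    stop("read_contact_matrix: malformed line ", bad[1], " in ", path,
         " (expected 3 whitespace-delimited fields)")
  rec <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3L,
                byrow = TRUE)
  if (any(!is.finite(rec))) {
    bad <- which(rowSums(!is.finite(rec)) > 0)[1]
    stop("read_contact_matrix: non-numeric field on line ", bad, " in ", path)
  }
  if (any(rec[, 3] < 0)) {
    bad <- which(rec[, 3] < 0)[1]
    stop("read_contact_matrix: negative count on line ", bad, " in ", path)
  }
  if (any(rec[, 1:2] < 0) || any(rec[, 1:2] != floor(rec[, 1:2]))) {
    stop("read_contact_matrix: bin indices must be non-negative integers ",
         "(0-based) in ", path)
  }
  n <- if (is.null(n_bins)) as.integer(max(rec[, 1:2])) + 1L else
    as.integer(n_bins)
  if (max(rec[, 1:2]) >= n)
    stop("read_contact_matrix: bin index ", max(rec[, 1:2]),
         " exceeds n_bins = ", n)
  m <- matrix(0, n, n)
  m[rec[, 1:2, drop = FALSE] + 1L] <- rec[, 3]
  m <- pmax(m, t(m))
  contact_matrix(m, resolution, chromosome)
}

#' Write a contact matrix as sparse triplets
#'
#' Writes the upper triangle (including the diagonal) of the matrix as
#' tab-delimited `bin_i bin_j value` lines with 0-based indices.
#'
#' @param m a [contact_matrix()].
#' @param path output file path.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "ContactMatrix"))
  idx <- which(upper.tri(m$values, diag = TRUE) & m$values != 0,
               arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   v = m$values[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Clip and normalize a contact matrix to the unit interval
#'
#' Contacts are truncated at `cutoff` and divided by it, so entries at or
#' above the cutoff map to exactly 1 and the order of entries below it is
#' preserved.
#'
#' @param m a [contact_matrix()].
#' @param cutoff positive maximum retained contact value.
#' @return a normalized [contact_matrix()] with entries in `[0, 1]`.
#' @export
clip_normalize <- function(m, cutoff = 100) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (cutoff <= 0) stop("clip_normalize: cutoff must be > 0")
  out <- m
  out$values <- pmin(m$values, cutoff) / cutoff
  out
}

#' Invert the clip-and-normalize scaling
#'
#' @param m a normalized [contact_matrix()] with entries in `[0, 1]`.
#' @param cutoff the cutoff used for normalization.
#' @return a [contact_matrix()] on the original count scale. Round-tripping
#'   `clip_normalize()` then `denormalize()` is the identity on matrices
#'   already below the cutoff.
#' @export
denormalize <- function(m, cutoff = 100) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (cutoff <= 0) stop("denormalize: cutoff must be > 0")
  if (min(m$values) < 0 || max(m$values) > 1 + 1e-9)
    stop("denormalize: entries must lie in [0, 1]")
  out <- m
  out$values <- m$values * cutoff
  out
}
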