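#' Parcel time series
#'
#' @param values `T x P` numeric matrix of BOLD-like values (rows = TRs).
#' @param tr Repetition time in seconds.
#' @param subject_id,run_id Identifiers.
#' @return Object of class `parcel_ts`.
#' @export
parcel_ts <- function(values, tr = 0.8, subject_id = NA, run_id = NA) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("time series needs at least 2 TRs")
  if (!all(is.finite(values))) stop("time series contains non-finite values")
  structure(list(values = values, tr = tr,
                 subject_id = subject_id, run_id = run_id),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("parcel_ts: %d TRs x %d parcels, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Motion-based exclusion of runs or blocks
#'
#' Retains rows whose framewise displacement satisfies `fd_mean < fd_mean_max`
#' and `fd_max < fd_max_max` (both strict). The default thresholds are the
#' stringent profile (0.2 mm / 2 mm); the liberal profile is 0.5 mm / 5 mm.
#'
#' @param x Data frame with columns `fd_mean` and `fd_max` (mm).
#' @param fd_mean_max,fd_max_max Strict upper thresholds in mm.
#' @param profile Shorthand: `"strict"` (0.2, 2) or `"liberal"` (0.5, 5);
#'   overrides the threshold arguments when given.
#' @param on_missing `"error"` (default) or `"exclude"` rows with missing FD.
#' @return List with `retained` (subset of `x`), `excluded`, and `log`
#'   (character vector, one reason per excluded row).
#' @export
motion_filter <- function(x, fd_mean_max = 0.2, fd_max_max = 2.0,
                          profile = NULL, on_missing = c("error", "exclude")) {
  on_missing <- match.arg(on_missing)
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("strict", "liberal"))
    if (profile == "strict") { fd_mean_max <- 0.2; fd_max_max <- 2.0 }
    else { fd_mean_max <- 0.5; fd_max_max <- 5.0 }
  }
  if (!all(c("fd_mean", "fd_max") %in% names(x)))
    stop("motion_filter needs fd_mean and fd_max columns")
  miss <- is.na(x$fd_mean) | is.na(x$fd_max)
  if (any(miss) && on_missing == "error")
    stop("missing FD values in rows: ", paste(which(miss), collapse = ", "))
  ok <- !miss & x$fd_mean < fd_mean_max & x$fd_max < fd_max_max
  reason <- character(sum(!ok))
  bad <- which(!ok)
  for (k in seq_along(bad)) {
    r <- bad[k]
    reason[k] <- if (miss[r]) sprintf("row %d: missing FD", r)
    else sprintf("row %d: fd_mean=%.3f fd_max=%.3f vs thresholds (%.3f, %.3f)",
                 r, x$fd_mean[r], x$fd_max[r], fd_mean_max, fd_max_max)
  }
  list(retained = x[ok, , drop = FALSE],
       excluded = x[!ok, , drop = FALSE],
       log = reason)
}

#' Confound regression and frequency-domain band-pass
#'
#' Projects each parcel series onto the orthogonal complement of the confound
#' columns (always including an intercept, so the mean is removed), then zeroes
#' FFT bins outside `[band[1], band[2]]` Hz. Applied per run, before block
#' extraction.
#'
#' @param ts A `parcel_ts`.
#' @param confounds Optional `T x C` matrix, row-aligned with `ts`.
#' @param band Pass band in Hz, within (0, Nyquist]; `NULL` skips filtering.
#' @return A `parcel_ts` of denoised values.
#' @export
denoise <- function(ts, confounds = NULL, band = c(0.008, 0.12)) {
  v <- ts$values
  n <- nrow(v)
  X <- matrix(1, n, 1)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confounds must be row-aligned with ts")
    X <- cbind(X, confounds)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    warning("rank-deficient confounds; dropping redundant columns")
  res <- qr.resid(qr_x, v)
  if (!is.null(band)) {
    fs <- 1 / ts$tr
    nyq <- fs / 2
    if (band[1] < 0 || band[2] > nyq + 1e-12 || band[1] >= band[2])
      stop("band must lie within (0, Nyquist]")
    freq <- (seq_len(n) - 1) / n * fs
    freq <- pmin(freq, fs - freq)        # two-sided spectrum
    keep <- freq >= band[1] & freq <= band[2]
    ft <- stats::mvfft(res)
    ft[!keep, ] <- 0
    res <- Re(stats::mvfft(ft, inverse = TRUE)) / n
  }
  parcel_ts(res, tr = ts$tr, subject_id = ts$subject_id, run_id = ts$run_id)
}

#' Block-wise Fisher-z connectivity matrix
#'
#' Pearson-correlates all parcel pairs over the TRs of one task block and
#' Fisher-z transforms the result. TR indexing is 0-based with a half-open
#' `[onset_tr, offset_tr)` window; `lag_trs` shifts the window.
#'
#' @param ts A `parcel_ts`.
#' @param block One-row data frame (or list) with `onset_tr` and `offset_tr`.
#' @param lag_trs Integer TR shift applied to both ends (default 0).
#' @return Object of class `edge_matrix`: list with `z` (`P x P` symmetric,
#'   zero diagonal), `subject_id`, `block`.
#' @export
block_fc <- function(ts, block, lag_trs = 0L) {
  onset <- block$onset_tr + lag_trs
  offset <- block$offset_tr + lag_trs
  n <- nrow(ts$values)
  if (onset < 0 || offset > n) stop("block window outside run")
  if (offset - onset < 3) stop("block too short (< 3 TRs)")
  seg <- ts$values[(onset + 1):offset, , drop = FALSE]
  sds <- apply(seg, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance parcel(s) in block: ",
         paste(which(sds == 0) - 1L, collapse = ", "))
  r <- stats::cor(seg)
  z <- fisher_z(r)
  diag(z) <- 0
  edge_matrix(z, subject_id = ts$subject_id, block = block)
}

#' Edge matrix constructor
#'
#' @param z `P x P` symmetric Fisher-z matrix, zero diagonal.
#' @param subject_id,block Provenance.
#' @return Object of class `edge_matrix`.
#' @export
edge_matrix <- function(z, subject_id = NA, block = NULL) {
  z <- as.matrix(z)
  if (max(abs(z - t(z))) > 1e-10) stop("edge matrix must be symmetric")
  if (!all(is.finite(z))) stop("edge matrix must be finite")
  z <- (z + t(z)) / 2
  diag(z) <- 0
  structure(list(z = z, subject_id = subject_id, block = block),
            class = "edge_matrix")
}

#' Signed network strength
#'
#' Sums Fisher-z edge values over the unique (upper-triangle) edges of a
#' trinary mask, weighted by the mask sign: positive-edge sum minus
#' negative-edge sum. Summing unique edges (rather than both triangles) halves
#' the scale and changes no correlation-based result.
#'
#' @param em An `edge_matrix` or a plain symmetric matrix.
#' @param mask A `network_mask`.
#' @return Scalar strength.
#' @export
network_strength <- function(em, mask) {
  z <- if (inherits(em, "edge_matrix")) em$z else as.matrix(em)
  if (!all(dim(z) == dim(mask$w))) stop("edge matrix / mask shape mismatch")
  sum(ut_vec(z) * mask_vec(mask))
}

#' Z-score a connectome within participant
#'
#' Standardises the upper-triangle edge values of one edge matrix to mean 0,
#' SD 1 (used before comparing group-average network strengths across samples
#' acquired on different scanners).
#'
#' @param em An `edge_matrix`.
#' @return An `edge_matrix` with standardized edges.
#' @export
standardize_connectome <- function(em) {
  v <- ut_vec(em$z)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant edge matrix")
  edge_matrix(vec_ut((v - mean(v)) / s, nrow(em$z)),
              subject_id = em$subject_id, block = em$block)
}

#' Per-block network strengths for a set of edge matrices
#'
#' @param edge_list List of `edge_matrix`, one per retained block.
#' @param blocks Data frame of the matching block records (same order), with at
#'   least `subject_id`, `condition`.
#' @param mask A `network_mask`.
#' @return `blocks` with an added `strength` column.
#' @export
block_strengths <- function(edge_list, blocks, mask) {
  stopifnot(length(edge_list) == nrow(blocks))
  blocks$strength <- vapply(edge_list, network_strength, numeric(1), mask = mask)
  blocks
}

#' Per-subject condition-average network strength
#'
#' Averages block-wise strengths over all retained blocks of one condition per
#' subject, optionally z-scoring the resulting scores across included subjects.
#' Subjects with no retained block in the condition are dropped (logged).
#'
#' @param strengths Data frame with columns `subject_id`, `condition`,
#'   `strength` (e.g. from [block_strengths()]), or a `sim_study`.
#' @param condition Condition label to average (`"zero_back"`, `"two_back"`,
#'   or `"all"` for every block).
#' @param zscore Z-score scores across subjects (default `TRUE`).
#' @param mask For the `sim_study` method: which ground-truth strength column.
#' @param ... Passed between methods.
#' @return Data frame `subject_id`, `score`, `n_blocks`, with attribute
#'   `dropped` listing subjects without retained blocks.
#' @export
condition_strengths <- function(strengths, condition, ...) {
  UseMethod("condition_strengths")
}

#' @rdname condition_strengths
#' @export
condition_strengths.data.frame <- function(strengths, condition,
                                           zscore = TRUE, ...) {
  stopifnot(all(c("subject_id", "condition", "strength") %in% names(strengths)))
  all_subj <- unique(strengths$subject_id)
  sel <- if (identical(condition, "all")) strengths
         else strengths[strengths$condition == condition, , drop = FALSE]
  if (nrow(sel) == 0) stop("no blocks for condition '", condition, "'")
  agg <- stats::aggregate(strength ~ subject_id, data = sel, FUN = mean)
  cnt <- stats::aggregate(strength ~ subject_id, data = sel, FUN = length)
  out <- data.frame(subject_id = agg$subject_id, score = agg$strength,
                    n_blocks = cnt$strength)
  out <- out[match(intersect(all_subj, out$subject_id), out$subject_id), ]
  rownames(out) <- NULL
  if (zscore) {
    if (stats::sd(out$score) == 0) stop("constant strengths; cannot z-score")
    out$score <- as.numeric(scale(out$score))
  }
  attr(out, "dropped") <- setdiff(all_subj, out$subject_id)
  out
}

#' Read / write parcel time series as TSV
#'
#' TSV layout: T rows x P columns, header row of parcel ids.
#'
#' @param path File path.
#' @param tr,subject_id,run_id Metadata attached on read.
#' @param ts A `parcel_ts` (write).
#' @return `read_timeseries` returns a `parcel_ts`.
#' @export
read_timeseries <- function(path, tr = 0.8, subject_id = NA, run_id = NA) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
  parcel_ts(m, tr = tr, subject_id = subject_id, run_id = run_id)
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(ts$values)
  names(df) <- sprintf("p%03d", seq_len(ncol(ts$values)) - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a block table
#'
#' Expects columns `run_id`, `block_index`, `condition`, `stimulus`,
#' `onset_tr`, `offset_tr`, `fd_mean`, `fd_max`.
#'
#' @param path TSV path.
#' @return Data frame of block records.
#' @export
read_block_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  need <- c("run_id", "block_index", "condition", "stimulus",
            "onset_tr", "offset_tr", "fd_mean", "fd_max")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("block table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- df$condition[!df$condition %in% c("zero_back", "two_back")]
  if (length(bad)) stop("unknown condition label(s): ",
                        paste(unique(bad), collapse = ", "))
  df
}
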