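#' Number of unique edges in a symmetric connectome
#'
#' For `p` parcels the connectome has `p * (p - 1) / 2` unique (upper-triangle)
#' edges; with the standard 268-parcel atlas this is 35,778.
#'
#' @param p Number of parcels (>= 2).
#' @return Integer edge count.
#' @export
#' @examples
#' total_edges(268)  # 35778
total_edges <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 2, p == round(p))
  as.integer(p * (p - 1) / 2)
}

#' Upper-triangle edge index table
#'
#' Edge order matches `m[upper.tri(m)]` (column-major, `i < j`) so the table
#' maps vectorised edge positions back to parcel pairs exactly.
#'
#' @param p Number of parcels.
#' @return Data frame with 0-based parcel columns `i`, `j`, one row per edge.
#' @export
edge_table <- function(p) {
  j <- rep(seq_len(p), each = p)
  i <- rep(seq_len(p), times = p)
  keep <- i < j
  data.frame(i = i[keep] - 1L, j = j[keep] - 1L)  # 0-based parcel ids
}

#' Vectorise the upper triangle of a symmetric matrix
#'
#' @param m Symmetric matrix.
#' @return Numeric vector, order matching [edge_table()].
#' @export
ut_vec <- function(m) m[upper.tri(m)]

#' Rebuild a symmetric matrix from an upper-triangle vector
#'
#' @param v Edge vector in [edge_table()] order.
#' @param p Number of parcels.
#' @return A `p x p` symmetric matrix with zero diagonal.
#' @export
vec_ut <- function(v, p) {
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Deterministic sub-seed fan-out
#'
#' Expands one global seed into per-stage seeds via a fixed multiplicative
#' counter scheme, kept below `2^31 - 1`, so pipeline stages stay independent
#' and reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage counter.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((abs(as.double(seed)) * 48271 + 7919 * as.double(stage)) %% 2147483629)
}

#' Fisher z transform with clipping
#'
#' `atanh` of the correlation after clipping to `|r| <= clip` so degenerate
#' (`|r| = 1`) blocks stay finite.
#'
#' @param r Correlation values.
#' @param clip Clipping bound (default `1 - 1e-6`).
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, clip = 1 - 1e-6) atanh(pmin(pmax(r, -clip), clip))

# Fast column-wise Pearson correlation of a matrix with a vector.
col_cor <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  num <- as.vector(crossprod(xc, yc))
  den <- sqrt(colSums(xc^2) * sum(yc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

# Two-sided p for a Pearson r at sample size n (t transform, n - 2 df).
cor_p <- function(r, n) {
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
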