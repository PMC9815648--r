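#' Hypergeometric tail probability for edge-set overlap
#'
#' Probability of an overlap this large arising by chance when a K-edge set and
#' an N-edge set are drawn independently from M total edges. The default
#' convention follows the cumulative-distribution formulation `1 - F(x)`
#' = P(X > x); `greater_equal` gives P(X >= x). Computed in log space
#' (lchoose + log-sum-exp) so connectome-scale M (~35,778) does not overflow.
#'
#' @param x Observed overlap count.
#' @param K,N Sizes of the two edge sets.
#' @param M Total number of edges.
#' @param convention `"greater"` (default, `1 - F(x)`) or `"greater_equal"`.
#' @return Tail probability.
#' @export
#' @examples
#' hypergeom_p(37, 757, 1674, 35778)   # ~0.351
hypergeom_p <- function(x, K, N, M,
                        convention = c("greater", "greater_equal")) {
  convention <- match.arg(convention)
  vals <- c(x, K, N, M)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("x, K, N, M must be non-negative integers")
  if (K > M || N > M) stop("K and N must not exceed M")
  if (x > min(K, N)) stop("x cannot exceed min(K, N)")
  hi <- if (convention == "greater") x else x - 1L
  lo_i <- hi + 1L                      # first term of the upper tail
  up_i <- min(K, N)
  if (lo_i > up_i) return(0)
  i <- lo_i:up_i
  lp <- lchoose(K, i) + lchoose(M - K, N - i) - lchoose(M, N)
  lp <- lp[is.finite(lp)]
  if (!length(lp)) return(0)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Overlap statistics for two network masks
#'
#' Counts the shared edges between the chosen sign components of two masks on
#' the same parcellation and tests the overlap against the hypergeometric null
#' over all `P(P-1)/2` edges.
#'
#' @param mask_a,mask_b `network_mask` objects with equal parcel counts.
#' @param signs Length-2 vector choosing the component of each mask:
#'   `"pos"`, `"neg"`, or `"all"` (any nonzero edge).
#' @return Object of class `overlap_result`: `x`, `K`, `N`, `M`,
#'   `pct_combined` (100 x / union size), `expected` (K N / M), `p_gt`
#'   = P(X > x), `p_ge` = P(X >= x).
#' @export
network_overlap <- function(mask_a, mask_b, signs = c("pos", "pos")) {
  if (mask_a$p != mask_b$p) stop("masks have different parcel counts")
  pick <- function(mask, s) {
    v <- mask_vec(mask)
    switch(match.arg(s, c("pos", "neg", "all")),
           pos = v == 1L, neg = v == -1L, all = v != 0L)
  }
  a <- pick(mask_a, signs[1])
  b <- pick(mask_b, signs[2])
  x <- sum(a & b); K <- sum(a); N <- sum(b); M <- total_edges(mask_a$p)
  union_n <- K + N - x
  structure(
    list(x = x, K = K, N = N, M = M,
         pct_combined = if (union_n > 0) 100 * x / union_n else NA_real_,
         expected = K * N / M,
         p_gt = hypergeom_p(x, K, N, M, "greater"),
         p_ge = hypergeom_p(x, K, N, M, "greater_equal")),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "edge-set overlap: x = %d (K = %d, N = %d, M = %d)\n%s%s",
    x$x, x$K, x$N, x$M,
    sprintf("  %.2f%% of combined edges; expected by chance %.1f\n",
            x$pct_combined, x$expected),
    sprintf("  hypergeometric P(X > x) = %.4g, P(X >= x) = %.4g\n",
            x$p_gt, x$p_ge)))
  invisible(x)
}

#' Macroscale region composition of a mask
#'
#' Tallies each mask edge into its unordered region-pair cell and normalises
#' to percentages of the mask's edge count.
#'
#' @param mask A `network_mask`.
#' @param region_labels Data frame from [read_region_labels()].
#' @param sign `"pos"`, `"neg"`, or `"all"` (default) edges to count.
#' @return Object of class `region_composition`: `counts` and `pct`, both
#'   `R x R` symmetric-by-construction upper-triangle-plus-diagonal matrices
#'   (each undirected edge counted once), plus `total`.
#' @export
region_composition <- function(mask, region_labels, sign = "all") {
  reg <- region_of_parcel(region_labels, mask$p)
  regions <- sort(unique(reg))
  edges <- mask_edges(mask)
  edges <- switch(match.arg(sign, c("all", "pos", "neg")),
                  all = edges,
                  pos = edges[edges$w == 1L, , drop = FALSE],
                  neg = edges[edges$w == -1L, , drop = FALSE])
  R <- length(regions)
  counts <- matrix(0L, R, R, dimnames = list(regions, regions))
  if (nrow(edges)) {
    ra <- match(reg[edges$i + 1L], regions)
    rb <- match(reg[edges$j + 1L], regions)
    lo <- pmin(ra, rb); hi <- pmax(ra, rb)
    t <- table(factor(lo, levels = seq_len(R)), factor(hi, levels = seq_len(R)))
    counts[] <- as.integer(t)
  }
  total <- sum(counts)
  structure(list(counts = counts,
                 pct = if (total > 0) 100 * counts / total else counts * 0,
                 total = total, regions = regions),
            class = "region_composition")
}

#' Difference of two region compositions
#'
#' Percentage-point difference per region pair, as used to contrast the
#' anatomy of two predictive networks.
#'
#' @param a,b `region_composition` objects over the same regions.
#' @return Matrix `a$pct - b$pct`.
#' @export
composition_diff <- function(a, b) {
  if (!identical(a$regions, b$regions)) stop("compositions use different regions")
  a$pct - b$pct
}
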