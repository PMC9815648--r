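#' Computationally lesion a mask by macroscale region
#'
#' Removes every mask edge with at least one endpoint in the given region;
#' all other edges are untouched.
#'
#' @param mask A `network_mask`.
#' @param region Region name.
#' @param region_labels Data frame from [read_region_labels()] /
#'   [make_region_labels()].
#' @return The lesioned `network_mask`; attribute `n_removed` counts removed
#'   edges.
#' @export
lesion_mask <- function(mask, region, region_labels) {
  reg <- region_of_parcel(region_labels, mask$p)
  if (!region %in% reg) stop("unknown region '", region, "'")
  in_region <- which(reg == region) - 1L  # 0-based parcels
  w <- mask$w
  before <- sum(ut_vec(w) != 0L)
  w[in_region + 1L, ] <- 0L
  w[, in_region + 1L] <- 0L
  out <- network_mask(w, name = paste0(mask$name %||% "mask", "_less_", region))
  attr(out, "n_removed") <- before - (out$n_pos + out$n_neg)
  out
}

#' Predictive-power loss from lesioning
#'
#' R-squared of ordinary least squares of behavior on network strength
#' (optionally plus covariates), for the full and the lesioned strength, and
#' their difference.
#'
#' @param strength_full,strength_lesioned Per-subject strengths.
#' @param behavior Per-subject outcome.
#' @param covariates Optional numeric matrix of covariates.
#' @return List `r2_full`, `r2_lesioned`, `delta_r2`.
#' @export
lesion_delta_r2 <- function(strength_full, strength_lesioned, behavior,
                            covariates = NULL) {
  r2 <- function(x) {
    X <- cbind(strength = x, covariates)
    if (nrow(X) <= ncol(X) + 2) stop("too few subjects for the design")
    if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("collinear design")
    fit <- stats::lm.fit(cbind(1, X), behavior)
    1 - sum(fit$residuals^2) / sum((behavior - mean(behavior))^2)
  }
  r2f <- r2(strength_full)
  r2l <- r2(strength_lesioned)
  list(r2_full = r2f, r2_lesioned = r2l, delta_r2 = r2f - r2l)
}

#' Bootstrap group comparison of lesion effects
#'
#' Compares the drop in predictive R-squared (delta R2 = full minus lesioned)
#' between two groups for one region. Subjects are resampled with replacement
#' within group (group sizes fixed, shared iteration), the delta-R2
#' difference recomputed per resample, and a two-sided add-one p formed from
#' the fraction of resampled differences crossing zero relative to the
#' observed sign.
#'
#' @param group_a,group_b Lists with `strength_full`, `strength_lesioned`,
#'   `behavior` (and optional `covariates`).
#' @param n_boot Bootstrap iterations (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @param region Optional region name carried into the result.
#' @return Object of class `lesion_result`: per-group R2s and delta R2,
#'   `diff` (A minus B), `p` (two-sided bootstrap), `n_boot`, `region`.
#' @export
compare_lesion_groups <- function(group_a, group_b, n_boot = 1000, seed = 1,
                                  region = NULL) {
  if (n_boot < 100) warning("n_boot < 100 gives a coarse p-value")
  dr <- function(g, idx = seq_along(g$behavior)) {
    lesion_delta_r2(g$strength_full[idx], g$strength_lesioned[idx],
                    g$behavior[idx],
                    if (is.null(g$covariates)) NULL
                    else g$covariates[idx, , drop = FALSE])
  }
  obs_a <- dr(group_a)
  obs_b <- dr(group_b)
  obs <- obs_a$delta_r2 - obs_b$delta_r2
  set.seed(seed)
  na <- length(group_a$behavior)
  nb <- length(group_b$behavior)
  boot <- vapply(seq_len(n_boot), function(i) {
    ia <- sample.int(na, na, replace = TRUE)
    ib <- sample.int(nb, nb, replace = TRUE)
    dr(group_a, ia)$delta_r2 - dr(group_b, ib)$delta_r2
  }, numeric(1))
  crossing <- if (obs >= 0) sum(boot <= 0) else sum(boot >= 0)
  p <- min(1, 2 * (1 + crossing) / (n_boot + 1))
  structure(list(region = region,
                 group_a = obs_a, group_b = obs_b,
                 diff = obs, p = p, n_boot = n_boot,
                 boot = boot),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf(
    "lesion%s: dR2 A = %.4f, dR2 B = %.4f, diff = %.4f, bootstrap p = %.4g (%d resamples)\n",
    if (is.null(x$region)) "" else paste0(" [", x$region, "]"),
    x$group_a$delta_r2, x$group_b$delta_r2, x$diff, x$p, x$n_boot))
  invisible(x)
}

#' Region-wise lesion profile
#'
#' Lesions each region in turn and reports the delta R2 for predicting a
#' behavior from a mask's strength computed on subject-level edge rows.
#'
#' @param edges `n x E` matrix of subject edge rows.
#' @param behavior Per-subject outcome.
#' @param mask A `network_mask`.
#' @param region_labels Region labels covering the mask's parcels.
#' @param covariates Optional covariate matrix.
#' @return Data frame `region`, `n_removed`, `r2_full`, `r2_lesioned`,
#'   `delta_r2`.
#' @export
lesion_profile <- function(edges, behavior, mask, region_labels,
                           covariates = NULL) {
  edges <- as_edge_rows(edges, mask$p)
  full <- as.numeric(edges %*% mask_vec(mask))
  regions <- sort(unique(as.character(region_labels$region_name)))
  rows <- lapply(regions, function(rg) {
    lm_ <- lesion_mask(mask, rg, region_labels)
    les <- as.numeric(edges %*% mask_vec(lm_))
    d <- lesion_delta_r2(full, les, behavior, covariates)
    data.frame(region = rg, n_removed = attr(lm_, "n_removed"),
               r2_full = d$r2_full, r2_lesioned = d$r2_lesioned,
               delta_r2 = d$delta_r2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
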