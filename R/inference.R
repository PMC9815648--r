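#' Williams test for two dependent correlations sharing one variable
#'
#' Tests r13 against r23 when variables 1 and 2 are both correlated with
#' variable 3 in the same sample (Williams' t2 as codified by Steiger 1980):
#' `t = (r13 - r23) * sqrt((n - 1)(1 + r12) / (2 (n-1)/(n-3) |R| +
#' rbar^2 (1 - r12)^3))` with `|R| = 1 - r12^2 - r13^2 - r23^2 +
#' 2 r12 r13 r23`, `rbar = (r13 + r23) / 2`, df = n - 3.
#'
#' @param r13,r23 The two correlations being compared.
#' @param r12 Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return Object of class `dependent_cor_test`: `statistic`, `df`, `p`
#'   (two-sided), `method`, echoed inputs.
#' @export
williams_t <- function(r13, r23, r12, n) {
  check_r_triple(r13, r23, r12, n)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) stop("inconsistent correlation triple (|R| <= 0)")
  rbar <- (r13 + r23) / 2
  tval <- (r13 - r23) *
    sqrt((n - 1) * (1 + r12) /
           (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
  p <- 2 * stats::pt(abs(tval), df = n - 3, lower.tail = FALSE)
  structure(list(statistic = tval, df = n - 3, p = p,
                 method = "Williams t (dependent correlations, shared variable)",
                 r13 = r13, r23 = r23, r12 = r12, n = n),
            class = "dependent_cor_test")
}

#' Steiger Z for two dependent correlations sharing one variable
#'
#' Fisher-z based test of r(x, y1) against r(x, y2) with r(y1, y2) known
#' (Steiger 1980, pooled-r variant): the covariance of the two z-transformed
#' correlations is estimated at the pooled `rbar = (r1 + r2) / 2`, giving
#' `Z = (z1 - z2) sqrt(n - 3) / sqrt(2 - 2 c)` with
#' `c = [r_y1y2 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_y1y2^2) / ...]`
#' per the standard formulation.
#'
#' @param r_xy1,r_xy2 The two correlations being compared.
#' @param r_y1y2 Correlation between y1 and y2.
#' @param n Sample size (> 3).
#' @return A `dependent_cor_test` (normal reference distribution, no df).
#' @export
steiger_z <- function(r_xy1, r_xy2, r_y1y2, n) {
  check_r_triple(r_xy1, r_xy2, r_y1y2, n)
  detR <- 1 - r_y1y2^2 - r_xy1^2 - r_xy2^2 + 2 * r_y1y2 * r_xy1 * r_xy2
  if (detR <= 0) stop("inconsistent correlation triple (|R| <= 0)")
  rbar <- (r_xy1 + r_xy2) / 2
  psi <- r_y1y2 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
    (1 - 2 * rbar^2 - r_y1y2^2)
  cbar <- psi / (1 - rbar^2)^2
  z1 <- atanh(r_xy1)
  z2 <- atanh(r_xy2)
  zval <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cbar))
  p <- 2 * stats::pnorm(abs(zval), lower.tail = FALSE)
  structure(list(statistic = zval, df = NA_real_, p = p,
                 method = "Steiger Z (dependent correlations, shared variable)",
                 r13 = r_xy1, r23 = r_xy2, r12 = r_y1y2, n = n),
            class = "dependent_cor_test")
}

check_r_triple <- function(ra, rb, rc, n) {
  if (any(abs(c(ra, rb, rc)) >= 1)) stop("correlations must satisfy |r| < 1")
  if (n <= 3) stop("n must exceed 3")
  invisible(TRUE)
}

#' @export
print.dependent_cor_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.3f%s, two-sided p = %.4g (n = %d)\n",
              x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p, x$n))
  invisible(x)
}

#' Z-test between two regression coefficients
#'
#' `Z = (b1 - b2) / sqrt(se1^2 + se2^2)`, two-sided normal p.
#'
#' @param b1,b2 Coefficients.
#' @param se1,se2 Their standard errors (> 0).
#' @return List `z`, `p`.
#' @export
beta_z <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Bootstrap test of the difference between two standardized slopes
#'
#' For each resample (subjects with replacement) the outcome is regressed on
#' each standardized predictor (plus optional covariates) separately; the
#' difference between the two standardized slopes forms the bootstrap
#' distribution, and a two-sided add-one p is returned. Degenerate resamples
#' (collinear design) are redrawn and counted.
#'
#' @param outcome Numeric outcome.
#' @param predictor_a,predictor_b Numeric predictors.
#' @param covariates Optional covariate matrix.
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @return List `diff` (observed), `p`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_beta_diff <- function(outcome, predictor_a, predictor_b,
                                covariates = NULL, n_boot = 1000, seed = 1) {
  if (n_boot < 100) warning("n_boot < 100 gives a coarse p-value")
  n <- length(outcome)
  std_beta <- function(y, x, cv) {
    X <- cbind(1, scale(cbind(x, cv)))
    if (qr(X)$rank < ncol(X)) return(NULL)
    stats::lm.fit(X, as.numeric(scale(y)))$coefficients[2]
  }
  obs <- std_beta(outcome, predictor_a, covariates) -
    std_beta(outcome, predictor_b, covariates)
  set.seed(seed)
  boot <- numeric(n_boot)
  redrawn <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      cv <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
      ba <- std_beta(outcome[idx], predictor_a[idx], cv)
      bb <- std_beta(outcome[idx], predictor_b[idx], cv)
      if (!is.null(ba) && !is.null(bb) && is.finite(ba) && is.finite(bb)) {
        boot[i] <- ba - bb
        break
      }
      redrawn <- redrawn + 1L
      if (redrawn > 10 * n_boot) stop("too many degenerate resamples")
    }
  }
  crossing <- if (obs >= 0) sum(boot <= 0) else sum(boot >= 0)
  list(diff = unname(obs), p = min(1, 2 * (1 + crossing) / (n_boot + 1)),
       n_boot = n_boot, n_redrawn = redrawn)
}

#' Weighted Pearson correlation
#'
#' Correlation from weighted moments: `m_w(x) = sum(w x) / sum(w)`,
#' `cov_w(x, y) = sum(w (x - m_w(x)) (y - m_w(y))) / sum(w)`. With integer
#' weights this equals the unweighted correlation on the dataset with each
#' point replicated `w` times (used with non-participation x
#' post-stratification weights).
#'
#' @param x,y Numeric vectors.
#' @param weights Non-negative weights, not all zero.
#' @return Weighted correlation.
#' @export
weighted_correlation <- function(x, y, weights) {
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  sw <- sum(weights)
  mx <- sum(weights * x) / sw
  my <- sum(weights * y) / sw
  vx <- sum(weights * (x - mx)^2) / sw
  vy <- sum(weights * (y - my)^2) / sw
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  sum(weights * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

#' Within-subject block-level tracking
#'
#' Correlates two block-level measures (e.g. network strength and accuracy)
#' across blocks within each subject, summarises by the mean per-subject r,
#' and attaches a percentile bootstrap CI over subjects.
#'
#' @param strengths,accuracies Data frames with `subject_id`, `block` (any
#'   block key), and `value`; or a single merged data frame via
#'   `data` with columns `subject_id`, `x`, `y`.
#' @param data Alternative interface: merged data frame.
#' @param min_blocks Minimum paired blocks per included subject.
#' @param n_boot Bootstrap resamples of subjects for the CI.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return List `per_subject` (data frame `subject_id`, `r`, `n_blocks`),
#'   `mean_r`, `ci`, `n_subjects`.
#' @export
within_subject_tracking <- function(strengths = NULL, accuracies = NULL,
                                    data = NULL, min_blocks = 4,
                                    n_boot = 1000, conf = 0.95, seed = 1) {
  if (is.null(data)) {
    stopifnot(!is.null(strengths), !is.null(accuracies))
    data <- merge(strengths, accuracies,
                  by = c("subject_id", "block"),
                  suffixes = c("_x", "_y"))
    names(data)[names(data) == "value_x"] <- "x"
    names(data)[names(data) == "value_y"] <- "y"
  }
  per <- lapply(split(data, data$subject_id), function(d) {
    d <- d[stats::complete.cases(d$x, d$y), , drop = FALSE]
    if (nrow(d) < min_blocks || stats::sd(d$x) == 0 || stats::sd(d$y) == 0)
      return(NULL)
    data.frame(subject_id = d$subject_id[1], r = stats::cor(d$x, d$y),
               n_blocks = nrow(d))
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0)
    stop("no subject has >= min_blocks paired blocks")
  rownames(per) <- NULL
  set.seed(seed)
  ns <- nrow(per)
  boot <- vapply(seq_len(n_boot), function(i)
    mean(per$r[sample.int(ns, ns, replace = TRUE)]), numeric(1))
  alpha <- (1 - conf) / 2
  list(per_subject = per, mean_r = mean(per$r),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n_subjects = ns)
}

#' Recognition-memory discrimination index (d-prime)
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`. The default log-linear
#' correction adds 0.5 to each count and 1 to each total so extreme rates
#' stay finite.
#'
#' @param hits,false_alarms Counts.
#' @param n_old,n_new Totals of old / new items.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return d-prime.
#' @export
dprime <- function(hits, n_old, false_alarms, n_new,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (hits < 0 || hits > n_old || false_alarms < 0 || false_alarms > n_new)
    stop("counts out of range")
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (n_old + 1)
    fr <- (false_alarms + 0.5) / (n_new + 1)
  } else {
    hr <- hits / n_old
    fr <- false_alarms / n_new
  }
  stats::qnorm(hr) - stats::qnorm(fr)
}
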