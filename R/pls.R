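#' Build the group-stacked brain-behavior cross-block matrix
#'
#' Behavioral PLS with groups: edges and behavior are z-scored across
#' subjects within each group, and row g of the result is the Pearson
#' correlation of every edge with behavior within group g. With two groups
#' and one behavior this yields a 2 x E matrix whose SVD has exactly two
#' latent variables — a group-common and a group-differential
#' brain-behavior pattern.
#'
#' @param edges `n x E` matrix of vectorised upper-triangle Fisher-z values.
#' @param behavior Numeric vector, length n.
#' @param groups Group label per subject (>= 2 subjects per group).
#' @return `G x E` matrix with group names as row names.
#' @export
build_crossblock <- function(edges, behavior, groups) {
  groups <- as.character(groups)
  ug <- unique(groups)
  R <- matrix(NA_real_, length(ug), ncol(edges),
              dimnames = list(ug, NULL))
  for (g in ug) {
    ix <- which(groups == g)
    if (length(ix) < 2) stop("group '", g, "' has fewer than 2 subjects")
    if (stats::sd(behavior[ix]) == 0)
      stop("behavior is constant within group '", g, "'")
    r <- col_cor(edges[ix, , drop = FALSE], behavior[ix])
    r[is.na(r)] <- 0  # constant edges carry no covariance
    R[g, ] <- r
  }
  R
}

#' SVD of the cross-block matrix
#'
#' Thin SVD with a deterministic sign convention (each LV oriented so its
#' largest-magnitude edge salience is positive) and squared-singular-value
#' covariance fractions.
#'
#' @param R `G x E` cross-block matrix.
#' @return List `U` (E x L edge saliences), `s` (singular values,
#'   non-increasing), `V` (G x L behavior/design saliences), `sigma_frac`
#'   (`s^2 / sum(s^2)`).
#' @export
pls_svd <- function(R) {
  if (!all(is.finite(R))) stop("cross-block matrix must be finite")
  sv <- svd(t(R))  # E x G
  U <- sv$u
  V <- sv$v
  for (l in seq_along(sv$d)) {
    k <- which.max(abs(U[, l]))
    if (U[k, l] < 0) {
      U[, l] <- -U[, l]
      V[, l] <- -V[, l]
    }
  }
  rownames(V) <- rownames(R)
  s2 <- sv$d^2
  list(U = U, s = sv$d, V = V,
       sigma_frac = if (sum(s2) > 0) s2 / sum(s2) else s2)
}

# Z-score edges and behavior within group; returns the transformed copies.
zscore_within_group <- function(edges, behavior, groups) {
  for (g in unique(groups)) {
    ix <- which(groups == g)
    eg <- edges[ix, , drop = FALSE]
    mu <- colMeans(eg)
    sdv <- sqrt(colMeans(eg^2) - mu^2) * sqrt(length(ix) / (length(ix) - 1))
    sdv[sdv == 0] <- 1
    edges[ix, ] <- sweep(sweep(eg, 2, mu), 2, sdv, "/")
    behavior[ix] <- as.numeric(scale(behavior[ix]))
  }
  list(edges = edges, behavior = behavior)
}

# Procrustes rotation aligning a bootstrap solution to the original.
procrustes_rotation <- function(U_orig, U_boot) {
  m <- crossprod(U_boot, U_orig)
  sv <- svd(m)
  sv$u %*% t(sv$v)
}

#' Two-group behavioral PLS with permutation and bootstrap inference
#'
#' Fits the behavioral PLS: SVD of the group-stacked edge-behavior
#' correlation matrix, per-LV permutation p (subject rows of the edge matrix
#' shuffled against the behavior/group labels), bootstrap-ratio edge
#' reliability (subjects resampled within group, bootstrap solutions aligned
#' to the original by Procrustes rotation), and per-group LV-score/behavior
#' correlations with percentile bootstrap CIs.
#'
#' @param edges `n x E` matrix of vectorised Fisher-z edge values.
#' @param behavior Numeric vector, length n.
#' @param groups Group label per subject.
#' @param n_perm Permutations (default 500; 0 skips).
#' @param n_boot Bootstrap resamples (default 500; 0 skips).
#' @param zbr_threshold Bootstrap-ratio cut for significant edges.
#' @param seed Integer seed.
#' @param p Parcel count (stored; inferred when possible).
#' @return Object of class `bpls`: `U`, `s`, `V`, `sigma_frac`, `perm_p`,
#'   `boot_se`, `boot_ratio`, `sig_edges` (list per LV of edge indices with
#'   `|Z_BR| >=` threshold), `lv_behavior_corr`, `n_perm`, `n_boot`, `seed`,
#'   `groups`, `n`.
#' @export
bpls <- function(edges, behavior, groups, n_perm = 500, n_boot = 500,
                 zbr_threshold = 3, seed = 1, p = NULL) {
  edges <- as_edge_rows(edges, p)
  p <- attr(edges, "p")
  groups <- as.character(groups)
  zs <- zscore_within_group(edges, behavior, groups)
  R <- build_crossblock(zs$edges, zs$behavior, groups)
  fit <- pls_svd(R)
  L <- length(fit$s)

  perm_p <- rep(NA_real_, L)
  if (n_perm > 0) {
    if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
    set.seed(derive_seed(seed, 11))
    count <- integer(L)
    n <- nrow(edges)
    for (i in seq_len(n_perm)) {
      pr <- sample.int(n)
      Rp <- build_crossblock(zs$edges[pr, , drop = FALSE], zs$behavior,
                             groups)
      sp <- svd(t(Rp), nu = 0, nv = 0)$d
      count <- count + as.integer(sp >= fit$s)
    }
    perm_p <- (1 + count) / (n_perm + 1)
  }

  boot_se <- boot_ratio <- NULL
  sig_edges <- NULL
  if (n_boot > 0) {
    if (n_boot < 100) warning("n_boot < 100 gives unstable bootstrap ratios")
    set.seed(derive_seed(seed, 12))
    idx_by_group <- split(seq_len(nrow(edges)), groups)
    sum1 <- matrix(0, nrow(fit$U), L)
    sum2 <- matrix(0, nrow(fit$U), L)
    n_redrawn <- 0L
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- unlist(lapply(idx_by_group, function(ix)
          ix[sample.int(length(ix), length(ix), replace = TRUE)]),
          use.names = FALSE)
        # degenerate when behavior is constant within a resampled group
        bg <- split(behavior[idx], groups[idx])
        ok <- all(vapply(bg, function(v) stats::sd(v) > 0, logical(1)))
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 10 * n_boot) stop("too many degenerate resamples")
      }
      zb <- zscore_within_group(edges[idx, , drop = FALSE], behavior[idx],
                                groups[idx])
      Rb <- build_crossblock(zb$edges, zb$behavior, groups[idx])
      fb <- svd(t(Rb))
      rot <- procrustes_rotation(fit$U, fb$u)
      # accumulate singular-value-scaled saliences: the unit-norm constraint
      # on U alone understates per-edge sampling variability and inflates
      # bootstrap ratios, whereas U %*% diag(s) carries the full scale of the
      # underlying edge-behavior correlations
      Ub <- (fb$u %*% diag(fb$d, L)) %*% rot
      sum1 <- sum1 + Ub
      sum2 <- sum2 + Ub^2
    }
    boot_se <- sqrt(pmax(sum2 / n_boot - (sum1 / n_boot)^2, 0))
    boot_ratio <- (fit$U %*% diag(fit$s, L)) / boot_se
    boot_ratio[boot_se == 0] <- 0
    sig_edges <- lapply(seq_len(L), function(l)
      which(abs(boot_ratio[, l]) >= zbr_threshold))
  }

  out <- structure(
    c(fit,
      list(perm_p = perm_p, boot_se = boot_se, boot_ratio = boot_ratio,
           sig_edges = sig_edges, zbr_threshold = zbr_threshold,
           n_perm = n_perm, n_boot = n_boot, seed = seed,
           groups = groups, n = nrow(edges), p = p,
           lv_behavior_corr = NULL)),
    class = "bpls")
  out$lv_behavior_corr <- lv_behavior_correlations(
    out, edges, behavior, groups, n_boot = max(n_boot, 0),
    seed = derive_seed(seed, 13))
  out
}

#' @export
print.bpls <- function(x, ...) {
  cat(sprintf("bpls: %d subjects, %d groups, %d edges\n",
              x$n, length(unique(x$groups)), nrow(x$U)))
  for (l in seq_along(x$s)) {
    cat(sprintf(
      "  LV%d: sigma_frac = %.3f%s%s\n", l, x$sigma_frac[l],
      if (is.na(x$perm_p[l])) "" else sprintf(", perm p = %.4g", x$perm_p[l]),
      if (is.null(x$sig_edges)) ""
      else sprintf(", %d edges with |Z_BR| >= %g",
                   length(x$sig_edges[[l]]), x$zbr_threshold)))
  }
  invisible(x)
}

#' @export
summary.bpls <- function(object, ...) {
  print(object)
  if (!is.null(object$lv_behavior_corr)) {
    cat("LV-score / behavior correlations by group:\n")
    print(object$lv_behavior_corr, digits = 3)
  }
  invisible(object)
}

#' Per-group correlations of LV brain scores with behavior
#'
#' Brain score = edge rows x LV salience vector; correlated with behavior
#' within each group, with a percentile bootstrap CI (resampling subjects
#' within group).
#'
#' @param fit A `bpls`.
#' @param edges,behavior,groups The data the fit was built on (or new data).
#' @param n_boot Bootstrap resamples (0 skips the CI).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Data frame `lv`, `group`, `r`, `ci_lo`, `ci_hi`.
#' @export
lv_behavior_correlations <- function(fit, edges, behavior, groups,
                                     n_boot = 500, conf = 0.95, seed = 1) {
  edges <- as_edge_rows(edges, fit$p)
  groups <- as.character(groups)
  scores <- edges %*% fit$U
  alpha <- (1 - conf) / 2
  rows <- list()
  set.seed(seed)
  for (l in seq_along(fit$s)) {
    for (g in unique(groups)) {
      ix <- which(groups == g)
      r <- stats::cor(scores[ix, l], behavior[ix])
      lo <- hi <- NA_real_
      if (n_boot > 0) {
        boot <- vapply(seq_len(n_boot), function(i) {
          bi <- ix[sample.int(length(ix), length(ix), replace = TRUE)]
          if (stats::sd(behavior[bi]) == 0 || stats::sd(scores[bi, l]) == 0)
            return(NA_real_)
          stats::cor(scores[bi, l], behavior[bi])
        }, numeric(1))
        qs <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)
        lo <- unname(qs[1])
        hi <- unname(qs[2])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lv = l, group = g, r = r, ci_lo = lo, ci_hi = hi)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Balanced-group PLS by repeated subsampling
#'
#' When one group is larger, draws `n_rep` subsamples of the larger group at
#' `match_n` (without replacement), runs a full PLS per replicate, sign-aligns
#' the replicate saliences to the first replicate, and averages saliences,
#' covariance fractions, permutation p-values and bootstrap ratios.
#'
#' @param edges,behavior,groups As for [bpls()].
#' @param match_n Target size for the larger group; default: size of the
#'   smaller group.
#' @param n_rep Number of balanced replicates (default 200).
#' @param n_perm,n_boot Per-replicate inference settings (defaults 0 for
#'   speed; set to 500 for full inference).
#' @param seed Integer seed.
#' @param p Parcel count.
#' @return Object of class `bpls_balanced`: averaged `U`, `sigma_frac`,
#'   `perm_p`, `boot_ratio` (when computed), plus `n_rep`, `match_n`, and the
#'   last replicate's fit under `last_fit`.
#' @export
balanced_bpls <- function(edges, behavior, groups, match_n = NULL,
                          n_rep = 200, n_perm = 0, n_boot = 0, seed = 1,
                          p = NULL) {
  edges <- as_edge_rows(edges, p)
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[which.min(sizes)]
  large <- names(sizes)[which.max(sizes)]
  if (is.null(match_n)) match_n <- min(sizes)
  if (match_n > sizes[[large]]) stop("match_n exceeds the larger group size")
  ix_small <- which(groups == small)
  ix_large <- which(groups == large)
  set.seed(derive_seed(seed, 21))
  U_sum <- NULL
  sf_sum <- 0
  pp_sum <- 0
  br_sum <- NULL
  ref_U <- NULL
  last <- NULL
  for (rpt in seq_len(n_rep)) {
    sub <- sort(c(ix_small,
                  ix_large[sample.int(length(ix_large), match_n)]))
    fit <- bpls(edges[sub, , drop = FALSE], behavior[sub], groups[sub],
                n_perm = n_perm, n_boot = n_boot,
                seed = derive_seed(seed, 100 + rpt), p = attr(edges, "p"))
    if (is.null(ref_U)) {
      ref_U <- fit$U
      U_sum <- matrix(0, nrow(fit$U), ncol(fit$U))
      if (!is.null(fit$boot_ratio))
        br_sum <- matrix(0, nrow(fit$U), ncol(fit$U))
    }
    flip <- sign(colSums(fit$U * ref_U))
    flip[flip == 0] <- 1
    U_sum <- U_sum + sweep(fit$U, 2, flip, "*")
    sf_sum <- sf_sum + fit$sigma_frac
    if (n_perm > 0) pp_sum <- pp_sum + fit$perm_p
    if (!is.null(br_sum))
      br_sum <- br_sum + sweep(fit$boot_ratio, 2, flip, "*")
    last <- fit
  }
  structure(list(U = U_sum / n_rep, sigma_frac = sf_sum / n_rep,
                 perm_p = if (n_perm > 0) pp_sum / n_rep else NULL,
                 boot_ratio = if (!is.null(br_sum)) br_sum / n_rep else NULL,
                 n_rep = n_rep, match_n = match_n, last_fit = last),
            class = "bpls_balanced")
}

#' @export
print.bpls_balanced <- function(x, ...) {
  cat(sprintf("balanced bpls: %d replicates at n = %d per group\n",
              x$n_rep, x$match_n))
  cat("  averaged sigma_frac:", sprintf("%.3f", x$sigma_frac), "\n")
  invisible(x)
}
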