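#' Univariate edge selection against behavior
#'
#' The selection step of connectome-based predictive modelling: every edge is
#' Pearson-correlated with the behavioral score across training subjects and
#' kept, signed by its correlation, when the two-tailed p (t transform of r,
#' n - 2 df) falls below `alpha`. Edge-level p-values are deliberately not
#' multiplicity-corrected.
#'
#' @param edges `n x E` matrix of vectorised upper-triangle Fisher-z values
#'   (one row per subject, typically averaged over all task blocks), or a
#'   list of `edge_matrix` objects.
#' @param behavior Numeric vector, length n.
#' @param alpha Two-tailed selection threshold (default 0.01).
#' @param p Parcel count; required when `edges` is a matrix.
#' @return A `network_mask` with +1/-1 on selected edges. Attribute
#'   `n_skipped` counts constant edges skipped.
#' @export
select_edges <- function(edges, behavior, alpha = 0.01, p = NULL) {
  edges <- as_edge_rows(edges, p)
  p <- attr(edges, "p")
  if (is.na(p)) stop("cannot infer parcel count; supply p")
  n <- nrow(edges)
  if (n < 10) stop("edge selection needs at least 10 subjects")
  if (stats::sd(behavior) == 0) stop("behavior is constant")
  r <- col_cor(edges, behavior)
  skipped <- sum(is.na(r))
  pv <- cor_p(r, n)
  sel <- !is.na(r) & pv < alpha
  w <- integer(length(r))
  w[sel] <- ifelse(r[sel] > 0, 1L, -1L)
  out <- network_mask(vec_ut(w, p))
  attr(out, "n_skipped") <- skipped
  out
}

# Coerce edge input (matrix or list of edge_matrix) to an n x E matrix with a
# "p" attribute.
as_edge_rows <- function(edges, p = NULL) {
  if (is.list(edges) && length(edges) && inherits(edges[[1]], "edge_matrix")) {
    p <- nrow(edges[[1]]$z)
    edges <- t(vapply(edges, function(e) ut_vec(e$z),
                      numeric(total_edges(p))))
  }
  edges <- as.matrix(edges)
  if (is.null(p)) {
    p <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
    # a non-triangular column count cannot map back to a connectome; keep NA
    # and let mask-producing callers insist on a parcel count
    if (p != round(p)) p <- NA_real_
  }
  attr(edges, "p") <- as.integer(p)
  edges
}

#' Fit a connectome-based predictive model with leave-one-site-out CV
#'
#' For each site, edges are selected ([select_edges()]) on the subjects of
#' all other sites; the held-out site is scored by the signed network
#' strength under that fold's mask. A consensus mask keeps edges present
#' (with consistent sign) in at least `binarize_threshold` of the site
#' models.
#'
#' @param edges `n x E` matrix (or list of `edge_matrix`), averaged over all
#'   task blocks.
#' @param behavior Numeric vector, length n.
#' @param sites Site label per subject (>= 2 sites, >= 2 subjects each).
#' @param alpha Selection threshold.
#' @param binarize_threshold Consensus fraction (inclusive, default 0.5).
#' @param p Parcel count (when `edges` is a matrix).
#' @return Object of class `cpm`: `site_models` (named list of
#'   `network_mask`), `train_n`, `consensus`, `holdout` (data frame of
#'   held-out strengths aligned with the input order), `alpha`,
#'   `binarize_threshold`, `sites`, `p`.
#' @export
cpm <- function(edges, behavior, sites, alpha = 0.01,
                binarize_threshold = 0.5, p = NULL) {
  edges <- as_edge_rows(edges, p)
  p <- attr(edges, "p")
  sites <- as.character(sites)
  us <- sort(unique(sites))
  if (length(us) < 2) stop("leave-one-site-out needs at least 2 sites")
  if (any(table(sites) < 2)) stop("every site needs at least 2 subjects")
  site_models <- list()
  train_n <- integer(0)
  strength <- rep(NA_real_, nrow(edges))
  for (k in us) {
    train <- sites != k
    m <- select_edges(edges[train, , drop = FALSE], behavior[train],
                      alpha = alpha, p = p)
    m$name <- paste0("heldout_", k)
    site_models[[k]] <- m
    train_n[k] <- sum(train)
    strength[!train] <- edges[!train, , drop = FALSE] %*% mask_vec(m)
  }
  fit <- structure(
    list(site_models = site_models, train_n = train_n,
         consensus = NULL, alpha = alpha,
         binarize_threshold = binarize_threshold,
         holdout = data.frame(site = sites, strength = strength,
                              behavior = behavior),
         sites = sites, p = p),
    class = "cpm")
  fit$consensus <- consensus_mask(fit)
  fit
}

#' Consensus mask of a fitted CPM
#'
#' Averages the signed edge indicators over all site models and keeps edges
#' whose mean signed vote has absolute value at or above the binarization
#' threshold (inclusive, so an even split of votes at exactly the threshold
#' counts).
#'
#' @param model A `cpm` fit.
#' @param threshold Binarization fraction; defaults to the fit's.
#' @return A `network_mask`.
#' @export
consensus_mask <- function(model, threshold = model$binarize_threshold) {
  if (!length(model$site_models)) stop("no site models")
  votes <- Reduce(`+`, lapply(model$site_models, mask_vec)) /
    length(model$site_models)
  w <- integer(length(votes))
  keep <- abs(votes) >= threshold
  w[keep] <- ifelse(votes[keep] > 0, 1L, -1L)
  network_mask(vec_ut(w, model$p), name = "consensus")
}

#' @export
print.cpm <- function(x, ...) {
  cat(sprintf("cpm: %d site folds (alpha = %g), consensus %d+/%d- edges of %d\n",
              length(x$site_models), x$alpha,
              x$consensus$n_pos, x$consensus$n_neg, total_edges(x$p)))
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  rep <- evaluate_prediction(object$holdout$strength, object$holdout$behavior,
                             sites = object$holdout$site)
  out <- list(fit = object, prediction = rep)
  class(out) <- "summary.cpm"
  out
}

#' @export
print.summary.cpm <- function(x, ...) {
  print(x$fit)
  cat("held-out prediction (pooled across sites):\n")
  print(x$prediction)
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) mask_edges(object$consensus)

#' Score new subjects with a fitted CPM
#'
#' Applies the consensus mask (default) or a named site model to new edge
#' rows; the score is the signed network strength.
#'
#' @param object A `cpm` fit.
#' @param edges `n x E` matrix or list of `edge_matrix`.
#' @param mask `"consensus"` or a held-out site name.
#' @param ... Unused.
#' @return Numeric vector of strengths.
#' @export
predict.cpm <- function(object, edges, mask = "consensus", ...) {
  edges <- as_edge_rows(edges, object$p)
  m <- if (identical(mask, "consensus")) object$consensus
       else object$site_models[[mask]]
  if (is.null(m)) stop("unknown mask '", mask, "'")
  as.numeric(edges %*% mask_vec(m))
}

#' Evaluate strength-based prediction
#'
#' Pearson and Spearman correlations (two-tailed p) between network-strength
#' scores and behavior, pooled and per site.
#'
#' @param strengths Numeric scores (e.g. held-out strengths).
#' @param behavior Numeric vector, same length.
#' @param sites Optional site labels for a per-site breakdown.
#' @return Object of class `prediction_report`: `r`, `r_p`, `rho`, `rho_p`,
#'   `n`, and `per_site` data frame (when sites given).
#' @export
evaluate_prediction <- function(strengths, behavior, sites = NULL) {
  ok <- stats::complete.cases(strengths, behavior)
  s <- strengths[ok]
  b <- behavior[ok]
  if (length(s) < 3) stop("need at least 3 subjects")
  if (stats::sd(s) == 0 || stats::sd(b) == 0) stop("constant input")
  ct <- stats::cor.test(s, b)
  # Spearman with average ranks for ties; p via the t approximation
  rho <- stats::cor(rank(s), rank(b))
  rho_p <- cor_p(rho, length(s))
  per_site <- NULL
  if (!is.null(sites)) {
    sites <- sites[ok]
    per_site <- do.call(rbind, lapply(split(seq_along(s), sites), function(ix) {
      if (length(ix) < 3 || stats::sd(s[ix]) == 0 || stats::sd(b[ix]) == 0)
        return(data.frame(site = sites[ix[1]], n = length(ix),
                          r = NA_real_, rho = NA_real_))
      data.frame(site = sites[ix[1]], n = length(ix),
                 r = stats::cor(s[ix], b[ix]),
                 rho = stats::cor(rank(s[ix]), rank(b[ix])))
    }))
    rownames(per_site) <- NULL
  }
  structure(list(r = unname(ct$estimate), r_p = ct$p.value,
                 rho = rho, rho_p = rho_p, n = length(s),
                 per_site = per_site),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("  r = %.3f (p = %.3g), rho = %.3f (p = %.3g), n = %d\n",
              x$r, x$r_p, x$rho, x$rho_p, x$n))
  invisible(x)
}

#' Mean within-network strength for a canonical network
#'
#' Average Fisher-z value over the unique edges whose both endpoints carry
#' the given canonical-network label.
#'
#' @param em An `edge_matrix` or symmetric matrix.
#' @param partition Network label per parcel (length P).
#' @param network_id Label of the network.
#' @return Scalar mean strength.
#' @export
canonical_network_strength <- function(em, partition, network_id) {
  z <- if (inherits(em, "edge_matrix")) em$z else as.matrix(em)
  members <- which(partition == network_id)
  if (length(members) < 2)
    stop("network '", network_id, "' has no within-network edge")
  sub <- z[members, members, drop = FALSE]
  mean(ut_vec(sub))
}

#' Random size-matched network baseline
#'
#' Draws `n_random` masks with exactly the reference mask's positive and
#' negative edge counts from the edges outside the reference, and computes an
#' add-one empirical p for an observed effect against the distribution of
#' the effect over the random masks.
#'
#' @param reference A `network_mask`.
#' @param n_random Number of random masks (default 200).
#' @param seed Integer seed.
#' @param effect_fn Optional function(`network_mask`) -> scalar effect.
#' @param observed Observed effect of the reference (required with
#'   `effect_fn`).
#' @return List with `masks` (when `effect_fn` is `NULL`) or `effects` and
#'   `p` (add-one convention: `(1 + #{random >= observed}) / (n_random + 1)`).
#' @export
random_matched_networks <- function(reference, n_random = 200, seed = 1,
                                    effect_fn = NULL, observed = NULL) {
  set.seed(seed)
  E <- total_edges(reference$p)
  v <- mask_vec(reference)
  pool <- which(v == 0L)
  need <- reference$n_pos + reference$n_neg
  if (length(pool) < need)
    stop("not enough edges outside the reference mask")
  make_one <- function() {
    pick <- pool[sample.int(length(pool), need)]
    w <- integer(E)
    if (reference$n_pos) w[pick[seq_len(reference$n_pos)]] <- 1L
    if (reference$n_neg) w[pick[reference$n_pos + seq_len(reference$n_neg)]] <- -1L
    network_mask(vec_ut(w, reference$p))
  }
  if (is.null(effect_fn)) {
    return(list(masks = replicate(n_random, make_one(), simplify = FALSE)))
  }
  if (is.null(observed)) stop("observed effect required with effect_fn")
  effects <- vapply(seq_len(n_random), function(i) effect_fn(make_one()),
                    numeric(1))
  list(effects = effects,
       p = (1 + sum(effects >= observed)) / (n_random + 1))
}
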