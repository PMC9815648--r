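#' Configuration for the synthetic study generator
#'
#' Bundles every generator parameter with defaults that emulate the structure
#' of a two-cohort developmental n-back study: a youth cohort and an adult
#' cohort (`n_per_group` each) across `n_sites` sites, latent sustained
#' attention (SA) and working memory (WM) abilities correlated
#' `ability_corr`, 16 task blocks per subject (8 per condition, 30/31 TRs at
#' TR = 0.8 s), planted positive/negative predictive edge sets for each
#' ability, and group-common plus group-differential brain-behavior edges.
#'
#' Mask sizes default to the canonical published network sizes (757/630 for
#' SA, 1674/1203 for WM at 268 parcels), rescaled proportionally to the edge
#' count when `p != 268`; likewise the planted pairwise overlaps (37 and 33).
#'
#' @param p Parcel count.
#' @param n_per_group Subjects per age group.
#' @param n_sites Number of acquisition sites.
#' @param ability_corr Correlation of the two latent abilities.
#' @param mask_sizes Named sizes for `sa_pos`, `sa_neg`, `wm_pos`, `wm_neg`;
#'   `NULL` rescales the canonical sizes.
#' @param overlap_spec Named overlap counts (`"a:b"` = count); `NULL` rescales
#'   the canonical 37/33 overlaps.
#' @param n_common,n_differential Planted group-common / group-differential
#'   edge-set sizes; `NULL` rescales 300/150 (268-parcel scale).
#' @param effect_sizes Per-mask edge effect in z-units per ability SD.
#' @param beta_common,beta_differential Effects of the common / differential
#'   edge sets (z-units per SD of SA ability; differential sign flips for
#'   adults).
#' @param edge_noise_sd Per-block edge noise SD (z-units).
#' @param state_sd SD of the per-block latent attentional state, which scales
#'   the mask effects jointly with ability.
#' @param lambda Accuracy loading per ability SD (0-back on SA, 2-back on WM).
#' @param cross_loading Accuracy cross-loading of the other ability.
#' @param acc_base Baseline accuracy per condition (youth).
#' @param acc_noise_sd Per-block accuracy noise SD.
#' @param stimulus_effects Accuracy offsets by stimulus type (accuracy units).
#' @param run_effect Accuracy offset of run 2 relative to run 1.
#' @param motion_coef Accuracy change per mm of block FD.
#' @param state_acc_coef Accuracy loading of the block state (couples block
#'   strength and block accuracy within subject).
#' @param group_offsets List with `ability` (adult mean shift of `a_sa`,
#'   `a_wm`) and `accuracy` (adult accuracy shift per condition).
#' @param hub Anatomical concentration of the SA masks: list with `region`
#'   (1-based index into the sorted region names, or a name) and `frac`
#'   (fraction of SA edges required to touch it). `NULL` disables.
#' @param group_region_effect Optional list(`region`, `beta`, `group`) adding
#'   an extra mask effect for edges touching a region in one group only.
#' @param mode `"direct_edges"` (default) or `"timeseries"`.
#' @param fd_meanlog,fd_sdlog Log-normal parameters of subject mean FD (mm).
#' @param site_assignment `"round_robin"` or `"multinomial"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(p = 268, n_per_group = 754, n_sites = 18,
                       ability_corr = 0.62,
                       mask_sizes = NULL, overlap_spec = NULL,
                       n_common = NULL, n_differential = NULL,
                       effect_sizes = c(sa_pos = 0.02, sa_neg = 0.02,
                                        wm_pos = 0.02, wm_neg = 0.02),
                       beta_common = 0.02, beta_differential = 0.02,
                       edge_noise_sd = 0.1, state_sd = 1,
                       lambda = c(zero_back = 0.03, two_back = 0.03),
                       cross_loading = 0,
                       acc_base = c(zero_back = 0.87, two_back = 0.77),
                       acc_noise_sd = 0.17,
                       stimulus_effects = c(neutral_face = 0,
                                            positive_face = -0.005,
                                            negative_face = -0.01,
                                            place = -0.022),
                       run_effect = -0.005,
                       motion_coef = -0.05,
                       state_acc_coef = 0.012,
                       group_offsets = list(
                         ability = c(a_sa = 0.5, a_wm = 0.3),
                         accuracy = c(zero_back = 0.045, two_back = 0.02)),
                       hub = list(region = 1L, frac = 0.4),
                       group_region_effect = NULL,
                       mode = c("direct_edges", "timeseries"),
                       fd_meanlog = log(0.10), fd_sdlog = 0.35,
                       site_assignment = c("round_robin", "multinomial")) {
  mode <- match.arg(mode)
  site_assignment <- match.arg(site_assignment)
  E <- total_edges(p)
  scale <- E / total_edges(268)
  if (is.null(mask_sizes))
    mask_sizes <- pmax(round(c(sa_pos = 757, sa_neg = 630,
                               wm_pos = 1674, wm_neg = 1203) * scale), 2)
  if (is.null(overlap_spec))
    overlap_spec <- round(c("sa_pos:wm_pos" = 37, "sa_neg:wm_neg" = 33) * scale)
  if (is.null(n_common)) n_common <- max(4, round(300 * scale))
  if (is.null(n_differential)) n_differential <- max(4, round(150 * scale))
  cfg <- list(p = p, n_per_group = n_per_group, n_sites = n_sites,
              ability_corr = ability_corr, mask_sizes = mask_sizes,
              overlap_spec = overlap_spec, n_common = n_common,
              n_differential = n_differential, effect_sizes = effect_sizes,
              beta_common = beta_common,
              beta_differential = beta_differential,
              edge_noise_sd = edge_noise_sd, state_sd = state_sd,
              lambda = lambda, cross_loading = cross_loading,
              acc_base = acc_base, acc_noise_sd = acc_noise_sd,
              stimulus_effects = stimulus_effects, run_effect = run_effect,
              motion_coef = motion_coef, state_acc_coef = state_acc_coef,
              group_offsets = group_offsets, hub = hub,
              group_region_effect = group_region_effect, mode = mode,
              fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
              site_assignment = site_assignment)
  class(cfg) <- "sim_config"
  cfg
}

#' Macroscale region labels for a parcellation
#'
#' Assigns parcels to 20 macroscale regions (10 per hemisphere) in contiguous
#' chunks, mirroring the coarse anatomical grouping used for network anatomy
#' and lesioning.
#'
#' @param p Parcel count.
#' @param n_regions Number of base regions per hemisphere.
#' @return Data frame with `parcel_id` (0-based), `region_name`, `hemisphere`.
#' @export
make_region_labels <- function(p, n_regions = 10) {
  base <- c("prefrontal", "motor", "insula", "parietal", "temporal",
            "occipital", "limbic", "cerebellum", "subcortex", "brainstem")
  base <- rep_len(base, n_regions)
  hemi <- rep(c("L", "R"), each = ceiling(p / 2))[seq_len(p)]
  n_l <- sum(hemi == "L")
  within_h <- c(seq_len(n_l), seq_len(p - n_l))
  chunk <- ceiling(p / 2) / n_regions
  idx <- pmin(ceiling(within_h / chunk), n_regions)
  data.frame(parcel_id = seq_len(p) - 1L,
             region_name = paste0(base[idx], "_", hemi),
             hemisphere = hemi)
}

#' Plant ground-truth predictive edge sets
#'
#' Draws the four predictive network masks (`sa_pos`, `sa_neg`, `wm_pos`,
#' `wm_neg`) with exact edge counts and exact pairwise overlaps, plus a
#' group-common and a group-differential brain-behavior edge set disjoint
#' from the masks. `sa_pos`/`wm_pos` carry weight +1, `sa_neg`/`wm_neg`
#' weight -1, so summing a pos/neg pair yields the trinary model mask.
#'
#' @param p Parcel count.
#' @param mask_sizes Named integer sizes (see [sim_config()]).
#' @param overlap_spec Named overlap counts, names `"maskA:maskB"`; pairs not
#'   listed are disjoint.
#' @param n_common,n_differential Sizes of the extra planted edge sets.
#' @param region_labels Optional labels (needed for `hub`).
#' @param hub Optional list(`region`, `frac`): fraction of each SA mask's
#'   edges forced to touch the given region.
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: `masks` (named `network_mask`
#'   list), `common` / `differential` (data frames with `edge` (1-based index
#'   into the upper-triangle vector), `i`, `j`, `sign`), `p`, `region_labels`,
#'   `params`.
#' @export
make_ground_truth <- function(p, mask_sizes, overlap_spec = NULL,
                              n_common = 0, n_differential = 0,
                              region_labels = NULL, hub = NULL, seed = 1) {
  E <- total_edges(p)
  mask_sizes <- mask_sizes[c("sa_pos", "sa_neg", "wm_pos", "wm_neg")]
  if (anyNA(mask_sizes))
    stop("mask_sizes must name sa_pos, sa_neg, wm_pos, wm_neg")
  if (any(mask_sizes > E))
    stop(sprintf("mask size exceeds the %d available edges", E))
  if (sum(mask_sizes) - sum(overlap_spec) + n_common + n_differential > E)
    stop("requested edge sets cannot fit disjointly into the connectome")

  committed <- stats::setNames(rep(list(integer(0)), length(mask_sizes)),
                               names(mask_sizes))
  used <- logical(E)
  set.seed(seed)

  draw <- function(n, from = NULL) {
    pool <- if (is.null(from)) which(!used) else from[!used[from]]
    if (length(pool) < n)
      stop(sprintf("infeasible request: need %d edges, only %d available",
                   n, length(pool)))
    picked <- pool[sample.int(length(pool), n)]
    used[picked] <<- TRUE
    picked
  }

  # exact pairwise overlaps first
  if (length(overlap_spec)) {
    for (k in seq_along(overlap_spec)) {
      pair <- strsplit(names(overlap_spec)[k], ":", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !all(pair %in% names(mask_sizes)))
        stop("overlap_spec names must be 'maskA:maskB'")
      n_ov <- overlap_spec[[k]]
      for (nm in pair)
        if (length(committed[[nm]]) + n_ov > mask_sizes[[nm]])
          stop(sprintf("overlaps overcommit mask '%s'", nm))
      shared <- draw(n_ov)
      for (nm in pair) committed[[nm]] <- c(committed[[nm]], shared)
    }
  }

  # hub-biased eligibility for SA masks
  hub_pool <- NULL
  et <- edge_table(p)
  if (!is.null(hub)) {
    if (is.null(region_labels)) region_labels <- make_region_labels(p)
    reg <- region_of_parcel(region_labels, p)
    regions <- sort(unique(reg))
    hub_name <- if (is.character(hub$region)) hub$region
                else regions[hub$region]
    if (is.na(hub_name) || !hub_name %in% regions) stop("unknown hub region")
    hub_pool <- which(reg[et$i + 1L] == hub_name | reg[et$j + 1L] == hub_name)
  }

  for (nm in names(mask_sizes)) {
    rest <- mask_sizes[[nm]] - length(committed[[nm]])
    if (!is.null(hub_pool) && grepl("^sa_", nm)) {
      n_hub <- min(rest, round(hub$frac * mask_sizes[[nm]]))
      committed[[nm]] <- c(committed[[nm]], draw(n_hub, from = hub_pool))
      rest <- rest - n_hub
    }
    if (rest > 0) committed[[nm]] <- c(committed[[nm]], draw(rest))
  }

  build_mask <- function(idx, w, name)
    network_mask(data.frame(i = et$i[idx], j = et$j[idx], w = w),
                 p = p, name = name)
  masks <- list(
    sa_pos = build_mask(committed$sa_pos, 1L, "sa_pos"),
    sa_neg = build_mask(committed$sa_neg, -1L, "sa_neg"),
    wm_pos = build_mask(committed$wm_pos, 1L, "wm_pos"),
    wm_neg = build_mask(committed$wm_neg, -1L, "wm_neg"))

  edge_set <- function(n) {
    idx <- if (n > 0) draw(n) else integer(0)
    data.frame(edge = idx, i = et$i[idx], j = et$j[idx],
               sign = if (n > 0) sample(c(-1L, 1L), n, replace = TRUE)
                      else integer(0))
  }
  common <- edge_set(n_common)
  differential <- edge_set(n_differential)

  structure(list(masks = masks, common = common, differential = differential,
                 p = p, region_labels = region_labels,
                 params = list(mask_sizes = mask_sizes,
                               overlap_spec = overlap_spec,
                               n_common = n_common,
                               n_differential = n_differential,
                               hub = hub, seed = seed)),
            class = "ground_truth")
}

#' Combine a positive and a negative mask into one trinary model mask
#'
#' @param pos,neg `network_mask` objects with disjoint edge sets.
#' @param name Name for the combined mask.
#' @return A `network_mask` holding the union of edges.
#' @export
combine_masks <- function(pos, neg, name = NULL) {
  network_mask(pos$w + neg$w, name = name)
}

#' Simulate the subject table
#'
#' Latent abilities are bivariate normal with correlation `ability_corr`;
#' adults receive the configured mean shifts. Sites are assigned round-robin
#' within group (balanced) or multinomially.
#'
#' @param n_per_group Subjects per group.
#' @param n_sites Number of sites.
#' @param ability_corr Ability correlation, |r| < 1.
#' @param group_offsets Adult mean ability shift, named `a_sa`, `a_wm`.
#' @param fd_meanlog,fd_sdlog Log-normal FD parameters.
#' @param site_assignment `"round_robin"` or `"multinomial"`.
#' @param seed Integer seed.
#' @return Data frame: `subject_id`, `group`, `site`, `a_sa`, `a_wm`,
#'   `mean_fd`, `weight`.
#' @export
simulate_subjects <- function(n_per_group, n_sites = 18, ability_corr = 0.62,
                              group_offsets = c(a_sa = 0.5, a_wm = 0.3),
                              fd_meanlog = log(0.10), fd_sdlog = 0.35,
                              site_assignment = c("round_robin",
                                                  "multinomial"),
                              seed = 1) {
  site_assignment <- match.arg(site_assignment)
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (abs(ability_corr) >= 1)
    stop("ability covariance not positive definite: |ability_corr| must be < 1")
  set.seed(seed)
  n <- 2L * n_per_group
  L <- chol(matrix(c(1, ability_corr, ability_corr, 1), 2))
  ab <- matrix(stats::rnorm(2 * n), n, 2) %*% L
  group <- rep(c("youth", "adult"), each = n_per_group)
  ab[group == "adult", 1] <- ab[group == "adult", 1] + group_offsets[["a_sa"]]
  ab[group == "adult", 2] <- ab[group == "adult", 2] + group_offsets[["a_wm"]]
  site <- integer(n)
  if (site_assignment == "round_robin") {
    for (g in unique(group))
      site[group == g] <- rep_len(seq_len(n_sites), sum(group == g))
  } else {
    site <- sample.int(n_sites, n, replace = TRUE)
  }
  data.frame(subject_id = sprintf("s%04d", seq_len(n)), group = group,
             site = sprintf("site%02d", site),
             a_sa = ab[, 1], a_wm = ab[, 2],
             mean_fd = stats::rlnorm(n, fd_meanlog, fd_sdlog),
             weight = stats::rgamma(n, shape = 8, rate = 8),
             stringsAsFactors = FALSE)
}

#' Default block design
#'
#' Two runs of eight blocks each: four 0-back and four 2-back per run, each of
#' the four stimulus types once per condition per run; block lengths alternate
#' 30/31 TRs with 5-TR gaps.
#'
#' @param tr Repetition time (s).
#' @return Data frame of 16 block records (per subject), without FD/accuracy.
#' @export
default_design <- function(tr = 0.8) {
  stim <- c("neutral_face", "negative_face", "positive_face", "place")
  rows <- vector("list", 16)
  k <- 0L
  for (run in 1:2) {
    cond <- rep(c("zero_back", "two_back"), 4)
    st <- c(stim[c(1, 3, 2, 4)], stim[c(4, 2, 3, 1)])
    onset <- 10L
    for (b in 1:8) {
      len <- if (b %% 2 == 1) 30L else 31L
      k <- k + 1L
      rows[[k]] <- data.frame(
        run_id = sprintf("run%d", run), block_index = b,
        condition = cond[b], stimulus = st[b],
        onset_tr = onset, offset_tr = onset + len)
      onset <- onset + len + 5L
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "tr") <- tr
  out
}

#' Simulate block-level behavior
#'
#' Block accuracy is generated on a linear scale and clipped to [0, 1]:
#' base + group offset + ability loading + stimulus offset + run offset +
#' motion effect + state coupling + noise. 0-back loads on SA ability, 2-back
#' on WM. The hidden per-block state (`state` column) is shared with the
#' connectome generator so block strength and block accuracy co-fluctuate
#' within subject.
#'
#' @param subjects Data frame from [simulate_subjects()].
#' @param config A `sim_config` (behavioral coefficients are read from it).
#' @param design Block design (default [default_design()]).
#' @param seed Integer seed.
#' @return Data frame: one row per subject x block with the design columns,
#'   FD summaries, hidden `state`, and `accuracy`.
#' @export
simulate_behavior <- function(subjects, config = sim_config(),
                              design = default_design(), seed = 1) {
  if (!all(design$stimulus %in% names(config$stimulus_effects)))
    stop("unknown stimulus label(s): ",
         paste(setdiff(design$stimulus, names(config$stimulus_effects)),
               collapse = ", "))
  set.seed(seed)
  n <- nrow(subjects)
  B <- nrow(design)
  beh <- design[rep(seq_len(B), times = n), , drop = FALSE]
  beh <- cbind(subject_id = rep(subjects$subject_id, each = B), beh)
  rownames(beh) <- NULL

  beh$fd_mean <- rep(subjects$mean_fd, each = B) * stats::rlnorm(n * B, 0, 0.2)
  beh$fd_max <- beh$fd_mean * stats::runif(n * B, 2, 6)
  beh$state <- stats::rnorm(n * B)

  grp <- rep(subjects$group, each = B)
  asa <- rep(subjects$a_sa, each = B)
  awm <- rep(subjects$a_wm, each = B)
  is0 <- beh$condition == "zero_back"
  ability_term <- ifelse(is0,
                         config$lambda[["zero_back"]] * asa +
                           config$cross_loading * awm,
                         config$lambda[["two_back"]] * awm +
                           config$cross_loading * asa)
  base <- ifelse(is0, config$acc_base[["zero_back"]],
                 config$acc_base[["two_back"]])
  adult_off <- ifelse(
    grp == "adult",
    ifelse(is0, config$group_offsets$accuracy[["zero_back"]],
           config$group_offsets$accuracy[["two_back"]]), 0)
  acc <- base + adult_off + ability_term +
    unname(config$stimulus_effects[beh$stimulus]) +
    ifelse(beh$run_id == "run2", config$run_effect, 0) +
    config$motion_coef * beh$fd_mean +
    config$state_acc_coef * beh$state +
    stats::rnorm(n * B, 0, config$acc_noise_sd)
  beh$accuracy <- pmin(pmax(acc, 0), 1)
  beh
}

# Signed effect vectors (length E) for each planted component.
effect_vectors <- function(gt, config) {
  E <- total_edges(gt$p)
  v <- function(mask, beta) mask_vec(mask) * beta
  vsa <- v(gt$masks$sa_pos, config$effect_sizes[["sa_pos"]]) +
    v(gt$masks$sa_neg, config$effect_sizes[["sa_neg"]])
  vwm <- v(gt$masks$wm_pos, config$effect_sizes[["wm_pos"]]) +
    v(gt$masks$wm_neg, config$effect_sizes[["wm_neg"]])
  vc <- numeric(E)
  vd <- numeric(E)
  if (nrow(gt$common)) vc[gt$common$edge] <- config$beta_common * gt$common$sign
  if (nrow(gt$differential))
    vd[gt$differential$edge] <- config$beta_differential * gt$differential$sign
  list(sa = vsa, wm = vwm, common = vc, differential = vd)
}

#' Simulate connectomes for every subject and block
#'
#' In `direct_edges` mode each block's Fisher-z edge vector is
#' `mu + mask effects x (ability + state) + common/differential effects x SA
#' ability + noise`; the differential term's sign flips for adults. Returns
#' compact cross-subject summaries (mean edges over all blocks and per
#' condition) plus per-block strengths for the planted masks, and optionally
#' the full per-block edge vectors. In `timeseries` mode the implied
#' correlation matrix `tanh(z)` is projected to the nearest PSD correlation
#' matrix (eigenvalue clipping, unit-diagonal rescale) and multivariate
#' normal TR samples are drawn, so estimated FC carries realistic T-limited
#' noise.
#'
#' @param subjects,behavior Generator tables.
#' @param gt A `ground_truth`.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param keep_blocks Keep the full per-block edge matrices (list of n x E;
#'   memory-heavy, for small configs and tests).
#' @return List of class `sim_connectomes`. Direct mode: `edges_mean`
#'   (n x E), `edges_cond` (named list of n x E), `block_strengths` (behavior
#'   table plus one strength column per planted mask and combined `sa` /
#'   `wm`), `mu`, optional `blocks`. Timeseries mode: `ts` (list subject ->
#'   run -> `parcel_ts`) plus `mu` and, with `keep_blocks`, the per-block
#'   target correlation matrices.
#' @export
simulate_connectomes <- function(subjects, behavior, gt,
                                 config = sim_config(), seed = 1,
                                 keep_blocks = FALSE) {
  if (gt$p != config$p) stop("ground truth parcel count mismatch")
  set.seed(seed)
  p <- gt$p
  E <- total_edges(p)
  n <- nrow(subjects)
  ev <- effect_vectors(gt, config)
  mu <- stats::rnorm(E, 0.25, 0.1)

  # optional group x region extra effect on SA-mask edges
  vx <- NULL
  gx <- NULL
  if (!is.null(config$group_region_effect)) {
    gre <- config$group_region_effect
    labs <- if (is.null(gt$region_labels)) make_region_labels(p)
            else gt$region_labels
    reg <- region_of_parcel(labs, p)
    et <- edge_table(p)
    touch <- reg[et$i + 1L] == gre$region | reg[et$j + 1L] == gre$region
    sa_comb <- mask_vec(gt$masks$sa_pos) + mask_vec(gt$masks$sa_neg)
    vx <- ifelse(touch, sa_comb * gre$beta, 0)
    gx <- as.numeric(subjects$group == gre$group)
  }

  gsign <- ifelse(subjects$group == "adult", -1, 1)
  ord <- order(match(behavior$subject_id, subjects$subject_id),
               behavior$run_id, behavior$block_index)
  behavior <- behavior[ord, , drop = FALSE]
  B <- nrow(behavior) / n
  if (B != round(B)) stop("behavior table is not balanced across subjects")
  block_of <- matrix(seq_len(nrow(behavior)), nrow = B)  # column = subject

  if (config$mode == "timeseries")
    return(simulate_connectomes_ts(subjects, behavior, gt, config, mu, ev,
                                   gsign, keep_blocks))

  masks_all <- c(gt$masks, list(
    sa = combine_masks(gt$masks$sa_pos, gt$masks$sa_neg, "sa"),
    wm = combine_masks(gt$masks$wm_pos, gt$masks$wm_neg, "wm")))
  wmat <- vapply(masks_all, mask_vec, numeric(E))

  sum_all <- matrix(0, n, E)
  sum_cond <- list(zero_back = matrix(0, n, E), two_back = matrix(0, n, E))
  n_cond <- c(zero_back = 0L, two_back = 0L)
  strengths <- matrix(NA_real_, nrow(behavior), length(masks_all),
                      dimnames = list(NULL, names(masks_all)))
  blocks <- if (keep_blocks) vector("list", B) else NULL

  for (b in seq_len(B)) {
    rows <- block_of[b, ]
    eta <- behavior$state[rows]
    Z <- matrix(stats::rnorm(n * E, 0, config$edge_noise_sd), n, E)
    Z <- Z + rep(mu, each = n)
    Z <- Z + outer(subjects$a_sa + config$state_sd * eta, ev$sa)
    Z <- Z + outer(subjects$a_wm + config$state_sd * eta, ev$wm)
    Z <- Z + outer(subjects$a_sa, ev$common)
    Z <- Z + outer(gsign * subjects$a_sa, ev$differential)
    if (!is.null(vx)) Z <- Z + outer(gx * subjects$a_sa, vx)
    sum_all <- sum_all + Z
    cond_b <- behavior$condition[rows[1]]
    sum_cond[[cond_b]] <- sum_cond[[cond_b]] + Z
    n_cond[cond_b] <- n_cond[cond_b] + 1L
    strengths[rows, ] <- Z %*% wmat
    if (keep_blocks) blocks[[b]] <- Z
  }
  bs <- cbind(behavior,
              stats::setNames(as.data.frame(strengths),
                              paste0("strength_", colnames(strengths))))
  structure(list(
    edges_mean = sum_all / B,
    edges_cond = stats::setNames(
      lapply(names(sum_cond), function(cn) sum_cond[[cn]] / n_cond[[cn]]),
      names(sum_cond)),
    block_strengths = bs, mu = mu, blocks = blocks,
    subject_id = subjects$subject_id, mode = "direct_edges"),
    class = "sim_connectomes")
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Clips negative eigenvalues at zero, rebuilds, and rescales to unit
#' diagonal. Deterministic and adequate for simulation use.
#'
#' @param r Symmetric correlation-like matrix.
#' @param eps Diagonal floor guarding against division by zero.
#' @return A PSD matrix with unit diagonal.
#' @export
nearest_psd_corr <- function(r, eps = 1e-10) {
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= 0) {
    diag(r) <- 1
    return(r)
  }
  v <- pmax(e$values, 0)
  m <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(m), eps))
  m <- m / outer(d, d)
  (m + t(m)) / 2
}

simulate_connectomes_ts <- function(subjects, behavior, gt, config, mu, ev,
                                    gsign, keep_blocks) {
  p <- gt$p
  n <- nrow(subjects)
  ts <- stats::setNames(vector("list", n), subjects$subject_id)
  targets <- list()
  for (s in seq_len(n)) {
    bs <- behavior[behavior$subject_id == subjects$subject_id[s], ,
                   drop = FALSE]
    ts[[s]] <- lapply(split(bs, bs$run_id), function(rb) {
      T_run <- max(rb$offset_tr) + 5L
      vals <- matrix(stats::rnorm(T_run * p), T_run, p)
      for (k in seq_len(nrow(rb))) {
        zv <- mu +
          ev$sa * (subjects$a_sa[s] + config$state_sd * rb$state[k]) +
          ev$wm * (subjects$a_wm[s] + config$state_sd * rb$state[k]) +
          ev$common * subjects$a_sa[s] +
          ev$differential * gsign[s] * subjects$a_sa[s] +
          stats::rnorm(length(mu), 0, config$edge_noise_sd)
        r <- vec_ut(tanh(zv), p)
        diag(r) <- 1
        r <- nearest_psd_corr(r)
        ch <- tryCatch(chol(r + diag(1e-8, p)),
                       error = function(e)
                         stop("PSD projection failed: ",
                              conditionMessage(e)))
        len <- rb$offset_tr[k] - rb$onset_tr[k]
        vals[(rb$onset_tr[k] + 1):rb$offset_tr[k], ] <-
          matrix(stats::rnorm(len * p), len, p) %*% ch
        if (keep_blocks)
          targets[[length(targets) + 1L]] <<- list(
            subject_id = subjects$subject_id[s], run_id = rb$run_id[1],
            block_index = rb$block_index[k], r_target = r)
      }
      parcel_ts(vals, tr = 0.8, subject_id = subjects$subject_id[s],
                run_id = rb$run_id[1])
    })
  }
  structure(list(ts = ts, mu = mu,
                 targets = if (keep_blocks) targets else NULL,
                 mode = "timeseries"),
            class = "sim_connectomes")
}

#' Simulate a complete study
#'
#' Runs the full generator: ground truth, subjects, behavior, connectomes.
#' One global seed is fanned out deterministically into per-stage sub-seeds
#' (ground truth = stage 1, subjects = 2, behavior = 3, connectomes = 4), so
#' stages can be regenerated independently.
#'
#' @param config A `sim_config`.
#' @param seed Global integer seed.
#' @param keep_blocks Keep full per-block edges (see
#'   [simulate_connectomes()]).
#' @return Object of class `sim_study`: `subjects`, `behavior`,
#'   `ground_truth`, `region_labels`, `connectomes`, `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1,
                           keep_blocks = FALSE) {
  labs <- make_region_labels(config$p)
  gt <- make_ground_truth(config$p, config$mask_sizes, config$overlap_spec,
                          config$n_common, config$n_differential,
                          region_labels = labs, hub = config$hub,
                          seed = derive_seed(seed, 1))
  subjects <- simulate_subjects(config$n_per_group, config$n_sites,
                                config$ability_corr,
                                config$group_offsets$ability,
                                config$fd_meanlog, config$fd_sdlog,
                                config$site_assignment,
                                seed = derive_seed(seed, 2))
  behavior <- simulate_behavior(subjects, config,
                                seed = derive_seed(seed, 3))
  conn <- simulate_connectomes(subjects, behavior, gt, config,
                               seed = derive_seed(seed, 4),
                               keep_blocks = keep_blocks)
  structure(list(subjects = subjects, behavior = behavior,
                 ground_truth = gt, region_labels = labs,
                 connectomes = conn, config = config, seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "sim_study: %d parcels, %d subjects (%d/group, %d sites), %d blocks/subject, mode %s\n",
    x$config$p, nrow(x$subjects), x$config$n_per_group, x$config$n_sites,
    nrow(x$behavior) / nrow(x$subjects), x$config$mode))
  invisible(x)
}

#' @rdname condition_strengths
#' @export
condition_strengths.sim_study <- function(strengths, condition,
                                          mask = "sa", zscore = TRUE, ...) {
  bs <- strengths$connectomes$block_strengths
  col <- paste0("strength_", mask)
  if (!col %in% names(bs)) stop("no stored strengths for mask '", mask, "'")
  df <- data.frame(subject_id = bs$subject_id, condition = bs$condition,
                   strength = bs[[col]])
  condition_strengths(df, condition, zscore = zscore)
}

#' Per-subject mean accuracy for one condition
#'
#' @param study A `sim_study`, or any behavior table with `subject_id`,
#'   `condition`, `accuracy`.
#' @param condition `"zero_back"`, `"two_back"`, or `"all"`.
#' @return Data frame `subject_id`, `accuracy`, ordered like the study's
#'   subject table when a `sim_study` is given.
#' @export
mean_accuracy <- function(study, condition = "zero_back") {
  beh <- if (inherits(study, "sim_study")) study$behavior else study
  sel <- if (identical(condition, "all")) beh
         else beh[beh$condition == condition, , drop = FALSE]
  agg <- stats::aggregate(accuracy ~ subject_id, data = sel, FUN = mean)
  if (inherits(study, "sim_study")) {
    agg <- agg[match(study$subjects$subject_id, agg$subject_id), ]
    rownames(agg) <- NULL
  }
  agg
}

#' Write a simulated study to disk
#'
#' Writes subjects, the behavior/block table, masks, region labels, planted
#' edge sets, mean edges (TSV) or per-run time series, plus a JSON manifest
#' with per-file MD5 checksums. Reproducible under (config, seed); a partial
#' write is cleaned up.
#'
#' @param config A `sim_config`.
#' @param seed Global seed.
#' @param dir Output directory (created).
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(config, seed, dir) {
  study <- simulate_study(config, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE), add = TRUE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    f
  }
  files <- c(
    wt(study$subjects, "subjects.tsv"),
    wt(study$behavior[, setdiff(names(study$behavior), "state")],
       "blocks.tsv"),
    wt(study$region_labels, "region_labels.tsv"))
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  for (nm in names(study$ground_truth$masks)) {
    write_mask(study$ground_truth$masks[[nm]],
               file.path(dir, "masks", paste0(nm, ".tsv")))
    files <- c(files, file.path("masks", paste0(nm, ".tsv")))
  }
  files <- c(files,
             wt(study$ground_truth$common, "common_edges.tsv"),
             wt(study$ground_truth$differential, "differential_edges.tsv"))
  if (config$mode == "direct_edges") {
    em <- as.data.frame(study$connectomes$edges_mean)
    names(em) <- sprintf("e%05d", seq_len(ncol(em)) - 1L)
    em <- cbind(subject_id = study$subjects$subject_id, em)
    files <- c(files, wt(em, "edges_mean.tsv"))
  } else {
    dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
    for (sid in names(study$connectomes$ts))
      for (rid in names(study$connectomes$ts[[sid]])) {
        f <- file.path("timeseries", sprintf("%s_%s.tsv", sid, rid))
        write_timeseries(study$connectomes$ts[[sid]][[rid]],
                         file.path(dir, f))
        files <- c(files, f)
      }
  }
  manifest <- list(
    seed = seed, p = config$p, n_per_group = config$n_per_group,
    mode = config$mode,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, files))), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
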