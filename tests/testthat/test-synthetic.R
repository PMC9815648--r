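small_cfg <- function(..., overlap_spec = c("sa_pos:wm_pos" = 4,
                                            "sa_neg:wm_neg" = 3)) {
  sim_config(p = 30, n_per_group = 24, n_sites = 4,
             mask_sizes = c(sa_pos = 20, sa_neg = 15, wm_pos = 30,
                            wm_neg = 25),
             overlap_spec = overlap_spec,
             n_common = 10, n_differential = 8, ...)
}

test_that("ground truth has exact sizes and exact overlaps", {
  cfg <- small_cfg()
  gt <- make_ground_truth(cfg$p, cfg$mask_sizes, cfg$overlap_spec,
                          cfg$n_common, cfg$n_differential,
                          hub = cfg$hub, seed = 9)
  for (nm in names(cfg$mask_sizes)) {
    m <- gt$masks[[nm]]
    expect_identical(m$n_pos + m$n_neg, as.integer(cfg$mask_sizes[[nm]]))
  }
  ov <- network_overlap(gt$masks$sa_pos, gt$masks$wm_pos, c("pos", "pos"))
  expect_identical(ov$x, 4L)
  ov2 <- network_overlap(gt$masks$sa_neg, gt$masks$wm_neg, c("neg", "neg"))
  expect_identical(ov2$x, 3L)
  # unspecified pairs are disjoint
  expect_identical(
    network_overlap(gt$masks$sa_pos, gt$masks$wm_neg, c("pos", "neg"))$x, 0L)
  # common/differential sets are disjoint from every mask and each other
  mask_idx <- unlist(lapply(gt$masks, function(m) which(mask_vec(m) != 0L)))
  expect_length(intersect(gt$common$edge, mask_idx), 0)
  expect_length(intersect(gt$differential$edge, mask_idx), 0)
  expect_length(intersect(gt$common$edge, gt$differential$edge), 0)
  expect_identical(nrow(gt$common), 10L)
  expect_identical(nrow(gt$differential), 8L)
})

test_that("hub concentration forces SA edges to touch the hub region", {
  p <- 40
  labs <- make_region_labels(p)
  regions <- sort(unique(labs$region_name))
  gt <- make_ground_truth(p, c(sa_pos = 30, sa_neg = 20, wm_pos = 40,
                               wm_neg = 30),
                          region_labels = labs,
                          hub = list(region = 1L, frac = 0.5), seed = 2)
  reg <- blockcpm:::region_of_parcel(labs, p)
  touch_frac <- function(m) {
    e <- mask_edges(m)
    mean(reg[e$i + 1L] == regions[1] | reg[e$j + 1L] == regions[1])
  }
  expect_gte(touch_frac(gt$masks$sa_pos), 0.5)
  expect_gte(touch_frac(gt$masks$sa_neg), 0.5)
})

test_that("simulate_study is deterministic under a fixed seed", {
  cfg <- small_cfg()
  s1 <- simulate_study(cfg, seed = 5)
  s2 <- simulate_study(cfg, seed = 5)
  expect_identical(s1$connectomes$edges_mean, s2$connectomes$edges_mean)
  expect_identical(s1$behavior$accuracy, s2$behavior$accuracy)
  expect_identical(s1$ground_truth$masks$sa_pos$w,
                   s2$ground_truth$masks$sa_pos$w)
  s3 <- simulate_study(cfg, seed = 6)
  expect_false(identical(s1$connectomes$edges_mean,
                         s3$connectomes$edges_mean))
})

test_that("at zero noise the planted strengths are exact in ability", {
  # disjoint masks so the SA strength carries no WM-effect contamination
  cfg <- small_cfg(edge_noise_sd = 0, state_sd = 0,
                   overlap_spec = c("sa_pos:wm_pos" = 0,
                                    "sa_neg:wm_neg" = 0))
  st <- simulate_study(cfg, seed = 3)
  bs <- st$connectomes$block_strengths
  one <- bs[bs$block_index == 1 & bs$run_id == "run1", ]
  one <- one[match(st$subjects$subject_id, one$subject_id), ]
  # strength_sa = const + beta * n_edges * a_sa exactly
  expect_equal(cor(one$strength_sa, st$subjects$a_sa), 1, tolerance = 1e-10)
  slope <- coef(lm(one$strength_sa ~ st$subjects$a_sa))[2]
  expect_equal(unname(slope), 0.02 * (20 + 15), tolerance = 1e-8)
  expect_equal(cor(one$strength_wm, st$subjects$a_wm), 1, tolerance = 1e-10)
})

test_that("the differential edge effect flips sign for adults", {
  cfg <- small_cfg(edge_noise_sd = 0, state_sd = 0)
  st <- simulate_study(cfg, seed = 4, keep_blocks = TRUE)
  Z <- st$connectomes$blocks[[1]]
  gt <- st$ground_truth
  d <- gt$differential
  youth <- st$subjects$group == "youth"
  # per planted differential edge: z = mu + beta * sign * (+-1) * a_sa
  for (k in seq_len(2)) {
    e <- d$edge[k]
    sl_y <- coef(lm(Z[youth, e] ~ st$subjects$a_sa[youth]))[2]
    sl_a <- coef(lm(Z[!youth, e] ~ st$subjects$a_sa[!youth]))[2]
    expect_equal(unname(sl_y), 0.02 * d$sign[k], tolerance = 1e-8)
    expect_equal(unname(sl_a), -0.02 * d$sign[k], tolerance = 1e-8)
  }
  # common edges carry the same slope in both groups
  e <- gt$common$edge[1]
  sl_y <- coef(lm(Z[youth, e] ~ st$subjects$a_sa[youth]))[2]
  sl_a <- coef(lm(Z[!youth, e] ~ st$subjects$a_sa[!youth]))[2]
  expect_equal(unname(sl_y), unname(sl_a), tolerance = 1e-8)
})

test_that("subject table has the configured structure", {
  sub <- simulate_subjects(200, n_sites = 5, ability_corr = 0.62, seed = 8)
  expect_identical(nrow(sub), 400L)
  expect_equal(unname(table(sub$group)), c(200L, 200L),
               ignore_attr = TRUE)
  expect_equal(cor(sub$a_sa, sub$a_wm), 0.62, tolerance = 0.12)
  # adults shifted upward on average
  expect_gt(mean(sub$a_sa[sub$group == "adult"]),
            mean(sub$a_sa[sub$group == "youth"]))
  # round robin balances sites within group
  tab <- table(sub$site[sub$group == "youth"])
  expect_identical(length(unique(tab)), 1L)
  expect_error(simulate_subjects(10, ability_corr = 1.2),
               "positive definite")
})

test_that("nearest_psd_corr returns a PSD unit-diagonal matrix", {
  set.seed(11)
  p <- 12
  r <- vec_ut(runif(total_edges(p), -1, 1), p)
  diag(r) <- 1
  m <- nearest_psd_corr(r)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(m), rep(1, p), tolerance = 1e-12)
  # already-PSD input is returned unchanged
  good <- diag(p) * 0.5 + 0.5
  expect_equal(nearest_psd_corr(good), good, tolerance = 1e-12)
})

test_that("timeseries mode yields FC that tracks the target correlations", {
  cfg <- sim_config(p = 10, n_per_group = 2, n_sites = 2,
                    mask_sizes = c(sa_pos = 4, sa_neg = 3, wm_pos = 5,
                                   wm_neg = 4),
                    overlap_spec = NULL, n_common = 2, n_differential = 2,
                    hub = NULL, mode = "timeseries")
  st <- simulate_study(cfg, seed = 12, keep_blocks = TRUE)
  tg <- st$connectomes$targets[[1]]
  ts <- st$connectomes$ts[[tg$subject_id]][[tg$run_id]]
  blk <- st$behavior[st$behavior$subject_id == tg$subject_id &
                     st$behavior$run_id == tg$run_id &
                     st$behavior$block_index == tg$block_index, ]
  em <- block_fc(ts, blk)
  # 30-TR estimate of the target: noisy but strongly correlated
  expect_gt(cor(ut_vec(em$z), atanh(pmin(pmax(ut_vec(tg$r_target), -0.999),
                                         0.999))), 0.6)
})

test_that("generate_dataset writes a validating, checksummed dataset", {
  cfg <- small_cfg()
  dir <- tempfile("ds")
  man <- generate_dataset(cfg, seed = 7, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(all(file.exists(file.path(dir, names(man$files)))))
  # checksums recorded at write time still match the files on disk
  sums <- tools::md5sum(file.path(dir, names(man$files)))
  expect_equal(unname(sums), unlist(man$files, use.names = FALSE))
  rep <- validate_inputs(dir)
  expect_true(rep$pass)
  # masks round-trip with exact sizes
  m <- read_mask(file.path(dir, "masks", "sa_pos.tsv"), p = cfg$p)
  expect_identical(m$n_pos, 20L)
  unlink(dir, recursive = TRUE)
})

test_that("mean_accuracy aggregates by condition in subject order", {
  cfg <- small_cfg()
  st <- simulate_study(cfg, seed = 13)
  acc <- mean_accuracy(st, "zero_back")
  expect_identical(acc$subject_id, st$subjects$subject_id)
  beh1 <- st$behavior[st$behavior$subject_id == acc$subject_id[1] &
                      st$behavior$condition == "zero_back", ]
  expect_equal(acc$accuracy[1], mean(beh1$accuracy), tolerance = 1e-12)
})
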