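test_that("select_edges matches a per-edge cor.test oracle", {
  set.seed(20)
  p <- 12
  E <- total_edges(p)
  n <- 40
  edges <- matrix(rnorm(n * E), n, E)
  edges[, 5] <- edges[, 5] + 2 * seq_len(n) / n
  beh <- seq_len(n) / n + rnorm(n, 0, 0.3)
  m <- select_edges(edges, beh, alpha = 0.05, p = p)
  v <- mask_vec(m)
  for (e in seq_len(E)) {
    ct <- cor.test(edges[, e], beh)
    want <- if (ct$p.value < 0.05) sign(ct$estimate) else 0
    expect_identical(v[e], as.integer(want))
  }
})

test_that("select_edges saturates at alpha = 1 and skips constant edges", {
  set.seed(21)
  p <- 8
  E <- total_edges(p)
  edges <- matrix(rnorm(30 * E), 30, E)
  edges[, 3] <- 1  # constant
  beh <- rnorm(30)
  m <- select_edges(edges, beh, alpha = 1.0000001, p = p)
  expect_identical(m$n_pos + m$n_neg, E - 1L)
  expect_identical(attr(m, "n_skipped"), 1L)
  expect_identical(mask_vec(m)[3], 0L)
  expect_error(select_edges(edges, rep(1, 30), p = p), "constant")
  expect_error(select_edges(edges[1:5, ], beh[1:5], p = p), "10 subjects")
})

test_that("cpm performs leave-one-site-out bookkeeping correctly", {
  set.seed(22)
  p <- 10
  E <- total_edges(p)
  n <- 60
  sites <- rep(c("A", "B", "C"), each = 20)
  signal <- rnorm(n)
  edges <- matrix(rnorm(n * E, 0, 0.5), n, E)
  edges[, 1:6] <- edges[, 1:6] + signal
  fit <- cpm(edges, signal, sites, alpha = 0.01, p = p)
  expect_s3_class(fit, "cpm")
  expect_identical(sort(names(fit$site_models)), c("A", "B", "C"))
  expect_equal(unname(fit$train_n), rep(40L, 3), ignore_attr = TRUE)
  # held-out strengths equal the manual mask product for each site
  for (k in c("A", "B", "C")) {
    ix <- sites == k
    want <- as.numeric(edges[ix, ] %*% mask_vec(fit$site_models[[k]]))
    expect_equal(fit$holdout$strength[ix], want, tolerance = 1e-12)
  }
  # each site model was trained without the held-out site: re-fit oracle
  mA <- select_edges(edges[sites != "A", ], signal[sites != "A"],
                     alpha = 0.01, p = p)
  expect_identical(mask_vec(fit$site_models$A), mask_vec(mA))
  # predict() with the consensus mask reproduces strengths
  expect_equal(predict(fit, edges),
               as.numeric(edges %*% mask_vec(fit$consensus)),
               tolerance = 1e-12)
})

test_that("consensus binarization is inclusive at the threshold", {
  p <- 6
  mk <- function(edges_pos) {
    v <- integer(total_edges(p))
    v[edges_pos] <- 1L
    network_mask(vec_ut(v, p))
  }
  fake <- structure(list(
    site_models = list(s1 = mk(1), s2 = mk(1), s3 = mk(c(1, 2)),
                       s4 = mk(2)),
    binarize_threshold = 0.5, p = p), class = "cpm")
  cons <- consensus_mask(fake)
  v <- mask_vec(cons)
  expect_identical(v[1], 1L)  # 3/4 votes
  expect_identical(v[2], 1L)  # exactly 2/4 = threshold, kept (inclusive)
  expect_identical(sum(v != 0L), 2L)
  strict <- consensus_mask(fake, threshold = 0.51)
  expect_identical(mask_vec(strict)[2], 0L)
})

test_that("consensus votes are signed: opposite signs cancel", {
  p <- 6
  v_pos <- integer(total_edges(p)); v_pos[1] <- 1L
  v_neg <- integer(total_edges(p)); v_neg[1] <- -1L
  fake <- structure(list(
    site_models = list(s1 = network_mask(vec_ut(v_pos, p)),
                       s2 = network_mask(vec_ut(v_neg, p))),
    binarize_threshold = 0.5, p = p), class = "cpm")
  expect_identical(sum(mask_vec(consensus_mask(fake)) != 0L), 0L)
})

test_that("evaluate_prediction matches cor.test and handles sites", {
  set.seed(23)
  s <- rnorm(50)
  b <- s + rnorm(50)
  sites <- rep(c("x", "y"), 25)
  rep_ <- evaluate_prediction(s, b, sites)
  ct <- cor.test(s, b)
  expect_equal(rep_$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rep_$r_p, ct$p.value, tolerance = 1e-12)
  expect_equal(rep_$rho, cor(s, b, method = "spearman"), tolerance = 1e-12)
  expect_identical(nrow(rep_$per_site), 2L)
  expect_error(evaluate_prediction(rep(1, 10), rnorm(10)), "constant")
})

test_that("random_matched_networks matches sizes and bounds p", {
  set.seed(24)
  p <- 14
  v <- integer(total_edges(p))
  v[1:10] <- 1L
  v[11:15] <- -1L
  ref <- network_mask(vec_ut(v, p))
  rm_ <- random_matched_networks(ref, n_random = 25, seed = 1)
  expect_length(rm_$masks, 25)
  for (m in rm_$masks[1:5]) {
    expect_identical(m$n_pos, 10L)
    expect_identical(m$n_neg, 5L)
    # drawn outside the reference
    expect_identical(sum(mask_vec(m) != 0L & mask_vec(ref) != 0L), 0L)
  }
  # an observed effect above every random effect gets the add-one floor
  out <- random_matched_networks(ref, n_random = 50, seed = 2,
                                 effect_fn = function(m) 0, observed = 1)
  expect_equal(out$p, 1 / 51, tolerance = 1e-12)
  out2 <- random_matched_networks(ref, n_random = 50, seed = 2,
                                  effect_fn = function(m) 2, observed = 1)
  expect_equal(out2$p, 1, tolerance = 1e-12)
})
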