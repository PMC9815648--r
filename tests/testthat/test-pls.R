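pls_fixture <- function(n = 60, E = 40, beta = 0.6, seed = 50) {
  set.seed(seed)
  groups <- rep(c("g1", "g2"), each = n)
  beh <- rnorm(2 * n)
  edges <- matrix(rnorm(2 * n * E, 0, 1), 2 * n, E)
  edges[, 1:5] <- edges[, 1:5] + beta * beh
  list(edges = edges, behavior = beh, groups = groups)
}

test_that("build_crossblock rows are within-group correlations", {
  fx <- pls_fixture()
  zs <- blockcpm:::zscore_within_group(fx$edges, fx$behavior, fx$groups)
  R <- build_crossblock(zs$edges, zs$behavior, fx$groups)
  expect_identical(rownames(R), c("g1", "g2"))
  ix <- fx$groups == "g1"
  want <- apply(fx$edges[ix, ], 2, cor, y = fx$behavior[ix])
  expect_equal(unname(R["g1", ]), unname(want), tolerance = 1e-10)
  # constant edges carry zero covariance
  e2 <- fx$edges
  e2[, 7] <- 3
  zs2 <- blockcpm:::zscore_within_group(e2, fx$behavior, fx$groups)
  R2 <- build_crossblock(zs2$edges, zs2$behavior, fx$groups)
  expect_equal(unname(R2[, 7]), c(0, 0))
  expect_error(build_crossblock(fx$edges, rep(1, 120), fx$groups), "constant")
})

test_that("pls_svd satisfies the structural SVD properties", {
  fx <- pls_fixture()
  zs <- blockcpm:::zscore_within_group(fx$edges, fx$behavior, fx$groups)
  R <- build_crossblock(zs$edges, zs$behavior, fx$groups)
  fit <- pls_svd(R)
  expect_equal(crossprod(fit$U), diag(2), tolerance = 1e-10)
  expect_equal(crossprod(fit$V), diag(2), tolerance = 1e-10)
  expect_equal(fit$U %*% diag(fit$s) %*% t(fit$V), t(R), tolerance = 1e-10)
  expect_equal(sum(fit$sigma_frac), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$s) <= 0))
  # deterministic sign convention: largest-|salience| entry is positive
  for (l in 1:2) expect_gt(fit$U[which.max(abs(fit$U[, l])), l], 0)
})

test_that("rank-1 cross-block input gives sigma fractions [1, 0]", {
  v <- rnorm(30)
  R <- rbind(a = 2 * v, b = -1 * v)
  fit <- pls_svd(R)
  expect_equal(fit$sigma_frac, c(1, 0), tolerance = 1e-12)
})

test_that("sigma fractions are invariant to overall scaling", {
  fx <- pls_fixture()
  zs <- blockcpm:::zscore_within_group(fx$edges, fx$behavior, fx$groups)
  R <- build_crossblock(zs$edges, zs$behavior, fx$groups)
  expect_equal(pls_svd(5 * R)$sigma_frac, pls_svd(R)$sigma_frac,
               tolerance = 1e-12)
})

test_that("procrustes_rotation returns an orthogonal aligning rotation", {
  set.seed(51)
  U <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  theta <- 0.4
  rot_true <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Ub <- U %*% rot_true
  rot <- blockcpm:::procrustes_rotation(U, Ub)
  expect_equal(crossprod(rot), diag(2), tolerance = 1e-10)
  expect_equal(Ub %*% rot, U, tolerance = 1e-8)
})

test_that("bpls recovers a strong common signal and is deterministic", {
  fx <- pls_fixture(n = 80, E = 40, beta = 0.8)
  fit <- bpls(fx$edges, fx$behavior, fx$groups, n_perm = 200, n_boot = 200,
              seed = 3)
  expect_s3_class(fit, "bpls")
  expect_lt(fit$perm_p[1], 0.05)
  # the 5 planted edges dominate LV1's reliable edges
  expect_true(all(1:5 %in% fit$sig_edges[[1]]))
  expect_equal(sum(fit$sigma_frac), 1, tolerance = 1e-12)
  expect_identical(nrow(fit$lv_behavior_corr), 4L)
  expect_gt(min(abs(fit$lv_behavior_corr$r[fit$lv_behavior_corr$lv == 1])),
            0.4)
  fit2 <- bpls(fx$edges, fx$behavior, fx$groups, n_perm = 200, n_boot = 200,
               seed = 3)
  expect_equal(fit$boot_ratio, fit2$boot_ratio)
  expect_equal(fit$perm_p, fit2$perm_p)
})

test_that("a group-differential signal loads on LV2 with opposite scores", {
  set.seed(52)
  n <- 100
  E <- 30
  groups <- rep(c("g1", "g2"), each = n)
  beh <- rnorm(2 * n)
  edges <- matrix(rnorm(2 * n * E), 2 * n, E)
  flip <- ifelse(groups == "g1", 1, -1)
  edges[, 1:4] <- edges[, 1:4] + 0.8 * flip * beh
  fit <- bpls(edges, beh, groups, n_perm = 100, n_boot = 0, seed = 4)
  lv1 <- fit$lv_behavior_corr[fit$lv_behavior_corr$lv == 1, ]
  expect_lt(lv1$r[1] * lv1$r[2], 0)  # opposite-signed group correlations
  expect_lt(fit$perm_p[1], 0.05)
})

test_that("balanced_bpls averages over matched subsamples", {
  set.seed(53)
  E <- 25
  beh <- rnorm(90)
  groups <- rep(c("big", "small"), c(60, 30))
  edges <- matrix(rnorm(90 * E), 90, E)
  edges[, 1:3] <- edges[, 1:3] + 0.7 * beh
  out <- balanced_bpls(edges, beh, groups, n_rep = 10, seed = 5)
  expect_s3_class(out, "bpls_balanced")
  expect_identical(out$match_n, 30L)
  expect_identical(dim(out$U), c(25L, 2L))
  expect_equal(sum(out$sigma_frac), 1, tolerance = 1e-6)
  # the planted edges carry the largest averaged |saliences|
  expect_true(all(rank(-abs(out$U[, 1]))[1:3] <= 5))
})
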