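make_ts <- function(T_run = 80, p = 6, seed = 1, tr = 0.8) {
  set.seed(seed)
  parcel_ts(matrix(rnorm(T_run * p), T_run, p), tr = tr, subject_id = "s1",
            run_id = "run1")
}

test_that("block_fc matches a brute-force correlation oracle", {
  ts <- make_ts()
  block <- data.frame(onset_tr = 10L, offset_tr = 40L)
  em <- block_fc(ts, block)
  # oracle: loop over parcel pairs on the 0-based half-open window
  seg <- ts$values[11:40, ]
  p <- ncol(seg)
  want <- matrix(0, p, p)
  for (a in 1:(p - 1)) for (b in (a + 1):p) {
    z <- atanh(min(max(cor(seg[, a], seg[, b]), -(1 - 1e-6)), 1 - 1e-6))
    want[a, b] <- want[b, a] <- z
  }
  expect_equal(em$z, want, tolerance = 1e-12)
  expect_s3_class(em, "edge_matrix")
})

test_that("block_fc honors lag and rejects invalid windows", {
  ts <- make_ts()
  b <- data.frame(onset_tr = 10L, offset_tr = 40L)
  lagged <- block_fc(ts, b, lag_trs = 3L)
  shifted <- block_fc(ts, data.frame(onset_tr = 13L, offset_tr = 43L))
  expect_equal(lagged$z, shifted$z)
  expect_error(block_fc(ts, data.frame(onset_tr = -1L, offset_tr = 20L)),
               "outside")
  expect_error(block_fc(ts, data.frame(onset_tr = 70L, offset_tr = 90L)),
               "outside")
  expect_error(block_fc(ts, data.frame(onset_tr = 10L, offset_tr = 12L)),
               "too short")
})

test_that("block_fc errors on zero-variance parcels", {
  ts <- make_ts()
  ts$values[, 2] <- 1
  expect_error(block_fc(ts, data.frame(onset_tr = 0L, offset_tr = 30L)),
               "zero-variance")
})

test_that("denoise removes confound signal and out-of-band frequencies", {
  T_run <- 200
  tr <- 0.8
  t_s <- (seq_len(T_run) - 1) * tr
  conf <- cbind(drift = seq_len(T_run) / T_run)
  in_band <- sin(2 * pi * 0.05 * t_s)       # inside [0.008, 0.12] Hz
  out_band <- sin(2 * pi * 0.4 * t_s)       # outside the band
  v <- cbind(in_band + out_band + 2 * conf[, 1], rnorm(T_run))
  ts <- parcel_ts(v, tr = tr)
  dn <- denoise(ts, confounds = conf, band = c(0.008, 0.12))
  # the retained series should correlate strongly with the in-band component
  expect_gt(cor(dn$values[, 1], in_band), 0.95)
  # out-of-band power must be annihilated (FFT oracle)
  ft <- abs(fft(dn$values[, 1]))
  freq <- (seq_len(T_run) - 1) / T_run / tr
  freq <- pmin(freq, 1 / tr - freq)
  expect_lt(max(ft[freq > 0.13 | freq < 0.007]), 1e-8)
  # confound direction is orthogonal to residuals before filtering
  dn2 <- denoise(ts, confounds = conf, band = NULL)
  expect_lt(abs(sum(dn2$values[, 1] * (conf[, 1] - mean(conf[, 1])))), 1e-8)
})

test_that("motion_filter applies strict thresholds and profiles", {
  x <- data.frame(fd_mean = c(0.1, 0.2, 0.19, 0.3),
                  fd_max = c(1.0, 1.0, 2.0, 1.0))
  out <- motion_filter(x)
  # fd_mean must be < 0.2 and fd_max < 2.0 (both strict)
  expect_identical(nrow(out$retained), 1L)
  expect_identical(nrow(out$excluded), 3L)
  expect_length(out$log, 3)
  lib <- motion_filter(x, profile = "liberal")
  expect_identical(nrow(lib$retained), 4L)
  x$fd_mean[2] <- NA
  expect_error(motion_filter(x), "missing FD")
  ex <- motion_filter(x, on_missing = "exclude")
  expect_true(any(grepl("missing FD", ex$log)))
})

test_that("network_strength is linear and sign-antisymmetric", {
  set.seed(4)
  p <- 8
  z1 <- vec_ut(rnorm(total_edges(p)), p)
  z2 <- vec_ut(rnorm(total_edges(p)), p)
  v <- integer(total_edges(p))
  v[sample.int(length(v), 10)] <- sample(c(-1L, 1L), 10, replace = TRUE)
  m <- network_mask(vec_ut(v, p))
  s <- function(z) network_strength(edge_matrix(z), m)
  expect_equal(s(z1 + z2), s(z1) + s(z2), tolerance = 1e-12)
  expect_equal(s(2.5 * z1), 2.5 * s(z1), tolerance = 1e-12)
  neg <- network_mask(-m$w)
  expect_equal(network_strength(edge_matrix(z1), neg), -s(z1),
               tolerance = 1e-12)
})

test_that("standardize_connectome standardizes edges and is idempotent", {
  set.seed(5)
  p <- 10
  em <- edge_matrix(vec_ut(rnorm(total_edges(p), 3, 2), p))
  st <- standardize_connectome(em)
  v <- ut_vec(st$z)
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
  st2 <- standardize_connectome(st)
  expect_equal(st2$z, st$z, tolerance = 1e-12)
  const <- edge_matrix(vec_ut(rep(0.3, total_edges(p)), p))
  expect_error(standardize_connectome(const), "constant")
})

test_that("condition_strengths averages per subject and logs drops", {
  df <- data.frame(
    subject_id = c("a", "a", "a", "b", "b", "c"),
    condition = c("zero_back", "zero_back", "two_back",
                  "zero_back", "two_back", "two_back"),
    strength = c(1, 3, 10, 5, 20, 30))
  out <- condition_strengths(df, "zero_back", zscore = FALSE)
  expect_equal(out$score[out$subject_id == "a"], 2)
  expect_equal(out$score[out$subject_id == "b"], 5)
  expect_identical(attr(out, "dropped"), "c")
  z <- condition_strengths(df, "zero_back")
  expect_equal(mean(z$score), 0, tolerance = 1e-12)
  expect_equal(sd(z$score), 1, tolerance = 1e-12)
  expect_error(condition_strengths(df[df$condition == "zero_back", ],
                                   "missing_cond"), "no blocks")
})

test_that("time series and block table TSV round-trip", {
  ts <- make_ts(T_run = 20, p = 3)
  f <- tempfile(fileext = ".tsv")
  write_timeseries(ts, f)
  back <- read_timeseries(f, tr = ts$tr)
  expect_equal(unname(back$values), unname(ts$values), tolerance = 1e-12)
  unlink(f)

  blocks <- default_design()
  blocks$fd_mean <- 0.1
  blocks$fd_max <- 0.5
  f2 <- tempfile(fileext = ".tsv")
  write.table(blocks, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  rb <- read_block_table(f2)
  expect_identical(nrow(rb), 16L)
  blocks$condition[1] <- "three_back"
  write.table(blocks, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_block_table(f2), "unknown condition")
  unlink(f2)
})
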