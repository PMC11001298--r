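mk_z <- function(v) { z <- odor_trace(v, 25); attr(z, "valid") <- TRUE; z }

test_that("GI is the supra-threshold fraction of the odor window", {
  n <- 225
  idx <- trace_window(odor_trace(numeric(n), 25), 2, 8)
  v <- numeric(n); v[idx] <- 3
  expect_equal(compute_GI(mk_z(v)), 1)
  v[idx] <- 1
  expect_equal(compute_GI(mk_z(v)), 0)
  v <- numeric(n); v[idx[seq_len(length(idx) / 2)]] <- 5   # 3 of 6 s above
  expect_equal(compute_GI(mk_z(v)), 0.5)
  v[idx] <- 2                                              # inclusive >=
  expect_equal(compute_GI(mk_z(v)), 1)
  invalid <- mk_z(numeric(n)); attr(invalid, "valid") <- FALSE
  expect_true(is.na(compute_GI(invalid)))
})

test_that("GI slope fit recovers exact linear relations", {
  g <- rep(seq(0.1, 0.8, by = 0.1), each = 3)
  f1 <- fit_GI_slope(g, g)
  expect_equal(f1$slope, 1); expect_equal(f1$r2, 1)
  f2 <- fit_GI_slope(1 - g, g)
  expect_equal(f2$slope, -1)
  expect_error(fit_GI_slope(c(1, 2), c(0.1, 0.2)), "3 trials")
  expect_error(fit_GI_slope(c(1, 2, 3), c(0.1, 0.1, 0.1)), "intermittency values")
})

test_that("encoding ANOVA separates groups and matches a permutation oracle", {
  # identical group distributions: clearly not an encoder
  set.seed(10)
  gi0 <- rep(c(0.3, 0.35, 0.4, 0.45), times = 3)
  gam <- rep(c(0.2, 0.5, 0.8), each = 4)
  a0 <- encoding_anova(gi0, gam)
  expect_gt(a0$p, 0.5)
  expect_false(a0$is_encoder)
  # group means separated by >> within-group SD: encoder at p < 0.001
  gi1 <- rep(c(0.1, 0.4, 0.7), each = 60) + rnorm(180, 0, 0.02)
  a1 <- encoding_anova(gi1, rep(c(0.2, 0.5, 0.8), each = 60))
  expect_true(a1$is_encoder)
  # out-of-band trials are excluded; empty groups error
  expect_error(encoding_anova(gi0, rep(c(0.2, 0.5, 0.35), each = 4)), "empty")

  # permutation oracle on a small instance (1e5 draws, direct F statistic)
  gi <- c(0.2, 0.25, 0.22, 0.3, 0.35, 0.3, 0.4, 0.28, 0.5, 0.45, 0.55, 0.38)
  an <- encoding_anova(gi, gam)
  grp <- rep(1:3, each = 4)
  f_direct <- function(y, g) {
    m <- tapply(y, g, mean); n <- tapply(y, g, length)
    ssb <- sum(n * (m - mean(y))^2)
    ssw <- sum((y - m[g])^2)
    (ssb / 2) / (ssw / (length(y) - 3))
  }
  expect_equal(f_direct(gi, grp), an$F, tolerance = 1e-10)
  set.seed(42)
  perm <- vapply(seq_len(1e5), function(i) f_direct(sample(gi), grp), numeric(1))
  p_perm <- mean(perm >= an$F - 1e-12)
  expect_lt(abs(p_perm - an$p), 0.002)   # Monte-Carlo + F-approximation error
})

test_that("ANOVA F matches the textbook decomposition on a 2x3 example", {
  gi <- c(1, 2, 4, 6)                      # two groups of two
  gam <- c(0.2, 0.2, 0.5, 0.5)
  an <- encoding_anova(gi, gam, groups = c(0.2, 0.5))
  # hand computation: means 1.5 / 5, grand 3.25; SSB = 12.25; SSW = 2.5
  expect_equal(an$F, (12.25 / 1) / (2.5 / 2))
})

test_that("cross-correlation conventions: self, imposed delay, lag-0 equality", {
  set.seed(1)
  ref <- odor_trace(cumsum(rnorm(225)), 25)
  self <- xcorr_shuffled(ref, ref, seed = 2)
  expect_equal(self$peak_lag, 0)
  expect_gt(self$peak_r, 0.9)
  delayed <- odor_trace(c(rep(0, 4), ref$values[1:221]), 25)
  xc <- xcorr_shuffled(delayed, ref, seed = 2)
  expect_equal(xc$peak_lag, 0.160)        # rate lags reference: positive lag
  a <- rnorm(225); b <- rnorm(225)
  x2 <- xcorr_shuffled(odor_trace(a, 25), odor_trace(b, 25), seed = 3)
  expect_lt(abs(x2$raw[x2$lags == 0] - stats::cor(a, b)), 1e-10)
  lag_grid <- x2$lags
  expect_equal(lag_grid, -rev(lag_grid))  # symmetric about zero
  dead <- xcorr_shuffled(odor_trace(rep(1, 225), 25), ref, seed = 1)
  expect_false(dead$valid)
})

test_that("shuffle-corrected xcorr of i.i.d. rates is centred on zero", {
  n <- 225
  corr0 <- vapply(1:30, function(k) {
    set.seed(k)
    x <- odor_trace(rnorm(n), 25)
    r <- odor_trace(rnorm(n), 25)
    xc <- xcorr_shuffled(x, r, seed = 100 + k)
    mean(xc$corrected)
  }, numeric(1))
  sem <- stats::sd(corr0) / sqrt(length(corr0))
  expect_lte(abs(mean(corr0)), 3 * sem + 1e-3)
  # each fixed-lag raw coefficient is within 3/sqrt(N) for white noise
  set.seed(7)
  x <- rnorm(n); r <- rnorm(n)
  xc <- xcorr_shuffled(odor_trace(x, 25), odor_trace(r, 25), seed = 8)
  expect_true(all(abs(xc$raw) <= 3 / sqrt(n - 12) + 0.05))
})

test_that("spatial maps report coordinate correlations and flag degeneracy", {
  ap <- seq(10, 250, length.out = 12)
  ml <- seq(5, 120, length.out = 12)
  scalar <- matrix(rep(2 * ap + 1, 3), 3, 12, byrow = TRUE)
  sm <- spatiotemporal_map(scalar, ap, ml)
  expect_equal(sm$mean_r_ap, 1)
  const <- matrix(1, 3, 12)
  sm0 <- spatiotemporal_map(const, ap, ml)
  expect_true(all(is.na(sm0$per_trial$r_ap)))
  expect_true(is.nan(sm0$mean_r_ap) || is.na(sm0$mean_r_ap))
})

test_that("planted posterior-lateral gain gradient appears in amplitude maps", {
  # whiff-driven units on a sustained high-duty stimulus, so every unit is
  # active within its first-sniff window and amplitude tracks the planted gain
  cfg <- generator_config(seed = 9)
  gl <- gen_glomerulus_population(40, 0, cfg)
  ses <- gen_session(cfg, glomeruli = gl, trial_gammas = rep(0.8, 10),
                     kind = "binary")
  res <- process_session(ses)
  sm <- spatiotemporal_map(res$amplitude_matrix,
                           gl$ap_coord, gl$ml_coord)
  expect_gt(sm$mean_r_ap, 0)
  expect_gt(sm$mean_r_ml, 0)
  ma <- colMeans(res$amplitude_matrix, na.rm = TRUE)
  expect_gt(stats::cor(ma, gl$gain), 0.3)
})

test_that("whiff-driven planted units have GI increasing with duty cycle", {
  cfg <- generator_config(seed = 2)
  gl <- gen_glomerulus_population(1, 0, cfg)
  sn <- gen_sniff_trace(4, cfg)
  ev <- detect_sniffs(sn$trace)
  gis <- vapply(c(20, 80), function(d) {
    out <- gen_fluorescence(gl[1, ], gen_square_wave(5, d, cfg), sn, cfg)
    compute_GI(preprocess_trace(out$trace, ev)$z)
  }, numeric(1))
  expect_gt(gis[2], gis[1])
})
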