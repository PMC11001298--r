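test_that("dF/F conversion matches its defining formula", {
  const <- odor_trace(rep(100, 225), 25)
  expect_true(all(compute_dff(const)$values == 0))
  v <- rep(100, 225); v[60:80] <- 150
  expect_equal(max(compute_dff(odor_trace(v, 25))$values), 0.5)
  set.seed(5)
  raw <- odor_trace(100 + cumsum(rnorm(225)), 25)
  f0 <- mean(raw$values[trace_window(raw, 1.9, 2)])
  expect_equal(compute_dff(raw)$values, (raw$values - f0) / f0)
  expect_error(compute_dff(odor_trace(rep(-5, 225), 25)), "F0")
})

test_that("band filter passes 1 Hz, rejects DC and 12 Hz, guards short input", {
  tt <- (0:2249) / 25           # 90 s probe, long enough to read gains off
  mid <- 500:1750
  dc <- bandpass(odor_trace(rep(7, 2250), 25))
  expect_lt(max(abs(dc$values)), 1e-6)
  s1 <- bandpass(odor_trace(sin(2 * pi * tt), 25))
  expect_lt(abs(max(abs(s1$values[mid])) - 1), 0.05)
  s12 <- bandpass(odor_trace(sin(2 * pi * 12 * tt), 25))
  expect_lt(max(abs(s12$values[mid])), 0.1)
  expect_error(bandpass(odor_trace(rnorm(10), 25)), "too short")
  expect_error(bandpass(odor_trace(rnorm(225), 25), high = 13), "Nyquist")
})

test_that("bleach correction removes polynomial drift but keeps the response", {
  tt <- (0:224) / 25
  quad <- odor_trace(0.3 - 0.05 * tt + 0.01 * tt^2, 25)
  expect_lt(max(abs(bleach_correct(quad)$values)), 1e-10)
  lin <- odor_trace(2 + 0.5 * tt, 25)
  expect_lt(max(abs(bleach_correct(lin)$values)), 1e-10)
  # quadratic plus odor-window boxcar: the boxcar survives untouched
  box <- as.numeric(tt >= 3 & tt < 6) * 0.4
  mix <- odor_trace(0.3 - 0.05 * tt + 0.01 * tt^2 + box, 25)
  expect_equal(bleach_correct(mix)$values, box, tolerance = 1e-10)
  expect_error(bleach_correct(odor_trace(1:5, 25), c(0, 0.04), c(0.16, 0.2)),
               "3 samples")
})

test_that("deconvolution is the exact inverse of the kernel", {
  set.seed(1)
  x <- pmax(0, rnorm(225))
  y <- convolve_kernel(x, 0.150, 25)
  expect_equal(deconvolve(y, 0.150, 25), x, tolerance = 1e-12)
  expect_equal(convolve_kernel(deconvolve(y, 0.150, 25), 0.150, 25), y,
               tolerance = 1e-10)
  # constant input is a fixed point (unit DC gain)
  expect_equal(deconvolve(rep(2, 50), 0.150, 25), rep(2, 50))
  # a kernel-convolved impulse deconvolves back to a single dominant sample
  imp <- numeric(50); imp[10] <- 1
  r <- deconvolve(convolve_kernel(imp, 0.150, 25), 0.150, 25)
  expect_equal(which.max(abs(r)), 10L)
  expect_lt(max(abs(r[-10])), 1e-10)
})

test_that("z-scoring matches the formula and flags dead baselines", {
  set.seed(6)
  x <- odor_trace(rnorm(225, 3, 2), 25)
  z <- zscore_response(x)
  idx <- trace_window(x, 0, 2)
  expect_equal(z$values,
               (x$values - mean(x$values[idx])) / stats::sd(x$values[idx]))
  # affine invariance with matching baseline
  x2 <- x; x2$values <- 5 * x$values + 3
  expect_equal(zscore_response(x2)$values, z$values, tolerance = 1e-10)
  dead <- zscore_response(odor_trace(rep(1, 225), 25))
  expect_false(attr(dead, "valid"))
  expect_true(all(is.na(dead$values)))
})

test_that("first-sniff amplitude and T75 on an analytic ramp", {
  # one sniff at odor onset; z ramps 0 -> 4 over the 1 s response window
  ev <- sniff_events(onsets = 2, peaks = 2.2)
  v <- numeric(225)
  widx <- trace_window(odor_trace(v, 25), 2, 3)
  v[widx] <- seq(0, 4, length.out = length(widx))
  z <- odor_trace(v, 25); attr(z, "valid") <- TRUE
  fr <- first_sniff_response(z, ev)
  expect_equal(fr$amplitude, 4)
  # 75% of a linear ramp is reached 75% of the way through the window
  expect_equal(fr$t75, 0.75 * (length(widx) - 1) / 25, tolerance = 0.05)
  flat <- odor_trace(numeric(225), 25)
  fr_flat <- first_sniff_response(flat, ev)
  expect_equal(fr_flat$amplitude, 0)
  expect_false(fr_flat$valid)
  expect_true(is.na(fr_flat$t75))
  no_sniff <- sniff_events(onsets = 0.5, peaks = 0.7)
  expect_false(first_sniff_response(z, no_sniff)$valid)
})

test_that("responder rule is strict at both thresholds", {
  amp <- matrix(0, 64, 3)
  amp[1:7, 1] <- 5      # 7/64 = 0.109  -> kept
  amp[1:6, 2] <- 5      # 6/64 = 0.094  -> excluded
  amp[1:64, 3] <- 2.0   # amplitude exactly 2 never counts (strict >)
  dr <- detect_responders(amp)
  expect_identical(unname(dr$responder), c(TRUE, FALSE, FALSE))
})

test_that("T75 tracks the planted response latency (rank correlation)", {
  cfg <- generator_config(seed = 4)
  gl <- gen_glomerulus_population(1, 0, cfg)
  stim <- gen_square_wave(5, 80, cfg)   # odor present from the first sniff on
  sn <- gen_sniff_trace(3, cfg, jitter = 0)
  ev <- detect_sniffs(sn$trace)
  lat <- seq(0.04, 0.28, by = 0.04)
  for (rep_i in 1:3) {
    t75 <- vapply(seq_along(lat), function(i) {
      g <- gl[1, ]; g$latency_s <- lat[i]
      out <- gen_fluorescence(g, stim, sn, cfg, noise_sd = 0.1,
                              seed = 900 + 100 * rep_i + i)
      preprocess_trace(out$trace, ev)$t75
    }, numeric(1))
    ok <- is.finite(t75)
    expect_gt(stats::cor(lat[ok], t75[ok], method = "spearman"), 0.5)
  }
})

test_that("full preprocessing on noise-free generator output recovers the planted rate", {
  cfg <- generator_config(seed = 2)
  gl <- gen_glomerulus_population(6, 0.5, cfg)
  stim <- gen_plume_trace(0.5, cfg, seed = 31)
  sn <- gen_sniff_trace(4, cfg)
  ev <- detect_sniffs(sn$trace)
  for (j in c(1, 4)) {
    out <- gen_fluorescence(gl[j, ], stim, sn, cfg, noise_sd = 0)
    pp <- preprocess_trace(out$trace, ev)
    expect_gte(stats::cor(pp$rate$values, out$rate), 0.99)
  }
})

test_that("the planted responder set is recovered exactly without noise", {
  cfg <- generator_config(seed = 14)
  gl <- gen_glomerulus_population(10, 0.5, cfg)
  gl$responder[c(3, 8)] <- FALSE
  ses <- gen_session(cfg, glomeruli = gl,
                     trial_gammas = rep(c(0.3, 0.6), each = 5))
  # noise-free variant: rebuild fluorescence without noise
  for (i in seq_along(ses$trials)) {
    tr <- ses$trials[[i]]
    for (j in seq_len(nrow(gl))) {
      out <- gen_fluorescence(gl[j, ], tr$stimulus, tr$sniff, cfg, noise_sd = 0)
      ses$trials[[i]]$fluor[, j] <- out$trace$values
    }
  }
  res <- process_session(ses)
  expect_identical(unname(res$responders$responder), gl$responder)
})
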