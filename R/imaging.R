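#' @importFrom signal butter
NULL

# cache of Butterworth designs keyed by (rate, low, high, order)
.filter_cache <- new.env(parent = emptyenv())

butter_design <- function(rate, low, high, order) {
  key <- paste(rate, low, high, order, sep = "_")
  if (is.null(.filter_cache[[key]])) {
    ny <- rate / 2
    if (high >= ny) stop("upper band edge must be below Nyquist")
    .filter_cache[[key]] <- signal::butter(order, c(low, high) / ny, type = "pass")
  }
  .filter_cache[[key]]
}

# Zero-phase filtering with odd-reflection padding and steady-state initial
# conditions (so constant inputs produce no edge transients), applied forward
# then backward. The effective magnitude response is the square of the
# single-pass filter.
filtfilt_ss <- function(b, a, x, padlen = NULL) {
  n <- max(length(a), length(b))
  min_pad <- 3L * (n - 1L)
  if (length(x) <= min_pad)
    stop(sprintf("trace too short for zero-phase filtering (need > %d samples)",
                 min_pad))
  padlen <- max(min_pad, min(length(x) - 1L, padlen %||% min_pad))
  h1 <- sum(b) / sum(a)
  run <- function(x) as.numeric(
    signal::filter(b, a, x, init.x = rep(x[1], n - 1),
                   init.y = rep(x[1] * h1, n - 1)))
  nx <- length(x)
  xe <- c(2 * x[1] - x[(padlen + 1):2], x,
          2 * x[nx] - x[(nx - 1):(nx - padlen)])
  y <- run(xe)
  y <- rev(run(rev(y)))
  y[(padlen + 1):(padlen + nx)]
}

# vector-level band filter used by both the preprocessing pipeline and the
# synthetic generator's measurement-band ground truth; reflection padding is
# sized to ~2.5 times the slowest filter time constant (1 / (2 pi low)) so
# the long-memory high-pass sees a plausible continuation at both ends
bandpass_values <- function(x, rate, low = 0.075, high = 10, order = 4) {
  flt <- butter_design(rate, low, high, order)
  filtfilt_ss(flt$b, flt$a, x,
              padlen = ceiling(2.5 * rate / (2 * pi * low)))
}

#' Band filter a fluorescence trace (zero-phase Butterworth)
#'
#' Fourth-order Butterworth band filter, 0.075-10 Hz by default, applied
#' forward and backward so response latencies are not biased by filter delay
#' (the effective order is therefore doubled). Edge transients are controlled
#' with odd-reflection padding and steady-state initial conditions.
#'
#' @param x an [odor_trace()] (dF/F at the imaging rate).
#' @param low,high band edges in Hz; `high` must lie below Nyquist.
#' @param order filter order of the single pass.
#' @return the filtered [odor_trace()].
#' @export
bandpass <- function(x, low = 0.075, high = 10, order = 4) {
  stopifnot(inherits(x, "odor_trace"))
  x$values <- bandpass_values(x$values, x$rate, low, high, order)
  x
}

#' Convert raw fluorescence to dF/F
#'
#' Baseline `F0` is the mean fluorescence over the 100 ms window ending at
#' odor onset; the result is `(F - F0) / F0`.
#'
#' @param raw an [odor_trace()] of raw fluorescence.
#' @param odor_onset odor onset time (s).
#' @param baseline_s baseline window length before onset (s).
#' @return an [odor_trace()] of dF/F.
#' @export
compute_dff <- function(raw, odor_onset = 2, baseline_s = 0.1) {
  stopifnot(inherits(raw, "odor_trace"))
  idx <- trace_window(raw, odor_onset - baseline_s, odor_onset)
  if (length(idx) == 0L) stop("no pre-odor samples for the dF/F baseline")
  f0 <- mean(raw$values[idx])
  if (!is.finite(f0) || f0 <= 0) stop("invalid dF/F baseline (F0 <= 0)")
  raw$values <- (raw$values - f0) / f0
  raw
}

#' Photobleaching correction by quadratic baseline fit
#'
#' Fits a second-degree polynomial to the trace over the pre- and post-odor
#' windows only and subtracts the fit from the whole trace, removing slow
#' bleaching drift without touching the odor-evoked response.
#'
#' @param x an [odor_trace()].
#' @param pre_window,post_window half-open time windows `c(from, to)` (s)
#'   used for the fit.
#' @return the drift-corrected [odor_trace()].
#' @export
bleach_correct <- function(x, pre_window = c(0, 2), post_window = c(8, 9)) {
  stopifnot(inherits(x, "odor_trace"))
  x$values <- bleach_correct_values(x$values, x$rate, x$t0,
                                    pre_window, post_window)
  x
}

bleach_correct_values <- function(v, rate, t0, pre_window, post_window) {
  tt <- t0 + (seq_along(v) - 1) / rate
  idx <- which((tt >= pre_window[1] - 1e-9 & tt < pre_window[2] - 1e-9) |
                 (tt >= post_window[1] - 1e-9 & tt < post_window[2] - 1e-9))
  if (length(idx) < 3L) stop("need at least 3 samples in the fit windows")
  fit <- stats::lm.fit(cbind(1, tt[idx], tt[idx]^2), v[idx])
  v - drop(cbind(1, tt, tt^2) %*% fit$coefficients)
}

# discrete first-order kernel parameters: y_t = a y_{t-1} + (1 - a) r_t,
# a = exp(-dt / tau); unit gain at DC so constant rates map to themselves
kernel_coef <- function(tau_s, rate) exp(-1 / (rate * tau_s))

#' Convolve a rate with the causal exponential indicator kernel
#'
#' Discrete first-order low-pass `y_t = a y_{t-1} + (1 - a) r_t` with
#' `a = exp(-dt/tau)`: the exact discrete counterpart of convolution with
#' `exp(-t/tau)/tau`, normalized to unit steady-state gain. The filter state
#' is initialized at steady state for the first sample, so constant rates map
#' to themselves. This is the forward model that [deconvolve()] inverts
#' exactly.
#'
#' @param x numeric vector or [odor_trace()] of rates.
#' @param tau_s kernel time constant (s).
#' @param rate sampling rate (Hz); taken from the trace if one is given.
#' @return same type as `x`.
#' @export
convolve_kernel <- function(x, tau_s = 0.150, rate = NULL) {
  if (inherits(x, "odor_trace")) {
    x$values <- convolve_kernel(x$values, tau_s, x$rate)
    return(x)
  }
  stopifnot(!is.null(rate), tau_s > 0)
  a <- kernel_coef(tau_s, rate)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive", init = x[1]))
}

#' Deconvolve a fluorescence trace with the exponential kernel
#'
#' Exact discrete inversion of [convolve_kernel()]:
#' `r_t = (c_t - a c_{t-1}) / (1 - a)`, with `r_1 = c_1` from the
#' steady-state initialization of the forward kernel (so constant traces are
#' fixed points). No non-negativity constraint or sparsity prior is applied.
#' Convolving the output reproduces the input to numerical precision.
#'
#' @param x numeric vector or [odor_trace()] of (filtered, drift-corrected)
#'   dF/F.
#' @param tau_s kernel time constant (s), default 0.150.
#' @param rate sampling rate (Hz); taken from the trace if one is given.
#' @return same type as `x`: the estimated rate trace.
#' @export
deconvolve <- function(x, tau_s = 0.150, rate = NULL) {
  if (inherits(x, "odor_trace")) {
    x$values <- deconvolve(x$values, tau_s, x$rate)
    return(x)
  }
  stopifnot(!is.null(rate), tau_s > 0)
  a <- kernel_coef(tau_s, rate)
  n <- length(x)
  r <- numeric(n)
  r[1] <- x[1]
  if (n > 1) r[2:n] <- (x[2:n] - a * x[1:(n - 1)]) / (1 - a)
  r
}

#' Z-score a rate trace against its pre-odor baseline
#'
#' `(rate - mu_pre) / sigma_pre`, with mean and SD taken over the
#' `baseline_s` seconds preceding odor onset. A zero-variance baseline (dead
#' trace) makes the z-score undefined; the trace is returned all-`NA` with
#' attribute `valid = FALSE` so downstream statistics can exclude the
#' glomerulus-trial rather than propagate infinities.
#'
#' @param x an [odor_trace()] of deconvolved rates.
#' @param odor_onset odor onset time (s).
#' @param baseline_s baseline window length (s), default 2.
#' @return the z-scored [odor_trace()] with attribute `valid`.
#' @export
zscore_response <- function(x, odor_onset = 2, baseline_s = 2) {
  stopifnot(inherits(x, "odor_trace"))
  idx <- trace_window(x, odor_onset - baseline_s, odor_onset)
  if (length(idx) < 2L) stop("need >= 2 pre-odor samples for z-scoring")
  mu <- mean(x$values[idx])
  sdv <- stats::sd(x$values[idx])
  # dead-trace guard is relative to the trace's own scale so that numerically
  # flat baselines are flagged, not divided by
  dead <- !is.finite(sdv) ||
    sdv <= 1e-9 * max(abs(range(x$values)), .Machine$double.eps)
  if (dead) {
    x$values <- rep(NA_real_, length(x$values))
    attr(x, "valid") <- FALSE
    return(x)
  }
  x$values <- (x$values - mu) / sdv
  attr(x, "valid") <- TRUE
  x
}

#' Response amplitude and T75 of the first odor sniff
#'
#' Within a response window starting at the first sniff onset at or after
#' odor onset and ending at the next sniff onset (capped at
#' `max_window_s`), the amplitude is the trough-to-peak range of the z-scored
#' trace. T75 is the time from the sniff onset to the first sample at which
#' the response reaches trough + 75% of the amplitude; it is measured on the
#' dF/F-scale trace when one is supplied (`dff`), otherwise on the z trace.
#'
#' @param z z-scored [odor_trace()].
#' @param events a [sniff_events()].
#' @param odor_onset odor onset time (s).
#' @param dff optional dF/F [odor_trace()] on which T75 is measured.
#' @param max_window_s cap on the response window length (s).
#' @return list with `amplitude` (z units), `t75` (s), `onset` (s of the
#'   first odor sniff), `valid`.
#' @export
first_sniff_response <- function(z, events, odor_onset = 2, dff = NULL,
                                 max_window_s = 1) {
  stopifnot(inherits(z, "odor_trace"), inherits(events, "sniff_events"))
  flagged <- list(amplitude = NA_real_, t75 = NA_real_, onset = NA_real_,
                  valid = FALSE)
  if (!isTRUE(attr(z, "valid") %||% TRUE)) return(flagged)
  k <- which(events$onsets >= odor_onset - 1e-9)
  if (length(k) == 0L) return(flagged)
  k <- k[1]
  w0 <- events$onsets[k]
  w1 <- if (k < length(events$onsets)) min(events$onsets[k + 1], w0 + max_window_s)
        else w0 + max_window_s
  idx <- trace_window(z, w0, w1)
  if (length(idx) < 2L) return(flagged)
  amp <- max(z$values[idx]) - min(z$values[idx])

  s <- if (is.null(dff)) z else dff
  sidx <- trace_window(s, w0, w1)
  sv <- s$values[sidx]
  t75 <- NA_real_
  if (length(sv) >= 2L && (max(sv) - min(sv)) > 0) {
    thr <- min(sv) + 0.75 * (max(sv) - min(sv))
    hit <- which(sv >= thr - 1e-12)[1]
    t75 <- trace_times(s)[sidx[hit]] - w0
  }
  list(amplitude = amp, t75 = t75, onset = w0,
       valid = is.finite(amp) && amp > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identify responding glomeruli across a session
#'
#' A glomerulus responds on a trial when its first-sniff amplitude strictly
#' exceeds a z-score of 2; it is kept when the fraction of responding trials
#' strictly exceeds `min_frac` (10%, about 6 of 64 trials). Trials with
#' undefined amplitude (`NA`) count as non-responding.
#'
#' @param amplitudes matrix of first-sniff amplitudes, trials x glomeruli.
#' @param z_threshold trial-level amplitude threshold (strict `>`).
#' @param min_frac session-level responding-trial fraction (strict `>`).
#' @return list with `responder` (logical per glomerulus), `frac` (responding
#'   trial fraction), `trial_responses` (logical matrix).
#' @export
detect_responders <- function(amplitudes, z_threshold = 2, min_frac = 0.10) {
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) < 1L) stop("need at least one trial")
  resp <- !is.na(amplitudes) & amplitudes > z_threshold
  frac <- colMeans(resp)
  list(responder = frac > min_frac, frac = frac, trial_responses = resp)
}

#' Full preprocessing of one raw fluorescence trace
#'
#' Pipeline: dF/F conversion, zero-phase Butterworth band filtering,
#' quadratic bleach correction on the pre/post windows, exponential-kernel
#' deconvolution, baseline z-scoring, and first-sniff amplitude/T75
#' extraction.
#'
#' @param raw raw fluorescence [odor_trace()] at the imaging rate.
#' @param events a [sniff_events()] for the same trial.
#' @param odor_onset,odor_dur odor window (s).
#' @param tau_s deconvolution time constant (s).
#' @param use_bandpass apply the band filter (the standard pipeline does).
#' @return list with `dff`, `rate`, `z` (traces), `amplitude`, `t75`,
#'   `valid`.
#' @export
preprocess_trace <- function(raw, events, odor_onset = 2, odor_dur = 6,
                             tau_s = 0.150, use_bandpass = TRUE) {
  dff <- compute_dff(raw, odor_onset)
  x <- if (use_bandpass) bandpass(dff) else dff
  x <- bleach_correct(x, pre_window = c(raw$t0, odor_onset),
                      post_window = c(odor_onset + odor_dur,
                                      raw$t0 + length(raw$values) / raw$rate))
  rate <- deconvolve(x, tau_s)
  z <- zscore_response(rate, odor_onset)
  fr <- first_sniff_response(z, events, odor_onset, dff = x)
  list(dff = dff, rate = rate, z = z,
       amplitude = fr$amplitude, t75 = fr$t75, valid = fr$valid)
}
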