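#' Glomerular intermittency (GI)
#'
#' The fraction of odor-window samples at which the z-scored response trace
#' meets or exceeds the threshold (`z >= 2`), mirroring the stimulus
#' intermittency statistic on the neural side.
#'
#' @param z z-scored [odor_trace()].
#' @param odor_window half-open window `c(from, to)` (s).
#' @param threshold z threshold (inclusive `>=`).
#' @return GI in `[0, 1]`, or `NA` for an invalid (flagged) trace.
#' @export
compute_GI <- function(z, odor_window = c(2, 8), threshold = 2) {
  stopifnot(inherits(z, "odor_trace"))
  if (!isTRUE(attr(z, "valid") %||% TRUE)) return(NA_real_)
  idx <- trace_window(z, odor_window[1], odor_window[2])
  if (length(idx) == 0L) stop("empty odor window")
  mean(z$values[idx] >= threshold)
}

#' GI-vs-intermittency slope of one glomerulus
#'
#' Ordinary least squares of GI on odor intermittency across trials. The
#' slope's sign separates the two glomerular phenotypes (whiff-driven
#' positive, blank-driven negative).
#'
#' @param gi per-trial GI values.
#' @param gamma per-trial odor intermittency values.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @export
fit_GI_slope <- function(gi, gamma) {
  ok <- is.finite(gi) & is.finite(gamma)
  gi <- gi[ok]; gamma <- gamma[ok]
  if (length(gi) < 3L || length(unique(gamma)) < 2L)
    stop("need >= 3 trials spanning >= 2 intermittency values")
  fit <- stats::lm(gi ~ gamma)
  ss_tot <- sum((gi - mean(gi))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, n = length(gi))
}

# assign values to the nearest target bin within +/- tol; NA when out of band
bin_gamma <- function(gamma, targets, tol = 0.05) {
  vapply(gamma, function(g) {
    d <- abs(g - targets)
    j <- which.min(d)
    if (d[j] <= tol + 1e-9) targets[j] else NA_real_
  }, numeric(1))
}

#' Intermittency-encoding ANOVA for one glomerulus
#'
#' One-way fixed-effects ANOVA of GI across intermittency groups (defaults
#' 0.2, 0.5, 0.8; trials binned to the nearest group within +/- 0.05,
#' out-of-band trials excluded). A glomerulus encodes intermittency when the
#' main effect has `p < 0.001`.
#'
#' @param gi per-trial GI values.
#' @param gamma per-trial odor intermittency values.
#' @param groups group centers.
#' @param tol binning half-width.
#' @param alpha encoder criterion on the p-value.
#' @return list with `F`, `p`, `is_encoder`, `n_per_group`.
#' @export
encoding_anova <- function(gi, gamma, groups = c(0.2, 0.5, 0.8), tol = 0.05,
                           alpha = 0.001) {
  grp <- bin_gamma(gamma, groups, tol)
  ok <- is.finite(gi) & !is.na(grp)
  gi <- gi[ok]; grp <- factor(grp[ok], levels = groups)
  counts <- table(grp)
  if (any(counts == 0)) stop("empty intermittency group in encoding ANOVA")
  if (sum(counts >= 2) < 2L) stop("need >= 2 groups with >= 2 trials")
  fit <- stats::aov(gi ~ grp)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  list(F = Fv, p = p, is_encoder = is.finite(p) && p < alpha,
       n_per_group = as.integer(counts))
}

# Pearson correlation of x delayed by `lag` samples relative to ref
# (positive lag: x lags the reference)
cor_at_lag <- function(x, ref, lag) {
  n <- length(x)
  if (lag >= 0) {
    a <- x[(1 + lag):n]; b <- ref[1:(n - lag)]
  } else {
    a <- x[1:(n + lag)]; b <- ref[(1 - lag):n]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Shuffle-corrected cross-correlation of a rate trace with a reference
#'
#' Pearson-normalized cross-correlation on a lag grid tied to the imaging
#' clock (40 ms steps over +/- 500 ms at 25 Hz; positive lags mean the rate
#' lags the reference). The shuffle control destroys temporal structure while
#' preserving the marginal: the rate samples are randomly permuted
#' (`n_shuffle` iterations), the full lag curve computed for each, and the
#' per-lag shuffle mean subtracted from the raw curve. The peak is the
#' maximum of the corrected curve.
#'
#' @param rate [odor_trace()] of deconvolved rates (imaging clock).
#' @param reference [odor_trace()] of the reference signal (stimulus
#'   concentration or sniff pressure); downsampled to the rate's clock by box
#'   averaging if needed.
#' @param n_shuffle number of shuffle iterations.
#' @param max_lag_s lag range (s).
#' @param window optional half-open analysis window (s).
#' @param seed RNG seed for the permutations.
#' @return list of class `xcorr_result`: `lags` (s), `raw`, `shuffle_mean`,
#'   `corrected`, `peak_r`, `peak_lag`, `valid`.
#' @export
xcorr_shuffled <- function(rate, reference, n_shuffle = 10, max_lag_s = 0.5,
                           window = NULL, seed = 1L) {
  stopifnot(inherits(rate, "odor_trace"), inherits(reference, "odor_trace"))
  if (reference$rate != rate$rate) reference <- downsample_trace(reference, rate$rate)
  x <- rate$values
  r <- reference$values[seq_along(x)]
  if (!is.null(window)) {
    idx <- trace_window(rate, window[1], window[2])
    x <- x[idx]; r <- r[idx]
  }
  x <- x - mean(x); r <- r - mean(r)
  max_lag <- round(max_lag_s * rate$rate)
  lags <- (-max_lag):max_lag
  if (stats::sd(x) == 0 || stats::sd(r) == 0) {
    return(structure(list(lags = lags / rate$rate,
                          raw = rep(NA_real_, length(lags)),
                          shuffle_mean = rep(NA_real_, length(lags)),
                          corrected = rep(NA_real_, length(lags)),
                          peak_r = NA_real_, peak_lag = NA_real_,
                          valid = FALSE),
                     class = "xcorr_result"))
  }
  raw <- vapply(lags, function(L) cor_at_lag(x, r, L), numeric(1))
  sh <- matrix(NA_real_, n_shuffle, length(lags))
  with_seed(seed, {
    for (s in seq_len(n_shuffle)) {
      xs <- sample(x)
      sh[s, ] <- vapply(lags, function(L) cor_at_lag(xs, r, L), numeric(1))
    }
  })
  shuffle_mean <- colMeans(sh)
  corrected <- raw - shuffle_mean
  j <- which.max(corrected)
  structure(list(lags = lags / rate$rate, raw = raw,
                 shuffle_mean = shuffle_mean, corrected = corrected,
                 peak_r = corrected[j], peak_lag = lags[j] / rate$rate,
                 valid = TRUE),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> peak r = %.3f at lag %+.0f ms\n",
              x$peak_r, 1000 * x$peak_lag))
  invisible(x)
}

#' Spatial correlation maps of a per-glomerulus scalar
#'
#' Pearson correlation of a response scalar (amplitude, T75 or odor
#' correlation) with glomerular position along the anterior-posterior axis
#' and with the medial-lateral distance from the midline, per trial, averaged
#' over trials. Trials where either variable has zero variance (or fewer than
#' 3 finite glomeruli) are flagged undefined and excluded from the averages.
#'
#' @param scalar matrix trials x glomeruli of the response scalar.
#' @param ap_coord,ml_coord per-glomerulus coordinates.
#' @return list with `per_trial` (data.frame `trial`, `r_ap`, `r_ml`) and
#'   `mean_r_ap`, `mean_r_ml`.
#' @export
spatiotemporal_map <- function(scalar, ap_coord, ml_coord) {
  scalar <- as.matrix(scalar)
  stopifnot(ncol(scalar) == length(ap_coord), length(ap_coord) == length(ml_coord))
  one <- function(v, coord) {
    ok <- is.finite(v) & is.finite(coord)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(v[ok]) == 0 || stats::sd(coord[ok]) == 0) return(NA_real_)
    stats::cor(v[ok], coord[ok])
  }
  per_trial <- data.frame(
    trial = seq_len(nrow(scalar)),
    r_ap = apply(scalar, 1, one, coord = ap_coord),
    r_ml = apply(scalar, 1, one, coord = ml_coord))
  list(per_trial = per_trial,
       mean_r_ap = mean(per_trial$r_ap, na.rm = TRUE),
       mean_r_ml = mean(per_trial$r_ml, na.rm = TRUE))
}
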