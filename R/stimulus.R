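#' Odor concentration trace with stimulus metadata
#'
#' A [odor_trace()] carrying the source concentration `C0` (the gain-1 maximum
#' concentration all stimuli are normalized to), the stimulus kind, the gain
#' and the nominal intermittency. Concentrations are in arbitrary units
#' (PID-like). The odor presentation window is `[odor_onset, odor_onset +
#' odor_dur)`; samples outside it are the pre/post baseline.
#'
#' @param values non-negative concentration samples.
#' @param rate sampling rate in Hz.
#' @param C0 source (gain-1 maximum) concentration, > 0.
#' @param kind one of `"naturalistic"`, `"binary"`, `"square"`.
#' @param gain stimulus gain in (0, 1]; gain 0.5 halves the delivered maximum
#'   while `C0` keeps recording the gain-1 reference.
#' @param nominal_intermittency target intermittency of the stimulus, or `NA`.
#' @param t0 time of first sample (s).
#' @param odor_onset,odor_dur odor window start and duration (s).
#' @return an object of classes `stimulus_trace`, `odor_trace`.
#' @export
stimulus_trace <- function(values, rate, C0 = 1,
                           kind = c("naturalistic", "binary", "square"),
                           gain = 1, nominal_intermittency = NA_real_,
                           t0 = 0, odor_onset = 2, odor_dur = 6) {
  kind <- match.arg(kind)
  if (!is.finite(C0) || C0 <= 0) stop("`C0` must be positive")
  if (any(values < -1e-9)) stop("concentrations must be non-negative")
  x <- odor_trace(values, rate, t0)
  x$C0 <- C0
  x$kind <- kind
  x$gain <- gain
  x$nominal_intermittency <- nominal_intermittency
  x$odor_onset <- odor_onset
  x$odor_dur <- odor_dur
  class(x) <- c("stimulus_trace", class(x))
  x
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf(
    "<stimulus_trace> kind=%s gain=%g C0=%g nominal gamma=%s; %d samples @ %g Hz\n",
    x$kind, x$gain, x$C0,
    if (is.na(x$nominal_intermittency)) "NA" else format(x$nominal_intermittency),
    length(x$values), x$rate))
  invisible(x)
}

odor_window_of <- function(stim) c(stim$odor_onset, stim$odor_onset + stim$odor_dur)

#' Intermittency of a stimulus trace
#'
#' Intermittency is the probability that odor concentration meets or exceeds a
#' threshold: the fraction of samples in the window with
#' `C >= threshold_frac * C0`. The threshold is always relative to the gain-1
#' source concentration `C0`, never to the trace's own maximum, so halving the
#' gain does not move the threshold.
#'
#' @param stim a [stimulus_trace()].
#' @param window half-open time window `c(from, to)` in seconds; defaults to
#'   the stimulus's odor presentation window.
#' @param threshold_frac threshold as a fraction of `C0` (default 0.1).
#' @return intermittency in `[0, 1]`.
#' @export
compute_intermittency <- function(stim, window = NULL, threshold_frac = 0.1) {
  stopifnot(inherits(stim, "stimulus_trace"))
  if (is.null(window)) window <- odor_window_of(stim)
  idx <- trace_window(stim, window[1], window[2])
  if (length(idx) == 0L) stop("empty intermittency window")
  mean(stim$values[idx] >= threshold_frac * stim$C0 - 1e-12)
}

#' Normalize a stimulus so its peak equals the source concentration
#'
#' Affine rescaling by `C0 / max(values)`, preserving shape. With the
#' intermittency threshold tracking `C0`, intermittency is invariant under
#' normalization.
#'
#' @param stim a [stimulus_trace()].
#' @return the rescaled [stimulus_trace()].
#' @export
normalize_trace <- function(stim) {
  stopifnot(inherits(stim, "stimulus_trace"))
  m <- max(stim$values)
  if (m <= 0) stop("cannot normalize an all-zero trace")
  stim$values <- stim$values * (stim$C0 / m)
  stim
}

#' Binarize a stimulus at the intermittency threshold
#'
#' Samples with `C >= 0.1 C0` are set to the delivered maximum
#' (`C0 * gain`), all others to zero. Intermittency is preserved exactly, and
#' the operation is idempotent.
#'
#' @param stim a [stimulus_trace()].
#' @param threshold_frac threshold as a fraction of `C0`.
#' @return a [stimulus_trace()] of kind `"binary"`.
#' @export
binarize_trace <- function(stim, threshold_frac = 0.1) {
  stopifnot(inherits(stim, "stimulus_trace"))
  hi <- stim$values >= threshold_frac * stim$C0 - 1e-12
  stim$values <- ifelse(hi, stim$C0 * stim$gain, 0)
  stim$kind <- "binary"
  stim
}

#' Apply a gain to a stimulus
#'
#' Rescales the delivered concentration to `gain` relative to the gain-1
#' reference; `C0` (and hence the intermittency threshold) is unchanged, as is
#' the nominal intermittency. For binary and square stimuli a gain above the
#' 0.1 threshold fraction leaves the realized intermittency unchanged.
#'
#' @param stim a [stimulus_trace()].
#' @param gain new gain in (0, 1].
#' @return the rescaled [stimulus_trace()].
#' @export
apply_gain <- function(stim, gain) {
  stopifnot(inherits(stim, "stimulus_trace"))
  if (!is.finite(gain) || gain <= 0 || gain > 1) stop("`gain` must be in (0, 1]")
  if (gain <= 0.1)
    warning("gain <= 0.1: whiffs fall at or below the intermittency threshold")
  stim$values <- stim$values * (gain / stim$gain)
  stim$gain <- gain
  stim
}

#' Count whiffs in a stimulus
#'
#' A whiff is a maximal contiguous run of supra-threshold samples
#' (`C >= 0.1 C0`) within the odor window. Whiffs separated by even a single
#' sub-threshold sample count as distinct (no gap merging).
#'
#' @param stim a [stimulus_trace()].
#' @param window time window; defaults to the odor presentation window.
#' @param threshold_frac threshold as a fraction of `C0`.
#' @return integer whiff count.
#' @export
count_whiffs <- function(stim, window = NULL, threshold_frac = 0.1) {
  stopifnot(inherits(stim, "stimulus_trace"))
  if (is.null(window)) window <- odor_window_of(stim)
  idx <- trace_window(stim, window[1], window[2])
  if (length(idx) == 0L) return(0L)
  hi <- stim$values[idx] >= threshold_frac * stim$C0 - 1e-12
  r <- rle(hi)
  sum(r$values)
}

#' Label a stimulus as CS+ / CS- by nominal intermittency
#'
#' Go/No-Go contingency: animals lick for intermittency >= 0.2 (CS+) and
#' withhold for <= 0.15 (CS-). Values strictly between the two bands get an
#' explicit `"excluded"` label.
#'
#' @param nominal_intermittency numeric vector in `[0, 1]`.
#' @return character vector with values `"CSplus"`, `"CSminus"`, `"excluded"`.
#' @export
label_cs <- function(nominal_intermittency) {
  stopifnot(all(is.na(nominal_intermittency) |
                  (nominal_intermittency >= 0 & nominal_intermittency <= 1)))
  out <- rep(NA_character_, length(nominal_intermittency))
  out[nominal_intermittency <= 0.15 + 1e-12] <- "CSminus"
  out[nominal_intermittency >= 0.2 - 1e-12] <- "CSplus"
  out[is.na(out) & !is.na(nominal_intermittency)] <- "excluded"
  out
}
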