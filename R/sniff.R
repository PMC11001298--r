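#' Sniff event container
#'
#' Onsets and inhalation peaks in seconds, with inhalation intervals taken as
#' half-open `[onset, peak)` so shared boundary samples are never counted
#' twice. Onsets must be strictly increasing and each onset must precede its
#' peak.
#'
#' @param onsets sniff onset times (s).
#' @param peaks inhalation peak times (s), same length.
#' @return an object of class `sniff_events`.
#' @export
sniff_events <- function(onsets, peaks) {
  stopifnot(length(onsets) == length(peaks))
  if (length(onsets) > 1 && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  if (any(onsets >= peaks)) stop("each onset must precede its peak")
  structure(list(onsets = as.numeric(onsets), peaks = as.numeric(peaks)),
            class = "sniff_events")
}

#' @export
print.sniff_events <- function(x, ...) {
  cat(sprintf("<sniff_events> %d sniffs\n", length(x$onsets)))
  invisible(x)
}

# Topographic prominence of local maxima: height above the higher of the two
# minima separating the peak from the nearest higher ground on each side. A
# side whose search reaches the record boundary without meeting higher ground
# is uninformative (an artifact of the finite window) and is ignored when the
# other side did find higher ground.
peak_prominence <- function(v, peaks_idx) {
  side_base <- function(p, step) {
    h <- v[p]
    i <- p
    lo <- h
    bounded <- FALSE
    while ((step < 0 && i > 1) || (step > 0 && i < length(v))) {
      i <- i + step
      lo <- min(lo, v[i])
      if (v[i] >= h) { bounded <- TRUE; break }   # ties bound like higher ground
    }
    list(lo = lo, bounded = bounded)
  }
  vapply(peaks_idx, function(p) {
    l <- side_base(p, -1L)
    r <- side_base(p, +1L)
    base <- if (l$bounded && r$bounded) max(l$lo, r$lo)
    else if (l$bounded) l$lo
    else if (r$bounded) r$lo
    else max(l$lo, r$lo)
    v[p] - base
  }, numeric(1))
}

#' Detect sniffs in a nasal pressure trace
#'
#' Positive deflections indicate inhalation. Peaks are local maxima whose
#' topographic prominence exceeds `min_prominence` and that are spaced at
#' least `min_interval_s` apart (taller peaks win ties). Each onset is the
#' most recent non-positive to positive sign change before its peak; a peak
#' with no such crossing is dropped, and when two peaks share an onset (a
#' double-humped inhalation lobe) only the taller is kept.
#'
#' @param pressure an [odor_trace()] of nasal pressure.
#' @param min_interval_s minimum inter-peak interval; default 1/12 s (a 12 Hz
#'   ceiling on plausible sniff rates).
#' @param min_prominence minimum peak prominence; default twice the median
#'   absolute deviation of the trace (a robust spread measure insensitive to
#'   the peaks themselves).
#' @return a [sniff_events()] object (empty if no peaks qualify).
#' @export
detect_sniffs <- function(pressure, min_interval_s = 1 / 12,
                          min_prominence = NULL) {
  stopifnot(inherits(pressure, "odor_trace"), min_interval_s > 0)
  v <- pressure$values
  if (any(!is.finite(v))) stop("pressure trace must be finite")
  if (is.null(min_prominence)) min_prominence <- 2 * stats::mad(v, constant = 1)
  n <- length(v)
  cand <- which(diff(sign(diff(v))) < 0) + 1L       # strict local maxima
  cand <- cand[v[cand] > 0]
  if (length(cand) == 0) return(sniff_events(numeric(0), numeric(0)))
  prom <- peak_prominence(v, cand)
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(sniff_events(numeric(0), numeric(0)))

  # enforce minimum spacing, keeping taller peaks
  ord <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer(0)
  min_gap <- min_interval_s * pressure$rate
  for (p in ord) if (all(abs(p - keep) >= min_gap)) keep <- c(keep, p)
  keep <- sort(keep)

  tt <- trace_times(pressure)
  onsets <- peaks <- numeric(0)
  onset_idx <- integer(0)
  for (p in keep) {
    j <- p
    while (j > 1 && v[j - 1] > 0) j <- j - 1
    if (j == 1 && v[1] > 0) next                    # no crossing before peak
    if (length(onset_idx) > 0 && j == onset_idx[length(onset_idx)]) {
      # same lobe: keep the taller peak
      last_p <- which(tt == peaks[length(peaks)])
      if (v[p] > v[last_p]) peaks[length(peaks)] <- tt[p]
      next
    }
    onset_idx <- c(onset_idx, j)
    onsets <- c(onsets, tt[j])
    peaks <- c(peaks, tt[p])
  }
  sniff_events(onsets, peaks)
}

#' Estimated perceived odor: stimulus samples falling within inhalations
#'
#' Concatenates, in temporal order, the concentration samples that fall inside
#' inhalation intervals (`[onset, peak)`) intersected with the odor
#' presentation window. The attribute `"T"` records the total inhalation time
#' within the window (seconds), so `length(out) == T * rate`.
#'
#' @param stim a [stimulus_trace()].
#' @param events a [sniff_events()].
#' @param window odor window; defaults to the stimulus odor window.
#' @return numeric vector of perceived concentration samples with attribute
#'   `"T"` (total inhalation time, s).
#' @export
perceived_odor <- function(stim, events, window = NULL) {
  stopifnot(inherits(stim, "stimulus_trace"), inherits(events, "sniff_events"))
  if (is.null(window)) window <- odor_window_of(stim)
  idx <- integer(0)
  for (k in seq_along(events$onsets)) {
    a <- max(events$onsets[k], window[1])
    b <- min(events$peaks[k], window[2])
    if (b > a) idx <- c(idx, trace_window(stim, a, b))
  }
  idx <- sort(unique(idx))
  out <- stim$values[idx]
  attr(out, "T") <- length(idx) / stim$rate
  out
}

#' Estimated perceived intermittency
#'
#' Intermittency computed on the perceived odor only: the fraction of
#' inhalation-gated samples in the odor window with `C >= threshold_frac *
#' C0`. When no inhalation falls in the window (`T = 0`) the value is
#' undefined and `NA` is returned with a warning.
#'
#' @inheritParams perceived_odor
#' @param threshold_frac threshold as a fraction of `C0`.
#' @return perceived intermittency in `[0, 1]`, or `NA` if `T = 0`.
#' @export
perceived_intermittency <- function(stim, events, window = NULL,
                                    threshold_frac = 0.1) {
  po <- perceived_odor(stim, events, window)
  if (length(po) == 0L) {
    warning("no inhalation samples in the odor window (T = 0); perceived intermittency undefined")
    return(NA_real_)
  }
  mean(po >= threshold_frac * stim$C0 - 1e-12)
}

#' Cumulative estimated perceived intermittency across trial time
#'
#' For each time point `t` of `t_grid`, the perceived intermittency computed
#' on inhalation samples from odor onset up to `t`. The value at the end of
#' the odor window equals [perceived_intermittency()] exactly. Time points
#' with no inhalation samples yet give `NA`.
#'
#' @inheritParams perceived_intermittency
#' @param t_grid evaluation times (s), within the odor window.
#' @return numeric vector, one value per element of `t_grid`.
#' @export
cumulative_perceived_intermittency <- function(stim, events, t_grid,
                                               threshold_frac = 0.1) {
  win <- odor_window_of(stim)
  if (any(t_grid < win[1] - 1e-9 | t_grid > win[2] + 1e-9))
    stop("`t_grid` must lie within the odor window")
  vapply(t_grid, function(t) {
    po <- perceived_odor(stim, events, window = c(win[1], t))
    if (length(po) == 0L) NA_real_
    else mean(po >= threshold_frac * stim$C0 - 1e-12)
  }, numeric(1))
}

#' Mean sniff frequency over a window
#'
#' @param events a [sniff_events()].
#' @param window half-open time window `c(from, to)` (s).
#' @return peak count divided by window duration (Hz).
#' @export
mean_sniff_frequency <- function(events, window) {
  stopifnot(inherits(events, "sniff_events"))
  dur <- window[2] - window[1]
  if (dur <= 0) stop("window length must be positive")
  sum(events$peaks >= window[1] & events$peaks < window[2]) / dur
}
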