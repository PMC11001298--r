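#' Uniformly sampled scalar time series
#'
#' The universal signal carrier used throughout the package: a numeric vector
#' of values sampled at a fixed rate, starting at time `t0` (seconds). All
#' window conventions are half-open `[from, to)` in time, so that e.g. a 6 s
#' odor window at 1 kHz contains exactly 6000 samples.
#'
#' @param values numeric vector of samples.
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return an object of class `odor_trace`: a list with elements `values`,
#'   `rate`, `t0`.
#' @export
odor_trace <- function(values, rate, t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number")
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 t0 = as.numeric(t0)),
            class = "odor_trace")
}

#' @export
print.odor_trace <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz, t = [%.3f, %.3f) s\n",
              class(x)[1L], length(x$values), x$rate, x$t0,
              x$t0 + length(x$values) / x$rate))
  invisible(x)
}

#' Time axis of a trace
#' @param x an `odor_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "odor_trace"))
  x$t0 + (seq_along(x$values) - 1) / x$rate
}

#' Sample indices falling in a half-open time window
#'
#' @param x an `odor_trace`.
#' @param from,to window bounds in seconds; samples with `from <= t < to`.
#' @return integer index vector (possibly empty).
#' @export
trace_window <- function(x, from, to) {
  tt <- trace_times(x)
  which(tt >= from - 1e-9 & tt < to - 1e-9)
}

#' Box-average downsampling of a trace to a lower rate
#'
#' Used to bring a 1 kHz stimulus or pressure channel onto the 25 Hz imaging
#' clock before cross-correlation. The source rate must be an integer multiple
#' of the target rate; each output sample is the mean of the corresponding
#' block of input samples.
#'
#' @param x an `odor_trace`.
#' @param to_rate target rate in Hz.
#' @return an `odor_trace` at `to_rate`.
#' @export
downsample_trace <- function(x, to_rate) {
  stopifnot(inherits(x, "odor_trace"))
  f <- x$rate / to_rate
  if (abs(f - round(f)) > 1e-8 || f < 1)
    stop("source rate must be an integer multiple of `to_rate`")
  f <- as.integer(round(f))
  n_out <- length(x$values) %/% f
  v <- colMeans(matrix(x$values[seq_len(n_out * f)], nrow = f))
  odor_trace(v, to_rate, x$t0)
}

# Derive a reproducible 31-bit sub-seed from a base seed and character tags.
# Stable polynomial hash so that adding a glomerulus or trial does not perturb
# the streams of the others.
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(tags)) h <- (h * 31 + cc) %% 2147483587
  as.integer(h + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
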