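#' Configuration for the synthetic session generator
#'
#' Collects the timing, acquisition and noise parameters shared by all
#' generator functions. Defaults follow the recording conditions the analysis
#' is designed for: 9 s trials (2 s pre-odor, 6 s odor, 1 s post), a 1 kHz
#' stimulus/pressure channel, 25 frames/s imaging, a 150 ms indicator decay
#' time constant, and a quadratic photobleaching drift.
#'
#' @param pre_s,odor_s,post_s trial segment durations in seconds.
#' @param stim_rate stimulus/pressure channel sampling rate (Hz).
#' @param imaging_rate fluorescence frame rate (Hz).
#' @param sniff_freq default sniff frequency (Hz), 2-8 Hz physiological range.
#' @param sniff_jitter fractional SD of cycle-period jitter.
#' @param tau_s indicator (GCaMP-like) decay time constant in seconds.
#' @param f0 baseline fluorescence (a.u.).
#' @param amp response amplitude of an active glomerulus, in dF/F units.
#' @param noise_sd white fluorescence noise SD (a.u., on the `f0` scale).
#' @param bleach_coeffs quadratic drift coefficients `c(b0, b1, b2)` applied as
#'   a fractional fluorescence change `b0 + b1 t + b2 t^2`.
#' @param seed integer base seed; all generator randomness derives from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(pre_s = 2, odor_s = 6, post_s = 1,
                             stim_rate = 1000, imaging_rate = 25,
                             sniff_freq = 4, sniff_jitter = 0.1,
                             tau_s = 0.150, f0 = 100, amp = 0.25,
                             noise_sd = 1.0,
                             bleach_coeffs = c(0, -0.004, 0.0002),
                             seed = 1L) {
  cfg <- list(pre_s = pre_s, odor_s = odor_s, post_s = post_s,
              duration_s = pre_s + odor_s + post_s,
              stim_rate = stim_rate, imaging_rate = imaging_rate,
              sniff_freq = sniff_freq, sniff_jitter = sniff_jitter,
              tau_s = tau_s, f0 = f0, amp = amp, noise_sd = noise_sd,
              bleach_coeffs = bleach_coeffs, seed = as.integer(seed))
  with(cfg, {
    stopifnot(stim_rate > 0, imaging_rate > 0, duration_s > 0, tau_s > 0,
              pre_s >= 0, odor_s > 0, post_s >= 0, f0 > 0, noise_sd >= 0,
              length(bleach_coeffs) == 3)
  })
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a plume-like fluctuating concentration trace
#'
#' Whiff/blank alternation is modelled as a two-state renewal process with
#' exponentially distributed durations (memoryless, the simplest process with
#' a tunable duration fraction). The blank mean duration is rescaled
#' iteratively (at most `max_iter` redraws) until the realized intermittency,
#' recomputed with [compute_intermittency()], lands within `tol` of the
#' target. Naturalistic traces are low-pass smoothed and amplitude-modulated
#' for plume-like texture, then normalized so every trace reaches the same
#' maximum concentration `C0`.
#'
#' @param target_intermittency target in (0, 1).
#' @param config a [generator_config()].
#' @param kind `"naturalistic"` (smoothed) or `"binary"` (telegraph).
#' @param C0 source concentration.
#' @param mean_whiff_s mean whiff duration (s) of the renewal process.
#' @param tol acceptance tolerance on realized intermittency.
#' @param max_iter maximum redraw/rescale iterations.
#' @param seed optional seed override; defaults to a sub-seed of the config.
#' @return a [stimulus_trace()] whose realized intermittency is within `tol`
#'   of the target.
#' @export
gen_plume_trace <- function(target_intermittency, config = generator_config(),
                            kind = c("naturalistic", "binary"), C0 = 1,
                            mean_whiff_s = 0.2, tol = 0.02, max_iter = 50L,
                            seed = NULL) {
  kind <- match.arg(kind)
  g <- target_intermittency
  if (!is.finite(g) || g <= 0 || g >= 1)
    stop("`target_intermittency` must be in (0, 1)")
  if (is.null(seed))
    seed <- derive_seed(config$seed, "plume", signif(g, 6), kind)
  rate <- config$stim_rate
  n_od <- round(config$odor_s * rate)

  with_seed(seed, {
    mw <- mean_whiff_s
    mb <- mw * (1 - g) / g
    # draw the whiff/blank renewal sequence and the plume texture once; the
    # blank mean duration is then rescaled deterministically (bisection on a
    # monotone duty curve) until the realized intermittency matches
    n_events <- ceiling(4 * config$odor_s / (mw + mb)) + 20
    k <- max(1L, round(0.04 * rate))
    draw_sequence <- function() {
      whiffs <<- stats::rexp(n_events, 1 / mw)
      blanks <<- stats::rexp(n_events, 1 / mb)
      start_on <<- stats::runif(1) < g
      env <<- stats::approx(seq(0, config$odor_s, length.out = 32),
                            stats::runif(32, 0.4, 1),
                            xout = (seq_len(n_od) - 1) / rate)$y
    }
    whiffs <- blanks <- env <- NULL; start_on <- FALSE
    draw_sequence()

    assemble <- function(scale) {
      odor <- numeric(n_od)
      pos <- if (start_on) 0 else blanks[1] * scale
      i <- 1L
      while (pos < n_od / rate && i <= n_events) {
        w <- max(1 / rate, whiffs[i])
        j0 <- floor(pos * rate) + 1L
        j1 <- min(n_od, ceiling((pos + w) * rate))
        if (j0 <= n_od) odor[j0:j1] <- 1
        pos <- pos + w + max(1 / rate, blanks[min(i + 1L, n_events)] * scale)
        i <- i + 1L
      }
      conc <- odor * C0
      if (kind == "naturalistic") {
        conc <- conc * env
        conc <- stats::filter(conc, rep(1 / k, k), sides = 2)
        conc[is.na(conc)] <- 0
        conc <- as.numeric(conc)
        if (max(conc) > 0) conc <- conc * (C0 / max(conc))
      }
      vals <- c(numeric(round(config$pre_s * rate)), conc,
                numeric(round(config$post_s * rate)))
      stimulus_trace(vals, rate, C0 = C0, kind = kind, gain = 1,
                     nominal_intermittency = g,
                     odor_onset = config$pre_s, odor_dur = config$odor_s)
    }

    lo <- 0.005; hi <- 200; scale <- 1
    realized <- NA_real_
    for (it in seq_len(max_iter)) {
      stim <- assemble(scale)
      realized <- compute_intermittency(stim)
      if (abs(realized - g) <= tol) return(stim)
      if (realized > g) lo <- scale else hi <- scale   # duty falls as blanks grow
      if (hi / lo < 1.0001) {
        # bracket exhausted (e.g. an over-long opening whiff): fresh sequence
        draw_sequence()
        lo <- 0.005; hi <- 200
      }
      scale <- sqrt(lo * hi)                            # geometric bisection
    }
    stop(sprintf(
      "plume generator failed to converge: target %.3f, last realized %.3f after %d iterations",
      g, realized, max_iter))
  })
}

#' Generate a square-wave stimulus
#'
#' `n_pulses` equal pulses evenly spanning the odor window, each on for
#' `duty`% of its period at amplitude `C0`. Realized intermittency equals
#' `duty / 100` up to sample quantization.
#'
#' @param n_pulses number of pulses, 1-8.
#' @param duty duty cycle in percent, in (0, 100).
#' @param config a [generator_config()].
#' @param C0 source concentration.
#' @return a [stimulus_trace()] of kind `"square"`.
#' @export
gen_square_wave <- function(n_pulses, duty, config = generator_config(), C0 = 1) {
  if (!is.numeric(n_pulses) || n_pulses < 1 || n_pulses > 8 ||
      n_pulses != round(n_pulses))
    stop("`n_pulses` must be an integer in 1..8")
  if (!is.finite(duty) || duty <= 0 || duty >= 100)
    stop("`duty` must be in (0, 100)")
  rate <- config$stim_rate
  n_od <- round(config$odor_s * rate)
  period_n <- n_od / n_pulses
  on_n <- round(period_n * duty / 100)
  odor <- numeric(n_od)
  for (k in seq_len(n_pulses)) {
    start <- round((k - 1) * period_n)
    odor[(start + 1):(start + on_n)] <- C0
  }
  vals <- c(numeric(round(config$pre_s * rate)), odor,
            numeric(round(config$post_s * rate)))
  stimulus_trace(vals, rate, C0 = C0, kind = "square", gain = 1,
                 nominal_intermittency = duty / 100,
                 odor_onset = config$pre_s, odor_dur = config$odor_s)
}

#' Generate a quasi-periodic sniff pressure trace with ground truth
#'
#' Each sniff cycle is a biphasic waveform: a positive inhalation lobe
#' occupying the first 40% of the cycle (pressure peak a quarter of the way
#' into the lobe region) followed by a shallower negative exhalation lobe.
#' Cycle periods are optionally jittered. Returns the trace together with the
#' true onset (non-positive to positive crossing) and peak times, which
#' downstream sniff-detection tests compare against.
#'
#' @param sniff_freq mean sniff frequency in Hz (1-12 accepted; 2-8
#'   physiological).
#' @param config a [generator_config()].
#' @param jitter fractional SD of the cycle period (`NULL` uses the config).
#' @param phase start time of the first cycle (s), for phase randomization.
#' @param duration_s trace duration (`NULL` uses the config trial duration).
#' @param seed optional seed override.
#' @return a list with `trace` (an [odor_trace()]), `onsets`, `peaks` (s).
#' @export
gen_sniff_trace <- function(sniff_freq, config = generator_config(),
                            jitter = NULL, phase = 0, duration_s = NULL,
                            seed = NULL) {
  if (!is.finite(sniff_freq) || sniff_freq < 1 || sniff_freq > 12)
    stop("`sniff_freq` must be in [1, 12] Hz")
  if (is.null(jitter)) jitter <- config$sniff_jitter
  if (is.null(duration_s)) duration_s <- config$duration_s
  if (is.null(seed)) seed <- derive_seed(config$seed, "sniff", sniff_freq)
  rate <- config$stim_rate
  n <- round(duration_s * rate)
  with_seed(seed, {
    p0 <- 1 / sniff_freq
    starts <- c()
    t <- phase
    while (t < duration_s) {
      starts <- c(starts, t)
      z <- if (jitter > 0) max(-2, min(2, stats::rnorm(1))) else 0
      t <- t + p0 * (1 + jitter * z)
    }
    periods <- diff(c(starts, t))
    v <- numeric(n)
    onsets <- peaks <- numeric(0)
    tt <- (seq_len(n) - 1) / rate
    inh_frac <- 0.4
    for (k in seq_along(starts)) {
      s <- starts[k]; p <- periods[k]
      idx <- which(tt >= s & tt < s + p)
      if (length(idx) == 0) next
      ph <- (tt[idx] - s) / p
      w <- ifelse(ph < inh_frac,
                  sin(pi * ph / inh_frac),
                  -0.6 * sin(pi * (ph - inh_frac) / (1 - inh_frac)))
      v[idx] <- w
      pk <- s + inh_frac * p / 2
      if (pk < duration_s) {
        onsets <- c(onsets, s)
        peaks <- c(peaks, pk)
      }
    }
    list(trace = odor_trace(v, rate, 0), onsets = onsets, peaks = peaks)
  })
}

#' Generate a glomerular population with planted encoding phenotypes
#'
#' Two response phenotypes are planted. Cluster-2 units are whiff-driven
#' (active when sampled odor concentration is high), so their glomerular
#' intermittency (GI) rises with stimulus intermittency; cluster-1 units are
#' blank-driven (active when odor is absent within the odor period), so their
#' GI falls with intermittency. Each unit carries a planted GI-vs-intermittency
#' line (`gi_intercept + gi_slope * gamma`); the default slope magnitudes are
#' the generator presets `+0.89` (cluster 2) and `-0.59` (cluster 1). Response
#' gain and latency follow a posterior-lateral gradient across the 256 x 256
#' imaging frame so spatial-map analyses have planted signal.
#'
#' @param n number of glomeruli (> 0).
#' @param frac_cluster1 fraction of blank-driven (negative-slope) units.
#' @param config a [generator_config()].
#' @param slope1,slope2 planted GI slopes for clusters 1 and 2.
#' @param intercept1,intercept2 planted GI intercepts (chosen so GI stays in
#'   `[0, 1]` over the 0-0.8 intermittency range).
#' @param slope_sd per-unit SD around the planted cluster slope.
#' @param frac_silent fraction of non-responding units (zero planted rate).
#' @param seed optional seed override.
#' @return a data.frame with one row per glomerulus: `roi_id`, `cluster`,
#'   `gi_slope`, `gi_intercept`, `gain`, `latency_s`, `ap_coord`, `ml_coord`,
#'   `responder`.
#' @export
gen_glomerulus_population <- function(n, frac_cluster1 = 0.2,
                                      config = generator_config(),
                                      slope1 = -0.59, slope2 = 0.89,
                                      intercept1 = 0.65, intercept2 = 0.05,
                                      slope_sd = 0, frac_silent = 0,
                                      seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive count")
  if (frac_cluster1 < 0 || frac_cluster1 > 1)
    stop("`frac_cluster1` must be in [0, 1]")
  if (is.null(seed)) seed <- derive_seed(config$seed, "population", n)
  n <- as.integer(n)
  with_seed(seed, {
    n1 <- round(n * frac_cluster1)
    cluster <- c(rep(1L, n1), rep(2L, n - n1))
    slope <- ifelse(cluster == 1L, slope1, slope2) +
      if (slope_sd > 0) stats::rnorm(n, 0, slope_sd) else 0
    intercept <- ifelse(cluster == 1L, intercept1, intercept2)
    ap <- stats::runif(n, 1, 256)         # anterior (1) -> posterior (256)
    ml <- stats::runif(n, 0, 128)         # pixel distance from midline
    grad <- (ap / 256 + ml / 128) / 2     # posterior-lateral gradient in [0,1]
    gain <- 0.7 + 0.6 * grad              # relative response gain
    latency <- 0.04 + 0.12 * grad         # s from whiff arrival to response
    responder <- rep(TRUE, n)
    if (frac_silent > 0)
      responder[sample.int(n, round(n * frac_silent))] <- FALSE
    data.frame(roi_id = sprintf("g%03d", seq_len(n)), cluster = cluster,
               gi_slope = ifelse(responder, slope, 0),
               gi_intercept = ifelse(responder, intercept, 0),
               gain = gain, latency_s = latency,
               ap_coord = ap, ml_coord = ml, responder = responder,
               stringsAsFactors = FALSE)
  })
}

# Phenotype drive (whiff- or blank-driven), sniff-gated and brought to the
# imaging clock; depends only on the cluster, so sessions cache it per trial.
gated_drive_img <- function(cluster, stimulus, sniff, config) {
  cmax <- stimulus$C0 * stimulus$gain
  cnorm <- stimulus$values / cmax
  drive <- if (cluster == 1L) 1 - cnorm else cnorm
  win <- odor_window_of(stimulus)
  tt_stim <- trace_times(stimulus)
  drive[tt_stim < win[1] | tt_stim >= win[2]] <- 0
  gated <- sniff_gate(drive, stimulus$rate, sniff$onsets, sniff$peaks,
                      config$duration_s)
  downsample_trace(odor_trace(gated, stimulus$rate),
                   config$imaging_rate)$values
}

# Sample-and-hold sniff gating of a drive signal: at each inhalation interval
# the mean drive over the interval is sampled and held until the next onset.
sniff_gate <- function(drive, rate, onsets, peaks, duration_s) {
  n <- length(drive)
  out <- numeric(n)
  if (length(onsets) == 0) return(out)
  cs <- c(0, cumsum(drive))
  i_on <- pmin(n, floor(onsets * rate) + 1L)
  i_pk <- pmax(i_on + 1L, pmin(n + 1L, floor(peaks * rate) + 1L))
  sampled <- (cs[i_pk] - cs[i_on]) / (i_pk - i_on)
  tt <- (seq_len(n) - 1) / rate
  k <- findInterval(tt, onsets)            # 0 before the first onset
  out[k > 0] <- sampled[k[k > 0]]
  out
}

#' Generate a raw fluorescence trace for one glomerulus and one trial
#'
#' Forward model for the imaging pipeline. The phenotype drive (odor
#' concentration for cluster 2, its complement for cluster 1, both confined to
#' the odor window) is sniff-gated by sample-and-hold at each inhalation, then
#' converted into a binary activity mask whose odor-window duty equals the
#' planted GI line `gi_intercept + gi_slope * gamma` (the most-driven samples
#' are active). The mask, delayed by the unit's latency, is band-limited to
#' the measurement band (0.075-10 Hz) - the component of the rate a calcium
#' indicator can carry - then convolved with the causal exponential kernel
#' `exp(-t/tau)/tau`, scaled to dF/F units, and combined with baseline
#' fluorescence, quadratic bleaching drift and white noise at the imaging
#' rate.
#'
#' @param glom one row of [gen_glomerulus_population()].
#' @param stimulus a [stimulus_trace()].
#' @param sniff a list as returned by [gen_sniff_trace()].
#' @param config a [generator_config()].
#' @param noise_sd,bleach_coeffs optional overrides of the config values.
#' @param seed optional seed override (noise stream).
#' @param gated_img optional precomputed sniff-gated drive at the imaging
#'   rate for this trial and phenotype (a per-trial cache shared across
#'   glomeruli of the same cluster).
#' @return a list with `trace` (raw fluorescence [odor_trace()] at the imaging
#'   rate), `rate` (ground-truth band-limited rate, dF/F scale), `active`
#'   (binary activity mask), `gi_target` (planted odor-window duty).
#' @export
gen_fluorescence <- function(glom, stimulus, sniff, config = generator_config(),
                             noise_sd = NULL, bleach_coeffs = NULL,
                             seed = NULL, gated_img = NULL) {
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  if (is.null(bleach_coeffs)) bleach_coeffs <- config$bleach_coeffs
  if (is.null(seed)) seed <- derive_seed(config$seed, "fluor", glom$roi_id)
  ir <- config$imaging_rate
  n_img <- round(config$duration_s * ir)
  tt <- (seq_len(n_img) - 1) / ir

  gamma <- compute_intermittency(stimulus)
  win <- odor_window_of(stimulus)
  if (is.null(gated_img))
    gated_img <- gated_drive_img(glom$cluster, stimulus, sniff, config)

  # activity mask with planted odor-window duty
  p <- min(1, max(0, glom$gi_intercept + glom$gi_slope * gamma))
  if (!isTRUE(glom$responder)) p <- 0
  odor_idx <- which(tt >= win[1] & tt < win[2])
  active <- numeric(n_img)
  k <- round(p * length(odor_idx))
  if (k > 0) {
    ord <- odor_idx[order(gated_img[odor_idx], decreasing = TRUE)]
    active[ord[seq_len(k)]] <- 1
  }
  lag <- round(glom$latency_s * ir)
  if (lag > 0) active <- c(numeric(lag), active)[seq_len(n_img)]

  # fluorescence carries the raw planted rate through the indicator kernel;
  # the reported ground-truth rate is the planted activity as seen through
  # the pipeline's linear measurement operator (band filter + baseline-window
  # quadratic projection) - the component the measurement chain preserves
  raw_rate <- active * config$amp * glom$gain
  rate_true <- bleach_correct_values(
    bandpass_values(raw_rate, ir), ir, 0,
    pre_window = c(0, config$pre_s),
    post_window = c(config$pre_s + config$odor_s, config$duration_s))
  dff <- convolve_kernel(raw_rate, config$tau_s, ir)
  drift <- bleach_coeffs[1] + bleach_coeffs[2] * tt + bleach_coeffs[3] * tt^2
  f <- with_seed(seed, {
    config$f0 * (1 + dff + drift) + stats::rnorm(n_img, 0, noise_sd)
  })
  list(trace = odor_trace(f, ir, 0), rate = rate_true, active = active,
       gi_target = p)
}

#' Generate a complete Go/No-Go session with ground truth
#'
#' Default layout follows the task structure: 8 high-intermittency (> 0.6)
#' engagement trials, then a random interleaving of 28 CS+ (intermittency in
#' `[0.2, 0.8]`) and 28 CS- (<= 0.15) trials with gains 1 and 0.5 balanced.
#' Licking follows a logistic policy on the trial's estimated perceived
#' intermittency (odor sampled during inhalations), with first-lick latency
#' decreasing in perceived intermittency; trials whose policy says "lick" get
#' a lick train through the decision window.
#'
#' @param config a [generator_config()].
#' @param n_cs_plus,n_cs_minus numbers of CS+ / CS- trials after engagement.
#' @param n_engage number of engagement trials.
#' @param menu_plus,menu_minus nominal intermittency menus for CS+ / CS-.
#' @param gains gain levels interleaved across non-engagement trials.
#' @param kind stimulus kind for all trials.
#' @param glomeruli population data.frame from [gen_glomerulus_population()]
#'   (`NULL` for a behavior-only session without imaging).
#' @param lick_policy list with `slope`, `mid` (logistic policy on perceived
#'   intermittency), `lapse`, `lat_a`, `lat_b`, `lat_sd` (first-lick latency
#'   `lat_a - lat_b * gamma_perceived`, s from odor onset).
#' @param sniff_range range of per-trial mean sniff frequencies (Hz).
#' @param trial_gammas optional explicit vector of nominal intermittency
#'   values, one per trial, overriding the Go/No-Go layout (used for
#'   anesthetized-style imaging sessions with a fixed stimulus menu; no
#'   engagement block).
#' @param trial_gains optional per-trial gains accompanying `trial_gammas`
#'   (default all 1).
#' @return a list of class `plume_session` with `trials` (list of trial
#'   records), `glomeruli`, `config`, `lick_policy`. Each trial record holds
#'   `trial_id`, `stimulus`, `sniff`, `lick_times`, `cs_label`, `gain`,
#'   `gamma` (realized), `gamma_perceived_true`, `fluor` (matrix frames x
#'   glomeruli) and `rate_true` (same shape).
#' @export
gen_session <- function(config = generator_config(),
                        n_cs_plus = 28, n_cs_minus = 28, n_engage = 8,
                        menu_plus = seq(0.2, 0.8, by = 0.1),
                        menu_minus = c(0.05, 0.10, 0.15),
                        gains = c(1, 0.5), kind = "naturalistic",
                        glomeruli = NULL,
                        lick_policy = list(slope = 25, mid = 0.175,
                                           lapse = 0.02, lat_a = 5.5,
                                           lat_b = 2, lat_sd = 0.15),
                        sniff_range = c(2, 8),
                        trial_gammas = NULL, trial_gains = NULL) {
  if (!is.null(trial_gammas)) {
    if (any(trial_gammas <= 0) || any(trial_gammas >= 1))
      stop("trial gammas must be in (0, 1)")
    n_trials <- length(trial_gammas)
    plan <- data.frame(gamma_nominal = trial_gammas,
                       gain = trial_gains %||% rep(1, n_trials),
                       engagement = FALSE)
  } else {
    if (length(menu_plus) == 0 || length(menu_minus) == 0)
      stop("intermittency menus must be non-empty")
    if (any(c(menu_plus, menu_minus) <= 0) || any(c(menu_plus, menu_minus) >= 1))
      stop("menu values must be in (0, 1)")
    n_trials <- n_engage + n_cs_plus + n_cs_minus
    plan <- with_seed(derive_seed(config$seed, "session-plan"), {
      engage_g <- sample(menu_plus[menu_plus > 0.6], n_engage, replace = TRUE)
      gp <- sample(menu_plus, n_cs_plus, replace = TRUE)
      gm <- sample(menu_minus, n_cs_minus, replace = TRUE)
      mix <- sample(c(gp, gm))
      gg <- sample(rep(gains, length.out = n_cs_plus + n_cs_minus))
      data.frame(gamma_nominal = c(engage_g, mix),
                 gain = c(rep(1, n_engage), gg),
                 engagement = rep(c(TRUE, FALSE), c(n_engage, n_cs_plus + n_cs_minus)))
    })
  }

  odor_on <- config$pre_s
  odor_off <- config$pre_s + config$odor_s
  decision <- c(odor_off + 0.5, odor_off + 2.0)

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    g <- plan$gamma_nominal[i]
    stim <- gen_plume_trace(g, config, kind = kind,
                            seed = derive_seed(config$seed, "trial-stim", i))
    if (plan$gain[i] != 1) stim <- apply_gain(stim, plan$gain[i])
    sfreq <- with_seed(derive_seed(config$seed, "trial-sniff-freq", i),
                       stats::runif(1, sniff_range[1], sniff_range[2]))
    sniff <- gen_sniff_trace(sfreq, config,
                             phase = with_seed(derive_seed(config$seed, "trial-phase", i),
                                               stats::runif(1, 0, 1 / sfreq)),
                             seed = derive_seed(config$seed, "trial-sniff", i))
    ev <- sniff_events(sniff$onsets, sniff$peaks)
    gp <- suppressWarnings(perceived_intermittency(stim, ev))
    if (is.na(gp)) gp <- compute_intermittency(stim)

    lick_times <- with_seed(derive_seed(config$seed, "trial-lick", i), {
      p_lick <- lick_policy$lapse +
        (1 - 2 * lick_policy$lapse) *
          stats::plogis(lick_policy$slope * (gp - lick_policy$mid))
      if (stats::runif(1) < p_lick) {
        first <- odor_on + max(0.3, lick_policy$lat_a - lick_policy$lat_b * gp +
                                 stats::rnorm(1, 0, lick_policy$lat_sd))
        first <- min(first, decision[1] + 0.2)
        seq(first, decision[2] - 0.05, by = 1 / 7)  # ~7 Hz lick train
      } else numeric(0)
    })

    fluor <- rate_true <- NULL
    if (!is.null(glomeruli) && nrow(glomeruli) > 0) {
      n_img <- round(config$duration_s * config$imaging_rate)
      fluor <- matrix(0, n_img, nrow(glomeruli),
                      dimnames = list(NULL, glomeruli$roi_id))
      rate_true <- fluor
      gated_cache <- lapply(1:2, function(cl)
        if (any(glomeruli$cluster == cl))
          gated_drive_img(cl, stim, sniff, config))
      for (j in seq_len(nrow(glomeruli))) {
        out <- gen_fluorescence(glomeruli[j, ], stim, sniff, config,
                                seed = derive_seed(config$seed, "trial-fluor",
                                                   i, glomeruli$roi_id[j]),
                                gated_img = gated_cache[[glomeruli$cluster[j]]])
        fluor[, j] <- out$trace$values
        rate_true[, j] <- out$rate
      }
    }

    trials[[i]] <- list(trial_id = i, stimulus = stim, sniff = sniff,
                        lick_times = lick_times,
                        cs_label = if (plan$engagement[i]) "CSplus" else label_cs(g),
                        gain = plan$gain[i],
                        engagement = plan$engagement[i],
                        gamma_nominal = g,
                        gamma = compute_intermittency(stim),
                        gamma_perceived_true = gp,
                        fluor = fluor, rate_true = rate_true)
  }
  structure(list(trials = trials, glomeruli = glomeruli, config = config,
                 lick_policy = lick_policy, decision_window = decision),
            class = "plume_session")
}

#' @export
print.plume_session <- function(x, ...) {
  cat(sprintf("<plume_session> %d trials, %d glomeruli, seed %d\n",
              length(x$trials),
              if (is.null(x$glomeruli)) 0L else nrow(x$glomeruli),
              x$config$seed))
  invisible(x)
}

#' Per-trial metadata table of a session
#'
#' @param session a `plume_session`.
#' @return data.frame with one row per trial: `trial_id`, `kind`,
#'   `intermittency` (realized), `nominal_intermittency`, `gain`, `cs_label`,
#'   `engagement`, `n_licks`.
#' @export
trial_table <- function(session) {
  stopifnot(inherits(session, "plume_session"))
  do.call(rbind, lapply(session$trials, function(tr) {
    data.frame(trial_id = tr$trial_id, kind = tr$stimulus$kind,
               intermittency = tr$gamma,
               nominal_intermittency = tr$gamma_nominal,
               gain = tr$gain, cs_label = tr$cs_label,
               engagement = tr$engagement, n_licks = length(tr$lick_times),
               stringsAsFactors = FALSE)
  }))
}

#' Write the session trial table as CSV
#' @param session a `plume_session`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trial_table <- function(session, path) {
  utils::write.csv(trial_table(session), path, row.names = FALSE)
  invisible(path)
}
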