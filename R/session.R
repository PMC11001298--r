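#' Run the full analysis pipeline on a session
#'
#' For each trial: sniff detection on the pressure trace, estimated perceived
#' intermittency, and per-glomerulus preprocessing (dF/F, band filter, bleach
#' correction, deconvolution, z-scoring) with first-sniff amplitude/T75 and
#' GI extraction. Aggregates responder detection, GI-slope fits and session
#' behavior metrics.
#'
#' @param session a `plume_session` from [gen_session()] (or an equivalent
#'   structure with the same trial fields).
#' @param use_bandpass apply the band filter in preprocessing.
#' @param use_true_sniffs use the generator's ground-truth sniff events
#'   instead of running [detect_sniffs()] (for ablation tests).
#' @return list of class `session_result` with
#'   `gi` (data.frame `roi_id`, `trial_id`, `gi`, `gamma`, `gain`,
#'   `cs_label`), `responses` (`roi_id`, `trial_id`, `amplitude`, `t75`),
#'   `sniffs` (per trial: `n_sniffs`, `mean_freq`, `perceived_gamma`, `T`),
#'   `amplitude_matrix` (trials x glomeruli), `responders`, `slopes`
#'   (per glomerulus `roi_id`, `slope`, `intercept`, `r2`), `outcomes`,
#'   `metrics`.
#' @export
process_session <- function(session, use_bandpass = TRUE,
                            use_true_sniffs = FALSE) {
  stopifnot(inherits(session, "plume_session"))
  cfg <- session$config
  onset <- cfg$pre_s
  odor_win <- c(cfg$pre_s, cfg$pre_s + cfg$odor_s)
  gl <- session$glomeruli
  n_g <- if (is.null(gl)) 0L else nrow(gl)
  n_t <- length(session$trials)

  sniff_rows <- vector("list", n_t)
  gi_rows <- list()
  resp_rows <- list()
  amp <- if (n_g > 0) matrix(NA_real_, n_t, n_g, dimnames = list(NULL, gl$roi_id))

  for (i in seq_len(n_t)) {
    tr <- session$trials[[i]]
    ev <- if (use_true_sniffs) sniff_events(tr$sniff$onsets, tr$sniff$peaks)
          else detect_sniffs(tr$sniff$trace)
    pg <- suppressWarnings(perceived_intermittency(tr$stimulus, ev))
    po <- perceived_odor(tr$stimulus, ev)
    sniff_rows[[i]] <- data.frame(
      trial_id = tr$trial_id, n_sniffs = length(ev$onsets),
      mean_freq = mean_sniff_frequency(ev, odor_win),
      perceived_gamma = pg, T = attr(po, "T"))
    if (n_g > 0) {
      for (j in seq_len(n_g)) {
        raw <- odor_trace(tr$fluor[, j], cfg$imaging_rate)
        pp <- preprocess_trace(raw, ev, odor_onset = onset,
                               odor_dur = cfg$odor_s, tau_s = cfg$tau_s,
                               use_bandpass = use_bandpass)
        amp[i, j] <- pp$amplitude
        gi_rows[[length(gi_rows) + 1L]] <- data.frame(
          roi_id = gl$roi_id[j], trial_id = tr$trial_id,
          gi = compute_GI(pp$z, odor_win), gamma = tr$gamma,
          gain = tr$gain, cs_label = tr$cs_label,
          stringsAsFactors = FALSE)
        resp_rows[[length(resp_rows) + 1L]] <- data.frame(
          roi_id = gl$roi_id[j], trial_id = tr$trial_id,
          amplitude = pp$amplitude, t75 = pp$t75,
          stringsAsFactors = FALSE)
      }
    }
  }

  gi <- if (length(gi_rows)) do.call(rbind, gi_rows) else NULL
  slopes <- NULL
  responders <- NULL
  if (n_g > 0) {
    responders <- detect_responders(amp)
    slopes <- do.call(rbind, lapply(gl$roi_id, function(r) {
      sub <- gi[gi$roi_id == r, ]
      fit <- tryCatch(fit_GI_slope(sub$gi, sub$gamma),
                      error = function(e) list(slope = NA_real_,
                                               intercept = NA_real_,
                                               r2 = NA_real_, n = 0L))
      data.frame(roi_id = r, slope = fit$slope, intercept = fit$intercept,
                 r2 = fit$r2, n = fit$n, stringsAsFactors = FALSE)
    }))
  }

  outcomes <- score_trials(session)
  metrics <- suppressWarnings(session_metrics(outcomes))
  structure(list(gi = gi, responses = if (length(resp_rows))
                   do.call(rbind, resp_rows) else NULL,
                 sniffs = do.call(rbind, sniff_rows),
                 amplitude_matrix = amp, responders = responders,
                 slopes = slopes, outcomes = outcomes, metrics = metrics),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d trials, %d glomeruli\n",
              nrow(x$sniffs),
              if (is.null(x$slopes)) 0L else nrow(x$slopes)))
  if (!is.null(x$metrics) && is.finite(x$metrics$HR)) print(x$metrics)
  invisible(x)
}

#' GI feature matrix (trials x glomeruli) from a session result
#'
#' @param result a `session_result` from [process_session()].
#' @return list with `X` (GI matrix), `labels` (cs label per trial), `gamma`
#'   (realized intermittency per trial), `trial_id`.
#' @export
gi_matrix <- function(result) {
  stopifnot(inherits(result, "session_result"), !is.null(result$gi))
  gi <- result$gi
  rois <- unique(gi$roi_id)
  trials <- unique(gi$trial_id)
  X <- matrix(NA_real_, length(trials), length(rois),
              dimnames = list(trials, rois))
  X[cbind(match(gi$trial_id, trials), match(gi$roi_id, rois))] <- gi$gi
  meta <- gi[!duplicated(gi$trial_id), c("trial_id", "gamma", "cs_label")]
  meta <- meta[match(trials, meta$trial_id), ]
  list(X = X, labels = meta$cs_label, gamma = meta$gamma, trial_id = trials)
}
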