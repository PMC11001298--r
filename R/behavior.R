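#' Score Go/No-Go trial outcomes from lick times
#'
#' A trial's outcome is decided solely by lick presence in the decision
#' window (a 1.5 s period beginning 0.5 s after odor offset, when the
#' decision tone ends). Anticipatory licks before the window are recorded but
#' never change the outcome. CS+ with a decision lick is a hit, without one a
#' miss; CS- with a decision lick is a false alarm, without one a correct
#' rejection. Trials labelled `"excluded"` (intermittency in the gap between
#' the CS bands) get outcome `NA`.
#'
#' @param trials data.frame with columns `trial_id`, `cs_label`, and a
#'   list-column `lick_times` (seconds, trial clock); or a `plume_session`.
#' @param odor_onset,odor_dur odor window (s).
#' @param decision_window half-open window `c(from, to)` (s); default
#'   `odor_offset + 0.5` to `odor_offset + 2.0`.
#' @return data.frame: `trial_id`, `cs_label`, `licked_in_decision`,
#'   `outcome`, `first_lick_time` (s from odor onset; `NA` when no lick at or
#'   after onset), `n_anticipatory`.
#' @export
score_trials <- function(trials, odor_onset = 2, odor_dur = 6,
                         decision_window = NULL) {
  if (inherits(trials, "plume_session")) {
    ses <- trials
    odor_onset <- ses$config$pre_s
    odor_dur <- ses$config$odor_s
    decision_window <- ses$decision_window
    trials <- data.frame(trial_id = vapply(ses$trials, `[[`, 1, "trial_id"),
                         cs_label = vapply(ses$trials, `[[`, "", "cs_label"))
    trials$lick_times <- lapply(ses$trials, `[[`, "lick_times")
  }
  if (is.null(trials$lick_times)) stop("missing lick channel (`lick_times`)")
  if (is.null(decision_window))
    decision_window <- odor_onset + odor_dur + c(0.5, 2.0)
  out <- lapply(seq_len(nrow(trials)), function(i) {
    licks <- trials$lick_times[[i]]
    lab <- trials$cs_label[i]
    in_dec <- any(licks >= decision_window[1] & licks < decision_window[2])
    after_onset <- licks[licks >= odor_onset]
    outcome <- if (is.na(lab) || lab == "excluded") NA_character_
    else if (lab == "CSplus") { if (in_dec) "hit" else "miss" }
    else { if (in_dec) "false_alarm" else "correct_rejection" }
    data.frame(trial_id = trials$trial_id[i], cs_label = lab,
               licked_in_decision = in_dec, outcome = outcome,
               first_lick_time = if (length(after_onset))
                 min(after_onset) - odor_onset else NA_real_,
               n_anticipatory = sum(licks >= odor_onset &
                                      licks < decision_window[1]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Session hit rate, false-alarm rate and performance
#'
#' Performance bookkeeping with engagement trimming: all trials up to and
#' including the fourth hit are discarded (by default the fourth cumulative
#' hit, not necessarily consecutive; both readings coincide on sessions that
#' open with a high-intermittency engagement block). `HR` is hits over CS+
#' trials, `FA` false alarms over CS- trials, performance their difference.
#' The learning criterion is strict: `HR > 0.75` and `FA < 0.25`. Excluded
#' trials (intermittency in the CS band gap) are dropped.
#'
#' @param outcomes data.frame from [score_trials()].
#' @param engagement_rule trim up to the fourth hit before computing rates.
#' @param hit_mode `"cumulative"` (default) or `"consecutive"` fourth-hit
#'   reading.
#' @return list of class `session_metrics`: `HR`, `FA`, `performance`,
#'   `meets_criterion`, `n_trials_used`, `n_cs_plus`, `n_cs_minus`.
#' @export
session_metrics <- function(outcomes, engagement_rule = TRUE,
                            hit_mode = c("cumulative", "consecutive")) {
  hit_mode <- match.arg(hit_mode)
  o <- outcomes[!is.na(outcomes$outcome), , drop = FALSE]
  if (engagement_rule) {
    is_hit <- o$outcome == "hit"
    cut <- if (hit_mode == "cumulative") {
      w <- which(cumsum(is_hit) >= 4)
      if (length(w)) w[1] else nrow(o)
    } else {
      r <- rle(is_hit)
      ends <- cumsum(r$lengths)
      w <- which(r$values & r$lengths >= 4)
      if (length(w)) ends[w[1]] - (r$lengths[w[1]] - 4) else nrow(o)
    }
    o <- o[seq_len(nrow(o)) > cut, , drop = FALSE]
  }
  n_plus <- sum(o$cs_label == "CSplus")
  n_minus <- sum(o$cs_label == "CSminus")
  if (n_plus == 0L || n_minus == 0L) {
    warning("no CS+ or no CS- trials after trimming; metrics undefined")
    return(structure(list(HR = NA_real_, FA = NA_real_,
                          performance = NA_real_, meets_criterion = NA,
                          n_trials_used = nrow(o), n_cs_plus = n_plus,
                          n_cs_minus = n_minus),
                     class = "session_metrics"))
  }
  HR <- sum(o$outcome == "hit") / n_plus
  FA <- sum(o$outcome == "false_alarm") / n_minus
  structure(list(HR = HR, FA = FA, performance = HR - FA,
                 meets_criterion = HR > 0.75 && FA < 0.25,
                 n_trials_used = nrow(o), n_cs_plus = n_plus,
                 n_cs_minus = n_minus),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> HR %.3f, FA %.3f, performance %.3f (criterion %s; %d trials)\n",
              x$HR, x$FA, x$performance,
              if (isTRUE(x$meets_criterion)) "met" else "not met",
              x$n_trials_used))
  invisible(x)
}

#' First-lick latency vs intermittency
#'
#' Mean first-lick time (from odor onset) per intermittency bin together
#' with an OLS fit of first-lick time on the un-binned intermittency values.
#' Trials without a lick after odor onset are excluded and counted.
#'
#' @param first_lick per-trial first-lick times (s from odor onset; `NA`
#'   allowed).
#' @param gamma per-trial intermittency values (odor or estimated perceived).
#' @param bins bin centers for the binned means.
#' @return list with `binned` (data.frame `gamma_bin`, `mean_first_lick`,
#'   `n`), `slope`, `intercept`, `n_licked`, `n_lick_free`.
#' @export
first_lick_by_intermittency <- function(first_lick, gamma,
                                        bins = seq(0.1, 0.9, by = 0.1)) {
  ok <- is.finite(first_lick) & is.finite(gamma)
  if (!any(ok)) {
    return(list(binned = data.frame(gamma_bin = numeric(0),
                                    mean_first_lick = numeric(0),
                                    n = integer(0)),
                slope = NA_real_, intercept = NA_real_,
                n_licked = 0L, n_lick_free = sum(is.finite(gamma) & !ok)))
  }
  fl <- first_lick[ok]; g <- gamma[ok]
  b <- bins[pmax(1, pmin(length(bins), round((g - bins[1]) / diff(bins[1:2])) + 1))]
  binned <- stats::aggregate(fl, list(gamma_bin = b),
                             function(v) c(mean(v), length(v)))
  binned <- data.frame(gamma_bin = binned$gamma_bin,
                       mean_first_lick = binned$x[, 1],
                       n = as.integer(binned$x[, 2]))
  fit <- if (length(unique(g)) >= 2) stats::lm(fl ~ g) else NULL
  list(binned = binned,
       slope = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[2]),
       intercept = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[1]),
       n_licked = sum(ok), n_lick_free = sum(is.finite(gamma)) - sum(ok))
}

#' Decode trial identity from cumulative perceived intermittency over time
#'
#' For each cutoff time, a single-feature linear discriminant is trained on
#' the cumulative estimated perceived intermittency up to that cutoff to
#' separate CS+ trials of one intermittency bin from all CS- trials, with a
#' shuffled-label control run through the identical pipeline. Accuracies are
#' compared with the control by a two-sample t-test over CV repeats, with
#' Bonferroni correction across cutoffs.
#'
#' @param cum_gamma matrix trials x cutoffs of cumulative perceived
#'   intermittency (e.g. from [cumulative_perceived_intermittency()]).
#' @param labels trial labels (`"CSplus"` / `"CSminus"`).
#' @param gamma_bin_of per-trial intermittency bin (CS+ trials restricted to
#'   one bin at a time; use a constant to pool all CS+).
#' @param t_cutoffs cutoff times (s), one per column of `cum_gamma`.
#' @param min_trials bins with fewer CS+ trials are skipped.
#' @param n_repeats CV repeats.
#' @param seed base seed.
#' @return data.frame with one row per (bin, cutoff): `gamma_bin`,
#'   `t_cutoff`, `accuracy`, `accuracy_shuffled`, `p`, `p_bonferroni`,
#'   `significant`.
#' @export
decode_from_perceived <- function(cum_gamma, labels, gamma_bin_of, t_cutoffs,
                                  min_trials = 5L, n_repeats = 20, seed = 1L) {
  cum_gamma <- as.matrix(cum_gamma)
  stopifnot(ncol(cum_gamma) == length(t_cutoffs),
            nrow(cum_gamma) == length(labels))
  labels <- as.character(labels)
  bins <- sort(unique(gamma_bin_of[labels == "CSplus"]))
  rows <- list()
  for (bv in bins) {
    sel <- (labels == "CSplus" & gamma_bin_of == bv) | labels == "CSminus"
    if (sum(labels[sel] == "CSplus") < min_trials) {
      message(sprintf("skipping bin %s: fewer than %d CS+ trials", bv, min_trials))
      next
    }
    for (j in seq_along(t_cutoffs)) {
      x <- cum_gamma[sel, j]
      ok <- is.finite(x)
      if (sum(ok & labels[sel] == "CSplus") < 3 ||
          sum(ok & labels[sel] == "CSminus") < 3) next
      Xj <- matrix(x[ok], ncol = 1)
      labj <- labels[sel][ok]
      res <- crossval_classify(Xj, labj, n_repeats = n_repeats,
                               seed = derive_seed(seed, "dec", bv, j))
      labs_sh <- with_seed(derive_seed(seed, "dec-shuf", bv, j), sample(labj))
      res_sh <- crossval_classify(Xj, labs_sh, n_repeats = n_repeats,
                                  seed = derive_seed(seed, "dec-shcv", bv, j))
      acc_r <- tapply(res$folds$accuracy, res$folds$repeat_, mean)
      acc_s <- tapply(res_sh$folds$accuracy, res_sh$folds$repeat_, mean)
      p <- tryCatch(stats::t.test(acc_r, acc_s, alternative = "greater")$p.value,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        gamma_bin = bv, t_cutoff = t_cutoffs[j],
        accuracy = res$accuracy, accuracy_shuffled = res_sh$accuracy,
        p = p, p_bonferroni = min(1, p * length(t_cutoffs)),
        significant = is.finite(p) && p * length(t_cutoffs) < 0.05)
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}
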