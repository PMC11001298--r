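#' Mean-GI tuning profiles per glomerulus
#'
#' Averages GI within intermittency bins (0.1 to 0.8 in 0.1 steps by
#' default; trials assigned to the nearest bin within +/- `tol`, out-of-band
#' trials dropped). Rows are glomeruli, columns bins; empty bins are `NA`.
#'
#' @param gi_table data.frame with columns `roi_id`, `gi`, `gamma`.
#' @param bins bin centers.
#' @param tol binning half-width.
#' @return numeric matrix glomeruli x bins with `dimnames`.
#' @export
gi_profiles <- function(gi_table, bins = seq(0.1, 0.8, by = 0.1), tol = 0.05) {
  stopifnot(all(c("roi_id", "gi", "gamma") %in% names(gi_table)))
  b <- bin_gamma(gi_table$gamma, bins, tol)
  ok <- !is.na(b) & is.finite(gi_table$gi)
  rois <- unique(gi_table$roi_id)
  prof <- matrix(NA_real_, length(rois), length(bins),
                 dimnames = list(rois, format(bins)))
  agg <- stats::aggregate(gi ~ roi_id + bin,
                          data = data.frame(roi_id = gi_table$roi_id[ok],
                                            bin = b[ok], gi = gi_table$gi[ok]),
                          FUN = mean)
  for (i in seq_len(nrow(agg)))
    prof[agg$roi_id[i], format(agg$bin[i])] <- agg$gi[i]
  prof
}

#' Inter-glomerular correlation of GI tuning profiles
#'
#' Pearson correlation between every pair of GI-vs-intermittency profiles
#' (pairwise-complete over shared finite bins). Zero-variance profiles cannot
#' be correlated; their rows/columns are `NA` and reported in `excluded`.
#'
#' @param profiles matrix from [gi_profiles()].
#' @return list with `R` (correlation matrix, unit diagonal) and `excluded`
#'   (roi ids of zero-variance profiles).
#' @export
interglomerular_corr <- function(profiles) {
  if (nrow(profiles) < 2L) stop("need >= 2 profiles")
  sds <- apply(profiles, 1, stats::sd, na.rm = TRUE)
  degenerate <- !is.finite(sds) | sds == 0
  R <- suppressWarnings(stats::cor(t(profiles), use = "pairwise.complete.obs"))
  R[degenerate, ] <- NA_real_
  R[, degenerate] <- NA_real_
  diag(R) <- 1
  list(R = R, excluded = rownames(profiles)[degenerate])
}

#' Cluster glomeruli by correlation distance
#'
#' Agglomerative clustering on the distance `d = 1 - r` between GI tuning
#' profiles, cut at the given height (default 0.74). Profiles flagged `NA` in
#' the correlation matrix are excluded before clustering. The default single
#' linkage matches the classical linkage default; average linkage is
#' available via `method`.
#'
#' @param R correlation matrix from [interglomerular_corr()].
#' @param cutoff tree cut height on the `1 - r` scale.
#' @param method linkage method (`"single"` or `"average"`).
#' @return list with `cluster` (named integer vector), `tree` (an `hclust`),
#'   `n_clusters`.
#' @export
hierarchical_cluster <- function(R, cutoff = 0.74, method = c("single", "average")) {
  method <- match.arg(method)
  if (is.list(R) && !is.null(R$R)) R <- R$R
  keep <- rowSums(is.na(R)) < ncol(R) - 1L
  R <- R[keep, keep, drop = FALSE]
  if (nrow(R) == 0L) stop("no valid profiles to cluster")
  if (nrow(R) == 1L) {
    cl <- stats::setNames(1L, rownames(R))
    return(list(cluster = cl, tree = NULL, n_clusters = 1L))
  }
  d <- stats::as.dist(1 - R)
  tree <- stats::hclust(d, method = method)
  cl <- stats::cutree(tree, h = cutoff)
  list(cluster = cl, tree = tree, n_clusters = length(unique(cl)))
}

# ---- linear discriminant with pooled covariance and equal priors ----------

lda_fit <- function(X, y) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  k <- length(classes)
  p <- ncol(X)
  n <- nrow(X)
  means <- do.call(rbind, lapply(classes, function(c0)
    colMeans(X[y == c0, , drop = FALSE])))
  S <- matrix(0, p, p)
  for (c0 in classes) {
    Xc <- scale(X[y == c0, , drop = FALSE], center = TRUE, scale = FALSE)
    S <- S + crossprod(Xc)
  }
  S <- S / max(1, n - k)
  # ridge regularization when the pooled covariance is singular/ill-conditioned
  if (p > 0) {
    ev <- tryCatch(rcond(S), error = function(e) 0)
    if (!is.finite(ev) || ev < 1e-10 || n - k <= p) {
      S <- S + diag(1e-6 * sum(diag(S)) / p + 1e-12, p)
    }
  }
  Sinv <- solve(S)
  list(classes = classes, means = means, Sinv = Sinv)
}

lda_predict <- function(fit, X) {
  X <- as.matrix(X)
  scores <- vapply(seq_along(fit$classes), function(j) {
    m <- fit$means[j, ]
    drop(X %*% (fit$Sinv %*% m)) - 0.5 * drop(t(m) %*% fit$Sinv %*% m)
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

# stratified partition of indices into n_folds folds
stratified_folds <- function(strata, n_folds) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

#' Cross-validated linear-discriminant classification of trials
#'
#' Repeated threefold cross-validation: in each repeat, trials are
#' partitioned into three folds stratified by intermittency value (equal
#' sampling of each value per fold); the classifier is trained on one third
#' and tested on the remaining two thirds, exactly as specified (the reverse
#' of the conventional split). The linear discriminant uses class means and a
#' pooled covariance (ridge-regularized when singular) with equal priors.
#' Accuracy is correct predictions over test trials; the true-positive rate
#' is correctly predicted CS+ over CS+ test trials.
#'
#' @param X feature matrix, trials x glomeruli (e.g. GI values).
#' @param labels class labels per trial (e.g. `"CSplus"` / `"CSminus"`, or
#'   intermittency classes for the anesthetized variant).
#' @param strata stratification values per trial (defaults to `labels`);
#'   typically the nominal intermittency value.
#' @param n_folds,n_repeats cross-validation design (3-fold, 20 repeats).
#' @param positive label counted for the true-positive rate.
#' @param seed base seed; each repeat uses a derived sub-seed.
#' @return list of class `classifier_result`: `folds` (data.frame `repeat_`,
#'   `fold`, `accuracy`, `tpr`), `accuracy`, `accuracy_se`, `tpr`, `tpr_se`,
#'   `n_features`.
#' @export
crossval_classify <- function(X, labels, strata = NULL, n_folds = 3,
                              n_repeats = 20, positive = "CSplus", seed = 1L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need >= 2 classes")
  if (min(table(labels)) < n_folds)
    stop("each class needs at least `n_folds` trials")
  if (is.null(strata)) strata <- labels
  strata <- paste(labels, strata)   # stratify jointly on label and gamma
  if (ncol(X) == 0L) {
    # prior-only classifier: no features, predict at chance
    acc <- max(table(labels)) / length(labels)
    folds <- data.frame(repeat_ = rep(seq_len(n_repeats), each = n_folds),
                        fold = rep(seq_len(n_folds), n_repeats),
                        accuracy = acc, tpr = NA_real_)
    return(structure(list(folds = folds, accuracy = acc, accuracy_se = 0,
                          tpr = NA_real_, tpr_se = NA_real_, n_features = 0L),
                     class = "classifier_result"))
  }
  rows <- vector("list", n_repeats * n_folds)
  ri <- 0L
  for (rep_i in seq_len(n_repeats)) {
    fold <- with_seed(derive_seed(seed, "cvfold", rep_i), {
      f <- stratified_folds(strata, n_folds)
      # re-draw if a training fold misses a class entirely
      tries <- 0L
      while (tries < 20L &&
             any(vapply(seq_len(n_folds), function(k)
               length(unique(labels[f == k])) < length(unique(labels)),
               logical(1)))) {
        f <- stratified_folds(strata, n_folds)
        tries <- tries + 1L
      }
      f
    })
    for (k in seq_len(n_folds)) {
      train <- fold == k          # train on one third
      test <- !train              # test on the other two thirds
      fit <- lda_fit(X[train, , drop = FALSE], labels[train])
      pred <- lda_predict(fit, X[test, , drop = FALSE])
      truth <- labels[test]
      acc <- mean(pred == truth)
      tpr <- if (positive %in% truth)
        sum(pred == positive & truth == positive) / sum(truth == positive)
      else NA_real_
      ri <- ri + 1L
      rows[[ri]] <- data.frame(repeat_ = rep_i, fold = k,
                               accuracy = acc, tpr = tpr)
    }
  }
  folds <- do.call(rbind, rows)
  rep_acc <- tapply(folds$accuracy, folds$repeat_, mean)
  rep_tpr <- tapply(folds$tpr, folds$repeat_, mean)
  structure(list(folds = folds,
                 accuracy = mean(rep_acc),
                 accuracy_se = stats::sd(rep_acc) / sqrt(length(rep_acc)),
                 tpr = mean(rep_tpr),
                 tpr_se = stats::sd(rep_tpr) / sqrt(length(rep_tpr)),
                 n_features = ncol(X)),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> accuracy %.3f +/- %.3f (SE), TPR %s, %d features\n",
              x$accuracy, x$accuracy_se,
              if (is.na(x$tpr)) "NA" else sprintf("%.3f", x$tpr),
              x$n_features))
  invisible(x)
}

#' Decoding accuracy as a function of the number of glomeruli
#'
#' Repeats [crossval_classify()] over increasing glomerulus counts, drawing
#' features per the requested ordering: `"random"` (a fresh random subset per
#' count), `"top_slope"` / `"bottom_slope"` (|GI slope| ranking, quartile
#' boundaries computed on the session's own slopes).
#'
#' @param X feature matrix trials x glomeruli.
#' @param labels trial labels.
#' @param ns glomerulus counts to evaluate (values exceeding the pool are
#'   truncated with a warning).
#' @param ordering feature ordering rule.
#' @param slopes per-glomerulus GI slopes (required for slope orderings).
#' @param strata stratification values passed to [crossval_classify()].
#' @param n_repeats CV repeats per count.
#' @param seed base seed.
#' @return data.frame with `n_glomeruli`, `accuracy`, `accuracy_se`, `tpr`.
#' @export
glomerulus_curves <- function(X, labels, ns = c(0, 5, 10, 15, 20, 25),
                              ordering = c("random", "top_slope", "bottom_slope"),
                              slopes = NULL, strata = NULL, n_repeats = 20,
                              seed = 1L) {
  ordering <- match.arg(ordering)
  X <- as.matrix(X)
  if (ordering != "random" && is.null(slopes))
    stop("slope orderings require `slopes`")
  if (any(ns > ncol(X))) {
    warning("requested more glomeruli than available; truncating")
    ns <- unique(pmin(ns, ncol(X)))
  }
  rank_idx <- switch(ordering,
    random = NULL,
    top_slope = order(abs(slopes), decreasing = TRUE),
    bottom_slope = order(abs(slopes), decreasing = FALSE))
  out <- lapply(ns, function(n) {
    cols <- if (n == 0L) integer(0)
    else if (is.null(rank_idx))
      with_seed(derive_seed(seed, "curve", ordering, n),
                sample(ncol(X), n))
    else rank_idx[seq_len(n)]
    res <- crossval_classify(X[, cols, drop = FALSE], labels, strata = strata,
                             n_repeats = n_repeats,
                             seed = derive_seed(seed, "curve-cv", ordering, n))
    data.frame(n_glomeruli = n, accuracy = res$accuracy,
               accuracy_se = res$accuracy_se, tpr = res$tpr)
  })
  do.call(rbind, out)
}
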