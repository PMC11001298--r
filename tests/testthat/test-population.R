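test_that("profile correlations behave for identical, negated and planted profiles", {
  prof <- rbind(a = seq(0.1, 0.8, by = 0.1),
                b = seq(0.1, 0.8, by = 0.1),
                c = 0.9 - seq(0.1, 0.8, by = 0.1))
  ic <- interglomerular_corr(prof)
  expect_equal(ic$R["a", "b"], 1)
  expect_equal(ic$R["a", "c"], -1)
  expect_equal(diag(ic$R), c(a = 1, b = 1, c = 1))
  flat <- rbind(prof, d = rep(0.5, 8))
  ic2 <- interglomerular_corr(flat)
  expect_equal(ic2$excluded, "d")
  expect_true(all(is.na(ic2$R["d", c("a", "b", "c")])))
  expect_error(interglomerular_corr(prof[1, , drop = FALSE]), ">= 2")
})

test_that("clustering cutoff limits: singletons at 0, one cluster at 2", {
  set.seed(2)
  prof <- matrix(runif(40), 5, 8, dimnames = list(letters[1:5], NULL))
  R <- interglomerular_corr(prof)$R
  expect_equal(hierarchical_cluster(R, cutoff = 1e-9)$n_clusters, 5L)
  expect_equal(hierarchical_cluster(R, cutoff = 2)$n_clusters, 1L)
  allsame <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(hierarchical_cluster(allsame, 0.74)$n_clusters, 1L)
})

test_that("clustering is invariant to glomerulus input order", {
  fx <- cluster_fixture()
  prof <- gi_profiles(fx$result$gi)
  R <- interglomerular_corr(prof)$R
  cl1 <- hierarchical_cluster(R, 0.74)$cluster
  perm <- with_seed_test(5, sample(nrow(R)))
  cl2 <- hierarchical_cluster(R[perm, perm], 0.74)$cluster
  # same partition up to label names
  expect_equal(unname(cl2[names(cl1)] == cl2[names(cl1)][1]),
               unname(cl1 == cl1[1]))
})

test_that("two planted populations separate into exactly two clusters", {
  fx <- cluster_fixture()
  prof <- gi_profiles(fx$result$gi)
  hc <- hierarchical_cluster(interglomerular_corr(prof), 0.74)
  expect_equal(hc$n_clusters, 2L)
  truth <- fx$glomeruli$cluster[match(names(hc$cluster), fx$glomeruli$roi_id)]
  tab <- table(hc$cluster, truth)
  agree <- max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
  expect_gte(agree, 0.95)
  # recovered sizes within 5% of the planted 37 / 191 split
  sizes <- sort(as.integer(table(hc$cluster)))
  expect_lte(abs(sizes[1] - 37) / 228, 0.05)
  expect_lte(abs(sizes[2] - 191) / 228, 0.05)
  # planted phenotypes anti-correlate across clusters
  i1 <- which(truth == 1)[1:3]; i2 <- which(truth == 2)[1:3]
  R <- interglomerular_corr(prof)$R
  expect_true(all(R[i1, i2] < 0))
})

test_that("the linear discriminant agrees with a reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(3)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 2), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  fit <- odorint:::lda_fit(X, y)
  pred <- odorint:::lda_predict(fit, X)
  ref <- as.character(predict(MASS::lda(X, grouping = y,
                                        prior = c(0.5, 0.5)), X)$class)
  expect_equal(pred, ref)
})

test_that("accuracy and TPR formulas reproduce hand counts on a worked table", {
  # 10 test trials, single perfectly separating feature, known predictions
  X <- matrix(c(0.9, 0.8, 0.85, 0.75, 0.7, 0.2, 0.1, 0.15, 0.25, 0.65), ncol = 1)
  y <- c(rep("CSplus", 5), rep("CSminus", 5))
  fit <- odorint:::lda_fit(X[c(1, 6), , drop = FALSE], y[c(1, 6)])
  pred <- odorint:::lda_predict(fit, X)
  # nearest-class-mean boundary at 0.55: trial 10 (0.65, CSminus) is the one error
  expect_equal(sum(pred == y), 9L)
  acc <- sum(pred == y) / length(y)
  tpr <- sum(pred == "CSplus" & y == "CSplus") / sum(y == "CSplus")
  expect_equal(acc, 0.9)
  expect_equal(tpr, 1)
})

test_that("cross-validated decoding: separable data, chance floors, folds", {
  set.seed(8)
  X <- matrix(c(rnorm(30, 5, 0.1), rnorm(30, 0, 0.1)), ncol = 1)
  y <- rep(c("CSplus", "CSminus"), each = 30)
  res <- crossval_classify(X, y, n_repeats = 5, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_equal(res$tpr, 1)
  expect_equal(nrow(res$folds), 15L)   # repeats x folds evaluations
  # no features: prior-only classifier sits at chance
  res0 <- crossval_classify(X[, 0, drop = FALSE], y, n_repeats = 5, seed = 1)
  expect_equal(res0$accuracy, 0.5)
  expect_error(crossval_classify(X, rep("a", 60)), "2 classes")
})

test_that("planted separable session decodes at high accuracy; shuffles at chance", {
  fx <- decode_fixture()
  cv <- crossval_classify(fx$X, fx$labels, strata = round(fx$gamma, 1), seed = 42)
  expect_gte(cv$accuracy, 0.95)
  expect_equal(nrow(cv$folds), 60L)
  accs <- vapply(1:12, function(k) {
    labs <- with_seed_test(300 + k, sample(fx$labels))
    crossval_classify(fx$X, labs, strata = round(fx$gamma, 1),
                      n_repeats = 3, seed = 600 + k)$accuracy
  }, numeric(1))
  sem <- stats::sd(accs) / sqrt(length(accs))
  expect_lte(abs(mean(accs) - 0.5), 3 * sem)
})

test_that("accuracy grows with glomerulus count and slope-ranked ordering wins", {
  fx <- decode_fixture()
  slopes <- fx$result$slopes$slope[match(colnames(fx$X), fx$result$slopes$roi_id)]
  top <- glomerulus_curves(fx$X, fx$labels, ns = c(0, 4, 12, 25),
                           ordering = "top_slope", slopes = slopes,
                           strata = round(fx$gamma, 1), n_repeats = 5, seed = 2)
  bot <- glomerulus_curves(fx$X, fx$labels, ns = c(4, 12),
                           ordering = "bottom_slope", slopes = slopes,
                           strata = round(fx$gamma, 1), n_repeats = 5, seed = 2)
  expect_equal(top$accuracy[top$n_glomeruli == 0], 0.5)
  # monotone non-decreasing within CV noise
  expect_true(all(diff(top$accuracy) > -0.05))
  for (n in c(4, 12))
    expect_gte(top$accuracy[top$n_glomeruli == n] + 0.05,
               bot$accuracy[bot$n_glomeruli == n])
  expect_warning(glomerulus_curves(fx$X, fx$labels, ns = 40,
                                   strata = round(fx$gamma, 1),
                                   n_repeats = 2, seed = 3), "truncating")
})
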