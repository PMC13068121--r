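test_that("ROC/AUC agrees with the exhaustive concordance oracle and pROC", {
  cases <- list(
    list(s = c(2, 3, 0, 1), y = c(1, 1, -1, -1)),
    list(s = c(0.9, 0.4, 0.5, 0.1), y = c(1, 1, -1, -1)),
    list(s = rep(1, 6), y = rep(c(1, -1), 3)))
  expect_equal(roc_curve(cases[[1]]$s, cases[[1]]$y)$auc, 1)
  expect_equal(roc_curve(cases[[2]]$s, cases[[2]]$y)$auc, 0.75)
  expect_equal(roc_curve(cases[[3]]$s, cases[[3]]$y)$auc, 0.5)
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(6:40, 1)
    y <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
    s <- round(rnorm(n), sample(0:2, 1))  # induce ties
    r <- roc_curve(s, y)
    expect_equal(r$auc, oracle_auc(s, y), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- pROC::roc(response = y, predictor = s, levels = c(-1, 1),
                      direction = "<", quiet = TRUE)
      expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    }
    # sweep points are monotone
    expect_true(all(diff(r$sensitivity) >= 0))
    expect_true(all(diff(1 - r$specificity) >= 0))
  }
  expect_error(roc_curve(c(1, 2), c(1, 1)), "both classes")
})

test_that("Youden operating point maximizes J with the documented tie-break", {
  r <- roc_curve(c(2, 3, 0, 1), c(1, 1, -1, -1))
  oop <- optimal_operating_point(r)
  expect_equal(oop$youden, 1)
  expect_equal(oop$sensitivity, 1)
  expect_equal(oop$specificity, 1)
  # a point with sensitivity 1 and specificity 0.88 has J = 0.88
  expect_equal(1 + 0.88 - 1, 0.88)
  # ties resolved toward higher sensitivity
  r2 <- roc_curve(c(3, 2, 1, 0), c(1, -1, 1, -1))  # J ties
  oop2 <- optimal_operating_point(r2)
  alt_j <- r2$sensitivity + r2$specificity - 1
  expect_equal(oop2$youden, max(alt_j))
  expect_equal(oop2$sensitivity,
               max(r2$sensitivity[alt_j == max(alt_j)]))
})

test_that("LOOCV is deterministic and separates a strong synthetic signal", {
  lst <- make_feature_matrix(n = 24, p = 3, delta = 4, seed = 2)
  sc1 <- loocv_scores(lst$X, lst$y)
  sc2 <- loocv_scores(lst$X, lst$y)
  expect_identical(sc1, sc2)
  expect_true(all(sc1$pred == sc1$truth))
  expect_equal(roc_curve(sc1)$auc, 1)
  expect_equal(lpo_auc(lst$X, lst$y), 1)
  # duplicated patients with identical labels get identical scores
  X2 <- rbind(lst$X, lst$X[1, , drop = FALSE])
  rownames(X2) <- c(rownames(lst$X), "dup")
  sc3 <- loocv_scores(X2, c(lst$y, lst$y[1]))
  expect_equal(sc3$score[25], sc3$score[1], tolerance = 1e-8)
})

test_that("permuted labels give near-chance cross-validated AUC", {
  lst <- make_feature_matrix(n = 68, p = 2, delta = 3, seed = 6)
  set.seed(99)
  yperm <- sample(lst$y)
  a <- lpo_auc(lst$X, yperm, features = "m1")
  expect_gt(a, 0.3)
  expect_lt(a, 0.7)
})

test_that("the three classifier families agree on a separable problem", {
  lst <- make_feature_matrix(n = 20, p = 2, delta = 4, seed = 3)
  cmp <- compare_classifiers(lst$X, lst$y)
  expect_setequal(cmp$family, c("logistic", "naive_bayes", "linear_svm"))
  expect_true(all(cmp$auc > 0.95))
  expect_true(all(cmp$accuracy > 0.9))
})

test_that("bootstrap CI is seeded, stable and tight for a perfect AUC", {
  lst <- make_feature_matrix(n = 68, p = 1, delta = 6, seed = 4)
  sc <- loocv_scores(lst$X, lst$y)
  ci <- auc_ci(sc, n_boot = 500, seed = 7)
  expect_identical(ci, auc_ci(sc, n_boot = 500, seed = 7))
  expect_gte(ci[1], 0.9)
  expect_lte(ci[1], ci[2])
  # stability in n_boot
  set.seed(1)
  s <- rnorm(60); y <- rep(c(1, -1), 30)
  c1 <- auc_ci(s, y, n_boot = 2000, seed = 5)
  c2 <- auc_ci(s, y, n_boot = 4000, seed = 5)
  expect_lt(max(abs(c1 - c2)), 0.02)
})

test_that("SVM weight ranking finds the informative metric", {
  hits <- 0
  for (s in 1:10) {
    lst <- make_feature_matrix(n = 40, p = 4, delta = 2.5, seed = s,
                               informative = 2)
    rk <- svm_feature_ranking(lst$X, lst$y)
    if (rk$metric[1] == "m2") hits <- hits + 1
  }
  expect_gte(hits, 9)
  # duplicated informative metric occupies the top two ranks
  lst <- make_feature_matrix(n = 40, p = 3, delta = 3, seed = 5)
  X <- cbind(lst$X, dup = lst$X[, 1])
  rk <- svm_feature_ranking(X, lst$y)
  expect_setequal(rk$metric[1:2], c("m1", "dup"))
  # flipping a metric's sign leaves |weight| and rank unchanged
  Xf <- lst$X; Xf[, 1] <- -Xf[, 1]
  r1 <- svm_feature_ranking(lst$X, lst$y)
  r2 <- svm_feature_ranking(Xf, lst$y)
  expect_equal(r2$metric, r1$metric)
  expect_equal(abs(r2$weight), abs(r1$weight), tolerance = 1e-6)
})

test_that("stepwise traces are consistent and tolerate noise metrics", {
  lst <- make_feature_matrix(n = 30, p = 4, delta = 3, seed = 12)
  rk <- svm_feature_ranking(lst$X, lst$y)
  tr <- stepwise_auc(lst$X, lst$y, rk, n_boot = 200, seed = 1)
  expect_equal(nrow(tr), 4)
  expect_equal(tr$auc[1],
               lpo_auc(lst$X, lst$y, features = rk$metric[1]))
  # adding pure-noise metrics after the informative one never collapses AUC
  expect_true(all(tr$auc >= max(tr$auc) - 0.05))
  expect_true(attr(tr, "plateau_k") >= 1)
  # two strong metrics: combined at least close to the best univariate
  lst2 <- make_feature_matrix(n = 30, p = 2, delta = 2, seed = 13)
  lst2$X[, 2] <- lst2$X[, 2] + 2 * lst2$y
  a12 <- lpo_auc(lst2$X, lst2$y)
  a1 <- max(lpo_auc(lst2$X, lst2$y, features = "m1"),
            lpo_auc(lst2$X, lst2$y, features = "m2"))
  expect_gte(a12, a1 - 0.01)
})

test_that("paired bootstrap comparison behaves at the extremes", {
  lst <- make_feature_matrix(n = 68, p = 1, delta = 5, seed = 21)
  sc_good <- loocv_scores(lst$X, lst$y)
  expect_equal(paired_bootstrap_auc_test(sc_good, sc_good,
                                         n_boot = 200, seed = 3)$p, 1)
  set.seed(4)
  null_scores <- rnorm(68)
  res <- paired_bootstrap_auc_test(sc_good$score_cal, null_scores,
                                   labels = lst$y, n_boot = 500, seed = 5)
  expect_lt(res$p, 0.01)
  expect_gt(res$auc_a, res$auc_b)
})

test_that("grouped models validate their groups and report per-group ROCs", {
  lst <- make_feature_matrix(n = 24, p = 4, delta = 3, seed = 31)
  colnames(lst$X) <- c("rlll", "ralp", "cvemp_ar", "ovemp_ar")
  res <- grouped_models(lst$X, lst$y,
                        groups = list(canal = c("rlll", "ralp"),
                                      otolith = c("cvemp_ar", "ovemp_ar")),
                        n_boot = 100)
  expect_named(res, c("canal", "otolith"))
  expect_gt(res$canal$auc, 0.9)  # informative metric is rlll
  expect_error(grouped_models(lst$X, lst$y,
                              groups = list(canal = character())),
               "non-empty")
})

test_that("label-and-feature mirror flips predictions but not AUCs", {
  lst <- make_feature_matrix(n = 26, p = 3, delta = 1.5, seed = 41)
  sc <- loocv_scores(lst$X, lst$y)
  sc_m <- loocv_scores(-lst$X, -lst$y)
  expect_equal(sc_m$score, -sc$score, tolerance = 1e-8)
  nz <- abs(sc$score) > 1e-10
  expect_equal(sc_m$pred[nz], -sc$pred[nz])
  expect_equal(roc_curve(sc_m)$auc, roc_curve(sc)$auc, tolerance = 1e-10)
  expect_equal(lpo_auc(-lst$X, -lst$y), lpo_auc(lst$X, lst$y),
               tolerance = 1e-10)
})

test_that("degenerate folds and inputs raise the documented errors", {
  lst <- make_feature_matrix(n = 8, p = 2, delta = 1, seed = 51)
  expect_error(loocv_scores(lst$X[1:3, ], lst$y[1:3]), "n >= 4")
  expect_error(loocv_scores(lst$X, rep(1, 8)), "both classes")
  expect_error(loocv_scores(lst$X, lst$y, features = "nope"), "unknown")
  y_single <- c(1, rep(-1, 7))
  expect_warning(sc <- loocv_scores(lst$X, y_single), "single training class")
  expect_true(is.na(sc$score[1]))
})
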