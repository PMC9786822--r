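# Fold construction, metric arithmetic, fold CIs, DeLong's test (with both a
# direct placement oracle and pROC as independent cross-checks), feature-set
# assembly, and a small nested CV.

test_that("stratified folds balance classes and partition the data", {
  y <- c(rep(1, 10), rep(0, 10))
  f <- stratified_kfold(y, 5, seed = 1)
  for (k in 1:5) {
    expect_equal(sum(y[f == k] == 1), 2)
    expect_equal(sum(y[f == k] == 0), 2)
  }
  expect_setequal(seq_along(y), unlist(lapply(1:5, function(k) which(f == k))))
  expect_identical(f, stratified_kfold(y, 5, seed = 1))
  expect_error(stratified_kfold(c(1, 1, 1, 0), 3, seed = 1), "at least k")
})

test_that("confusion metrics match hand arithmetic (TP3 FN1 TN5 FP1)", {
  labels <- c(rep(1, 4), rep(0, 6))
  scores <- c(0.9, 0.8, 0.7, 0.2,   # 3 TP, 1 FN
              0.6, 0.1, 0.2, 0.3, 0.1, 0.4)  # 1 FP, 5 TN
  m <- binary_metrics(labels, scores)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 5 / 6)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["accuracy"]), 0.8)
})

test_that("midrank AUC: pair counting, perfect separation, ties", {
  expect_equal(unname(binary_metrics(c(1, 1, 0, 0),
                                     c(0.9, 0.2, 0.3, 0.4))["auc"]), 0.5)
  expect_equal(unname(binary_metrics(c(1, 1, 0, 0),
                                     c(0.9, 0.8, 0.3, 0.4))["auc"]), 1)
  expect_equal(strokeradiomics:::.auc_midrank(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(binary_metrics(c(1, 1), c(0.2, 0.3)), "one class")
})

test_that("fold CIs follow the t-interval formula", {
  expect_equal(fold_ci(c(0.7, 0.7, 0.7)), c(mean = 0.7, lower = 0.7, upper = 0.7))
  ci2 <- fold_ci(c(0, 1))
  expect_equal(unname(ci2["mean"]), 0.5)
  expect_equal(unname(ci2["upper"] - ci2["mean"]),
               unname(ci2["mean"] - ci2["lower"]))
  v <- c(0.6, 0.7, 0.8, 0.7, 0.7)
  ci <- fold_ci(v)
  expect_equal(unname(ci["mean"]), 0.7)
  half <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(unname(ci["upper"]), 0.7 + half)
  expect_error(fold_ci(0.5), ">= 2 folds")
})

test_that("identical score vectors give AUC difference 0 and p = 1", {
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(0.9, 0.6, 0.4, 0.5, 0.3, 0.1)
  dl <- delong_test(s, s, y)
  expect_equal(dl$auc_a, dl$auc_b)
  expect_equal(dl$p, 1)
})

test_that("the worked 4-sample comparison matches the placement oracle", {
  y <- c(1, 1, 0, 0)
  a <- c(0.9, 0.8, 0.1, 0.2)
  b <- c(0.9, 0.1, 0.8, 0.2)
  dl <- delong_test(a, b, y)
  expect_equal(dl$auc_a, 1)
  expect_equal(dl$auc_b, 0.5)
  ob <- oracle_delong(a, b, y)
  expect_equal(dl$var_diff, ob$var_diff, tolerance = 1e-10)
  expect_equal(dl$p, ob$p, tolerance = 1e-10)
})

test_that("DeLong agrees with the all-pairs oracle and pROC on random data", {
  skip_if_not_installed("pROC")
  for (s in 1:10) {
    set.seed(s)
    n <- sample(12:30, 1)
    y <- c(rep(1, ceiling(n / 2)), rep(0, floor(n / 2)))
    a <- rnorm(n) + y; b <- rnorm(n) + 0.5 * y
    if (s %% 3 == 0) a <- round(a, 1)   # induce ties sometimes
    dl <- delong_test(a, b, y)
    ob <- oracle_delong(a, b, y)
    expect_equal(dl$var_diff, ob$var_diff, tolerance = 1e-10)
    expect_equal(dl$p, ob$p, tolerance = 1e-10)
    rt <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                         pROC::roc(y, b, quiet = TRUE, direction = "<"),
                         method = "delong")
    expect_equal(dl$p, unname(rt$p.value), tolerance = 1e-8)
  }
})

test_that("mismatched lengths and one-class labels are rejected", {
  expect_error(delong_test(c(1, 2), c(1, 2, 3), c(1, 0, 1)), "identical length")
  expect_error(delong_test(c(1, 2), c(1, 2), c(1, 1)), "both classes")
})

test_that("feature sets have the documented cardinalities", {
  n <- 6
  dwi <- matrix(rnorm(n * 107), n, 107,
                dimnames = list(NULL, radiomic_feature_names()))
  flair <- matrix(rnorm(n * 107), n, 107,
                  dimnames = list(NULL, radiomic_feature_names()))
  clin <- as.data.frame(matrix(rnorm(n * 23), n, 23))
  names(clin) <- default_clinical_schema()$name
  sets <- build_feature_sets(dwi, flair, clin)
  expect_equal(vapply(sets, ncol, 1L),
               c(DWI = 107L, FLAIR = 107L, imaging = 214L, clinical = 23L,
                 combination = 237L))
  expect_identical(colnames(sets$combination),
                   c(colnames(sets$imaging), colnames(sets$clinical)))
  expect_error(build_feature_sets(dwi[1:3, ], flair, clin), "same number")
})

test_that("nested CV separates a strongly separable problem", {
  set.seed(41)
  n <- 80
  cls <- rep(0:1, n / 2)
  # two well-separated clusters on the signal features, pure noise elsewhere
  X <- cbind(s1 = (2 * cls - 1) * 1.5 + rnorm(n, 0, 0.4),
             s2 = (2 * cls - 1) * 1.5 + rnorm(n, 0, 0.4),
             n1 = rnorm(n), n2 = rnorm(n))
  y <- cls
  res <- nested_cv(X, y, grid = list(hyper_params(max_depth = 3, n_rounds = 30)),
                   config = cv_config(outer_k = 5, inner_k = 3, seed = 2))
  expect_false(anyNA(res$scores))                    # every sample scored once
  expect_equal(sort(unique(res$fold_assignment)), 1:5)
  expect_gt(res$summary["mean", "accuracy"], 0.9)
  expect_gt(res$summary["mean", "auc"], 0.95)
  # the top-ranked feature is a signal feature in every fold (the two signal
  # columns are redundant, so either one may carry the split mass)
  for (f in res$folds) {
    expect_true(f$ranking$feature[1] %in% c("s1", "s2"))
    expect_true(any(c("s1", "s2") %in% f$kept))
  }
})
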