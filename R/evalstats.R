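# Nested stratified cross-validation, the performance metric suite with
# per-fold confidence intervals, DeLong's test for correlated ROC curves, and
# construction of the five feature-set design matrices.

#' Cross-validation configuration
#'
#' @param outer_k outer folds (default 5: each sample is tested exactly once,
#'   20% of the data per test split)
#' @param inner_k inner folds for grid search and feature selection
#' @param seed fold-assignment seed
#' @return a `cv_config` list
#' @export
cv_config <- function(outer_k = 5, inner_k = 5, seed = 1L) {
  if (outer_k < 2 || inner_k < 2) stop("fold counts must be >= 2")
  structure(list(outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
                 seed = as.integer(seed), stratified = TRUE),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals samples round-robin, so per-fold
#' class proportions are within one sample of the global proportions.
#'
#' @param labels class labels
#' @param k number of folds
#' @param seed shuffle seed
#' @return integer vector of fold ids (1..k)
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  classes <- unique(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class must have at least k samples (k = ", k, ")")
  }
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

#' Classification metrics at a threshold, plus midrank AUC
#'
#' Positive class = unfavourable outcome (label 1). Precision falls back to 0
#' when no sample is predicted positive.
#'
#' @param labels 0/1 labels
#' @param scores predicted probabilities/scores
#' @param threshold classification threshold on the score (default 0.5)
#' @return named vector: accuracy, sensitivity, specificity, precision, auc
#' @export
binary_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("AUC undefined: labels contain one class")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    auc = .auc_midrank(labels, scores))
}

# Mann-Whitney AUC via midranks (ties get half credit)
.auc_midrank <- function(labels, scores) {
  m <- sum(labels == 1); n <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' Mean and 95% t-interval over outer-fold metric values
#'
#' @param values metric values, one per fold (>= 2)
#' @return named vector: mean, lower, upper
#' @export
fold_ci <- function(values) {
  k <- length(values)
  if (k < 2) stop("need >= 2 folds for a confidence interval")
  m <- mean(values)
  half <- stats::qt(0.975, k - 1) * stats::sd(values) / sqrt(k)
  c(mean = m, lower = m - half, upper = m + half)
}

# DeLong placement components: V10 (cases), V01 (controls), via midranks
.delong_placements <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  m <- length(cases); n <- length(controls)
  all_r <- rank(c(cases, controls), ties.method = "average")
  rx <- rank(cases, ties.method = "average")
  ry <- rank(controls, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated AUCs
#'
#' Both score vectors must come from the same samples. Uses the fast
#' placement formulation; the degenerate case of zero variance with zero AUC
#' difference returns p = 1 by convention.
#'
#' @param scores_a,scores_b score vectors of the two models
#' @param labels shared 0/1 labels
#' @return list: `auc_a`, `auc_b`, `z`, `p` (two-sided), `var_diff`
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("score and label vectors must have identical length")
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pa <- .delong_placements(scores_a, labels)
  pb <- .delong_placements(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= 1e-300) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p, var_diff = var_diff)
}

#' Build the five feature-set design matrices
#'
#' @param dwi 107-column DWI radiomics matrix/data.frame
#' @param flair 107-column FLAIR radiomics matrix/data.frame
#' @param clinical 23-column clinical data.frame
#' @param ids optional patient ids for each table (list with elements `dwi`,
#'   `flair`, `clinical`); all must match when given
#' @return named list of matrices: `DWI` (107), `FLAIR` (107), `imaging`
#'   (214), `clinical` (23), `combination` (237)
#' @export
build_feature_sets <- function(dwi, flair, clinical, ids = NULL) {
  if (!is.null(ids)) {
    if (!identical(ids$dwi, ids$flair) || !identical(ids$dwi, ids$clinical)) {
      stop("patient ids of the three tables do not match")
    }
  }
  if (nrow(dwi) != nrow(flair) || nrow(dwi) != nrow(clinical)) {
    stop("tables must have the same number of patients")
  }
  dm <- as.matrix(dwi); fm <- as.matrix(flair); cm <- data.matrix(clinical)
  colnames(dm) <- paste0("DWI_", sub("^DWI_", "", colnames(dm)))
  colnames(fm) <- paste0("FLAIR_", sub("^FLAIR_", "", colnames(fm)))
  list(DWI = dm,
       FLAIR = fm,
       imaging = cbind(dm, fm),
       clinical = cm,
       combination = cbind(dm, fm, cm))
}

#' Nested stratified cross-validation with SHAP feature selection
#'
#' For each outer fold: a grid search over `grid` maximises inner-CV
#' accuracy; with the chosen hyperparameters, SHAP attributions are computed
#' on each inner validation fold (fold-trained models) and features with mean
#' |SHAP| of zero are discarded; the model is refit on the full outer
#' training set with the kept features and scored on the held-out outer test
#' fold. SHAP values on the outer test sets are collected for reporting.
#'
#' @param features design matrix (samples x features, NA allowed)
#' @param labels 0/1 outcome labels
#' @param grid list of `hyper_params` (see [default_param_grid()])
#' @param config a [cv_config]
#' @return `nested_cv_result`: per-fold list (`params`, `kept`, `metrics`,
#'   `ranking`), pooled out-of-fold `scores`/`labels`/`fold`, test-set
#'   attribution matrix `test_shap`, per-metric `summary` (mean and 95% CI)
#' @export
nested_cv <- function(features, labels, grid = default_param_grid(),
                      config = cv_config()) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- as.integer(labels)
  outer <- stratified_kfold(labels, config$outer_k, seed = config$seed)
  oof_scores <- rep(NA_real_, length(labels))
  folds_out <- vector("list", config$outer_k)
  test_shap <- matrix(0, length(labels), ncol(X),
                      dimnames = list(NULL, colnames(X)))
  for (f in seq_len(config$outer_k)) {
    tr <- outer != f; te <- outer == f
    Xtr <- X[tr, , drop = FALSE]; ytr <- labels[tr]
    gs <- tryCatch(
      grid_search(Xtr, ytr, grid, inner_k = config$inner_k,
                  seed = derive_seed(config$seed, f)),
      error = function(e) stop("outer fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    best <- gs$best
    # SHAP selection on the inner validation folds, fold-trained models
    inner_attr <- vector("list", config$inner_k)
    for (g in seq_len(config$inner_k)) {
      itr <- gs$folds != g; iva <- gs$folds == g
      fit_g <- fit_ensemble(Xtr[itr, , drop = FALSE], ytr[itr], best)
      inner_attr[[g]] <- tree_shap_matrix(fit_g, Xtr[iva, , drop = FALSE])
    }
    sel <- select_features(inner_attr)
    kept <- sel$kept
    if (length(kept) == 0) kept <- colnames(X)   # degenerate: keep all
    fit <- fit_ensemble(Xtr[, kept, drop = FALSE], ytr, best)
    sc <- predict_proba(fit, X[te, kept, drop = FALSE])
    oof_scores[te] <- sc
    test_shap[te, kept] <- tree_shap_matrix(fit, X[te, kept, drop = FALSE])
    folds_out[[f]] <- list(params = best, kept = kept,
                           metrics = binary_metrics(labels[te], sc),
                           ranking = sel$ranking)
  }
  metr <- t(vapply(folds_out, function(x) x$metrics, numeric(5)))
  summary <- apply(metr, 2, fold_ci)
  structure(list(folds = folds_out, scores = oof_scores, labels = labels,
                 fold_assignment = outer, test_shap = test_shap,
                 summary = summary, config = config),
            class = "nested_cv_result")
}
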