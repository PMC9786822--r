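# Per-prediction feature attributions for the tree ensemble: an exact
# path-dependent TreeSHAP (cover-weighted conditional expectations as the
# value function), a brute-force Shapley oracle by subset enumeration, the
# zero-mean-|SHAP| feature-selection rule used inside the inner CV, and the
# summary export for beeswarm-style reporting. Sign convention, fixed
# pipeline-wide: the positive class is the unfavourable outcome, so positive
# attributions push towards poor outcome.

# cover-weighted conditional expectation of one tree given feature subset S
.expvalue <- function(tree, x32, S) {
  rec <- function(i) {
    if (!is.na(tree$value[i])) return(tree$value[i])
    f <- tree$feature[i]
    if (f %in% S) {
      v <- x32[f]
      j <- if (is.na(v)) tree$miss[i] else if (v < tree$threshold[i]) tree$yes[i] else tree$no[i]
      rec(j)
    } else {
      (tree$cover[tree$yes[i]] * rec(tree$yes[i]) +
       tree$cover[tree$no[i]] * rec(tree$no[i])) / tree$cover[i]
    }
  }
  rec(1L)
}

# the exact path-dependent TreeSHAP kernel lives in src/treeshap.cpp
# (.treeshap_ensemble_cpp); attribution is additive over trees

#' TreeSHAP attribution for one sample
#'
#' Exact Shapley values of the ensemble under the path-dependent
#' (cover-weighted) conditional-expectation value function. Satisfies local
#' accuracy: `base + sum(phi)` equals the model margin.
#'
#' @param model an `ensemble_model`
#' @param sample named numeric vector or 1-row matrix/data.frame matching the
#'   training schema (NA allowed)
#' @return list with `phi` (named per-feature attributions), `base` (expected
#'   margin) and `margin`
#' @export
tree_shap <- function(model, sample) {
  x <- .as_sample_vector(model, sample)
  x32 <- float32(x)
  nf <- length(model$feature_names)
  phi <- .treeshap_ensemble_cpp(model$trees, matrix(x32, nrow = 1), nf)[1, ]
  base <- model$base_margin +
    sum(vapply(model$trees, .expvalue, numeric(1), x32 = x32, S = integer(0)))
  margin <- model$base_margin +
    sum(vapply(model$trees, function(tr) tr$value[.route(tr, x32)], numeric(1)))
  list(phi = stats::setNames(phi, model$feature_names), base = base,
       margin = margin)
}

.as_sample_vector <- function(model, sample) {
  if (is.matrix(sample) || is.data.frame(sample)) {
    X <- .align_features(model, sample)
    if (nrow(X) != 1) stop("sample must be a single row")
    return(X[1, ])
  }
  if (!is.null(names(sample))) {
    miss <- setdiff(model$feature_names, names(sample))
    extra <- setdiff(names(sample), model$feature_names)
    if (length(miss) > 0 || length(extra) > 0) {
      stop("sample schema mismatch; missing: [", paste(miss, collapse = ", "),
           "], unknown: [", paste(extra, collapse = ", "), "]")
    }
    return(as.numeric(sample[model$feature_names]))
  }
  if (length(sample) != length(model$feature_names)) {
    stop("sample length mismatch")
  }
  as.numeric(sample)
}

#' Attributions for every row of a feature matrix
#'
#' @param model an `ensemble_model`
#' @param features matrix/data.frame
#' @return matrix (rows = samples, columns = features) of SHAP values
#' @export
tree_shap_matrix <- function(model, features) {
  X <- .align_features(model, features)
  X32 <- matrix(float32(X), nrow(X), ncol(X))
  nf <- length(model$feature_names)
  out <- .treeshap_ensemble_cpp(model$trees, X32, nf)
  dimnames(out) <- list(NULL, model$feature_names)
  out
}

#' Exact Shapley attribution by subset enumeration (test oracle)
#'
#' Enumerates all 2^d feature subsets of the cover-weighted
#' conditional-expectation game; exponential, so limited to d <= 12.
#'
#' @inheritParams tree_shap
#' @return list with `phi`, `base`, `margin` as in [tree_shap()]
#' @export
brute_force_shapley <- function(model, sample) {
  x <- .as_sample_vector(model, sample)
  x32 <- float32(x)
  d <- length(model$feature_names)
  if (d > 12) stop("brute-force Shapley limited to <= 12 features (2^d subsets)")
  nS <- 2^d
  v <- numeric(nS)
  for (s in 0:(nS - 1)) {
    S <- which(bitwAnd(s, bitwShiftL(1L, 0:(d - 1))) > 0)
    v[s + 1] <- model$base_margin +
      sum(vapply(model$trees, .expvalue, numeric(1), x32 = x32, S = S))
  }
  phi <- numeric(d)
  lw <- lfactorial(0:d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (s in 0:(nS - 1)) {
      if (bitwAnd(s, bit) > 0) next
      k <- sum(bitwAnd(s, bitwShiftL(1L, 0:(d - 1))) > 0)
      w <- exp(lw[k + 1] + lw[d - k] - lw[d + 1])
      phi[i] <- phi[i] + w * (v[s + bit + 1] - v[s + 1])
    }
  }
  list(phi = stats::setNames(phi, model$feature_names), base = v[1],
       margin = model$base_margin +
         sum(vapply(model$trees, function(tr) tr$value[.route(tr, x32)],
                    numeric(1))))
}

#' SHAP-zero feature selection from inner-fold attributions
#'
#' Mean |SHAP| is computed per feature within each inner validation fold and
#' then averaged across folds; features whose average is exactly zero (below
#' 1e-12, to absorb float noise) are discarded. The ranking of the remainder,
#' descending by mean |SHAP|, is returned alongside.
#'
#' @param inner_fold_attributions list of per-fold SHAP matrices
#'   (samples x features), as produced by [tree_shap_matrix()]
#' @return list: `kept` (character), `ranking` (data.frame with `feature`,
#'   `mean_abs_shap`, `mean_shap`, descending by `mean_abs_shap`)
#' @export
select_features <- function(inner_fold_attributions) {
  if (length(inner_fold_attributions) == 0) stop("no attributions supplied")
  per_fold_abs <- vapply(inner_fold_attributions,
                         function(m) colMeans(abs(m)),
                         numeric(ncol(inner_fold_attributions[[1]])))
  per_fold_signed <- vapply(inner_fold_attributions, colMeans,
                            numeric(ncol(inner_fold_attributions[[1]])))
  mean_abs <- rowMeans(per_fold_abs)
  mean_signed <- rowMeans(per_fold_signed)
  feats <- colnames(inner_fold_attributions[[1]])
  keep <- mean_abs > 1e-12
  ord <- order(mean_abs, decreasing = TRUE)
  ranking <- data.frame(feature = feats[ord],
                        mean_abs_shap = unname(mean_abs[ord]),
                        mean_shap = unname(mean_signed[ord]),
                        stringsAsFactors = FALSE)
  list(kept = feats[keep], ranking = ranking[ranking$mean_abs_shap > 1e-12, ])
}

#' Export test-set attributions for beeswarm-style reporting
#'
#' @param attributions SHAP matrix on the outer test sets (samples x features)
#' @param feature_values matching feature-value matrix
#' @return list: `summary` (per feature: mean |SHAP|, descending),
#'   `points` (long table of per-sample (SHAP, value) pairs, features ordered
#'   by impact)
#' @export
summary_export <- function(attributions, feature_values) {
  fv <- as.matrix(feature_values)
  stopifnot(identical(dim(attributions), dim(fv)))
  mean_abs <- colMeans(abs(attributions))
  ord <- order(mean_abs, decreasing = TRUE)
  feats <- colnames(attributions)
  summary <- data.frame(feature = feats[ord], mean_abs_shap = unname(mean_abs[ord]),
                        stringsAsFactors = FALSE)
  points <- data.frame(
    feature = factor(rep(feats, each = nrow(attributions)),
                     levels = feats[ord]),
    sample = rep(seq_len(nrow(attributions)), times = ncol(attributions)),
    shap = as.vector(attributions),
    value = as.vector(fv))
  points <- points[order(points$feature, points$sample), ]
  rownames(points) <- NULL
  list(summary = summary, points = points)
}
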