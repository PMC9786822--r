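#!/usr/bin/env Rscript
# Stage 3: the five feature-set experiments under nested stratified 5-fold CV
# with grid search and SHAP-zero feature selection, then pairwise DeLong
# comparisons against the best model.
#
# Reads results/cohort/clinical.csv and results/features_*.csv, writes
# results/metrics.csv (Table-1-shaped), results/delong.csv (Table-2-shaped),
# results/shap_ranking.csv and results/shap_points.csv.

suppressMessages(library(strokeradiomics))

clin_all <- read.csv("results/cohort/clinical.csv", na.strings = "")
dwi <- as.matrix(read.csv("results/features_dwi.csv", check.names = FALSE))
flair <- as.matrix(read.csv("results/features_flair.csv", check.names = FALSE))
labels <- clin_all$binary
clinical <- clin_all[, setdiff(names(clin_all), c("patient_id", "mrs90", "binary"))]
manifest <- jsonlite::read_json("results/cohort/manifest.json")

sets <- build_feature_sets(dwi, flair, clinical)
cvc <- cv_config(outer_k = 5, inner_k = 5,
                 seed = (manifest$seed * 7919 + 77 * 104729) %% 2147483629)
grid <- default_param_grid()

results <- list()
for (nm in names(sets)) {
  message("nested CV on the ", nm, " set (", ncol(sets[[nm]]), " features)")
  results[[nm]] <- nested_cv(sets[[nm]], labels, grid = grid, config = cvc)
}

fmt <- function(ci) sprintf("%.2f [%.2f, %.2f]", ci["mean"], ci["lower"], ci["upper"])
metrics <- do.call(rbind, lapply(names(results), function(nm) {
  s <- results[[nm]]$summary
  data.frame(feature_set = nm, accuracy = fmt(s[, "accuracy"]),
             sensitivity = fmt(s[, "sensitivity"]),
             specificity = fmt(s[, "specificity"]),
             precision = fmt(s[, "precision"]), auc = fmt(s[, "auc"]),
             auc_mean = s["mean", "auc"])
}))
print(metrics[, c("feature_set", "accuracy", "auc")])

best <- metrics$feature_set[which.max(metrics$auc_mean)]
message("best model by mean outer-fold AUC: ", best)
delong <- do.call(rbind, lapply(setdiff(names(results), best), function(nm) {
  dl <- delong_test(results[[best]]$scores, results[[nm]]$scores, labels)
  data.frame(comparison = paste0(best, "-", nm), auc_ref = dl$auc_a,
             auc_other = dl$auc_b, z = dl$z, p_value = dl$p)
}))
print(delong)

se <- summary_export(results[[best]]$test_shap, sets[[best]])
write.csv(metrics, "results/metrics.csv", row.names = FALSE)
write.csv(delong, "results/delong.csv", row.names = FALSE)
write.csv(se$summary, "results/shap_ranking.csv", row.names = FALSE)
write.csv(se$points, "results/shap_points.csv", row.names = FALSE)
message("evaluation tables written under results/")
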