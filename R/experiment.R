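# End-to-end orchestration: simulate -> preprocess -> extract -> evaluate ->
# report. One global seed fixes the whole run; intermediate artifacts
# (feature tables, fold assignments, reports) are persisted so any stage can
# be re-run in isolation. Volumes can optionally be persisted as NIfTI.

#' Experiment configuration
#'
#' @param cohort a [cohort_config]
#' @param white_stripe a [white_stripe_params]
#' @param radiomics a [radiomics_config]
#' @param grid list of `hyper_params`
#' @param cv a [cv_config]
#' @param target_spacing_mm isotropic resampling target (default 1 mm)
#' @param seed global seed; overrides the seeds of the component configs
#' @return an `experiment_config` (serialises round-trip to JSON)
#' @export
experiment_config <- function(cohort = cohort_config(),
                              white_stripe = white_stripe_params(),
                              radiomics = radiomics_config(),
                              grid = default_param_grid(),
                              cv = cv_config(),
                              target_spacing_mm = 1,
                              seed = 1L) {
  cohort$seed <- as.integer(seed)
  cv$seed <- derive_seed(seed, 77L)
  structure(list(cohort = cohort, white_stripe = white_stripe,
                 radiomics = radiomics, grid = grid, cv = cv,
                 target_spacing_mm = target_spacing_mm,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

config_to_json <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA)
}

#' Preprocess and extract both-modality features for a whole cohort
#'
#' Per patient and modality: resample volume and mask to the isotropic
#' target grid, white-stripe normalise against the full field of view, and
#' extract the 107 radiomic features.
#'
#' @param cohort result of [simulate_cohort()] (or [read_cohort()])
#' @param config an `experiment_config`
#' @param progress print per-patient progress
#' @return list: `dwi` and `flair` 107-column feature matrices
#' @export
extract_cohort_features <- function(cohort, config = experiment_config(),
                                    progress = FALSE) {
  n <- length(cohort$patients)
  fnames <- radiomic_feature_names()
  dwi_tab <- matrix(NA_real_, n, 107, dimnames = list(NULL, fnames))
  flair_tab <- matrix(NA_real_, n, 107, dimnames = list(NULL, fnames))
  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    dwi_tab[i, ] <- .process_one(p$dwi, p$dwi_mask, config)
    flair_tab[i, ] <- .process_one(p$flair, p$flair_mask, config)
    if (progress && i %% 20 == 0) message("  extracted ", i, "/", n, " patients")
  }
  list(dwi = dwi_tab, flair = flair_tab)
}

.process_one <- function(volume, mask, config) {
  rs <- resample_isotropic(volume, mask, config$target_spacing_mm)
  norm <- white_stripe_normalize(rs$volume, brain_mask = NULL,
                                 params = config$white_stripe)
  extract_all(norm, rs$mask, config$radiomics)
}

#' Run the full experiment on a (synthetic) cohort
#'
#' Simulates the cohort, preprocesses and extracts features, runs the nested
#' CV on all five feature sets, compares every other model against the
#' best-AUC model with DeLong's test on the pooled out-of-fold scores, and
#' writes report tables (CSV + JSON) plus a manifest.
#'
#' @param config an `experiment_config`
#' @param out_dir output directory for report artifacts; `NULL` writes
#'   nothing
#' @param cohort optionally, a pre-built cohort (must match the config seed
#'   for reproducibility claims)
#' @param progress print stage progress
#' @return list: `metrics` (Table-1-shaped data.frame), `delong`
#'   (Table-2-shaped data.frame), `ranking` (final SHAP ranking of the best
#'   model), `results` (per-feature-set `nested_cv_result`), `features`,
#'   `cohort`
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           cohort = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(...)
  say("[1/4] simulating cohort (n = ", config$cohort$n_patients, ")")
  if (is.null(cohort)) cohort <- simulate_cohort(config$cohort)
  say("[2/4] preprocessing + feature extraction")
  feats <- extract_cohort_features(cohort, config, progress = progress)
  sets <- build_feature_sets(feats$dwi, feats$flair, cohort$clinical)
  labels <- cohort$outcome$binary
  say("[3/4] nested cross-validation over the five feature sets")
  results <- list()
  for (nm in names(sets)) {
    say("  - ", nm, " set (", ncol(sets[[nm]]), " features)")
    results[[nm]] <- nested_cv(sets[[nm]], labels, grid = config$grid,
                               config = config$cv)
  }
  say("[4/4] reporting")
  metrics <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    data.frame(feature_set = nm,
               accuracy = .fmt_ci(s[, "accuracy"]),
               sensitivity = .fmt_ci(s[, "sensitivity"]),
               specificity = .fmt_ci(s[, "specificity"]),
               precision = .fmt_ci(s[, "precision"]),
               auc = .fmt_ci(s[, "auc"]),
               auc_mean = s["mean", "auc"],
               stringsAsFactors = FALSE)
  }))
  best <- metrics$feature_set[which.max(metrics$auc_mean)]
  others <- setdiff(names(results), best)
  delong <- do.call(rbind, lapply(others, function(nm) {
    dl <- delong_test(results[[best]]$scores, results[[nm]]$scores, labels)
    data.frame(comparison = paste0(best, "-", nm),
               auc_ref = dl$auc_a, auc_other = dl$auc_b,
               z = dl$z, p_value = dl$p, stringsAsFactors = FALSE)
  }))
  se <- summary_export(results[[best]]$test_shap, sets[[best]])
  out <- list(metrics = metrics, delong = delong, ranking = se$summary,
              shap_points = se$points, best = best, results = results,
              features = feats, cohort = cohort, config = config)
  if (!is.null(out_dir)) .write_report(out, out_dir)
  out
}

.fmt_ci <- function(ci) {
  sprintf("%.2f [%.2f, %.2f]", ci["mean"], ci["lower"], ci["upper"])
}

.write_report <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(out$delong, file.path(out_dir, "delong.csv"), row.names = FALSE)
  utils::write.csv(out$ranking, file.path(out_dir, "shap_ranking.csv"), row.names = FALSE)
  utils::write.csv(out$shap_points, file.path(out_dir, "shap_points.csv"), row.names = FALSE)
  fa <- data.frame(sample = seq_along(out$results[[1]]$fold_assignment),
                   lapply(out$results, function(r) r$fold_assignment))
  names(fa) <- c("sample", paste0("fold_", names(out$results)))
  utils::write.csv(fa, file.path(out_dir, "fold_assignment.csv"), row.names = FALSE)
  for (nm in names(out$features)) {
    utils::write.csv(out$features[[nm]],
                     file.path(out_dir, paste0("features_", nm, ".csv")),
                     row.names = FALSE)
  }
  cfg_json <- config_to_json(out$config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("strokeradiomics")),
    seed = out$config$seed,
    best_feature_set = out$best,
    config_sha1 = .sha1(cfg_json),
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# tiny dependency-free digest (FNV-1a over the serialised config), enough to
# detect config drift between runs
.sha1 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("fnv1a-%08x", as.integer(h))
}

#' Validate a cohort directory without mutating it
#'
#' Checks NIfTI volume/mask alignment, strict binary masks, clinical schema
#' completeness (23 covariates) and outcome label ranges, and returns the
#' violations found.
#'
#' @param directory cohort directory written by [write_cohort()]
#' @return data.frame of violations (zero rows = clean)
#' @export
validate_inputs <- function(directory) {
  if (!dir.exists(directory)) stop("directory does not exist: ", directory)
  viol <- list()
  add <- function(what, detail) {
    viol[[length(viol) + 1]] <<- data.frame(check = what, detail = detail,
                                            stringsAsFactors = FALSE)
  }
  csv <- file.path(directory, "clinical.csv")
  if (!file.exists(csv)) {
    add("clinical", "clinical.csv missing")
  } else {
    tab <- utils::read.csv(csv, na.strings = "")
    cov_cols <- setdiff(names(tab), c("patient_id", "mrs90", "binary"))
    if (length(cov_cols) != 23) {
      add("clinical", sprintf("expected 23 covariate columns, found %d",
                              length(cov_cols)))
    }
    if ("mrs90" %in% names(tab)) {
      bad <- which(!tab$mrs90 %in% 0:6)
      for (b in bad) add("outcome", sprintf("row %d: mrs90 = %s out of 0-6",
                                            b, tab$mrs90[b]))
      if ("binary" %in% names(tab)) {
        inc <- which(as.integer(tab$mrs90 >= 3) != tab$binary)
        for (b in inc) add("outcome", sprintf("row %d: binary label inconsistent with mrs90", b))
      }
    } else add("outcome", "mrs90 column missing")
  }
  vols <- list.files(directory, pattern = "_(dwi|flair)\\.nii\\.gz$")
  for (v in vols) {
    mpath <- file.path(directory, sub("\\.nii\\.gz$", "_mask.nii.gz", v))
    if (!file.exists(mpath)) {
      add("mask", paste0("missing mask for ", v))
      next
    }
    img <- RNifti::readNifti(file.path(directory, v))
    msk <- RNifti::readNifti(mpath)
    if (!identical(dim(img), dim(msk))) {
      add("alignment", paste0(v, ": volume and mask dimensions differ"))
    }
    mv <- unique(as.numeric(msk))
    if (!all(mv %in% c(0, 1))) {
      add("mask", sprintf("%s: non-binary mask values {%s}", basename(mpath),
                          paste(setdiff(mv, c(0, 1)), collapse = ",")))
    }
  }
  if (length(viol) == 0) {
    data.frame(check = character(0), detail = character(0))
  } else do.call(rbind, viol)
}
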