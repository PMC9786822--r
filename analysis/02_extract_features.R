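#!/usr/bin/env Rscript
# Stage 2: validate the cohort, preprocess every scan and extract radiomics.
#
# Preprocessing per scan: resample volume + mask to isotropic 1 mm
# (trilinear / nearest-neighbour), white-stripe intensity normalisation.
# Extraction: the 107 radiomic features per modality (first-order, 3D shape,
# GLCM/GLRLM/GLSZM/NGTDM/GLDM) with fixed bin width 25.
#
# Reads results/cohort/, writes results/features_{dwi,flair}.csv.

suppressMessages(library(strokeradiomics))

cohort_dir <- "results/cohort"
stopifnot(dir.exists(cohort_dir))

viol <- validate_inputs(cohort_dir)
if (nrow(viol) > 0) {
  print(viol)
  stop("cohort directory failed validation")
}
message("input validation: clean")

cohort <- read_cohort(cohort_dir)
cfg <- experiment_config(seed = cohort$manifest$seed)
t0 <- proc.time()
feats <- extract_cohort_features(cohort, cfg, progress = TRUE)
message(sprintf("extracted %d x 2 x 107 features in %.1f min",
                nrow(feats$dwi), (proc.time() - t0)[3] / 60))

write.csv(feats$dwi, "results/features_dwi.csv", row.names = FALSE)
write.csv(feats$flair, "results/features_flair.csv", row.names = FALSE)
message("feature tables written to results/features_{dwi,flair}.csv")
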