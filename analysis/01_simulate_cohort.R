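#!/usr/bin/env Rscript
# Stage 1: simulate a synthetic follow-up-MRI stroke cohort and persist it.
#
# Writes per patient: pseudo-DWI and pseudo-FLAIR volumes with their binary
# lesion masks (NIfTI), plus one clinical CSV (23 covariates + 90-day mRS)
# and a JSON manifest. Later stages only read this directory, so the whole
# workflow can be re-run from any stage.
#
# Usage: Rscript analysis/01_simulate_cohort.R [n_patients] [seed]

suppressMessages(library(strokeradiomics))

args <- commandArgs(trailingOnly = TRUE)
n <- if (length(args) >= 1) as.integer(args[1]) else 40L
seed <- if (length(args) >= 2) as.integer(args[2]) else 20260921L
out_dir <- "results/cohort"

cfg <- cohort_config(n_patients = n, seed = seed)
message("simulating ", n, " patients (seed ", seed, ") ...")
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out_dir)

message("prevalence of unfavourable outcome (mRS 3-6): ",
        round(mean(cohort$outcome$binary), 3))
message("median lesion volume: ",
        round(median(cohort$lesion_volume_mm3)), " mm^3")
message("cohort written to ", out_dir)
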