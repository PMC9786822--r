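# Synthetic cohort generator. The trial data behind the analysis (follow-up
# DWI/T2-FLAIR with expert-corrected lesion masks, clinical covariates, 90-day
# mRS) are not public, so this module generates seeded cohorts carrying the
# statistical structure the downstream analysis assumes: lesions of varying
# size and shape, within-lesion texture with a controllable heterogeneity
# level h, a 23-covariate clinical table, and a binary outcome whose log-odds
# depend on heterogeneity, lesion volume and clinical severity.

#' Default clinical covariate schema (23 covariates)
#'
#' The eight covariates named in the study design (age, sex, glucose, ASPECTS,
#' treatment arm, pre-stroke mRS, baseline and 24-h NIHSS) plus fifteen
#' generic comorbidity / physiology / workflow covariates. The full trial
#' covariate list is not public; the fifteen extra fields are a stand-in with
#' realistic kinds and ranges, and the schema can be replaced by the user.
#'
#' @return data.frame with columns `name` and `kind`
#'   (continuous / binary / ordinal)
#' @export
default_clinical_schema <- function() {
  data.frame(
    name = c("age", "sex", "glucose", "aspects", "treatment_arm",
             "prestroke_mrs", "nihss_baseline", "nihss_24h",
             "hypertension", "diabetes", "atrial_fibrillation", "smoking",
             "prior_stroke", "statin_use", "antiplatelet_use",
             "systolic_bp", "diastolic_bp", "cholesterol", "creatinine",
             "onset_to_groin_min", "onset_to_needle_min",
             "collateral_score", "etici_score"),
    kind = c("continuous", "binary", "continuous", "ordinal", "binary",
             "ordinal", "ordinal", "ordinal",
             "binary", "binary", "binary", "binary",
             "binary", "binary", "binary",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous",
             "ordinal", "ordinal"),
    stringsAsFactors = FALSE
  )
}

#' Cohort generation configuration
#'
#' Defaults emulate the follow-up imaging setting of the multicentre trial the
#' analysis targets: 164 patients, thick-slice acquisition (1.5 x 1.5 x 3 mm
#' voxels), lesion radii of 4-10 mm, the full range of texture heterogeneity,
#' and an outcome model in which lesion heterogeneity, lesion volume, age and
#' 24-h NIHSS all push towards the unfavourable class.
#'
#' @param n_patients number of patients (>= 2)
#' @param grid_shape image grid in voxels, length 3
#' @param voxel_spacing_mm voxel spacing in mm, length 3
#' @param lesion_radius_range_mm interval of mean lesion radii, mm
#' @param heterogeneity_range interval on \[0, 1\] from which the per-patient
#'   texture-heterogeneity level h is drawn
#' @param irregularity_range interval on \[0, 1\] of lesion shape irregularity
#' @param outcome_betas named numeric vector: `b0` (intercept on the logit
#'   scale), `b_het`, `b_vol`, `b_age`, `b_nihss` (log-odds per SD)
#' @param missing_rate clinical missingness rate in \[0, 1)
#' @param seed integer seed; the same config and seed give a bit-identical
#'   cohort
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_patients = 164,
                          grid_shape = c(40, 40, 22),
                          voxel_spacing_mm = c(1.5, 1.5, 3),
                          lesion_radius_range_mm = c(4, 10),
                          heterogeneity_range = c(0.05, 0.95),
                          irregularity_range = c(0.1, 0.7),
                          outcome_betas = c(b0 = 0, b_het = 1.2, b_vol = 0.8,
                                            b_age = 0.8, b_nihss = 1.2),
                          missing_rate = 0.03,
                          seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (any(lesion_radius_range_mm <= 0)) stop("lesion radius range must be positive")
  if (diff(lesion_radius_range_mm) < 0) stop("lesion radius range must be an interval")
  if (any(heterogeneity_range < 0 | heterogeneity_range > 1)) {
    stop("heterogeneity_range must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  need <- c("b0", "b_het", "b_vol", "b_age", "b_nihss")
  if (!all(need %in% names(outcome_betas))) {
    stop("outcome_betas must contain ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(outcome_betas))) stop("outcome betas must be finite")
  structure(list(n_patients = as.integer(n_patients),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
                 heterogeneity_range = as.numeric(heterogeneity_range),
                 irregularity_range = as.numeric(irregularity_range),
                 outcome_betas = outcome_betas[need],
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic lesion mask
#'
#' A union of randomly perturbed ellipsoids: the implicit field of 1-3
#' ellipsoidal lobes is perturbed by a smooth random field whose amplitude
#' scales with `irregularity`, thresholded, lightly smoothed and re-thresholded,
#' and reduced to its largest 26-connected component. With `irregularity = 0`
#' the mask is exactly the digital ball of the requested radius.
#'
#' @param grid_shape grid in voxels, length 3
#' @param spacing voxel spacing mm, length 3
#' @param radius_mm mean lesion radius in mm; must fit inside the grid
#' @param irregularity shape irregularity in \[0, 1\]
#' @param seed integer seed
#' @return a [roi_mask] with a single 26-connected component of >= 10 voxels
#' @export
make_lesion_mask <- function(grid_shape, spacing, radius_mm, irregularity, seed) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (irregularity < 0 || irregularity > 1) stop("irregularity must be in [0, 1]")
  half_extent <- grid_shape * spacing / 2
  if (any(radius_mm >= half_extent - spacing)) {
    stop("radius_mm too large for the grid")
  }
  for (attempt in 1:5) {
    m <- .lesion_mask_once(grid_shape, spacing, radius_mm, irregularity,
                           derive_seed(seed, attempt - 1L))
    if (sum(m) >= 10) return(roi_mask(m, spacing))
  }
  stop("failed to generate a lesion mask of >= 10 voxels after 5 attempts")
}

.lesion_mask_once <- function(grid_shape, spacing, radius_mm, irregularity, seed) {
  set.seed(seed)
  ax <- lapply(1:3, function(k) (seq_len(grid_shape[k]) - (grid_shape[k] + 1) / 2) * spacing[k])
  centre <- c(0, 0, 0)
  if (irregularity > 0) {
    centre <- stats::runif(3, -0.15, 0.15) * radius_mm
  }
  # implicit field: max over lobes of 1 - ||(x - c)/semiaxes||^2
  n_lobes <- if (irregularity == 0) 1L else 1L + stats::rbinom(1, 2, irregularity)
  field <- array(-Inf, grid_shape)
  X <- array(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape)
  Y <- array(rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]), grid_shape)
  Z <- array(rep(ax[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  for (l in seq_len(n_lobes)) {
    if (irregularity == 0) {
      semi <- rep(radius_mm, 3)
      cl <- centre
    } else {
      semi <- radius_mm * (1 + stats::runif(3, -0.35, 0.35) * irregularity)
      cl <- centre + if (l == 1) c(0, 0, 0) else stats::runif(3, -0.5, 0.5) * radius_mm
    }
    f <- 1 - ((X - cl[1]) / semi[1])^2 - ((Y - cl[2]) / semi[2])^2 - ((Z - cl[3]) / semi[3])^2
    field <- pmax(field, f)
  }
  if (irregularity > 0) {
    noise <- array(stats::rnorm(prod(grid_shape)), grid_shape)
    noise <- gauss_smooth3d(noise, sigma = 1.5 / spacing * min(spacing))
    noise <- noise / max(stats::sd(noise), 1e-12)
    field <- field + 0.35 * irregularity * noise
    m <- array(as.numeric(field >= 0), grid_shape)
    m <- gauss_smooth3d(m, sigma = 0.6)
    m <- m >= 0.5
  } else {
    m <- field >= 0
  }
  if (!any(m)) return(array(0L, grid_shape))
  lab <- label_components_26(m)
  tab <- tabulate(lab[lab > 0])
  array(as.integer(lab == which.max(tab)), grid_shape)
}

#' Generate a textured lesion volume
#'
#' Inside the mask, intensities are `mean_in` plus a Gaussian random field
#' standardised within the mask and scaled to a standard deviation that grows
#' linearly with the heterogeneity level `h`; the smoothing kernel of the
#' field shrinks with `h`, so both variance and spatial roughness increase
#' monotonically with `h`. Outside the mask the volume holds low-level
#' background noise around the nominal tissue intensity.
#'
#' Scale conventions (arbitrary MR units, documented defaults): background
#' tissue mean 100, sd 10; lesion mean `mean_in` = 300 (hyperintense on both
#' modalities); within-lesion sd `sigma_h = 15 + 135 h`, kernel sd
#' `2.2 - 1.8 h` voxels. At `h = 0` the within-mask variance is below the
#' documented homogeneous-limit threshold of 20^2.
#'
#' @param mask a [roi_mask] (nonempty)
#' @param h heterogeneity level in \[0, 1\]
#' @param mean_in mean within-lesion intensity
#' @param seed integer seed
#' @param modality modality tag for the output volume
#' @return an [image_volume]
#' @export
make_texture_volume <- function(mask, h, mean_in = 300, seed = 1L,
                                modality = "DWI") {
  stopifnot(inherits(mask, "roi_mask"))
  if (h < 0 || h > 1) stop("h must be in [0, 1]")
  idx <- which(mask$data == 1)
  if (length(idx) == 0) stop("mask is empty")
  set.seed(seed)
  dim3 <- dim(mask$data)
  vol <- 100 + array(stats::rnorm(prod(dim3), 0, 10), dim3)
  noise <- array(stats::rnorm(prod(dim3)), dim3)
  noise <- gauss_smooth3d(noise, sigma = 2.2 - 1.8 * h)
  inside <- noise[idx]
  s <- stats::sd(inside)
  if (s < 1e-12 || length(idx) < 2) {
    inside <- rep(0, length(idx))
  } else {
    inside <- (inside - mean(inside)) / s
  }
  sigma_h <- 15 + 135 * h
  vol[idx] <- mean_in + sigma_h * inside
  vol[vol < 0] <- 0
  image_volume(vol, mask$spacing, modality)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

.sample_covariate <- function(name, kind, n) {
  switch(name,
    age = .rtrunc_norm(n, 69, 12, 18, 95),
    sex = stats::rbinom(n, 1, 0.45),
    glucose = round(.rtrunc_norm(n, 7, 2.2, 3, 25), 1),
    aspects = pmin(pmax(round(stats::rnorm(n, 8.3, 1.6)), 0), 10),
    treatment_arm = stats::rbinom(n, 1, 0.5),
    prestroke_mrs = sample(0:2, n, replace = TRUE, prob = c(0.8, 0.13, 0.07)),
    nihss_baseline = pmin(pmax(round(stats::rnorm(n, 16, 5)), 0), 42),
    nihss_24h = NA,  # filled from baseline, see make_clinical
    hypertension = stats::rbinom(n, 1, 0.5),
    diabetes = stats::rbinom(n, 1, 0.15),
    atrial_fibrillation = stats::rbinom(n, 1, 0.25),
    smoking = stats::rbinom(n, 1, 0.25),
    prior_stroke = stats::rbinom(n, 1, 0.1),
    statin_use = stats::rbinom(n, 1, 0.35),
    antiplatelet_use = stats::rbinom(n, 1, 0.3),
    systolic_bp = round(.rtrunc_norm(n, 150, 22, 90, 230)),
    diastolic_bp = round(.rtrunc_norm(n, 85, 13, 50, 140)),
    cholesterol = round(.rtrunc_norm(n, 5, 1.1, 2, 10), 1),
    creatinine = round(.rtrunc_norm(n, 82, 25, 30, 300)),
    onset_to_groin_min = round(.rtrunc_norm(n, 200, 60, 60, 480)),
    onset_to_needle_min = round(.rtrunc_norm(n, 150, 50, 40, 400)),
    collateral_score = sample(0:3, n, replace = TRUE, prob = c(0.1, 0.3, 0.4, 0.2)),
    etici_score = sample(0:5, n, replace = TRUE, prob = c(0.05, 0.05, 0.1, 0.3, 0.2, 0.3)),
    # generic fallbacks for user-supplied schema entries
    switch(kind,
      continuous = stats::rnorm(n),
      binary = stats::rbinom(n, 1, 0.3),
      ordinal = sample(0:4, n, replace = TRUE))
  )
}

#' Generate a clinical covariate table
#'
#' @param n number of patients
#' @param schema covariate schema, see [default_clinical_schema()]; must have
#'   exactly 23 uniquely named rows
#' @param missing_rate completely-at-random missingness rate in \[0, 1)
#' @param seed integer seed
#' @return data.frame with `n` rows and 23 columns (NA = missing)
#' @export
make_clinical <- function(n, schema = default_clinical_schema(),
                          missing_rate = 0, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (nrow(schema) != 23) stop("clinical schema must have exactly 23 covariates")
  if (anyDuplicated(schema$name)) stop("clinical covariate names must be unique")
  set.seed(seed)
  cols <- lapply(seq_len(nrow(schema)), function(i) {
    .sample_covariate(schema$name[i], schema$kind[i], n)
  })
  names(cols) <- schema$name
  df <- as.data.frame(cols)
  if ("nihss_24h" %in% names(df) && "nihss_baseline" %in% names(df)) {
    df$nihss_24h <- pmin(pmax(round(df$nihss_baseline + stats::rnorm(n, -3, 4)), 0), 42)
  } else if ("nihss_24h" %in% names(df)) {
    df$nihss_24h <- pmin(pmax(round(stats::rnorm(n, 13, 6)), 0), 42)
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * ncol(df)) < missing_rate, n, ncol(df))
    for (j in seq_len(ncol(df))) df[[j]][miss[, j]] <- NA
  }
  df
}

#' Draw 90-day functional outcomes
#'
#' The unfavourable-outcome probability follows a logistic model on internally
#' standardised covariates:
#' `P(unfavourable) = logistic(b0 + b_het z_h + b_vol z_vol + b_age z_age +
#' b_nihss z_nihss)`. An mRS in 3-6 is then drawn uniformly when the binary
#' label is 1, and in 0-2 otherwise.
#'
#' @param h per-patient heterogeneity levels
#' @param lesion_volume per-patient lesion volumes (mm^3)
#' @param age per-patient age
#' @param nihss24 per-patient 24-h NIHSS
#' @param betas named vector (`b0`, `b_het`, `b_vol`, `b_age`, `b_nihss`)
#' @param seed integer seed
#' @return data.frame with columns `mrs90` (0-6) and `binary`
#'   (1 = mRS 3-6, unfavourable)
#' @export
make_outcome <- function(h, lesion_volume, age, nihss24, betas, seed = 1L) {
  if (!all(is.finite(betas))) stop("outcome betas must be finite")
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  lp <- betas[["b0"]] + betas[["b_het"]] * zs(h) + betas[["b_vol"]] * zs(lesion_volume) +
    betas[["b_age"]] * zs(age) + betas[["b_nihss"]] * zs(nihss24)
  p <- 1 / (1 + exp(-lp))
  set.seed(seed)
  binary <- as.integer(stats::runif(length(p)) < p)
  mrs90 <- ifelse(binary == 1, sample(3:6, length(p), replace = TRUE),
                  sample(0:2, length(p), replace = TRUE))
  data.frame(mrs90 = as.integer(mrs90), binary = binary)
}

#' Simulate a complete synthetic cohort
#'
#' Per patient: a lesion mask per modality (the FLAIR mask is a lightly
#' perturbed variant of the DWI mask, mimicking modality-specific
#' segmentation), a textured volume per modality sharing the patient's
#' heterogeneity level h, a clinical row, and a 90-day outcome.
#'
#' @param config a [cohort_config]
#' @return list with elements `patients` (list of per-patient lists with
#'   `dwi`, `flair`, `dwi_mask`, `flair_mask`, `h`), `clinical`, `outcome`,
#'   `h`, `lesion_volume_mm3`, and `config`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(config$seed)
  h <- stats::runif(n, config$heterogeneity_range[1], config$heterogeneity_range[2])
  radius <- stats::runif(n, config$lesion_radius_range_mm[1], config$lesion_radius_range_mm[2])
  irr <- stats::runif(n, config$irregularity_range[1], config$irregularity_range[2])
  clinical <- make_clinical(n, missing_rate = 0, seed = derive_seed(config$seed, 900001L))
  patients <- vector("list", n)
  vol_mm3 <- numeric(n)
  for (i in seq_len(n)) {
    sd_i <- derive_seed(config$seed, i)
    dwi_mask <- make_lesion_mask(config$grid_shape, config$voxel_spacing_mm,
                                 radius[i], irr[i], sd_i)
    # modality-specific segmentation: regenerate with slightly different seed
    # and irregularity, then fall back to the DWI mask if degenerate
    flair_mask <- tryCatch(
      make_lesion_mask(config$grid_shape, config$voxel_spacing_mm,
                       radius[i] * 1.05, min(1, irr[i] * 1.1),
                       derive_seed(sd_i, 7L)),
      error = function(e) dwi_mask)
    dwi <- make_texture_volume(dwi_mask, h[i], mean_in = 300,
                               seed = derive_seed(sd_i, 1L), modality = "DWI")
    flair <- make_texture_volume(flair_mask, h[i], mean_in = 250,
                                 seed = derive_seed(sd_i, 2L), modality = "FLAIR")
    vol_mm3[i] <- sum(dwi_mask$data) * prod(config$voxel_spacing_mm)
    patients[[i]] <- list(dwi = dwi, flair = flair, dwi_mask = dwi_mask,
                          flair_mask = flair_mask, h = h[i])
  }
  outcome <- make_outcome(h, vol_mm3, clinical$age, clinical$nihss_24h,
                          config$outcome_betas,
                          seed = derive_seed(config$seed, 900002L))
  if (config$missing_rate > 0) {
    set.seed(derive_seed(config$seed, 900003L))
    miss <- matrix(stats::runif(n * ncol(clinical)) < config$missing_rate,
                   n, ncol(clinical))
    for (j in seq_len(ncol(clinical))) clinical[[j]][miss[, j]] <- NA
  }
  list(patients = patients, clinical = clinical, outcome = outcome, h = h,
       lesion_volume_mm3 = vol_mm3, config = config)
}

#' Write a cohort to disk (NIfTI volumes + masks, clinical CSV, manifest)
#'
#' @param cohort result of [simulate_cohort()]
#' @param directory output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_cohort <- function(cohort, directory) {
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  probe <- file.path(directory, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE))) {
    stop("directory not writable: ", directory)
  }
  unlink(probe)
  n <- length(cohort$patients)
  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    id <- sprintf("patient_%03d", i)
    .write_nifti(p$dwi$data, p$dwi$spacing, file.path(directory, paste0(id, "_dwi.nii.gz")))
    .write_nifti(p$flair$data, p$flair$spacing, file.path(directory, paste0(id, "_flair.nii.gz")))
    .write_nifti(p$dwi_mask$data, p$dwi_mask$spacing, file.path(directory, paste0(id, "_dwi_mask.nii.gz")))
    .write_nifti(p$flair_mask$data, p$flair_mask$spacing, file.path(directory, paste0(id, "_flair_mask.nii.gz")))
  }
  tab <- cbind(patient_id = sprintf("patient_%03d", seq_len(n)),
               cohort$clinical, cohort$outcome)
  utils::write.csv(tab, file.path(directory, "clinical.csv"), row.names = FALSE, na = "")
  manifest <- list(n_patients = n, seed = cohort$config$seed,
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

.write_nifti <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory cohort directory
#' @return list with `patients`, `clinical`, `outcome`, `manifest`
#' @export
read_cohort <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  n <- manifest$n_patients
  tab <- utils::read.csv(file.path(directory, "clinical.csv"), na.strings = "")
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("patient_%03d", i)
    rd <- function(suffix) {
      img <- RNifti::readNifti(file.path(directory, paste0(id, suffix)))
      list(data = array(as.numeric(img), dim(img)),
           spacing = RNifti::pixdim(img))
    }
    dwi <- rd("_dwi.nii.gz"); flair <- rd("_flair.nii.gz")
    dm <- rd("_dwi_mask.nii.gz"); fm <- rd("_flair_mask.nii.gz")
    patients[[i]] <- list(
      dwi = image_volume(dwi$data, dwi$spacing, "DWI"),
      flair = image_volume(flair$data, flair$spacing, "FLAIR"),
      dwi_mask = roi_mask(round(dm$data), dm$spacing),
      flair_mask = roi_mask(round(fm$data), fm$spacing))
  }
  outcome <- tab[, c("mrs90", "binary")]
  clinical <- tab[, setdiff(names(tab), c("patient_id", "mrs90", "binary"))]
  list(patients = patients, clinical = clinical, outcome = outcome,
       manifest = manifest)
}
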