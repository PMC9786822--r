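# Full per-lesion feature extraction: 18 first-order + 14 shape + 24 GLCM +
# 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM = 107 features.

.FAMILY_SIZES <- c(firstorder = 18L, shape = 14L, glcm = 24L, glrlm = 16L,
                   glszm = 16L, ngtdm = 5L, gldm = 14L)

#' Extract all 107 radiomic features for one lesion
#'
#' The ROI is cropped to its bounding box before the texture matrices are
#' built (the matrices only involve in-mask voxels, so cropping does not
#' change them).
#'
#' @param volume a preprocessed [image_volume]
#' @param mask an [roi_mask] aligned to it (nonempty)
#' @param config a [radiomics_config]
#' @return named numeric vector of exactly 107 finite values, names prefixed
#'   by family (`firstorder_`, `shape_`, `glcm_`, ...)
#' @export
extract_all <- function(volume, mask, config = radiomics_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  idx <- which(mask$data == 1)
  if (length(idx) == 0) stop("mask is empty")
  d <- dim(mask$data)
  coords <- coords_of(idx, d)
  lo <- pmax(apply(coords, 2, min) - 1L, 1L)
  hi <- pmin(apply(coords, 2, max) + 1L, d)
  vsub <- image_volume(volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                       volume$spacing, volume$modality)
  msub <- roi_mask(mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                   mask$spacing)
  disc <- discretize(vsub, msub, config$bin_width)
  wrap <- function(fam, expr) {
    v <- tryCatch(expr, error = function(e) {
      stop(sprintf("feature family '%s' failed: %s", fam, conditionMessage(e)),
           call. = FALSE)
    })
    stats::setNames(v, paste0(fam, "_", names(v)))
  }
  out <- c(
    wrap("firstorder", first_order_features(vsub, msub, disc)),
    wrap("shape", shape3d_features(msub, mesh_sigma = config$mesh_sigma)),
    wrap("glcm", glcm_features(disc)),
    wrap("glrlm", glrlm_features(disc)),
    wrap("glszm", glszm_features(disc)),
    wrap("ngtdm", ngtdm_features(disc)),
    wrap("gldm", gldm_features(disc, config$gldm_alpha)))
  if (length(out) != 107) stop("internal error: expected 107 features, got ", length(out))
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Names of the 107 radiomic features
#'
#' @param prefix optional modality prefix (e.g. `"DWI"`) prepended as
#'   `"DWI_"`
#' @return character vector of 107 feature names
#' @export
radiomic_feature_names <- function(prefix = NULL) {
  base <- c(
    paste0("firstorder_", c("Energy", "TotalEnergy", "Entropy", "Minimum",
      "10Percentile", "90Percentile", "Maximum", "Mean", "Median",
      "InterquartileRange", "Range", "MeanAbsoluteDeviation",
      "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
      "Kurtosis", "Variance", "Uniformity")),
    paste0("shape_", c("MeshVolume", "VoxelVolume", "SurfaceArea",
      "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
      "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
      "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
      "LeastAxisLength", "Elongation", "Flatness")),
    paste0("glcm_", c("Autocorrelation", "JointAverage", "ClusterProminence",
      "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
      "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
      "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn", "Id",
      "Idn", "InverseVariance", "MaximumProbability", "MCC", "SumAverage",
      "SumEntropy", "SumSquares")),
    paste0("glrlm_", .GLRLM_NAMES),
    paste0("glszm_", .GLSZM_NAMES),
    paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness", "Complexity",
      "Strength")),
    paste0("gldm_", c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis")))
  if (!is.null(prefix)) base <- paste0(prefix, "_", base)
  base
}
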