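# Gray Level Size Zone Matrix features. A zone is a maximal set of in-mask
# voxels sharing one gray level and connected under 26-connectivity; the
# matrix counts zones by (gray level, zone size). One matrix per ROI (the
# family has no directionality).

glszm_matrix <- function(disc) {
  mask <- !is.na(disc$levels)
  lab <- label_components_26(mask, values = disc$levels)
  zl <- lab[disc$idx]
  sizes <- tabulate(zl)
  lev_of_zone <- disc$levels[disc$idx][match(seq_along(sizes), zl)]
  Ns <- max(sizes)
  tab <- table(factor(lev_of_zone, levels = seq_len(disc$Ng)),
               factor(sizes, levels = seq_len(Ns)))
  m <- matrix(as.numeric(tab), disc$Ng, Ns)
  m
}

.GLSZM_NAMES <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
  "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

#' GLSZM texture features (16 features)
#'
#' @param disc a `discretized_roi` from [discretize()]
#' @return named numeric vector of 16 features
#' @export
glszm_features <- function(disc) {
  m <- glszm_matrix(disc)
  if (sum(m) == 0) stop("no zones found (empty mask?)")
  f <- .rl_sz_features(m, Np = length(disc$idx))
  stats::setNames(f, .GLSZM_NAMES)
}
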