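# Fixed-bin-width gray-level discretisation, the prerequisite of all texture
# families. Level of voxel x is floor((x - min_in_mask)/bin_width) + 1.

#' Radiomics extraction configuration
#'
#' @param bin_width fixed bin width for gray-level discretisation, applied to
#'   the (normalised) intensities; default 25
#' @param gldm_alpha dependence threshold for the gray-level dependence
#'   matrix: a neighbour is dependent when its level differs by at most
#'   `gldm_alpha`; default 0
#' @param mesh_sigma standard deviation (voxels) of the Gaussian used to
#'   anti-alias the binary mask before iso-surfacing; default 0.8
#' @return a `radiomics_config` list
#' @export
radiomics_config <- function(bin_width = 25, gldm_alpha = 0, mesh_sigma = 0.8) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (gldm_alpha < 0) stop("gldm_alpha must be >= 0")
  structure(list(bin_width = bin_width, gldm_alpha = gldm_alpha,
                 mesh_sigma = mesh_sigma), class = "radiomics_config")
}

#' Discretise an ROI into integer gray levels
#'
#' @param volume an [image_volume]
#' @param mask an [roi_mask] (nonempty) aligned to it
#' @param bin_width positive bin width
#' @return a `discretized_roi`: integer `levels` array (NA outside the mask),
#'   number of levels `Ng`, `bin_width`, voxel `spacing`, in-mask linear
#'   indices `idx` and their `coords`
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (bin_width <= 0) stop("bin_width must be positive")
  idx <- which(mask$data == 1)
  if (length(idx) == 0) stop("mask is empty")
  x <- volume$data[idx]
  lev <- as.integer(floor((x - min(x)) / bin_width) + 1)
  levels <- array(NA_integer_, dim(volume$data))
  levels[idx] <- lev
  structure(list(levels = levels, Ng = max(lev), bin_width = bin_width,
                 spacing = volume$spacing, idx = idx,
                 coords = coords_of(idx, dim(volume$data)),
                 intensities = x),
            class = "discretized_roi")
}

#' First-order intensity statistics (18 features)
#'
#' Distribution statistics of the within-ROI intensities; `Entropy` and
#' `Uniformity` are computed on the discretised histogram. Conventions for the
#' degenerate constant ROI: `Skewness` and `Kurtosis` fall back to 0 (kurtosis
#' is reported unadjusted, i.e. 3 for a Gaussian, so the fallback is the
#' degenerate-distribution convention, not the Gaussian reference).
#'
#' @param volume an [image_volume]
#' @param mask an [roi_mask]
#' @param discretized result of [discretize()]; recomputed if `NULL`
#' @return named numeric vector of 18 features
#' @export
first_order_features <- function(volume, mask, discretized = NULL) {
  if (is.null(discretized)) discretized <- discretize(volume, mask)
  x <- discretized$intensities
  n <- length(x)
  p <- tabulate(discretized$levels[discretized$idx], discretized$Ng) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  vv <- prod(discretized$spacing)
  skew <- if (m2 < 1e-30) 0 else mean((x - mu)^3) / m2^1.5
  kurt <- if (m2 < 1e-30) 0 else mean((x - mu)^4) / m2^2
  c(Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}
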