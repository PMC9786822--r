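# Gray Level Co-occurrence Matrix features. Co-occurrences are counted at
# Chebyshev distance 1 along the 13 unique 3D directions; each directional
# matrix is symmetrised and normalised, features are computed per direction
# and averaged. Directions with no valid voxel pair are excluded.

# directional co-occurrence count matrices (Ng x Ng, symmetrised)
glcm_matrices <- function(disc) {
  Ng <- disc$Ng
  dim3 <- dim(disc$levels)
  dirs <- unique_directions()
  lev <- disc$levels
  out <- list()
  for (r in seq_len(nrow(dirs))) {
    nb <- shift_index(disc$coords, dirs[r, ], dim3)
    ok <- !is.na(nb)
    a <- lev[disc$idx[ok]]
    b <- lev[nb[ok]]
    ok2 <- !is.na(b)
    a <- a[ok2]; b <- b[ok2]
    if (length(a) == 0) next
    counts <- matrix(tabulate((b - 1L) * Ng + a, Ng * Ng), Ng, Ng)
    out[[length(out) + 1]] <- counts + t(counts)
  }
  out
}

.glcm_features_one <- function(P) {
  Ng <- nrow(P)
  p <- P / sum(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p)                     # == py by symmetry
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  # diagonal |i-j| = k distributions, k = 0..Ng-1, and sums i+j = 2..2Ng
  pxmy <- vapply(0:(Ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  kxy <- 0:(Ng - 1)
  pxpy <- vapply(2:(2 * Ng), function(k) sum(p[(i + j) == k]), numeric(1))
  kxpy <- 2:(2 * Ng)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  HX <- ent(px)
  HXY <- ent(p)
  pxy_outer <- outer(px, px)
  nz <- p > 0 & pxy_outer > 0
  HXY1 <- -sum(p[nz] * log2(pxy_outer[nz]))
  HXY2 <- ent(pxy_outer)
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  da <- sum(kxy * pxmy)
  corr <- if (sigma2 > 1e-12) (sum(i * j * p) - mu^2) / sigma2 else 1
  # MCC: sqrt of second-largest eigenvalue of Q
  mcc <- if (Ng == 1) 1 else {
    # Q[i,j] = sum_k p(i,k) p(j,k) / (px(i) py(k))
    Q <- matrix(0, Ng, Ng)
    for (kk in seq_len(Ng)) {
      if (px[kk] <= 0) next
      Q <- Q + outer(p[, kk] , p[, kk]) / (px[kk])
    }
    Q <- Q / pmax(matrix(px, Ng, Ng), 1e-300)
    evs <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(evs) < 2 || evs[2] < 0) 0 else sqrt(evs[2])
  }
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pxmy),
    DifferenceVariance = sum((kxy - da)^2 * pxmy),
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / Ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / Ng)),
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum(kxpy * pxpy),
    SumEntropy = ent(pxpy),
    SumSquares = sigma2)
}

#' GLCM texture features (24 features)
#'
#' @param disc a `discretized_roi` from [discretize()]
#' @return named numeric vector of 24 direction-averaged features
#' @export
glcm_features <- function(disc) {
  mats <- glcm_matrices(disc)
  if (length(mats) == 0) stop("no valid voxel pair in any direction")
  rowMeans(vapply(mats, .glcm_features_one, numeric(24)))
}
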