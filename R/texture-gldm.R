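# Gray Level Dependence Matrix features. A 26-neighbour is "dependent" on the
# centre voxel when their levels differ by at most alpha. The dependence size
# of a voxel is its dependent-neighbour count plus one (the centre itself is
# counted), so matrix entries sum to the number of in-mask voxels.

gldm_matrix <- function(disc, alpha = 0) {
  if (alpha < 0) stop("alpha must be >= 0")
  dim3 <- dim(disc$levels)
  lev <- disc$levels
  idx <- disc$idx
  centre <- lev[idx]
  offs <- all_neighbour_offsets()
  dep <- rep(0L, length(idx))
  for (r in seq_len(nrow(offs))) {
    nbi <- shift_index(disc$coords, offs[r, ], dim3)
    ok <- !is.na(nbi)
    v <- rep(NA_integer_, length(idx))
    v[ok] <- lev[nbi[ok]]
    dep <- dep + (!is.na(v) & abs(v - centre) <= alpha)
  }
  size <- dep + 1L
  Nd <- max(size)
  tab <- table(factor(centre, levels = seq_len(disc$Ng)),
               factor(size, levels = seq_len(Nd)))
  matrix(as.numeric(tab), disc$Ng, Nd)
}

#' GLDM texture features (14 features)
#'
#' @param disc a `discretized_roi` from [discretize()]
#' @param alpha dependence threshold on the level difference (default 0)
#' @return named numeric vector of 14 features
#' @export
gldm_features <- function(disc, alpha = 0) {
  P <- gldm_matrix(disc, alpha)
  Nz <- sum(P)
  Ng <- nrow(P); Nd <- ncol(P)
  ivec <- seq_len(Ng); jvec <- seq_len(Nd)
  gi <- rowSums(P); dj <- colSums(P)
  p <- P / Nz
  mu_i <- sum(ivec * rowSums(p))
  mu_j <- sum(jvec * colSums(p))
  pe <- p[p > 0]
  c(SmallDependenceEmphasis = sum(dj / jvec^2) / Nz,
    LargeDependenceEmphasis = sum(dj * jvec^2) / Nz,
    GrayLevelNonUniformity = sum(gi^2) / Nz,
    DependenceNonUniformity = sum(dj^2) / Nz,
    DependenceNonUniformityNormalized = sum(dj^2) / Nz^2,
    GrayLevelVariance = sum((ivec - mu_i)^2 * rowSums(p)),
    DependenceVariance = sum((jvec - mu_j)^2 * colSums(p)),
    DependenceEntropy = -sum(pe * log2(pe)),
    LowGrayLevelEmphasis = sum(gi / ivec^2) / Nz,
    HighGrayLevelEmphasis = sum(gi * ivec^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / outer(ivec^2, jvec^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * outer(ivec^2, 1 / jvec^2)) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * outer(1 / ivec^2, jvec^2)) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * outer(ivec^2, jvec^2)) / Nz)
}
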