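# Gray Level Run Length Matrix features. A run is a maximal sequence of
# consecutive in-mask voxels of equal gray level along one of the 13 unique
# 3D directions; runs are broken by the mask boundary. Features are computed
# per direction and averaged.

# run-length count matrix (Ng x max run length) for one direction
.glrlm_one_direction <- function(disc, dir) {
  lev <- disc$levels[disc$idx]
  co <- disc$coords
  step2 <- sum(dir^2)
  t_par <- co %*% dir                        # position along the direction
  key <- co * step2 - as.vector(t_par) %*% t(dir)  # constant along a line
  ord <- order(key[, 1], key[, 2], key[, 3], t_par)
  kl <- key[ord, , drop = FALSE]
  tt <- t_par[ord]
  lv <- lev[ord]
  n <- length(lv)
  if (n == 0) return(NULL)
  same_line <- c(FALSE, kl[-1, 1] == kl[-n, 1] & kl[-1, 2] == kl[-n, 2] &
                        kl[-1, 3] == kl[-n, 3])
  contiguous <- c(FALSE, tt[-1] - tt[-n] == step2)
  same_level <- c(FALSE, lv[-1] == lv[-n])
  new_run <- !(same_line & contiguous & same_level)
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  run_lev <- lv[new_run]
  Nr_max <- max(run_len)
  m <- matrix(0, disc$Ng, Nr_max)
  tab <- table(factor(run_lev, levels = seq_len(disc$Ng)),
               factor(run_len, levels = seq_len(Nr_max)))
  m[] <- as.numeric(tab)
  m
}

glrlm_matrices <- function(disc) {
  dirs <- unique_directions()
  out <- list()
  for (r in seq_len(nrow(dirs))) {
    m <- .glrlm_one_direction(disc, dirs[r, ])
    if (!is.null(m) && sum(m) > 0) out[[length(out) + 1]] <- m
  }
  out
}

# the 16 features shared (up to naming) with the size-zone family:
# `P` is a gray-level x size count matrix, `Np` the number of in-mask voxels
.rl_sz_features <- function(P, Np) {
  Nr <- sum(P)
  Ng <- nrow(P); Ns <- ncol(P)
  ivec <- seq_len(Ng); svec <- seq_len(Ns)
  gi <- rowSums(P); sj <- colSums(P)
  p <- P / Nr
  mu_i <- sum(ivec * rowSums(p))
  mu_s <- sum(svec * colSums(p))
  pe <- p[p > 0]
  c(SmallEmphasis = sum(sj / svec^2) / Nr,
    LargeEmphasis = sum(sj * svec^2) / Nr,
    GrayLevelNonUniformity = sum(gi^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(gi^2) / Nr^2,
    SizeNonUniformity = sum(sj^2) / Nr,
    SizeNonUniformityNormalized = sum(sj^2) / Nr^2,
    Percentage = Nr / Np,
    GrayLevelVariance = sum((ivec - mu_i)^2 * rowSums(p)),
    SizeVariance = sum((svec - mu_s)^2 * colSums(p)),
    Entropy = -sum(pe * log2(pe)),
    LowGrayLevelEmphasis = sum(gi / ivec^2) / Nr,
    HighGrayLevelEmphasis = sum(gi * ivec^2) / Nr,
    SmallLowGrayLevelEmphasis = sum(P / outer(ivec^2, svec^2)) / Nr,
    SmallHighGrayLevelEmphasis = sum(P * outer(ivec^2, 1 / svec^2)) / Nr,
    LargeLowGrayLevelEmphasis = sum(P * outer(1 / ivec^2, svec^2)) / Nr,
    LargeHighGrayLevelEmphasis = sum(P * outer(ivec^2, svec^2)) / Nr)
}

.GLRLM_NAMES <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

#' GLRLM texture features (16 features)
#'
#' @param disc a `discretized_roi` from [discretize()]
#' @return named numeric vector of 16 direction-averaged features
#' @export
glrlm_features <- function(disc) {
  mats <- glrlm_matrices(disc)
  if (length(mats) == 0) stop("no valid run in any direction")
  Np <- length(disc$idx)
  f <- rowMeans(vapply(mats, .rl_sz_features, numeric(16), Np = Np))
  stats::setNames(f, .GLRLM_NAMES)
}
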