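# Neighbouring Gray Tone Difference Matrix features. For each gray level i,
# s_i accumulates |i - mean level of the 26-neighbourhood| over in-mask voxels
# of level i (neighbourhood restricted to in-mask voxels); voxels with no
# in-mask neighbour are excluded. Documented degenerate fallbacks: with a
# single occupied level, Contrast, Busyness and Strength are 0 and Coarseness
# is capped at 1e6.

ngtdm_table <- function(disc) {
  dim3 <- dim(disc$levels)
  lev <- disc$levels
  idx <- disc$idx
  offs <- all_neighbour_offsets()
  nb_sum <- rep(0, length(idx))
  nb_cnt <- rep(0L, length(idx))
  for (r in seq_len(nrow(offs))) {
    nbi <- shift_index(disc$coords, offs[r, ], dim3)
    ok <- !is.na(nbi)
    v <- rep(NA_integer_, length(idx))
    v[ok] <- lev[nbi[ok]]
    ok <- ok & !is.na(v)
    nb_sum[ok] <- nb_sum[ok] + v[ok]
    nb_cnt <- nb_cnt + ok
  }
  has_nb <- nb_cnt > 0
  li <- lev[idx][has_nb]
  abar <- nb_sum[has_nb] / nb_cnt[has_nb]
  Ng <- disc$Ng
  n_i <- tabulate(li, Ng)
  s_i <- vapply(seq_len(Ng), function(g) sum(abs(g - abar)[li == g]), numeric(1))
  list(n = n_i, s = s_i, Nvp = sum(n_i))
}

#' NGTDM texture features (5 features)
#'
#' @param disc a `discretized_roi` from [discretize()]
#' @return named numeric vector: Coarseness, Contrast, Busyness, Complexity,
#'   Strength
#' @export
ngtdm_features <- function(disc) {
  tb <- ngtdm_table(disc)
  if (tb$Nvp == 0) stop("no voxel with an in-mask neighbour")
  p <- tb$n / tb$Nvp
  s <- tb$s
  lv <- seq_along(p)
  nz <- p > 0
  Ngp <- sum(nz)
  coarse <- if (sum(p * s) < 1e-12) 1e6 else min(1 / sum(p * s), 1e6)
  if (Ngp <= 1) {
    contrast <- 0; busy <- 0; cplx <- 0; strength <- 0
  } else {
    pi_ <- p[nz]; si_ <- s[nz]; li_ <- lv[nz]
    dd <- outer(li_, li_, "-")
    contrast <- sum(outer(pi_, pi_) * dd^2) / (Ngp * (Ngp - 1)) * sum(si_) / tb$Nvp
    denom <- sum(abs(outer(li_ * pi_, li_ * pi_, "-")))
    busy <- if (denom < 1e-12) 0 else sum(pi_ * si_) / denom
    num <- abs(dd) * (outer(pi_ * si_, pi_ * si_, "+")) / outer(pi_, pi_, "+")
    cplx <- sum(num) / tb$Nvp
    strength <- if (sum(si_) < 1e-12) 0 else
      sum(outer(pi_, pi_, "+") * dd^2) / sum(si_)
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = cplx, Strength = strength)
}
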