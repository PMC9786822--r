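# Separable 3D Gaussian smoothing, used by the lesion generator (to soften
# implicit shapes), the texture model (to control spatial roughness) and the
# shape module (to anti-alias the binary indicator before iso-surfacing).

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-hw:hw) / sigma)^2)
  k / sum(k)
}

smooth_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  hw <- (length(kernel) - 1L) / 2L
  # replicate-pad the filtered axis so edges keep unit kernel mass
  mp <- rbind(m[rep(1L, hw), , drop = FALSE], m,
              m[rep(nrow(m), hw), , drop = FALSE])
  f <- stats::filter(mp, kernel, sides = 2)
  f <- f[(hw + 1L):(hw + nrow(m)), , drop = FALSE]
  a <- array(as.numeric(f), dim = d[perm])
  aperm(a, order(perm))
}

#' Gaussian-smooth a 3D array (separable, replicate-padded edges)
#'
#' @param arr 3D numeric array
#' @param sigma kernel standard deviation per axis, in voxels; scalar or
#'   length 3
#' @return smoothed array of the same dimension
#' @keywords internal
gauss_smooth3d <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) arr <- smooth_axis(arr, gauss_kernel(sigma[ax]), ax)
  arr
}
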