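# Preprocessing before feature extraction: resampling volumes and masks to an
# isotropic 1 mm grid, and white-stripe intensity normalisation. Volumes are
# assumed to already live in a common space (registration and skull stripping
# are upstream, external concerns).

#' White-stripe normalisation parameters
#'
#' @param tau quantile half-width of the stripe in (0, 0.5); the stripe is the
#'   set of voxels whose empirical CDF value lies within `tau` of the CDF
#'   value of the histogram mode
#' @param bandwidth smoothing bandwidth for the within-mask intensity density;
#'   `NULL` uses the default bandwidth of [stats::density()]
#' @return a `white_stripe_params` list
#' @export
white_stripe_params <- function(tau = 0.05, bandwidth = NULL) {
  if (tau <= 0 || tau >= 0.5) stop("tau must be in (0, 0.5)")
  if (!is.null(bandwidth) && bandwidth <= 0) stop("bandwidth must be positive")
  structure(list(tau = tau, bandwidth = bandwidth), class = "white_stripe_params")
}

.trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  x0 <- pmin(pmax(floor(xi), 1), d[1] - 1); x1 <- x0 + 1
  y0 <- pmin(pmax(floor(yi), 1), d[2] - 1); y1 <- y0 + 1
  z0 <- pmin(pmax(floor(zi), 1), d[3] - 1); z1 <- z0 + 1
  fx <- pmin(pmax(xi - x0, 0), 1)
  fy <- pmin(pmax(yi - y0, 0), 1)
  fz <- pmin(pmax(zi - z0, 0), 1)
  at <- function(x, y, z) arr[cbind(x, y, z)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

.nearest3 <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  arr[cbind(pmin(pmax(round(xi), 1), d[1]),
            pmin(pmax(round(yi), 1), d[2]),
            pmin(pmax(round(zi), 1), d[3]))]
}

#' Resample a volume (and its mask) to an isotropic grid
#'
#' The output grid has `round(size * spacing / target)` voxels per axis, with
#' voxel centres corner-aligned to the input grid (world coordinate of voxel
#' `i` is `(i - 0.5) * spacing`). Intensities are interpolated trilinearly,
#' masks by nearest neighbour (so they stay strictly binary). An
#' already-isotropic volume at the target spacing is returned unchanged.
#'
#' @param volume an [image_volume]
#' @param mask an [roi_mask] aligned to it, or `NULL`
#' @param target_spacing target isotropic spacing in mm (default 1)
#' @return list with `volume` and `mask` (NULL if no mask given)
#' @export
resample_isotropic <- function(volume, mask = NULL, target_spacing = 1) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  if (any(d < 2)) stop("cannot resample a degenerate (single-voxel axis) volume")
  sp <- volume$spacing
  if (all(abs(sp - target_spacing) < 1e-9)) {
    return(list(volume = volume, mask = mask))
  }
  out_d <- pmax(2L, as.integer(round(d * sp / target_spacing)))
  cx <- ((seq_len(out_d[1]) - 0.5) * target_spacing) / sp[1] + 0.5
  cy <- ((seq_len(out_d[2]) - 0.5) * target_spacing) / sp[2] + 0.5
  cz <- ((seq_len(out_d[3]) - 0.5) * target_spacing) / sp[3] + 0.5
  xi <- rep(cx, times = out_d[2] * out_d[3])
  yi <- rep(rep(cy, each = out_d[1]), times = out_d[3])
  zi <- rep(cz, each = out_d[1] * out_d[2])
  vout <- array(.trilinear(volume$data, xi, yi, zi), out_d)
  new_vol <- image_volume(vout, rep(target_spacing, 3), volume$modality)
  new_mask <- NULL
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "roi_mask"))
    mout <- array(.nearest3(mask$data, xi, yi, zi), out_d)
    new_mask <- roi_mask(mout, rep(target_spacing, 3))
  }
  list(volume = new_vol, mask = new_mask)
}

#' White-stripe intensity normalisation
#'
#' Finds the highest-density mode mu of the smoothed within-mask intensity
#' histogram, takes the "stripe" of voxels whose empirical CDF value lies
#' within `tau` of `F(mu)`, and z-scores the whole volume by the stripe mean
#' and standard deviation. The procedure is invariant under positive affine
#' intensity transforms and idempotent up to numerical tolerance.
#'
#' @param volume an [image_volume]
#' @param brain_mask an [roi_mask] of the voxels defining the histogram
#'   (e.g. the brain); `NULL` uses the whole field of view
#' @param params a [white_stripe_params]
#' @return the normalised [image_volume]
#' @export
white_stripe_normalize <- function(volume, brain_mask = NULL,
                                   params = white_stripe_params()) {
  stopifnot(inherits(volume, "image_volume"))
  vals <- if (is.null(brain_mask)) as.numeric(volume$data) else {
    stopifnot(inherits(brain_mask, "roi_mask"))
    volume$data[brain_mask$data == 1]
  }
  if (length(vals) == 0) stop("brain mask is empty")
  if (stats::sd(vals) < 1e-12) {
    stop("white-stripe normalisation failed: within-mask intensities are constant")
  }
  dens <- if (is.null(params$bandwidth)) stats::density(vals, n = 2048) else
    stats::density(vals, bw = params$bandwidth, n = 2048)
  mu <- dens$x[which.max(dens$y)]
  Fn <- stats::ecdf(vals)
  fmu <- Fn(mu)
  stripe <- vals[abs(Fn(vals) - fmu) <= params$tau]
  m <- mean(stripe); s <- stats::sd(stripe)
  if (!is.finite(s) || s < 1e-12) {
    stop(sprintf(paste0("white-stripe normalisation failed: stripe sd is zero ",
                        "(mode %.4g, stripe of %d voxels)"), mu, length(stripe)))
  }
  image_volume((volume$data - m) / s, volume$spacing, volume$modality)
}
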