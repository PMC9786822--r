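# Core containers: an image volume with voxel spacing and modality tag, and a
# binary region-of-interest mask aligned to it. Deliberately lightweight lists
# so that every pipeline stage can be exercised without file I/O.

#' Construct an image volume
#'
#' @param data 3D numeric array of intensities (all finite)
#' @param spacing voxel spacing in mm, length 3, all positive
#' @param modality modality tag, `"DWI"` or `"FLAIR"`
#' @return an object of class `image_volume`
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), modality = c("DWI", "FLAIR")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3) stop("image data must be a 3D array")
  if (!all(is.finite(data))) stop("image intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "image_volume")
}

#' Construct a binary ROI mask
#'
#' @param data 3D array with values in {0, 1}
#' @param spacing voxel spacing in mm, length 3, all positive
#' @return an object of class `roi_mask`
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3) stop("mask data must be a 3D array")
  if (!all(data %in% c(0, 1))) stop("mask values must be strictly {0, 1}")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  structure(list(data = array(as.integer(data), dim(data)), spacing = spacing),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s  %s  spacing %s mm>\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask  %s  %d voxels  spacing %s mm>\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}
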