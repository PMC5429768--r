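#' Mask area in square micrometres
#'
#' @param mask An `ifc_mask`.
#' @param pixel_size Pixel edge length in µm.
#' @return Area in µm² (0 for an empty mask).
#' @export
mask_area <- function(mask, pixel_size) {
  stopifnot(is_mask(mask), pixel_size > 0)
  sum(mask$raster) * pixel_size^2
}

#' Intensity-weighted image moments and best-fit-ellipse axes
#'
#' Computes, over the in-mask pixels of a channel, the total intensity, the
#' intensity-weighted centroid and the axes of the ellipse whose second
#' central moments match the intensity-weighted second central moments of the
#' signal. With eigenvalues `lambda1 >= lambda2` of the 2x2 weighted
#' covariance, axis lengths are `4*sqrt(lambda)` pixels (the +/-2-sigma extent
#' of the equivalent-moment ellipse) converted to µm. The minor axis is the
#' "Minor Axis Intensity" feature: the intensity-weighted narrowest dimension
#' of the best-fit ellipse.
#'
#' @param channel Numeric intensity matrix.
#' @param mask An `ifc_mask` (non-empty).
#' @param pixel_size Pixel edge length in µm.
#' @return A list with `total_intensity` (au), `centroid_x`, `centroid_y`
#'   (px, 0-based), `minor_axis`, `major_axis` (µm), and `valid` (FALSE when
#'   the in-mask intensity sums to zero, in which case axis fields are `NA`).
#' @export
intensity_moments <- function(channel, mask, pixel_size) {
  stopifnot(is_mask(mask), all(dim(channel) == dim(mask$raster)))
  if (mask$empty) stop("intensity_moments: empty mask", call. = FALSE)
  idx <- which(mask$raster)
  w <- channel[idx]
  tot <- sum(w)
  if (tot <= 0) {
    return(list(total_intensity = 0, centroid_x = NA_real_,
                centroid_y = NA_real_, minor_axis = NA_real_,
                major_axis = NA_real_, valid = FALSE))
  }
  nr <- nrow(channel)
  y <- (idx - 1L) %% nr
  x <- (idx - 1L) %/% nr
  cx <- sum(w * x) / tot
  cy <- sum(w * y) / tot
  dx <- x - cx; dy <- y - cy
  mxx <- sum(w * dx * dx) / tot
  myy <- sum(w * dy * dy) / tot
  mxy <- sum(w * dx * dy) / tot
  tr2 <- (mxx + myy) / 2
  det_rt <- sqrt(max(((mxx - myy) / 2)^2 + mxy^2, 0))
  l1 <- tr2 + det_rt
  l2 <- max(tr2 - det_rt, 0)
  list(total_intensity = tot, centroid_x = cx, centroid_y = cy,
       minor_axis = 4 * sqrt(l2) * pixel_size,
       major_axis = 4 * sqrt(l1) * pixel_size,
       valid = TRUE)
}

#' Aspect ratio of a mask (minor/major, binary weights)
#'
#' Same moment construction as [intensity_moments()] with unit weights;
#' by convention a single-pixel (degenerate) mask has aspect ratio 1.
#'
#' @param mask An `ifc_mask` (non-empty).
#' @return Ratio in (0, 1].
#' @export
aspect_ratio <- function(mask) {
  stopifnot(is_mask(mask))
  if (mask$empty) stop("aspect_ratio: empty mask", call. = FALSE)
  ones <- matrix(1, nrow(mask$raster), ncol(mask$raster))
  m <- intensity_moments(ones, mask, pixel_size = 1)
  if (!is.finite(m$major_axis) || m$major_axis == 0) return(1)
  m$minor_axis / m$major_axis
}

# internal: Sobel gradient magnitude with edge-replicated borders
sobel_magnitude <- function(channel) {
  nr <- nrow(channel); nc <- ncol(channel)
  pad <- rbind(channel[1, , drop = FALSE], channel, channel[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  s <- function(di, dj) pad[(1 + di):(nr + di), (1 + dj):(nc + dj)]
  # x = column direction, y = row direction
  gx <- (s(0, 2) + 2 * s(1, 2) + s(2, 2)) - (s(0, 0) + 2 * s(1, 0) + s(2, 0))
  gy <- (s(2, 0) + 2 * s(2, 1) + s(2, 2)) - (s(0, 0) + 2 * s(0, 1) + s(0, 2))
  sqrt(gx^2 + gy^2)
}

#' Gradient RMS (image sharpness / focus metric)
#'
#' Root-mean-square of the 3x3 Sobel gradient magnitude over the in-mask
#' pixels. Sharp, in-focus cells have high values; defocused cells low ones.
#'
#' @inheritParams intensity_moments
#' @return Gradient RMS in au.
#' @export
gradient_rms <- function(channel, mask) {
  stopifnot(is_mask(mask), all(dim(channel) == dim(mask$raster)))
  if (mask$empty) stop("gradient_rms: empty mask", call. = FALSE)
  g <- sobel_magnitude(channel)
  sqrt(mean(g[mask$raster]^2))
}

#' Brightfield contrast (brightness-invariant texture metric)
#'
#' [gradient_rms()] divided by the mean in-mask intensity, so a global
#' brightness rescaling cancels. High for the speckled brightfield texture of
#' apoptotic cells, low for smooth healthy cells.
#'
#' @inheritParams intensity_moments
#' @return Dimensionless contrast; `NA` (flagged) when the mean in-mask
#'   intensity is zero.
#' @export
bf_contrast <- function(channel, mask) {
  stopifnot(is_mask(mask))
  if (mask$empty) stop("bf_contrast: empty mask", call. = FALSE)
  m <- mean(channel[mask$raster])
  if (m <= 0) return(NA_real_)
  gradient_rms(channel, mask) / m
}

#' Bright detail intensity (top-hat spot intensity)
#'
#' Sum over in-mask pixels of the positive part of the channel minus its
#' grayscale opening with a disc structuring element: the intensity of
#' localized bright areas after local-background subtraction. High for
#' condensed or speckled (mitotic/apoptotic) nuclei.
#'
#' @inheritParams intensity_moments
#' @param radius Disc radius of the structuring element in pixels (default 3).
#' @return Bright detail intensity in au.
#' @export
bright_detail_intensity <- function(channel, mask, radius = 3L) {
  stopifnot(is_mask(mask), radius >= 1)
  if (mask$empty) return(0)
  radius <- as.integer(radius)
  # the opening at an in-mask pixel depends on a <= 2*radius neighbourhood,
  # so computing on the padded mask bounding box is exact and much faster
  idx <- which(mask$raster, arr.ind = TRUE)
  pad <- 2L * radius
  ri <- max(1L, min(idx[, 1]) - pad):min(nrow(channel), max(idx[, 1]) + pad)
  ci <- max(1L, min(idx[, 2]) - pad):min(ncol(channel), max(idx[, 2]) + pad)
  crop <- channel[ri, ci, drop = FALSE]
  opened <- .gray_morph(.gray_morph(crop, radius, 0L), radius, 1L)
  detail <- pmax(crop - opened, 0)
  sum(detail[mask$raster[ri, ci, drop = FALSE]])
}

#' Pulse-shape analysis (PulSA) triplet
#'
#' Projects the in-mask intensity of a channel onto the x-axis (column sums)
#' to emulate a cytometer pulse: `height` is the profile maximum (au), `area`
#' the profile sum (au), and `width` the number of columns at or above half
#' the maximum (FWHM convention) converted to µm.
#'
#' @inheritParams intensity_moments
#' @return A list with `area`, `width`, `height`, `valid` (`FALSE` with an
#'   all-zero triplet when the profile is identically zero).
#' @export
pulsa_triplet <- function(channel, mask, pixel_size) {
  stopifnot(is_mask(mask), all(dim(channel) == dim(mask$raster)))
  if (mask$empty) stop("pulsa_triplet: empty mask", call. = FALSE)
  prof <- colSums(channel * mask$raster)
  h <- max(prof)
  if (h <= 0) {
    return(list(area = 0, width = 0, height = 0, valid = FALSE))
  }
  list(area = sum(prof),
       width = sum(prof >= 0.5 * h) * pixel_size,
       height = h,
       valid = TRUE)
}
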