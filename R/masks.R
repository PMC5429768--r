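#' Region-of-interest masks
#'
#' A mask is a boolean raster aligned with a cell's channel rasters, together
#' with a recipe string that reconstructs it deterministically. Masks are the
#' regions over which per-cell features are computed.
#'
#' @param raster Logical matrix.
#' @param recipe Character recipe, e.g. `"Threshold(Object(GOLGI),GOLGI,60)"`.
#' @param channel Channel name the mask was derived from.
#' @return An object of class `ifc_mask`.
#' @export
new_mask <- function(raster, recipe = "", channel = NA_character_) {
  stopifnot(is.matrix(raster), is.logical(raster))
  structure(
    list(raster = raster, recipe = recipe, channel = channel,
         empty = !any(raster)),
    class = "ifc_mask"
  )
}

#' @rdname new_mask
#' @param x Object to test/print.
#' @param ... Unused.
#' @export
is_mask <- function(x) inherits(x, "ifc_mask")

#' @rdname new_mask
#' @export
print.ifc_mask <- function(x, ...) {
  cat("<ifc_mask> ", x$recipe, " | ", sum(x$raster), " px",
      if (x$empty) " (empty)" else "", "\n", sep = "")
  invisible(x)
}

#' Number of pixels in a mask
#' @param mask An `ifc_mask`.
#' @return Integer pixel count.
#' @export
mask_size <- function(mask) sum(mask$raster)

#' Default object mask (Otsu threshold + largest component + hole fill)
#'
#' Delineates the principal object on a channel: pixels above the global Otsu
#' threshold, reduced to the largest 8-connected component (or kept whole with
#' `keep = "all"`, appropriate for DNA staining where an anaphase/telophase
#' nucleus is legitimately two objects), with holes filled (4-connected
#' background). A raster in which no pixel exceeds the threshold yields an
#' empty mask, which is a valid, flagged result.
#'
#' @param channel Numeric intensity matrix (finite, non-negative).
#' @param keep `"largest"` (default) keeps only the largest 8-connected
#'   component; `"all"` keeps every component.
#' @param channel_name Optional channel name recorded in the recipe.
#' @return An `ifc_mask`.
#' @export
object_mask <- function(channel, keep = c("largest", "all"),
                        channel_name = NA_character_) {
  keep <- match.arg(keep)
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  rng <- range(channel)
  recipe <- sprintf("Object(%s%s)",
                    if (is.na(channel_name)) "" else channel_name,
                    if (keep == "all") ",all" else "")
  if (rng[1] == rng[2]) {
    return(new_mask(matrix(FALSE, nrow(channel), ncol(channel)),
                    recipe, channel_name))
  }
  norm <- (channel - rng[1]) / (rng[2] - rng[1])
  thr <- otsu_threshold(norm, levels = 256L)
  fg <- norm > thr
  if (!any(fg)) {
    return(new_mask(matrix(FALSE, nrow(channel), ncol(channel)),
                    recipe, channel_name))
  }
  lab <- .cc_label(fg, 8L)
  if (keep == "largest") {
    tab <- tabulate(lab[lab > 0L])
    fg <- lab == which.max(tab)
  }
  new_mask(fill_holes(fg), recipe, channel_name)
}

# Global Otsu threshold on values scaled to [0, 1]: the level (bin upper
# edge) maximising the between-class variance of the histogram.
otsu_threshold <- function(norm, levels = 256L) {
  h <- tabulate(pmin(floor(norm * levels) + 1L, levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  k / levels
}

# Fill holes: background components (4-connected) not touching the border
# are added to the foreground.
fill_holes <- function(fg) {
  bg <- !fg
  lab <- .cc_label(bg, 4L)
  nr <- nrow(fg); nc <- ncol(fg)
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- bg & !(lab %in% border_labels)
  fg | hole
}

#' Threshold mask: the p% highest-intensity pixels of a parent mask
#'
#' The central mask of the analysis: on a given channel, keep the
#' `k = ceiling(p/100 * |parent|)` highest-intensity pixels inside the parent
#' mask (`mode = "count"`, the default, reading "p% highest intensity pixels"
#' literally as a pixel-count fraction). With `mode = "intensity"` the smallest
#' set of highest-intensity pixels accounting for at least p% of the in-mask
#' total intensity is kept instead. Ties at the cutoff intensity are resolved
#' in row-major scan order so the result is bit-reproducible.
#'
#' @param parent Parent `ifc_mask` (must be non-empty).
#' @param channel Numeric intensity matrix aligned with the parent.
#' @param p Percentage in (0, 100].
#' @param mode `"count"` (pixel-count fraction, default) or `"intensity"`
#'   (intensity fraction).
#' @return An `ifc_mask`, a subset of the parent.
#' @export
#' @examples
#' ch <- matrix(1:100, 10, 10)
#' par <- new_mask(matrix(TRUE, 10, 10), "Object(GOLGI)")
#' t60 <- threshold_mask(par, ch, 60)
#' mask_size(t60)  # 60
threshold_mask <- function(parent, channel, p, mode = c("count", "intensity")) {
  mode <- match.arg(mode)
  stopifnot(is_mask(parent), is.matrix(channel),
            all(dim(channel) == dim(parent$raster)))
  if (parent$empty) stop("threshold_mask: parent mask is empty", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 100) {
    stop("`p` must be in (0, 100]", call. = FALSE)
  }
  idx <- which(parent$raster)            # column-major linear indices
  w <- channel[idx]
  nr <- nrow(channel)
  i <- ((idx - 1L) %% nr)                # 0-based row
  j <- ((idx - 1L) %/% nr)               # 0-based col
  rm_order <- i * ncol(channel) + j      # row-major scan position
  ord <- order(-w, rm_order)
  if (mode == "count") {
    k <- ceiling(p / 100 * length(idx))
  } else {
    tot <- sum(w)
    if (tot <= 0) {
      k <- length(idx)
    } else {
      k <- which(cumsum(w[ord]) >= p / 100 * tot)[1]
      if (is.na(k)) k <- length(idx)
    }
  }
  keep <- idx[ord[seq_len(k)]]
  out <- matrix(FALSE, nrow(channel), ncol(channel))
  out[keep] <- TRUE
  new_mask(out,
           sprintf("Threshold(%s,%s,%g%s)", parent$recipe,
                   if (is.na(parent$channel)) "" else parent$channel, p,
                   if (mode == "intensity") ",intensity" else ""),
           parent$channel)
}

#' Dilate a mask by a disc of the given pixel radius
#'
#' Used for intensity features where the thresholded foreground clips the
#' dim tails of the signal (e.g. total DNA content): dilating the object
#' mask recovers them.
#'
#' @param mask An `ifc_mask`.
#' @param radius Disc radius in px.
#' @return The dilated `ifc_mask`.
#' @export
dilate_mask <- function(mask, radius = 3L) {
  stopifnot(is_mask(mask), radius >= 1)
  if (mask$empty) return(mask)
  num <- matrix(as.numeric(mask$raster), nrow(mask$raster))
  out <- .gray_morph(num, as.integer(radius), 1L) > 0.5
  new_mask(out, sprintf("Dilate(%s,%d)", mask$recipe, as.integer(radius)),
           mask$channel)
}

#' Count 8-connected components of a mask
#'
#' @param mask An `ifc_mask`.
#' @return Integer count (0 for an empty mask).
#' @export
count_components <- function(mask) {
  stopifnot(is_mask(mask))
  if (mask$empty) return(0L)
  max(.cc_label(mask$raster, 8L))
}

# internal: per-component intensity-weighted centroids (px, 0-based),
# used for the anaphase/telophase separation rule.
component_centroids <- function(mask, channel) {
  if (mask$empty) return(matrix(numeric(0), ncol = 2))
  lab <- .cc_label(mask$raster, 8L)
  ks <- seq_len(max(lab))
  out <- t(vapply(ks, function(k) {
    idx <- which(lab == k)
    w <- channel[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    nr <- nrow(channel)
    y <- (idx - 1L) %% nr
    x <- (idx - 1L) %/% nr
    c(sum(w * x), sum(w * y)) / sum(w)
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}
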