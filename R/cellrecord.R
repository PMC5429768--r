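#' Single-cell image record
#'
#' The atomic unit of analysis: one cell's aligned channel rasters plus
#' metadata. Channels are named intensity matrices (arbitrary units, finite,
#' non-negative) sharing identical dimensions; pixel coordinates are row-major
#' and 0-based with pixel centers at integer coordinates, and all lengths are
#' reported in micrometres via `pixel_size`.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param channels Named list of numeric matrices. Names must be a subset of
#'   `c("BF", "GOLGI", "DNA")` (brightfield, Golgi marker fluorescence, DNA
#'   stain); all matrices must share the same dimensions.
#' @param pixel_size Pixel edge length in micrometres (square pixels, > 0).
#' @param meta Named list of character metadata (sample id, treatment,
#'   replicate, ...).
#'
#' @return An object of class `cell_record`.
#' @export
#' @examples
#' ch <- matrix(runif(64 * 64, 0, 100), 64, 64)
#' cr <- cell_record("c1", list(BF = ch, GOLGI = ch, DNA = ch), pixel_size = 0.5)
#' cr
cell_record <- function(cell_id, channels, pixel_size, meta = list()) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nzchar(cell_id))
  if (!is.list(channels) || is.null(names(channels)) ||
      !all(names(channels) %in% c("BF", "GOLGI", "DNA"))) {
    stop("`channels` must be a named list with names among BF, GOLGI, DNA",
         call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channel rasters of cell '", cell_id,
         "' must share identical dimensions", call. = FALSE)
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) {
      stop("channel '", nm, "' must be a numeric matrix", call. = FALSE)
    }
    if (!all(is.finite(ch)) || any(ch < 0)) {
      stop("channel '", nm, "' of cell '", cell_id,
           "' contains non-finite or negative intensities", call. = FALSE)
    }
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um)", call. = FALSE)
  }
  structure(
    list(cell_id = cell_id, channels = channels,
         pixel_size = as.numeric(pixel_size), meta = meta),
    class = "cell_record"
  )
}

#' @rdname cell_record
#' @param x Object to test or print.
#' @export
is_cell_record <- function(x) inherits(x, "cell_record")

#' @rdname cell_record
#' @param ... Unused.
#' @export
print.cell_record <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<cell_record> ", x$cell_id, ": ",
      paste(names(x$channels), collapse = "/"),
      " ", d[1], "x", d[2], " px @ ", x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

# internal: fetch a channel or fail loudly
get_channel <- function(cell, channel) {
  ch <- cell$channels[[channel]]
  if (is.null(ch)) {
    stop("cell '", cell$cell_id, "' has no channel '", channel, "'",
         call. = FALSE)
  }
  ch
}
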