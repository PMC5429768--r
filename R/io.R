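#' Write a sample (cells + manifest, optionally ground truth) to disk
#'
#' Each cell is written as one multi-page 16-bit TIFF with pages in the fixed
#' order BF, GOLGI, DNA, alongside a `manifest.csv` with columns `cell_id`,
#' `tiff_path`, `condition`, `replicate`, `pixel_size`. Intensities are
#' integers in 0..65535 and round-trip exactly through [read_sample()].
#'
#' @param cells List of [cell_record()]s.
#' @param dir Output directory (created if needed).
#' @param condition,replicate Sample annotations for the manifest.
#' @param truth Optional ground-truth tibble (written to `ground_truth.csv`).
#' @return Invisibly, the manifest path.
#' @export
write_sample <- function(cells, dir, condition = "unknown", replicate = 1L,
                         truth = NULL) {
  if (is_cell_record(cells)) cells <- list(cells)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cell_ids in sample", call. = FALSE)
  paths <- file.path(dir, paste0(ids, ".tif"))
  for (i in seq_along(cells)) {
    ch <- cells[[i]]$channels
    pages <- lapply(c("BF", "GOLGI", "DNA"), function(nm) {
      m <- ch[[nm]]
      if (is.null(m)) stop("cell '", ids[i], "' lacks channel ", nm,
                           call. = FALSE)
      if (any(m > 65535)) stop("intensities exceed 16-bit range",
                               call. = FALSE)
      round(m) / 65535
    })
    tiff::writeTIFF(pages, paths[i], bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
  }
  manifest <- data.frame(
    cell_id = ids, tiff_path = basename(paths),
    condition = condition, replicate = as.integer(replicate),
    pixel_size = vapply(cells, function(c) c$pixel_size, numeric(1)))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(truth)) {
    write.csv(as.data.frame(truth), file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  }
  invisible(mpath)
}

#' Read a sample from a manifest CSV
#'
#' The manifest must have columns `cell_id`, `tiff_path`, `condition`,
#' `replicate`; each TIFF must have at least 3 pages in the fixed order
#' BF, GOLGI, DNA. The pixel size is taken from TIFF resolution tags when
#' present, else from a manifest `pixel_size` column; otherwise reading
#' fails. Cells are returned in manifest order, never reordered.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list with `manifest` (tibble) and `cells`
#'   (list of [cell_record()] in manifest order).
#' @export
read_sample <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("cell_id", "tiff_path", "condition", "replicate")
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(man$cell_id)) {
    stop("duplicate cell_ids in manifest", call. = FALSE)
  }
  base <- dirname(manifest_path)
  cells <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$tiff_path[i]
    if (!file.exists(p)) p <- file.path(base, man$tiff_path[i])
    if (!file.exists(p)) {
      stop("cell '", man$cell_id[i], "': image file not found: ",
           man$tiff_path[i], call. = FALSE)
    }
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE, info = TRUE)
    if (length(pages) < 3L) {
      stop("cell '", man$cell_id[i], "': TIFF has ", length(pages),
           " page(s); need >= 3 (BF, GOLGI, DNA)", call. = FALSE)
    }
    dims <- lapply(pages[1:3], dim)
    if (length(unique(lapply(dims, as.integer))) != 1L) {
      stop("cell '", man$cell_id[i],
           "': channel rasters have mismatched shapes", call. = FALSE)
    }
    ps <- tiff_pixel_size(pages[[1]])
    if (is.na(ps)) ps <- suppressWarnings(as.numeric(man$pixel_size[i]))
    if (is.null(ps) || length(ps) == 0 || is.na(ps)) {
      stop("cell '", man$cell_id[i],
           "': pixel size neither in TIFF tags nor in a manifest ",
           "'pixel_size' column", call. = FALSE)
    }
    chs <- lapply(pages[1:3], function(m) {
      storage.mode(m) <- "double"
      matrix(m, nrow(m), ncol(m))
    })
    names(chs) <- c("BF", "GOLGI", "DNA")
    cells[[i]] <- cell_record(as.character(man$cell_id[i]), chs,
                              pixel_size = ps,
                              meta = list(condition = man$condition[i],
                                          replicate = man$replicate[i]))
  }
  list(manifest = tibble::as_tibble(man), cells = cells)
}

# pixel size (um) from TIFF resolution tags, NA if absent/unusable
tiff_pixel_size <- function(page) {
  info <- attr(page, "info")
  if (is.null(info) || is.null(info$x.resolution)) return(NA_real_)
  xr <- info$x.resolution
  if (!is.numeric(xr) || xr <= 0) return(NA_real_)
  unit <- if (is.null(info$resolution.unit)) "inch" else info$resolution.unit
  per_um <- switch(as.character(unit),
                   inch = xr / 25400, cm = xr / 10000, xr)
  if (per_um <= 0) return(NA_real_)
  1 / per_um
}

#' Write / read a feature table as CSV with a provenance sidecar
#'
#' The CSV has `cell_id` first and one column per feature with units in the
#' header as `name[unit]`; values are written with 15 significant digits so a
#' write/read round trip preserves them to at least 12. Provenance (channel,
#' mask recipe, unit per feature) goes to `<path>.provenance.json`.
#'
#' @param table An `ifc_features` tibble from [compute_features()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  prov <- attr(table, "provenance")
  if (is.null(prov)) prov <- default_feature_panel()
  df <- as.data.frame(table)
  units <- setNames(prov$unit, prov$feature)
  hdr <- vapply(names(df), function(nm) {
    if (nm == "cell_id") "cell_id"
    else sprintf("%s[%s]", nm, if (nm %in% names(units)) units[[nm]] else "au")
  }, character(1))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  if (nrow(df) > 0) {
    write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- sub("\\[[^]]*\\]$", "", names(df))
  num <- setdiff(names(df), "cell_id")
  df[num] <- lapply(df[num], as.numeric)
  tab <- tibble::new_tibble(tibble::as_tibble(df), class = "ifc_features")
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    attr(tab, "provenance") <-
      tibble::as_tibble(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  tab
}
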