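#' The default per-cell feature panel
#'
#' The mask-by-feature combinations the gating hierarchy operates on, with
#' units and mask recipes. Column names are fixed strings used throughout the
#' package and in exported CSVs.
#'
#' @return A tibble with columns `feature`, `channel`, `mask`, `unit`.
#' @export
default_feature_panel <- function() {
  tibble::tribble(
    ~feature,                        ~channel, ~mask,                          ~unit,
    "golgi_t60_area",                "GOLGI",  "Threshold(Object(GOLGI,all),GOLGI,60)", "um2",
    "golgi_t60_minor_axis_intensity","GOLGI",  "Threshold(Object(GOLGI,all),GOLGI,60)", "um",
    "bf_area",                       "BF",     "Object(BF)",                   "um2",
    "bf_aspect_ratio",               "BF",     "Object(BF)",                   "ratio",
    "bf_gradient_rms",               "BF",     "Object(BF)",                   "au",
    "bf_contrast",                   "BF",     "Object(BF)",                   "1",
    "dna_total_intensity",           "DNA",    "Dilate(Object(DNA,all),3)",    "au",
    "dna_bdi_r3",                    "DNA",    "Object(DNA,all)",              "au",
    "dna_t50_area",                  "DNA",    "Threshold(Object(DNA,all),DNA,50)", "um2",
    "dna_components",                "DNA",    "Object(DNA,all)",              "count",
    "dna_centroid_sep",              "DNA",    "Object(DNA,all)",              "um",
    "pulsa_area",                    "GOLGI",  "Object(BF)",                   "au",
    "pulsa_width",                   "GOLGI",  "Object(BF)",                   "um",
    "pulsa_height",                  "GOLGI",  "Object(BF)",                   "au"
  )
}

# internal: all panel features for one cell; NA marks flagged-invalid values
compute_cell_features <- function(cell, golgi_pct = 60, dna_pct = 50,
                                  bdi_radius = 3L,
                                  threshold_mode = "count") {
  ps <- cell$pixel_size
  bf <- get_channel(cell, "BF")
  golgi <- get_channel(cell, "GOLGI")
  dna <- get_channel(cell, "DNA")

  out <- list(cell_id = cell$cell_id)
  bf_obj <- object_mask(bf, channel_name = "BF")
  if (bf_obj$empty) {
    out[c("bf_area", "bf_aspect_ratio", "bf_gradient_rms", "bf_contrast",
          "pulsa_area", "pulsa_width", "pulsa_height")] <- NA_real_
  } else {
    out$bf_area <- mask_area(bf_obj, ps)
    out$bf_aspect_ratio <- aspect_ratio(bf_obj)
    out$bf_gradient_rms <- gradient_rms(bf, bf_obj)
    out$bf_contrast <- bf_contrast(bf, bf_obj)
    p <- pulsa_triplet(golgi, bf_obj, ps)
    out$pulsa_area <- p$area
    out$pulsa_width <- p$width
    out$pulsa_height <- p$height
  }

  golgi_obj <- object_mask(golgi, keep = "all", channel_name = "GOLGI")
  if (golgi_obj$empty) {
    out[c("golgi_t60_area", "golgi_t60_minor_axis_intensity")] <- NA_real_
  } else {
    t60 <- threshold_mask(golgi_obj, golgi, golgi_pct, mode = threshold_mode)
    out$golgi_t60_area <- mask_area(t60, ps)
    m <- intensity_moments(golgi, t60, ps)
    out$golgi_t60_minor_axis_intensity <-
      if (m$valid) m$minor_axis else NA_real_
  }

  dna_obj <- object_mask(dna, keep = "all", channel_name = "DNA")
  if (dna_obj$empty) {
    out[c("dna_total_intensity", "dna_bdi_r3", "dna_t50_area",
          "dna_centroid_sep")] <- NA_real_
    out$dna_components <- 0
  } else {
    out$dna_total_intensity <- sum(dna[dilate_mask(dna_obj, 3L)$raster])
    out$dna_bdi_r3 <- bright_detail_intensity(dna, dna_obj, bdi_radius)
    t50 <- threshold_mask(dna_obj, dna, dna_pct, mode = threshold_mode)
    out$dna_t50_area <- mask_area(t50, ps)
    ncomp <- count_components(dna_obj)
    out$dna_components <- as.numeric(ncomp)
    if (ncomp == 2L) {
      cen <- component_centroids(dna_obj, dna)
      out$dna_centroid_sep <-
        sqrt(sum((cen[1, ] - cen[2, ])^2)) * ps
    } else {
      out$dna_centroid_sep <- NA_real_
    }
  }
  out
}

#' Compute the per-cell feature table
#'
#' Turns a list of [cell_record()]s into a tidy feature table: one row per
#' cell, one column per feature of the default panel (see
#' [default_feature_panel()]). Invalid values (empty masks, zero in-mask
#' intensity) are flagged as `NA`, never dropped; row order equals input
#' order. The panel definition (channel, mask recipe, unit per feature) is
#' attached as the `"provenance"` attribute and written to a sidecar JSON by
#' [write_feature_table()].
#'
#' @param cells List of [cell_record()]s (or the `cells` element of
#'   [sample_population()] output).
#' @param golgi_pct Threshold-mask percentage for the Golgi channel
#'   (default 60).
#' @param dna_pct Threshold-mask percentage for the DNA channel (default 50).
#' @param bdi_radius Bright-detail disc radius in px (default 3).
#' @param threshold_mode `"count"` or `"intensity"`; see [threshold_mask()].
#' @return A tibble of class `ifc_features` with `cell_id` first.
#' @export
#' @examples
#' pop <- sample_population(get_preset("exemplars"), n = 5, seed = 1)
#' compute_features(pop$cells)
compute_features <- function(cells, golgi_pct = 60, dna_pct = 50,
                             bdi_radius = 3L, threshold_mode = "count") {
  if (is_cell_record(cells)) cells <- list(cells)
  stopifnot(length(cells) >= 1, all(vapply(cells, is_cell_record, logical(1))))
  rows <- purrr::map(cells, compute_cell_features,
                     golgi_pct = golgi_pct, dna_pct = dna_pct,
                     bdi_radius = bdi_radius,
                     threshold_mode = threshold_mode)
  tab <- dplyr::bind_rows(rows)
  panel <- default_feature_panel()
  tab <- tab[, c("cell_id", intersect(panel$feature, names(tab)))]
  tab <- tibble::new_tibble(tab, class = "ifc_features")
  attr(tab, "provenance") <- default_feature_panel()
  attr(tab, "params") <- list(golgi_pct = golgi_pct, dna_pct = dna_pct,
                              bdi_radius = bdi_radius,
                              threshold_mode = threshold_mode)
  tab
}

# internal: feature columns of a feature table (everything numeric but ids)
feature_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))], "cell_id")
}
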