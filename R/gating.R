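#' Fisher's discriminant separation (RD value)
#'
#' `RD = (mean(b) - mean(a)) / (sd(a) + sd(b))` with sample standard
#' deviations. The sign records direction; `|RD|` is used for ranking.
#' When both SDs are zero, equal means give 0 and unequal means give a
#' signed `Inf` (flagged infinite separation).
#'
#' @param values_a,values_b Numeric vectors (length >= 2, finite).
#' @return The signed RD value.
#' @export
#' @examples
#' rd_value(rnorm(100), rnorm(100, mean = 3))
rd_value <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2,
            all(is.finite(values_a)), all(is.finite(values_b)))
  denom <- sd(values_a) + sd(values_b)
  delta <- mean(values_b) - mean(values_a)
  if (denom == 0) {
    if (delta == 0) return(0)
    return(sign(delta) * Inf)
  }
  delta / denom
}

#' Rank features by Fisher's discriminant between two labeled populations
#'
#' Computes the RD value of every numeric feature column between the two
#' classes and orders by decreasing `|RD|` (deterministic tie-break by
#' feature name). Flagged-invalid (`NA`) entries are excluded pairwise per
#' feature and the exclusion count reported.
#'
#' @param table A feature table ([compute_features()]).
#' @param labels Two-class labeling, one label per row of `table`.
#' @return A tibble of class `rd_ranking` with columns `feature`, `rd`,
#'   `n_a`, `n_b`, `n_excluded`, ordered by descending `|rd|`. The class
#'   pair (sorted; `a` first) is attached as attribute `"classes"`.
#' @export
rank_features <- function(table, labels) {
  stopifnot(nrow(table) == length(labels))
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2) {
    stop("`labels` must contain exactly two classes, got: ",
         paste(cls, collapse = ", "), call. = FALSE)
  }
  feats <- feature_columns(table)
  rows <- purrr::map(feats, function(f) {
    x <- table[[f]]
    ok <- is.finite(x)
    a <- x[ok & labels == cls[1]]
    b <- x[ok & labels == cls[2]]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(feature = f, rd = NA_real_,
                            n_a = length(a), n_b = length(b),
                            n_excluded = sum(!ok)))
    }
    tibble::tibble(feature = f, rd = rd_value(a, b),
                   n_a = length(a), n_b = length(b), n_excluded = sum(!ok))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(abs(.data$rd)), .data$feature)
  out <- tibble::new_tibble(out, class = "rd_ranking")
  attr(out, "classes") <- cls
  out
}

# variance-weighted midpoint between two class centers: the boundary sits
# closer to the tighter class
vw_midpoint <- function(m1, s1, m2, s2) {
  if (s1 + s2 == 0) return((m1 + m2) / 2)
  (m1 * s2 + m2 * s1) / (s1 + s2)
}

require_columns <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

require_thresholds <- function(cfg, section, fields) {
  v <- unlist(cfg[[section]][fields])
  if (any(is.na(v))) {
    stop("gate config section '", section, "' has uncalibrated thresholds (",
         paste(fields[is.na(v)], collapse = ", "),
         "); run calibrate_gate_config()", call. = FALSE)
  }
}

#' Singlet and focus gates
#'
#' A cell passes the singlet gate when its brightfield object area lies in
#' the configured range and its aspect ratio is at least the configured
#' minimum (doublets are larger and more elongated); it passes the focus
#' gate when the brightfield gradient RMS is at least the configured minimum.
#'
#' @param table Feature table with `bf_area`, `bf_aspect_ratio`,
#'   `bf_gradient_rms`.
#' @param config A calibrated [gate_config()].
#' @return A tibble `cell_id`, `singlet`, `focused` (`NA` features fail).
#' @export
gate_singlets_focused <- function(table, config) {
  require_columns(table, c("bf_area", "bf_aspect_ratio", "bf_gradient_rms"))
  require_thresholds(config, "singlet", c("area_min", "area_max", "aspect_min"))
  require_thresholds(config, "focus", "gradient_rms_min")
  s <- config$singlet
  singlet <- !is.na(table$bf_area) & !is.na(table$bf_aspect_ratio) &
    table$bf_area >= s$area_min & table$bf_area <= s$area_max &
    table$bf_aspect_ratio >= s$aspect_min
  focused <- !is.na(table$bf_gradient_rms) &
    table$bf_gradient_rms >= config$focus$gradient_rms_min
  tibble::tibble(cell_id = table$cell_id, singlet = singlet,
                 focused = focused)
}

# G1 mode of a DNA-content distribution: the lowest-intensity density peak
# whose height is at least 25% of the tallest (robust to G2/M-arrested
# samples where the 4N peak dominates)
dna_g1_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite DNA intensities", call. = FALSE)
  if (sd(x) == 0) return(x[1])
  d <- density(x, n = 512)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  px <- d$x[is_peak]
  py <- y[is_peak]
  if (length(px) == 0) {
    stop("no detectable DNA-content peak; set the G1 mode manually",
         call. = FALSE)
  }
  keep <- py >= 0.25 * max(py)
  min(px[keep])
}

#' DNA-content (cell-cycle) gate
#'
#' Anchors the G1 (2N) mode of the total DNA-stain intensity distribution and
#' labels each cell by the configured windows relative to that mode:
#' G1 within 0.75-1.25x, G2/M within 1.7-2.3x, above 2.3x excluded
#' (aggregates), anything else S/indeterminate.
#'
#' @param table Feature table with `dna_total_intensity` (>= 50 cells).
#' @param config A [gate_config()] (supplies the windows).
#' @param g1_mode Optional known G1 mode (au); estimated when `NULL`.
#' @return A tibble `cell_id`, `cycle` (factor G1/S/G2M/excluded),
#'   with the estimated mode as attribute `"g1_mode"`.
#' @export
gate_dna_content <- function(table, config = gate_config(), g1_mode = NULL) {
  require_columns(table, "dna_total_intensity")
  if (nrow(table) < 50 && is.null(g1_mode)) {
    stop("need >= 50 cells to estimate the G1 mode; pass `g1_mode`",
         call. = FALSE)
  }
  x <- table$dna_total_intensity
  if (is.null(g1_mode)) g1_mode <- dna_g1_mode(x)
  g1w <- config$dna$g1_window
  g2w <- config$dna$g2m_window
  r <- x / g1_mode
  cycle <- dplyr::case_when(
    is.na(r) ~ NA_character_,
    r >= g1w[1] & r <= g1w[2] ~ "G1",
    r >= g2w[1] & r <= g2w[2] ~ "G2M",
    r > g2w[2] ~ "excluded",
    TRUE ~ "S"
  )
  out <- tibble::tibble(
    cell_id = table$cell_id,
    cycle = factor(cycle, levels = c("G1", "S", "G2M", "excluded")))
  attr(out, "g1_mode") <- g1_mode
  out
}

#' Mitotic sub-phase classification within G2/M
#'
#' Rule cascade on the G2/M population: DNA bright-detail intensity below
#' threshold means interphase G2 (`none`); otherwise a two-component DNA
#' object is anaphase when the inter-centroid separation exceeds the
#' configured minimum, else telophase; a single compact object
#' (Threshold-50 DNA area below threshold) is metaphase (prometaphase,
#' the microtubule-poison arrest state, folds in here); the remainder is
#' prophase.
#'
#' @param table Feature table with `dna_bdi_r3`, `dna_components`,
#'   `dna_centroid_sep`, `dna_t50_area`.
#' @param cycle Cycle labels from [gate_dna_content()] (vector or tibble).
#' @param config A calibrated [gate_config()].
#' @return A tibble `cell_id`, `mitotic` (factor none/prophase/metaphase/
#'   anaphase/telophase; `none` outside G2/M).
#' @export
classify_mitotic <- function(table, cycle, config) {
  require_columns(table, c("dna_bdi_r3", "dna_components",
                           "dna_centroid_sep", "dna_t50_area"))
  require_thresholds(config, "mitotic",
                     c("bdi_min", "metaphase_t50_area_max",
                       "anaphase_sep_min"))
  if (is.data.frame(cycle)) cycle <- cycle$cycle
  stopifnot(length(cycle) == nrow(table))
  m <- config$mitotic
  in_g2m <- !is.na(cycle) & cycle == "G2M"
  lab <- rep("none", nrow(table))
  hot <- in_g2m & !is.na(table$dna_bdi_r3) & table$dna_bdi_r3 >= m$bdi_min
  two <- hot & table$dna_components == 2
  lab[two & !is.na(table$dna_centroid_sep) &
        table$dna_centroid_sep > m$anaphase_sep_min] <- "anaphase"
  lab[two & (is.na(table$dna_centroid_sep) |
               table$dna_centroid_sep <= m$anaphase_sep_min)] <- "telophase"
  one <- hot & table$dna_components == 1
  lab[one & !is.na(table$dna_t50_area) &
        table$dna_t50_area < m$metaphase_t50_area_max] <- "metaphase"
  lab[hot & lab == "none"] <- "prophase"
  tibble::tibble(
    cell_id = table$cell_id,
    mitotic = factor(lab, levels = c("none", "prophase", "metaphase",
                                     "anaphase", "telophase")))
}

#' Apoptosis gate
#'
#' A cell is flagged apoptotic when its brightfield contrast is at least the
#' configured minimum and its Threshold-50 DNA area at most the configured
#' maximum — high contrast plus condensed (low-area) DNA staining.
#'
#' @param table Feature table with `bf_contrast`, `dna_t50_area`.
#' @param config A calibrated [gate_config()].
#' @return A tibble `cell_id`, `apoptotic` (logical; `NA` features fail).
#' @export
gate_apoptotic <- function(table, config) {
  require_columns(table, c("bf_contrast", "dna_t50_area"))
  require_thresholds(config, "apoptosis",
                     c("bf_contrast_min", "dna_t50_area_max"))
  a <- config$apoptosis
  flag <- !is.na(table$bf_contrast) & !is.na(table$dna_t50_area) &
    table$bf_contrast >= a$bf_contrast_min &
    table$dna_t50_area <= a$dna_t50_area_max
  tibble::tibble(cell_id = table$cell_id, apoptotic = flag)
}

#' Fit the three Golgi morphology gates from labeled exemplars
#'
#' Given exemplar cells labeled intact / partial / full, computes per-class
#' means and SDs of x = Threshold-60 minor axis intensity (µm) and
#' y = Threshold-60 area (µm²), places the boundary between adjacent classes
#' on each axis at the variance-weighted midpoint
#' `t = (mu1*s2 + mu2*s1) / (s1 + s2)`, and returns the resulting partition
#' (intact: both coordinates at or below the lower boundaries; full: both
#' strictly above the upper boundaries; partial: the rest). Class means must
#' be ordered intact < partial < full on both axes.
#'
#' @param table Feature table of the exemplars.
#' @param labels Class label per row (`INTACT`/`PARTIAL`/`FULL`, any case).
#' @return An object of class `golgi_gates` with elements `boundaries`,
#'   `class_stats` and `resubstitution` (accuracy on the exemplars).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_golgi_gates <- function(table, labels) {
  require_columns(table, c("golgi_t60_minor_axis_intensity",
                           "golgi_t60_area"))
  lab <- toupper(as.character(labels))
  stopifnot(nrow(table) == length(lab))
  bad <- setdiff(unique(lab), GOLGI_CLASSES)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  x <- table$golgi_t60_minor_axis_intensity
  y <- table$golgi_t60_area
  ok <- is.finite(x) & is.finite(y)
  stats <- dplyr::bind_rows(lapply(GOLGI_CLASSES, function(cl) {
    sel <- ok & lab == cl
    if (sum(sel) < 30) {
      stop("need >= 30 valid exemplars per class; '", cl, "' has ",
           sum(sel), call. = FALSE)
    }
    tibble::tibble(class = cl, n = sum(sel),
                   x_mean = mean(x[sel]), x_sd = sd(x[sel]),
                   y_mean = mean(y[sel]), y_sd = sd(y[sel]))
  }))
  for (ax in c("x", "y")) {
    m <- stats[[paste0(ax, "_mean")]]
    if (!(m[1] < m[2] && m[2] < m[3])) {
      stop("class means not ordered intact < partial < full on the ", ax,
           " axis (", paste(sprintf("%s=%.3g", stats$class, m),
                            collapse = ", "), ")", call. = FALSE)
    }
  }
  bnd <- list(
    x_intact_max = vw_midpoint(stats$x_mean[1], stats$x_sd[1],
                               stats$x_mean[2], stats$x_sd[2]),
    y_intact_max = vw_midpoint(stats$y_mean[1], stats$y_sd[1],
                               stats$y_mean[2], stats$y_sd[2]),
    x_full_min = vw_midpoint(stats$x_mean[2], stats$x_sd[2],
                             stats$x_mean[3], stats$x_sd[3]),
    y_full_min = vw_midpoint(stats$y_mean[2], stats$y_sd[2],
                             stats$y_mean[3], stats$y_sd[3])
  )
  gates <- structure(
    list(boundaries = bnd, class_stats = stats,
         x_feature = "golgi_t60_minor_axis_intensity",
         y_feature = "golgi_t60_area"),
    class = "golgi_gates")
  pred <- classify_golgi(table, gates)$golgi
  gates$resubstitution <- tibble::tibble(
    n = sum(ok),
    accuracy = mean(toupper(as.character(pred))[ok] == lab[ok]))
  gates
}

#' @rdname fit_golgi_gates
#' @param x A `golgi_gates` object.
#' @param ... Unused.
#' @export
print.golgi_gates <- function(x, ...) {
  b <- x$boundaries
  cat("<golgi_gates>\n",
      sprintf("  intact: x <= %.3f um  & y <= %.3f um2\n",
              b$x_intact_max, b$y_intact_max),
      sprintf("  full:   x >  %.3f um  & y >  %.3f um2\n",
              b$x_full_min, b$y_full_min),
      "  partial: elsewhere\n",
      sprintf("  resubstitution accuracy: %.1f%% (n = %d)\n",
              100 * x$resubstitution$accuracy, x$resubstitution$n), sep = "")
  invisible(x)
}

# boundaries from either a golgi_gates fit or a gate_config
golgi_boundaries <- function(gates) {
  b <- if (inherits(gates, "golgi_gates")) gates$boundaries
       else if (inherits(gates, "gate_config")) gates$golgi_gates
       else stop("`gates` must be a golgi_gates or gate_config object",
                 call. = FALSE)
  v <- unlist(b[c("x_intact_max", "y_intact_max", "x_full_min", "y_full_min")])
  if (any(is.na(v))) stop("golgi gates are not calibrated", call. = FALSE)
  if (b$x_intact_max > b$x_full_min || b$y_intact_max > b$y_full_min) {
    stop("invalid golgi gates: regions overlap", call. = FALSE)
  }
  b
}

#' Classify cells into Golgi morphology populations
#'
#' Applies fitted Golgi gates to the (minor axis intensity, area) plane:
#' every finite point receives exactly one of intact / partial / full
#' (boundaries closed below, open above); flagged-invalid coordinates give
#' `unassigned`.
#'
#' @param table Feature table.
#' @param gates A [fit_golgi_gates()] result or calibrated [gate_config()].
#' @param eligible Optional logical vector; ineligible cells are
#'   `unassigned`.
#' @return A tibble `cell_id`, `golgi`
#'   (factor intact/partial/full/unassigned).
#' @export
classify_golgi <- function(table, gates, eligible = NULL) {
  require_columns(table, c("golgi_t60_minor_axis_intensity",
                           "golgi_t60_area"))
  b <- golgi_boundaries(gates)
  x <- table$golgi_t60_minor_axis_intensity
  y <- table$golgi_t60_area
  lab <- dplyr::case_when(
    !is.finite(x) | !is.finite(y) ~ "unassigned",
    x <= b$x_intact_max & y <= b$y_intact_max ~ "intact",
    x > b$x_full_min & y > b$y_full_min ~ "full",
    TRUE ~ "partial"
  )
  if (!is.null(eligible)) lab[!eligible] <- "unassigned"
  tibble::tibble(
    cell_id = table$cell_id,
    golgi = factor(lab, levels = c("intact", "partial", "full",
                                   "unassigned")))
}

#' Run the full hierarchical gating
#'
#' Singlets -> focused -> DNA content -> (mitotic sub-phase | apoptosis) ->
#' Golgi morphology, in one call. Golgi labels are assigned only to eligible
#' (singlet and focused) cells; mitotic labels only within G2/M; cycle and
#' apoptosis are evaluated on eligible cells.
#'
#' @param table Feature table ([compute_features()]).
#' @param config A fully calibrated [gate_config()].
#' @return A `gating_result` tibble: `cell_id`, `singlet`, `focused`,
#'   `eligible`, `cycle`, `mitotic`, `apoptotic`, `golgi`.
#' @export
#' @examples
#' \donttest{
#' cfg <- calibrate_gate_config(seed = 2, n_exemplar = 40, n_calib = 40)
#' pop <- sample_population(get_preset("untreated"), n = 60, seed = 1)
#' gate_cells(compute_features(pop$cells), cfg)
#' }
gate_cells <- function(table, config) {
  sf <- gate_singlets_focused(table, config)
  eligible <- sf$singlet & sf$focused
  cycle <- factor(rep(NA_character_, nrow(table)),
                  levels = c("G1", "S", "G2M", "excluded"))
  if (sum(eligible) > 0) {
    cyc <- gate_dna_content(table[eligible, , drop = FALSE], config,
                            g1_mode = if (sum(eligible) < 50) {
                              dna_g1_mode(table$dna_total_intensity)
                            } else NULL)
    cycle[eligible] <- cyc$cycle
  }
  mit <- classify_mitotic(table, cycle, config)
  apo_all <- gate_apoptotic(table, config)
  apoptotic <- ifelse(eligible, apo_all$apoptotic, NA)
  golgi <- classify_golgi(table, config, eligible = eligible)
  out <- tibble::tibble(
    cell_id = table$cell_id,
    singlet = sf$singlet, focused = sf$focused, eligible = eligible,
    cycle = cycle, mitotic = mit$mitotic, apoptotic = apoptotic,
    golgi = golgi$golgi)
  tibble::new_tibble(out, class = "gating_result")
}
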