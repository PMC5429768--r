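GATE_CONFIG_KEYS <- c("schema_version", "masks", "singlet", "focus", "dna",
                      "mitotic", "apoptosis", "golgi_gates")

gate_config_defaults <- function() {
  list(
    schema_version = 1L,
    masks = list(golgi_threshold_pct = 60, dna_threshold_pct = 50,
                 bright_detail_radius = 3, threshold_mode = "count"),
    singlet = list(area_min = NA_real_, area_max = NA_real_,
                   aspect_min = NA_real_),
    focus = list(gradient_rms_min = NA_real_),
    dna = list(g1_window = c(0.75, 1.25), g2m_window = c(1.7, 2.3)),
    mitotic = list(bdi_min = NA_real_, metaphase_t50_area_max = NA_real_,
                   anaphase_sep_min = NA_real_),
    apoptosis = list(bf_contrast_min = NA_real_, dna_t50_area_max = NA_real_),
    golgi_gates = list(x_intact_max = NA_real_, y_intact_max = NA_real_,
                       x_full_min = NA_real_, y_full_min = NA_real_)
  )
}

#' Gating configuration
#'
#' Serialized thresholds and regions for every gate in the hierarchy plus the
#' mask parameters. Absent optional fields are filled with defaults
#' (Golgi threshold 60%, DNA threshold 50%, bright-detail radius 3 px,
#' conventional DNA-content windows 0.75-1.25x and 1.7-2.3x the G1 mode);
#' gate thresholds left `NA` must be calibrated (see
#' [calibrate_gate_config()]) before the corresponding gate is applied.
#' The three Golgi regions are defined by four boundaries on
#' x = Threshold-60 minor axis intensity (µm) and y = Threshold-60 area
#' (µm²): intact is `x <= x_intact_max & y <= y_intact_max`, full is
#' `x > x_full_min & y > y_full_min`, partial is everything else — a
#' partition of the quadrant (boundaries closed below, open above).
#'
#' @param ... Named sections among `masks`, `singlet`, `focus`, `dna`,
#'   `mitotic`, `apoptosis`, `golgi_gates` (each a named list); unknown
#'   sections or fields are an error.
#' @return A `gate_config` list.
#' @export
#' @examples
#' cfg <- gate_config(golgi_gates = list(x_intact_max = 2, y_intact_max = 15,
#'                                       x_full_min = 4, y_full_min = 30))
gate_config <- function(...) {
  user <- list(...)
  validate_gate_config(user)
  cfg <- gate_config_defaults()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]])) modifyList(cfg[[k]], user[[k]])
                else user[[k]]
  }
  validate_gate_config(cfg, complete = TRUE)
  structure(cfg, class = "gate_config")
}

validate_gate_config <- function(cfg, complete = FALSE) {
  unknown <- setdiff(names(cfg), GATE_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown gate-config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defs <- gate_config_defaults()
  for (k in intersect(names(cfg), names(defs))) {
    if (is.list(defs[[k]]) && !is.null(cfg[[k]])) {
      bad <- setdiff(names(cfg[[k]]), names(defs[[k]]))
      if (length(bad)) {
        stop("unknown gate-config keys in '", k, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  gg <- cfg$golgi_gates
  if (!is.null(gg) && complete) {
    b <- unlist(gg[c("x_intact_max", "y_intact_max",
                     "x_full_min", "y_full_min")])
    if (all(!is.na(b))) {
      if (any(!is.finite(b))) {
        stop("golgi gate boundaries must be finite", call. = FALSE)
      }
      if (gg$x_intact_max > gg$x_full_min ||
          gg$y_intact_max > gg$y_full_min) {
        stop("invalid golgi gates: intact and full regions overlap ",
             "(need x_intact_max <= x_full_min and ",
             "y_intact_max <= y_full_min)", call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' Save / load a gate configuration (JSON canonical, YAML accepted)
#'
#' Round-trips losslessly: `load_gate_config(save_gate_config(cfg, p))`
#' equals `cfg`. The format is chosen by file extension (`.yaml`/`.yml`
#' for YAML, JSON otherwise).
#'
#' @param config A [gate_config()].
#' @param path File path.
#' @return `save_gate_config()`: invisibly, `path`;
#'   `load_gate_config()`: a validated [gate_config()] with defaults filled.
#' @export
save_gate_config <- function(config, path) {
  stopifnot(inherits(config, "gate_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' @rdname save_gate_config
#' @export
load_gate_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw <- null_to_na(raw)
  do.call(gate_config, raw)
}

# JSON null / YAML ~ come back as NULL; restore them as NA so that
# modifyList() does not drop the field
null_to_na <- function(x) {
  if (!is.list(x)) return(x)
  lapply(x, function(el) {
    if (is.null(el) || (is.list(el) && length(el) == 0)) NA_real_
    else null_to_na(el)
  })
}
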