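#' Calibrate every gate threshold from labeled synthetic exemplars
#'
#' Stands in for the manual, visually verified gate drawing of an
#' interactive analysis: renders small labeled calibration populations
#' (balanced Golgi exemplars; clean vs doublet vs defocused cells; healthy
#' vs apoptotic; interphase G2 vs each mitotic sub-phase), computes their
#' features, and places every threshold at the variance-weighted midpoint
#' between the relevant class centers. The Golgi morphology gates are fitted
#' with [fit_golgi_gates()] on the balanced exemplar set.
#'
#' @param seed Integer seed for the calibration populations.
#' @param n_exemplar Exemplar cells per Golgi class (default 100).
#' @param n_calib Cells per auxiliary calibration group (default 120).
#' @return A fully calibrated [gate_config()]. The fitted `golgi_gates`
#'   object is attached as attribute `"golgi_fit"`.
#' @export
#' @examples
#' \donttest{
#' cfg <- calibrate_gate_config(seed = 2, n_exemplar = 40, n_calib = 40)
#' }
calibrate_gate_config <- function(seed, n_exemplar = 100L, n_calib = 120L) {
  group <- function(golgi, nucleus, n, sub_seed, doublet_rate = 0,
                    oof_rate = 0) {
    p <- new_preset("calibration",
                    mixture_tbl(golgi, nucleus, 1),
                    doublet_rate = doublet_rate,
                    out_of_focus_rate = oof_rate)
    pop <- sample_population(p, n, seed = sub_seed)
    compute_features(pop$cells)
  }
  seeds <- seed + seq_len(12) * 1000L

  # Golgi gates from balanced exemplars
  ex <- sample_population(get_preset("exemplars"), 3L * n_exemplar,
                          seed = seeds[1])
  ex_feat <- compute_features(ex$cells)
  golgi_fit <- fit_golgi_gates(ex_feat, ex$truth$golgi_class)

  # singlet / focus thresholds: clean vs doublet vs defocused
  clean <- group("INTACT", "INTERPHASE_G1", n_calib, seeds[2])
  doub <- group("INTACT", "INTERPHASE_G1", n_calib, seeds[3],
                doublet_rate = 1)
  blur <- group("INTACT", "INTERPHASE_G1", n_calib, seeds[4],
                oof_rate = 1)
  mid <- function(a, b) vw_midpoint(mean(a, na.rm = TRUE), sd(a, na.rm = TRUE),
                                    mean(b, na.rm = TRUE), sd(b, na.rm = TRUE))
  singlet <- list(
    area_min = 0.5 * quantile(clean$bf_area, 0.005, na.rm = TRUE, names = FALSE),
    area_max = mid(clean$bf_area, doub$bf_area),
    aspect_min = mid(doub$bf_aspect_ratio, clean$bf_aspect_ratio))
  focus <- list(gradient_rms_min = mid(blur$bf_gradient_rms,
                                       clean$bf_gradient_rms))

  # apoptosis thresholds: healthy interphase vs apoptotic
  apo <- group("PARTIAL", "APOPTOTIC", n_calib, seeds[5])
  apoptosis <- list(
    bf_contrast_min = mid(clean$bf_contrast, apo$bf_contrast),
    dna_t50_area_max = mid(apo$dna_t50_area, clean$dna_t50_area))

  # mitotic thresholds: G2 interphase vs the mitotic sub-phases
  g2 <- group("INTACT", "INTERPHASE_G2", n_calib, seeds[6])
  pro <- group("PARTIAL", "PROPHASE", n_calib, seeds[7])
  meta <- group("FULL", "METAPHASE", n_calib, seeds[8])
  ana <- group("FULL", "ANAPHASE", n_calib, seeds[9])
  telo <- group("INTACT", "TELOPHASE", n_calib, seeds[10])
  mitotic_bdi <- c(pro$dna_bdi_r3, meta$dna_bdi_r3)
  mitotic <- list(
    bdi_min = mid(g2$dna_bdi_r3, mitotic_bdi),
    metaphase_t50_area_max = mid(meta$dna_t50_area, pro$dna_t50_area),
    anaphase_sep_min = mid(telo$dna_centroid_sep[telo$dna_components == 2],
                           ana$dna_centroid_sep[ana$dna_components == 2]))

  cfg <- gate_config(
    singlet = lapply(singlet, unname),
    focus = focus,
    apoptosis = apoptosis,
    mitotic = mitotic,
    golgi_gates = golgi_fit$boundaries)
  attr(cfg, "golgi_fit") <- golgi_fit
  cfg
}
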