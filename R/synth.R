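GOLGI_CLASSES <- c("INTACT", "PARTIAL", "FULL")
NUCLEUS_CLASSES <- c("INTERPHASE_G1", "INTERPHASE_G2", "PROPHASE",
                     "METAPHASE", "ANAPHASE", "TELOPHASE", "APOPTOTIC")

#' Specification of one synthetic cell
#'
#' Parameters for [render_cell()]. Defaults encode the reference imaging
#' geometry (64x64 px canvas at 0.5 µm/px; 7.5 µm cell and 4 µm nucleus
#' radius, so a 15 µm cell fits the tile with margin) and the detection-noise
#' model `signal = Poisson(clean * gain)/gain + N(0, read_sd) + offset`
#' with gain 0.25, read SD 2 au and offset 5 au.
#'
#' @param golgi_class One of `"INTACT"`, `"PARTIAL"`, `"FULL"`.
#' @param nucleus_class One of `"INTERPHASE_G1"`, `"INTERPHASE_G2"`,
#'   `"PROPHASE"`, `"METAPHASE"`, `"ANAPHASE"`, `"TELOPHASE"`, `"APOPTOTIC"`.
#' @param focus_sigma Extra Gaussian blur in px applied to the clean image
#'   before noise; 0 = in focus.
#' @param is_doublet If `TRUE`, a second cell is rendered in the same tile,
#'   offset by about 1.5 cell radii.
#' @param noise List with `gain`, `read_sd` (au), `offset` (au).
#' @param geometry List with `canvas` (px, >= 48), `pixel_size` (µm),
#'   `cell_radius` (µm), `nucleus_radius` (µm).
#' @param morphology List of Golgi morphology parameters: `intact_sigma`,
#'   `partial_sigma`, `full_sigma` (blob SDs, px), `partial_dispersion`
#'   (puncta placement radius as a multiple of the nucleus radius) and
#'   `full_dispersion` (vesicle placement radius as a fraction of the cell
#'   radius).
#' @return An object of class `synth_cell_spec`.
#' @export
synth_cell_spec <- function(golgi_class, nucleus_class,
                            focus_sigma = 0, is_doublet = FALSE,
                            noise = list(), geometry = list(),
                            morphology = list()) {
  golgi_class <- match.arg(golgi_class, GOLGI_CLASSES)
  nucleus_class <- match.arg(nucleus_class, NUCLEUS_CLASSES)
  noise <- modifyList(list(gain = 0.25, read_sd = 2, offset = 5), noise)
  geometry <- modifyList(
    list(canvas = 64L, pixel_size = 0.5, cell_radius = 7.5,
         nucleus_radius = 4), geometry)
  morphology <- modifyList(
    list(intact_sigma = 1.3, partial_sigma = 1.5, full_sigma = 0.9,
         partial_dispersion = 1.5, full_dispersion = 0.9), morphology)
  if (geometry$canvas < 48) stop("canvas must be >= 48 px", call. = FALSE)
  r_px <- geometry$cell_radius / geometry$pixel_size
  if (r_px > geometry$canvas / 2 - 4) {
    stop("cell of radius ", geometry$cell_radius,
         " um does not fit the canvas with a 4 px margin", call. = FALSE)
  }
  if (noise$read_sd < 0 || focus_sigma < 0 || noise$gain <= 0) {
    stop("noise SDs must be >= 0 and gain > 0", call. = FALSE)
  }
  structure(
    list(golgi_class = golgi_class, nucleus_class = nucleus_class,
         focus_sigma = focus_sigma, is_doublet = isTRUE(is_doublet),
         noise = noise, geometry = geometry, morphology = morphology),
    class = "synth_cell_spec"
  )
}

# ---- low-level raster painters (0-based pixel-center coordinates) ----

# additive Gaussian blob restricted to a +/-4 sigma window
splat_gaussian <- function(img, cx, cy, amp, sigma) {
  n <- nrow(img)
  w <- ceiling(4 * sigma)
  rows <- max(1L, floor(cy) - w + 1L):min(n, ceiling(cy) + w + 1L)
  cols <- max(1L, floor(cx) - w + 1L):min(ncol(img), ceiling(cx) + w + 1L)
  y <- rows - 1; x <- cols - 1
  g <- exp(-outer((y - cy)^2, (x - cx)^2, "+") / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amp * g
  img
}

# anisotropic rotated Gaussian (for the metaphase plate)
splat_bar <- function(img, cx, cy, amp, sigma_long, sigma_short, theta) {
  n <- nrow(img)
  y <- (seq_len(n) - 1) - cy
  x <- (seq_len(ncol(img)) - 1) - cx
  X <- matrix(x, n, length(x), byrow = TRUE)
  Y <- matrix(y, n, length(x))
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  img + amp * exp(-(u^2 / (2 * sigma_long^2) + v^2 / (2 * sigma_short^2)))
}

# smooth-edged disk (logistic falloff)
soft_disk <- function(n, nc, cx, cy, radius, edge = 1.2) {
  y <- (seq_len(n) - 1) - cy
  x <- (seq_len(nc) - 1) - cx
  d <- sqrt(outer(y^2, x^2, "+"))
  1 / (1 + exp((d - radius) / edge))
}

scale_total <- function(img, total) {
  s <- sum(img)
  if (s <= 0) return(img)
  img * (total / s)
}

# uniform point in a disc of given radius around (cx, cy)
runif_disc <- function(k, cx, cy, radius) {
  th <- runif(k, 0, 2 * pi)
  r <- radius * sqrt(runif(k))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# ---- channel painters for one cell body ----

paint_golgi <- function(img, spec, cx, cy, r_nuc_px, r_cell_px) {
  total <- 20000 * runif(1, 0.9, 1.1)
  mo <- spec$morphology
  blob <- switch(spec$golgi_class,
    INTACT = {
      k <- sample(2:4, 1)
      theta0 <- runif(1, 0, 2 * pi)
      span <- 60 * pi / 180
      th <- theta0 + seq(-span / 2, span / 2, length.out = k) +
        runif(k, -0.06, 0.06)
      r_arc <- r_nuc_px + 2.5
      list(x = cx + r_arc * cos(th), y = cy + r_arc * sin(th),
           sigma = mo$intact_sigma)
    },
    PARTIAL = {
      k <- sample(4:8, 1)
      p <- runif_disc(k, cx, cy, mo$partial_dispersion * r_nuc_px)
      list(x = p[, "x"], y = p[, "y"], sigma = mo$partial_sigma)
    },
    FULL = {
      k <- sample(20:60, 1)
      p <- runif_disc(k, cx, cy, mo$full_dispersion * r_cell_px)
      list(x = p[, "x"], y = p[, "y"], sigma = mo$full_sigma)
    }
  )
  k <- length(blob$x)
  w <- runif(k, 0.7, 1.3)
  amps <- total * (w / sum(w)) / (2 * pi * blob$sigma^2)
  for (i in seq_len(k)) {
    img <- splat_gaussian(img, blob$x[i], blob$y[i], amps[i], blob$sigma)
  }
  img
}

paint_dna <- function(img, spec, cx, cy, r_nuc_px) {
  n <- nrow(img); nc <- ncol(img)
  t2n <- 40000   # 2N total DNA intensity (au); 4N states get 2x
  switch(spec$nucleus_class,
    INTERPHASE_G1 = img +
      scale_total(soft_disk(n, nc, cx, cy, r_nuc_px, 1.0), t2n),
    INTERPHASE_G2 = img +
      scale_total(soft_disk(n, nc, cx, cy, r_nuc_px, 1.0), 2 * t2n),
    PROPHASE = {
      base <- scale_total(soft_disk(n, nc, cx, cy, r_nuc_px, 1.0), 1.2 * t2n)
      spk <- matrix(0, n, nc)
      p <- runif_disc(12, cx, cy, 0.8 * r_nuc_px)
      for (i in 1:12) spk <- splat_gaussian(spk, p[i, 1], p[i, 2], 1, 1.0)
      img + base + scale_total(spk, 0.8 * t2n)
    },
    METAPHASE = {
      theta <- runif(1, 0, 2 * pi)
      bar <- splat_bar(matrix(0, n, nc), cx, cy, 1, 6, 1.7, theta)
      img + scale_total(bar, 2 * t2n)
    },
    ANAPHASE = ,
    TELOPHASE = {
      ana <- spec$nucleus_class == "ANAPHASE"
      sep <- if (ana) 22 else 14
      sg <- if (ana) 2.0 else 2.6
      theta <- runif(1, 0, 2 * pi)
      dx <- sep / 2 * cos(theta); dy <- sep / 2 * sin(theta)
      b <- splat_gaussian(matrix(0, n, nc), cx + dx, cy + dy, 1, sg)
      b <- splat_gaussian(b, cx - dx, cy - dy, 1, sg)
      img + scale_total(b, 2 * t2n)
    },
    APOPTOTIC = {
      k <- sample(2:4, 1)
      p <- runif_disc(k, cx, cy, 0.5 * r_nuc_px)
      b <- matrix(0, n, nc)
      for (i in seq_len(k)) b <- splat_gaussian(b, p[i, 1], p[i, 2], 1, 1.4)
      img + scale_total(b, t2n)
    }
  )
}

paint_bf <- function(img, spec, cx, cy, r_cell_px) {
  n <- nrow(img); nc <- ncol(img)
  img <- img + 300 * soft_disk(n, nc, cx, cy, r_cell_px, 1.6)
  if (spec$nucleus_class == "APOPTOTIC") {
    # speckled high-variance texture of dying cells
    p <- runif_disc(25, cx, cy, 0.8 * r_cell_px)
    amp <- runif(25, -150, 150)
    for (i in 1:25) img <- splat_gaussian(img, p[i, 1], p[i, 2], amp[i], 1.0)
  }
  img
}

gaussian_blur <- function(img, sigma) {
  EBImage::gblur(img, sigma = sigma)
}

#' Render one synthetic multichannel cell image
#'
#' Deterministically renders the BF/GOLGI/DNA rasters for a
#' [synth_cell_spec()]: an intact Golgi as 2-4 overlapping blobs along a
#' perinuclear arc (compact, elongated footprint), a partially fragmented
#' Golgi as 4-8 discrete puncta near the nucleus, a fully fragmented Golgi as
#' 20-60 small vesicles dispersed over the cell footprint; nuclei per cell
#' state (smooth interphase disk, speckled prophase, metaphase bar, separated
#' anaphase/telophase blobs, condensed bright apoptotic fragments with
#' brightfield speckle); 4N nuclei carry twice the 2N total DNA intensity.
#' Detection noise is applied last and intensities are quantized to 16-bit
#' integers, so written TIFFs round-trip exactly.
#'
#' @param spec A [synth_cell_spec()].
#' @param seed Integer seed; rendering is a pure function of `(spec, seed)`.
#' @param cell_id Identifier for the resulting [cell_record()].
#' @return A [cell_record()] with channels BF, GOLGI, DNA.
#' @export
#' @examples
#' cr <- render_cell(synth_cell_spec("INTACT", "INTERPHASE_G1"), seed = 7)
render_cell <- function(spec, seed, cell_id = "cell") {
  stopifnot(inherits(spec, "synth_cell_spec"))
  set.seed(as.integer(seed))
  g <- spec$geometry
  n <- as.integer(g$canvas)
  ps <- g$pixel_size
  r_cell <- g$cell_radius / ps
  r_nuc <- g$nucleus_radius / ps

  centers <- if (spec$is_doublet) {
    theta <- runif(1, 0, 2 * pi)
    off <- 1.5 * r_cell / 2
    c0 <- (n - 1) / 2
    lim <- function(v) pmin(pmax(v, r_cell * 0.6), n - 1 - r_cell * 0.6)
    scale2 <- runif(1, 0.8, 1.2)
    list(list(cx = lim(c0 + off * cos(theta)), cy = lim(c0 + off * sin(theta)),
              scale = 1),
         list(cx = lim(c0 - off * cos(theta)), cy = lim(c0 - off * sin(theta)),
              scale = scale2))
  } else {
    list(list(cx = (n - 1) / 2 + runif(1, -2, 2),
              cy = (n - 1) / 2 + runif(1, -2, 2), scale = 1))
  }

  bf <- matrix(100, n, n)          # brightfield background level
  golgi <- matrix(0, n, n)
  dna <- matrix(0, n, n)
  for (ct in centers) {
    rc <- r_cell * ct$scale
    rn <- r_nuc * ct$scale
    bf <- paint_bf(bf, spec, ct$cx, ct$cy, rc)
    golgi <- paint_golgi(golgi, spec, ct$cx, ct$cy, rn, rc)
    dna <- paint_dna(dna, spec, ct$cx, ct$cy, rn)
  }
  if (spec$focus_sigma > 0) {
    bf <- gaussian_blur(bf, spec$focus_sigma)
    golgi <- gaussian_blur(golgi, spec$focus_sigma)
    dna <- gaussian_blur(dna, spec$focus_sigma)
  }
  noisy <- function(clean) {
    clean <- pmax(clean, 0)
    lam <- clean * spec$noise$gain
    sig <- rpois(length(lam), lam) / spec$noise$gain +
      rnorm(length(lam), 0, spec$noise$read_sd) + spec$noise$offset
    m <- matrix(pmin(pmax(round(sig), 0), 65535), n, n)
    m
  }
  cell_record(cell_id,
              list(BF = noisy(bf), GOLGI = noisy(golgi), DNA = noisy(dna)),
              pixel_size = ps,
              meta = list(golgi_class = spec$golgi_class,
                          nucleus_class = spec$nucleus_class))
}

#' Built-in population presets
#'
#' Generative mixtures over (Golgi class, nucleus class) emulating the
#' studied conditions at the level of their published population claims:
#' an untreated transformed culture is >70% intact with <5% fully fragmented
#' and about 2% apoptotic; short/long microtubule-depolymerization arrest
#' (`noc_4h`/`noc_16h`) shifts mass to partial then full fragmentation with a
#' growing mitotic (G2/M) population; a trafficking block (`bfa_60min`) gives
#' predominantly partial fragmentation; 6 h of TNFa/cycloheximide
#' (`tnf_chx_6h`) makes 75% of nuclei apoptotic; untransformed fibroblasts
#' (`wi38`) resemble the untreated culture with <20% partial; `exemplars` is
#' the balanced 1/3-1/3-1/3 calibration set standing in for manually selected
#' exemplar cells of each morphology. All presets except `exemplars` include
#' 5% cell doublets and 5% out-of-focus cells.
#'
#' @param name One of `"untreated"`, `"noc_4h"`, `"noc_16h"`,
#'   `"thymidine_release_9h"`, `"bfa_60min"`, `"tnf_chx_6h"`, `"wi38"`,
#'   `"exemplars"`.
#' @return A `population_preset`: list with `name`, `mixture` (tibble of
#'   `golgi_class`, `nucleus_class`, `prob` summing to 1), `doublet_rate`,
#'   `out_of_focus_rate`, `n_default`.
#' @export
#' @examples
#' p <- get_preset("untreated")
#' sum(p$mixture$prob)  # 1
get_preset <- function(name) {
  presets <- preset_table()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' @rdname get_preset
#' @export
preset_names <- function() names(preset_table())

mixture_tbl <- function(...) {
  m <- tibble::tribble(~golgi_class, ~nucleus_class, ~prob, ...)
  stopifnot(abs(sum(m$prob) - 1) < 1e-9)
  m
}

new_preset <- function(name, mixture, doublet_rate = 0.05,
                       out_of_focus_rate = 0.05, n_default = 5000L) {
  stopifnot(doublet_rate >= 0, doublet_rate <= 1,
            out_of_focus_rate >= 0, out_of_focus_rate <= 1)
  structure(list(name = name, mixture = mixture,
                 doublet_rate = doublet_rate,
                 out_of_focus_rate = out_of_focus_rate,
                 n_default = as.integer(n_default)),
            class = "population_preset")
}

preset_table <- function() {
  list(
    untreated = new_preset("untreated", mixture_tbl(
      "INTACT",  "INTERPHASE_G1", 0.55,
      "INTACT",  "INTERPHASE_G2", 0.24,
      "INTACT",  "TELOPHASE",     0.01,
      "PARTIAL", "INTERPHASE_G1", 0.07,
      "PARTIAL", "INTERPHASE_G2", 0.065,
      "PARTIAL", "PROPHASE",      0.015,
      "PARTIAL", "APOPTOTIC",     0.02,
      "FULL",    "METAPHASE",     0.015,
      "FULL",    "ANAPHASE",      0.005,
      "FULL",    "INTERPHASE_G2", 0.01)),
    noc_4h = new_preset("noc_4h", mixture_tbl(
      "INTACT",  "INTERPHASE_G1", 0.13,
      "INTACT",  "INTERPHASE_G2", 0.11,
      "INTACT",  "TELOPHASE",     0.01,
      "PARTIAL", "INTERPHASE_G1", 0.10,
      "PARTIAL", "INTERPHASE_G2", 0.22,
      "PARTIAL", "PROPHASE",      0.13,
      "PARTIAL", "METAPHASE",     0.13,
      "PARTIAL", "APOPTOTIC",     0.02,
      "FULL",    "METAPHASE",     0.11,
      "FULL",    "PROPHASE",      0.02,
      "FULL",    "ANAPHASE",      0.01,
      "FULL",    "INTERPHASE_G2", 0.01)),
    noc_16h = new_preset("noc_16h", mixture_tbl(
      "INTACT",  "INTERPHASE_G1", 0.06,
      "INTACT",  "INTERPHASE_G2", 0.04,
      "PARTIAL", "INTERPHASE_G1", 0.04,
      "PARTIAL", "INTERPHASE_G2", 0.06,
      "PARTIAL", "PROPHASE",      0.07,
      "PARTIAL", "METAPHASE",     0.05,
      "PARTIAL", "APOPTOTIC",     0.03,
      "FULL",    "METAPHASE",     0.50,
      "FULL",    "PROPHASE",      0.08,
      "FULL",    "ANAPHASE",      0.02,
      "FULL",    "INTERPHASE_G2", 0.05)),
    thymidine_release_9h = new_preset("thymidine_release_9h", mixture_tbl(
      "INTACT",  "INTERPHASE_G1", 0.15,
      "INTACT",  "INTERPHASE_G2", 0.08,
      "INTACT",  "TELOPHASE",     0.07,
      "PARTIAL", "INTERPHASE_G1", 0.03,
      "PARTIAL", "INTERPHASE_G2", 0.12,
      "PARTIAL", "PROPHASE",      0.10,
      "PARTIAL", "TELOPHASE",     0.04,
      "PARTIAL", "APOPTOTIC",     0.01,
      "FULL",    "METAPHASE",     0.20,
      "FULL",    "ANAPHASE",      0.06,
      "FULL",    "PROPHASE",      0.06,
      "FULL",    "INTERPHASE_G2", 0.08)),
    bfa_60min = new_preset("bfa_60min", mixture_tbl(
      "INTACT",  "INTERPHASE_G1", 0.14,
      "INTACT",  "INTERPHASE_G2", 0.06,
      "PARTIAL", "INTERPHASE_G1", 0.42,
      "PARTIAL", "INTERPHASE_G2", 0.29,
      "PARTIAL", "PROPHASE",      0.02,
      "PARTIAL", "APOPTOTIC",     0.02,
      "FULL",    "METAPHASE",     0.03,
      "FULL",    "ANAPHASE",      0.01,
      "FULL",    "INTERPHASE_G2", 0.01)),
    tnf_chx_6h = new_preset("tnf_chx_6h", mixture_tbl(
      "INTACT",  "APOPTOTIC",     0.20,
      "PARTIAL", "APOPTOTIC",     0.52,
      "FULL",    "APOPTOTIC",     0.03,
      "INTACT",  "INTERPHASE_G1", 0.10,
      "INTACT",  "INTERPHASE_G2", 0.05,
      "PARTIAL", "INTERPHASE_G1", 0.05,
      "PARTIAL", "INTERPHASE_G2", 0.03,
      "FULL",    "METAPHASE",     0.015,
      "FULL",    "ANAPHASE",      0.005)),
    wi38 = new_preset("wi38", mixture_tbl(
      "INTACT",  "INTERPHASE_G1", 0.57,
      "INTACT",  "INTERPHASE_G2", 0.24,
      "INTACT",  "TELOPHASE",     0.01,
      "PARTIAL", "INTERPHASE_G1", 0.05,
      "PARTIAL", "INTERPHASE_G2", 0.065,
      "PARTIAL", "PROPHASE",      0.015,
      "PARTIAL", "APOPTOTIC",     0.02,
      "FULL",    "METAPHASE",     0.015,
      "FULL",    "ANAPHASE",      0.005,
      "FULL",    "INTERPHASE_G2", 0.01)),
    exemplars = new_preset("exemplars", mixture_tbl(
      "INTACT",  "INTERPHASE_G1", 1 / 3,
      "PARTIAL", "INTERPHASE_G1", 1 / 3,
      "FULL",    "INTERPHASE_G1", 1 / 3),
      doublet_rate = 0, out_of_focus_rate = 0, n_default = 300L)
  )
}

#' Sample a labeled synthetic population
#'
#' Draws cell classes multinomially from a preset's mixture, jitters per-cell
#' geometry, renders every cell and returns the images alongside their ground
#' truth. Fully reproducible for a fixed `(preset, n, seed)`.
#'
#' @param preset A `population_preset` from [get_preset()].
#' @param n Number of cells (>= 1).
#' @param seed Integer seed.
#' @param focus_sigma_range Blur SD range (px) for out-of-focus cells.
#' @param render If `FALSE`, skip rendering and return `cells = NULL` with
#'   the ground truth only (for studying the class-draw law at large n).
#' @return A list with `cells` (list of [cell_record()]) and `truth`
#'   (tibble: `cell_id`, `golgi_class`, `nucleus_class`, `is_doublet`,
#'   `out_of_focus`), rows in generation order.
#' @export
#' @examples
#' pop <- sample_population(get_preset("exemplars"), n = 6, seed = 1)
#' pop$truth
sample_population <- function(preset, n, seed,
                              focus_sigma_range = c(2.5, 3.5),
                              render = TRUE) {
  stopifnot(inherits(preset, "population_preset"), n >= 1)
  set.seed(as.integer(seed))
  mix <- preset$mixture
  ks <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$prob)
  doublet <- runif(n) < preset$doublet_rate
  oof <- runif(n) < preset$out_of_focus_rate
  fsig <- ifelse(oof, runif(n, focus_sigma_range[1], focus_sigma_range[2]), 0)
  cell_r <- 7.5 * runif(n, 0.92, 1.08)
  nuc_r <- 4 * runif(n, 0.92, 1.08)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("cell_%05d", seq_len(n))
  cells <- if (render) vector("list", n) else NULL
  for (i in if (render) seq_len(n) else integer(0)) {
    spec <- synth_cell_spec(
      mix$golgi_class[ks[i]], mix$nucleus_class[ks[i]],
      focus_sigma = fsig[i], is_doublet = doublet[i],
      geometry = list(cell_radius = cell_r[i], nucleus_radius = nuc_r[i]))
    cells[[i]] <- render_cell(spec, seeds[i], cell_id = ids[i])
    cells[[i]]$meta$preset <- preset$name
  }
  truth <- tibble::tibble(
    cell_id = ids,
    golgi_class = mix$golgi_class[ks],
    nucleus_class = mix$nucleus_class[ks],
    is_doublet = doublet,
    out_of_focus = oof
  )
  list(cells = cells, truth = truth)
}
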