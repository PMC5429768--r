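# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(fixture_cache[[name]])) assign(name, fn(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# balanced Golgi exemplars (100/class), the calibration-style population
exemplar_pop <- function() {
  fixture("exemplar_pop", function() {
    sample_population(get_preset("exemplars"), n = 300, seed = 101)
  })
}

exemplar_features <- function() {
  fixture("exemplar_features", function() compute_features(exemplar_pop()$cells))
}

# compact calibrated config for gating tests
test_config <- function() {
  fixture("test_config", function() {
    calibrate_gate_config(seed = 5, n_exemplar = 60, n_calib = 80)
  })
}

untreated_pop <- function() {
  fixture("untreated_pop", function() {
    sample_population(get_preset("untreated"), n = 500, seed = 7)
  })
}

untreated_features <- function() {
  fixture("untreated_features", function() compute_features(untreated_pop()$cells))
}

# a single-class preset derived from an existing one
single_class_preset <- function(golgi, nucleus, doublet_rate = 0,
                                out_of_focus_rate = 0) {
  p <- get_preset("exemplars")
  p$name <- paste0(tolower(golgi), "_", tolower(nucleus))
  p$mixture <- tibble::tibble(golgi_class = golgi, nucleus_class = nucleus,
                              prob = 1)
  p$doublet_rate <- doublet_rate
  p$out_of_focus_rate <- out_of_focus_rate
  p
}

full_mask <- function(nr, nc = nr) new_mask(matrix(TRUE, nr, nc))

# painted disk raster + its true support, for mask oracles
disk_raster <- function(n, cx, cy, r, amp = 100, bg = 0) {
  xy <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  d <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2)
  raster <- matrix(bg + amp * (d <= r), n, n)
  list(raster = raster, truth = matrix(d <= r, n, n))
}
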