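test_that("rd_value matches its formula and handles degenerate spreads", {
  expect_equal(rd_value(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  # constructed moments: means 0 and 3, SDs 1 and 0.5 -> RD = 3/1.5 = 2
  a <- c(-1, 0, 1); a <- (a - mean(a)) / sd(a)           # mean 0, sd 1
  b <- 3 + 0.5 * a                                       # mean 3, sd 0.5
  expect_equal(rd_value(a, b), 2, tolerance = 1e-12)

  set.seed(123)
  x <- rnorm(10000); y <- rnorm(10000, 2, 3)
  expect_equal(rd_value(x, y),
               (mean(y) - mean(x)) / (sd(x) + sd(y)), tolerance = 1e-12)

  expect_equal(rd_value(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_equal(rd_value(c(5, 5, 5), c(7, 7, 7)), Inf)
})

test_that("rank_features puts informative features first and flips sign on label swap", {
  set.seed(11)
  n <- 80
  tab <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:(2 * n)),
    informative = c(rnorm(n, 0, 1), rnorm(n, 5, 1)),
    noise = rnorm(2 * n))
  labels <- rep(c("A", "B"), each = n)
  rk <- rank_features(tab, labels)
  expect_equal(rk$feature[1], "informative")
  swapped <- rank_features(tab, rep(c("B", "A"), each = n))
  expect_equal(swapped$rd, -rk$rd, tolerance = 1e-12)
  expect_equal(swapped$feature, rk$feature)

  # invalid entries excluded pairwise and counted
  tab$informative[3] <- NA
  rk2 <- rank_features(tab, labels)
  expect_equal(rk2$n_excluded[rk2$feature == "informative"], 1)
})

test_that("Threshold-60 area and minor axis intensity top the panel ranking", {
  ft <- exemplar_features()
  cls <- exemplar_pop()$truth$golgi_class
  keep <- cls %in% c("INTACT", "FULL")
  rk <- rank_features(ft[keep, ], cls[keep])
  top3 <- rk$feature[1:3]
  expect_true("golgi_t60_area" %in% top3)
  expect_true("golgi_t60_minor_axis_intensity" %in% top3)
})

test_that("singlet and focus gates reject doublets and defocused cells", {
  cfg <- test_config()
  doub <- sample_population(single_class_preset("INTACT", "INTERPHASE_G1",
                                                doublet_rate = 0.5),
                            n = 160, seed = 71)
  sf <- gate_singlets_focused(compute_features(doub$cells), cfg)
  expect_gte(mean(!sf$singlet[doub$truth$is_doublet]), 0.90)

  blur <- sample_population(single_class_preset("INTACT", "INTERPHASE_G1",
                                                out_of_focus_rate = 0.5),
                            n = 160, seed = 72)
  sf2 <- gate_singlets_focused(compute_features(blur$cells), cfg)
  expect_gte(mean(!sf2$focused[blur$truth$out_of_focus]), 0.90)

  clean <- sample_population(get_preset("exemplars"), n = 120, seed = 73)
  sf3 <- gate_singlets_focused(compute_features(clean$cells), cfg)
  expect_gte(mean(sf3$singlet & sf3$focused), 0.95)

  expect_error(gate_singlets_focused(tibble::tibble(cell_id = "a"), cfg),
               "lacks column")
})

test_that("DNA-content gate anchors the G1 mode and labels ploidy windows", {
  # pure 2N population: nearly all G1
  g1 <- compute_features(sample_population(
    single_class_preset("INTACT", "INTERPHASE_G1"), 120, seed = 81)$cells)
  cyc <- gate_dna_content(g1)
  expect_gte(mean(cyc$cycle == "G1"), 0.95)

  # 50/50 2N/4N: G2M fraction within 5 points of 50%
  p <- get_preset("exemplars")
  p$mixture <- tibble::tibble(
    golgi_class = c("INTACT", "INTACT"),
    nucleus_class = c("INTERPHASE_G1", "INTERPHASE_G2"),
    prob = c(0.5, 0.5))
  mixpop <- sample_population(p, 400, seed = 82)
  cyc2 <- gate_dna_content(compute_features(mixpop$cells))
  expect_equal(mean(cyc2$cycle == "G2M"), 0.5, tolerance = 0.1)
  g2sel <- mixpop$truth$nucleus_class == "INTERPHASE_G2"
  expect_gte(mean(cyc2$cycle[g2sel] == "G2M"), 0.9)

  # all-equal intensities: single mode, everything G1
  flat <- tibble::tibble(cell_id = sprintf("c%02d", 1:60),
                         dna_total_intensity = rep(1000, 60))
  expect_true(all(gate_dna_content(flat)$cycle == "G1"))
})

test_that("mitotic sub-phases are recovered from DNA morphology", {
  cfg <- test_config()
  run <- function(golgi, nucleus, n = 120, seed) {
    pop <- sample_population(single_class_preset(golgi, nucleus), n, seed)
    ft <- compute_features(pop$cells)
    cyc <- factor(rep("G2M", n), levels = c("G1", "S", "G2M", "excluded"))
    classify_mitotic(ft, cyc, cfg)$mitotic
  }
  expect_gte(mean(run("FULL", "METAPHASE", seed = 91) == "metaphase"), 0.80)
  expect_gte(mean(run("FULL", "ANAPHASE", seed = 92) == "anaphase"), 0.80)
  expect_gte(mean(run("INTACT", "INTERPHASE_G2", seed = 93) == "none"), 0.90)
  # outside G2/M nothing is labeled mitotic
  pop <- sample_population(single_class_preset("FULL", "METAPHASE"), 30,
                           seed = 94)
  ft <- compute_features(pop$cells)
  cyc <- factor(rep("G1", 30), levels = c("G1", "S", "G2M", "excluded"))
  expect_true(all(classify_mitotic(ft, cyc, cfg)$mitotic == "none"))
})

test_that("the apoptosis gate detects condensed high-contrast cells", {
  cfg <- test_config()
  apo <- compute_features(sample_population(
    single_class_preset("PARTIAL", "APOPTOTIC"), 150, seed = 95)$cells)
  expect_gte(mean(gate_apoptotic(apo, cfg)$apoptotic), 0.85)
  healthy <- compute_features(sample_population(
    single_class_preset("INTACT", "INTERPHASE_G1"), 150, seed = 96)$cells)
  expect_lte(mean(gate_apoptotic(healthy, cfg)$apoptotic), 0.05)

  # boundary behavior at infinite thresholds
  all_cfg <- cfg
  all_cfg$apoptosis <- list(bf_contrast_min = -Inf, dna_t50_area_max = Inf)
  expect_true(all(gate_apoptotic(healthy, all_cfg)$apoptotic))
  none_cfg <- cfg
  none_cfg$apoptosis <- list(bf_contrast_min = Inf, dna_t50_area_max = Inf)
  expect_false(any(gate_apoptotic(healthy, none_cfg)$apoptotic))
})

test_that("fitted Golgi gates separate exemplars and validate ordering", {
  ft <- exemplar_features()
  cls <- exemplar_pop()$truth$golgi_class
  gates <- fit_golgi_gates(ft, cls)
  expect_gte(gates$resubstitution$accuracy, 0.90)
  expect_lte(gates$boundaries$x_intact_max, gates$boundaries$x_full_min)

  # tidy/glance accessors
  td <- tidy(gates)
  expect_equal(td$class, c("INTACT", "PARTIAL", "FULL"))
  gl <- glance(gates)
  expect_true(gl$resubstitution_accuracy >= 0.9)

  # identical class distributions: ordering error names the axis
  same <- ft
  lab2 <- rep(c("INTACT", "PARTIAL", "FULL"), length.out = nrow(ft))
  expect_error(fit_golgi_gates(same, lab2), "ordered")

  # equal SDs: boundary is the arithmetic midpoint of means
  set.seed(5)
  mk <- function(mx, my, lab) {
    tibble::tibble(cell_id = paste0(lab, 1:40),
                   golgi_t60_minor_axis_intensity = mx + (1:40 - 20.5) / 40,
                   golgi_t60_area = my + (1:40 - 20.5) / 40)
  }
  tab <- rbind(mk(1, 5, "i"), mk(3, 10, "p"), mk(6, 20, "f"))
  lab <- rep(c("INTACT", "PARTIAL", "FULL"), each = 40)
  g2 <- fit_golgi_gates(tab, lab)
  expect_equal(g2$boundaries$x_intact_max, 2, tolerance = 1e-9)
  expect_equal(g2$boundaries$y_full_min, 15, tolerance = 1e-9)
})

test_that("golgi classification partitions the plane with closed-below boundaries", {
  gates <- gate_config(golgi_gates = list(x_intact_max = 2, y_intact_max = 10,
                                          x_full_min = 5, y_full_min = 20))
  tab <- tibble::tibble(
    cell_id = sprintf("c%d", 1:5),
    golgi_t60_minor_axis_intensity = c(0, 10, 2, 2 + 1e-12, NA),
    golgi_t60_area = c(0, 50, 10, 10, 5))
  out <- classify_golgi(tab, gates)$golgi
  expect_equal(as.character(out),
               c("intact",      # origin: small area, small width
                 "full",        # above both upper bounds
                 "intact",      # exactly on the boundary: lower region
                 "partial",     # one ulp above: next region
                 "unassigned")) # flagged-invalid input

  # partition property: every finite point gets exactly one label
  set.seed(44)
  rnd <- tibble::tibble(
    cell_id = sprintf("r%d", 1:500),
    golgi_t60_minor_axis_intensity = runif(500, 0, 12),
    golgi_t60_area = runif(500, 0, 45))
  labs <- classify_golgi(rnd, gates)$golgi
  expect_false(any(labs == "unassigned"))
  expect_true(all(labs %in% c("intact", "partial", "full")))
})

test_that("the gate hierarchy is internally consistent end to end", {
  cfg <- test_config()
  ft <- untreated_features()
  res <- gate_cells(ft, cfg)
  # golgi labels only on eligible cells
  expect_true(all(res$golgi[!res$eligible] == "unassigned"))
  expect_true(all(res$golgi[res$eligible] != "unassigned"))
  # mitotic labels imply G2M
  mit <- res$mitotic != "none"
  expect_true(all(res$cycle[mit] == "G2M"))
  # apoptosis evaluated only on eligible cells
  expect_true(all(is.na(res$apoptotic[!res$eligible])))
  expect_s3_class(glance(res), "tbl_df")
})
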