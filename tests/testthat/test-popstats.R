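mk_result <- function(golgi, apoptotic = FALSE, eligible = TRUE) {
  n <- length(golgi)
  tibble::new_tibble(tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(n)),
    singlet = eligible, focused = eligible, eligible = eligible,
    cycle = factor(rep("G1", n), levels = c("G1", "S", "G2M", "excluded")),
    mitotic = factor(rep("none", n),
                     levels = c("none", "prophase", "metaphase", "anaphase",
                                "telophase")),
    apoptotic = rep_len(apoptotic, n),
    golgi = factor(golgi, levels = c("intact", "partial", "full",
                                     "unassigned"))),
    class = "gating_result")
}

test_that("population summaries count the gated classes exactly", {
  s <- summarize_population(mk_result(rep("intact", 10)))
  expect_equal(c(s$pct_intact, s$pct_partial, s$pct_full), c(100, 0, 0))

  r <- mk_result(c(rep("intact", 4), rep("partial", 4), rep("full", 2)))
  s2 <- summarize_population(r)
  expect_equal(c(s2$pct_intact, s2$pct_partial, s2$pct_full), c(40, 40, 20))
  expect_equal(s2$pct_intact + s2$pct_partial + s2$pct_full, 100)

  # independent tally oracle on a gated synthetic run
  res <- gate_cells(untreated_features(), test_config())
  s3 <- summarize_population(res)
  g <- res$golgi[res$eligible]
  g <- g[g != "unassigned"]
  expect_equal(s3$pct_intact, 100 * sum(g == "intact") / length(g))
  expect_equal(s3$pct_full, 100 * sum(g == "full") / length(g))
  expect_equal(s3$pct_intact + s3$pct_partial + s3$pct_full, 100,
               tolerance = 1e-10)

  # zero eligible cells: flagged, no division error
  s4 <- summarize_population(mk_result(rep("unassigned", 5),
                                       eligible = FALSE))
  expect_true(is.na(s4$pct_intact))
  expect_equal(s4$n_eligible, 0)
})

test_that("replicate statistics reproduce closed-form SEM and Welch t-tests", {
  sums <- tibble::tibble(
    condition = rep(c("ctrl", "treat"), each = 3),
    pct_intact = c(10, 12, 11, 30, 29, 31),
    pct_partial = c(80, 78, 79, 60, 61, 59),
    pct_full = c(10, 10, 10, 10, 10, 10),
    pct_apoptotic = c(2, 2, 2, 2, 2, 2))
  cmp <- compare_replicates(sums, reference = "ctrl")

  sem <- cmp$sem[cmp$condition == "ctrl" & cmp$metric == "pct_intact"]
  expect_equal(sem, sd(c(10, 12, 11)) / sqrt(3), tolerance = 1e-12)

  row <- cmp[cmp$condition == "treat" & cmp$metric == "pct_intact", ]
  expect_lt(row$p_value, 0.05)
  expect_true(row$significant)

  # closed-form Welch oracle
  a <- c(30, 29, 31); b <- c(10, 12, 11)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_manual <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_manual <- 2 * pt(-abs(t_manual), df)
  expect_equal(row$t, t_manual, tolerance = 1e-10)
  expect_equal(row$p_value, p_manual, tolerance = 1e-10)

  # identical constant replicates: t = 0, p = 1
  same <- cmp[cmp$condition == "treat" & cmp$metric == "pct_full", ]
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # single replicate: means reported, test unavailable
  one <- tibble::tibble(condition = c("ctrl", "ctrl", "solo"),
                        pct_intact = c(10, 11, 40),
                        pct_partial = 0, pct_full = 0, pct_apoptotic = 0)
  cmp1 <- compare_replicates(one, reference = "ctrl")
  solo <- cmp1[cmp1$condition == "solo" & cmp1$metric == "pct_intact", ]
  expect_equal(solo$mean, 40)
  expect_true(is.na(solo$t))
})

test_that("density grids conserve counts and are deterministic", {
  tab <- tibble::tibble(cell_id = "c1",
                        golgi_t60_minor_axis_intensity = 2,
                        golgi_t60_area = 9)
  g <- density_plot_data(tab, "golgi_t60_minor_axis_intensity",
                         "golgi_t60_area", bins = 8,
                         xlim = c(0, 10), ylim = c(0, 40))
  expect_equal(sum(g$count), 1)
  expect_equal(sum(g$count > 0), 1)

  ft <- untreated_features()
  g2 <- density_plot_data(ft, "golgi_t60_minor_axis_intensity",
                          "golgi_t60_area", bins = 32)
  expect_equal(sum(g2$count), attr(g2, "n_in_range"))
  g3 <- density_plot_data(ft, "golgi_t60_minor_axis_intensity",
                          "golgi_t60_area", bins = 32)
  expect_identical(as.data.frame(g2), as.data.frame(g3))
})

test_that("fragmentation shifts the population density up and to the right", {
  ft_un <- untreated_features()
  noc <- sample_population(get_preset("noc_16h"), n = 250, seed = 55)
  ft_noc <- compute_features(noc$cells)
  com <- function(ft) {
    ok <- is.finite(ft$golgi_t60_minor_axis_intensity) &
      is.finite(ft$golgi_t60_area)
    c(mean(ft$golgi_t60_minor_axis_intensity[ok]),
      mean(ft$golgi_t60_area[ok]))
  }
  c_un <- com(ft_un); c_noc <- com(ft_noc)
  expect_gt(c_noc[1], c_un[1])
  expect_gt(c_noc[2], c_un[2])
})

test_that("plot builders return ggplot objects", {
  ft <- exemplar_features()
  gates <- fit_golgi_gates(ft, exemplar_pop()$truth$golgi_class)
  p1 <- autoplot(gates, table = ft, labels = exemplar_pop()$truth$golgi_class)
  expect_s3_class(p1, "ggplot")
  g <- density_plot_data(ft, "golgi_t60_minor_axis_intensity",
                         "golgi_t60_area", bins = 16)
  expect_s3_class(plot_density_map(g), "ggplot")
  s <- summarize_population(gate_cells(untreated_features(), test_config()),
                            "untreated")
  expect_s3_class(plot_population_summary(s), "ggplot")
})
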