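#' Population-level summary of a gating result
#'
#' Percentages of intact / partially fragmented / fully fragmented Golgi over
#' the eligible (singlet and focused) cells with an assigned Golgi label,
#' the apoptotic percentage over eligible cells, cycle-phase percentages and
#' mitotic-phase percentages within G2/M. A zero-eligible result is returned
#' flagged (`NA` percentages), never a division error.
#'
#' @param result A `gating_result` tibble from [gate_cells()].
#' @param sample_id Sample identifier carried into the summary.
#' @param condition,replicate Optional annotations for replicate statistics.
#' @return A one-row tibble with counts and percentages.
#' @export
summarize_population <- function(result, sample_id = "sample",
                                 condition = NA_character_,
                                 replicate = NA_integer_) {
  stopifnot(nrow(result) > 0)
  elig <- result$eligible
  n_elig <- sum(elig)
  g <- result$golgi[elig]
  assigned <- g[g != "unassigned"]
  n_assigned <- length(assigned)
  pct <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  cyc <- result$cycle[elig]
  n_cyc <- sum(!is.na(cyc))
  mit <- result$mitotic[elig & !is.na(result$cycle) & result$cycle == "G2M"]
  n_g2m <- length(mit)
  tibble::tibble(
    sample_id = sample_id, condition = condition,
    replicate = as.integer(replicate),
    n_total = nrow(result), n_eligible = n_elig,
    n_assigned = n_assigned,
    pct_intact = pct(sum(assigned == "intact"), n_assigned),
    pct_partial = pct(sum(assigned == "partial"), n_assigned),
    pct_full = pct(sum(assigned == "full"), n_assigned),
    pct_apoptotic = pct(sum(result$apoptotic[elig], na.rm = TRUE), n_elig),
    pct_g1 = pct(sum(cyc == "G1", na.rm = TRUE), n_cyc),
    pct_s = pct(sum(cyc == "S", na.rm = TRUE), n_cyc),
    pct_g2m = pct(sum(cyc == "G2M", na.rm = TRUE), n_cyc),
    pct_prophase = pct(sum(mit == "prophase"), n_g2m),
    pct_metaphase = pct(sum(mit == "metaphase"), n_g2m),
    pct_anaphase = pct(sum(mit == "anaphase"), n_g2m),
    pct_telophase = pct(sum(mit == "telophase"), n_g2m)
  )
}

#' Replicate statistics: mean, SEM and two-tailed t-tests vs a reference
#'
#' For each condition and metric, the mean and standard error of the mean
#' over replicates; for non-reference conditions, the two-tailed t statistic
#' and p-value against the reference condition (Welch by default, pooled
#' variance with `var_equal = TRUE`) and a significance flag at p < 0.05.
#' Single-replicate conditions report means with the test flagged
#' unavailable.
#'
#' @param summaries Tibble of per-replicate [summarize_population()] rows
#'   with a `condition` column.
#' @param reference Reference condition name.
#' @param metrics Metric columns to compare (default: the Golgi and
#'   apoptosis percentages).
#' @param var_equal Use the pooled-variance (classic Student) test instead
#'   of Welch.
#' @return A tibble `condition`, `metric`, `n`, `mean`, `sem`, `t`,
#'   `p_value`, `significant`.
#' @export
compare_replicates <- function(summaries, reference,
                               metrics = c("pct_intact", "pct_partial",
                                           "pct_full", "pct_apoptotic"),
                               var_equal = FALSE) {
  stopifnot("condition" %in% names(summaries))
  if (!reference %in% summaries$condition) {
    stop("reference condition '", reference, "' not in summaries",
         call. = FALSE)
  }
  conds <- unique(summaries$condition)
  rows <- list()
  for (cond in conds) {
    for (m in metrics) {
      v <- summaries[[m]][summaries$condition == cond]
      v <- v[!is.na(v)]
      ref <- summaries[[m]][summaries$condition == reference]
      ref <- ref[!is.na(ref)]
      n <- length(v)
      mean_v <- mean(v)
      sem <- if (n > 1) sd(v) / sqrt(n) else NA_real_
      tt <- pp <- NA_real_
      if (cond != reference && n >= 2 && length(ref) >= 2) {
        if (sd(v) == 0 && sd(ref) == 0) {
          if (mean(v) == mean(ref)) { tt <- 0; pp <- 1 }
        } else {
          ht <- t.test(v, ref, var.equal = var_equal,
                       alternative = "two.sided")
          tt <- unname(ht$statistic); pp <- ht$p.value
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, metric = m, n = n, mean = mean_v, sem = sem,
        t = tt, p_value = pp,
        significant = !is.na(pp) & pp < 0.05)
    }
  }
  dplyr::bind_rows(rows)
}

#' Binned 2-D density data for a feature pair
#'
#' Deterministic 2-D histogram of two feature columns on fixed (configurable)
#' ranges, for density dot-plots of e.g. minor axis intensity vs area.
#'
#' @param table Feature table.
#' @param x,y Feature column names.
#' @param bins Number of bins per axis.
#' @param xlim,ylim Bin ranges; defaults to the finite data range.
#' @return A tibble `x_mid`, `y_mid`, `count` (all bins, zeros included),
#'   with attributes `"x_breaks"`, `"y_breaks"` and `"n_in_range"`.
#' @export
density_plot_data <- function(table, x, y, bins = 64, xlim = NULL,
                              ylim = NULL) {
  require_columns(table, c(x, y))
  xv <- table[[x]]; yv <- table[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  rng <- function(v, lim) {
    if (!is.null(lim)) return(lim)
    if (!any(ok)) return(c(0, 1))
    r <- range(v[ok])
    if (r[1] == r[2]) r + c(-0.5, 0.5) else r
  }
  xlim <- rng(xv, xlim); ylim <- rng(yv, ylim)
  xb <- seq(xlim[1], xlim[2], length.out = bins + 1)
  yb <- seq(ylim[1], ylim[2], length.out = bins + 1)
  sel <- ok & xv >= xlim[1] & xv <= xlim[2] & yv >= ylim[1] & yv <= ylim[2]
  xi <- pmin(findInterval(xv[sel], xb, rightmost.closed = TRUE), bins)
  yi <- pmin(findInterval(yv[sel], yb, rightmost.closed = TRUE), bins)
  counts <- matrix(0L, bins, bins)
  if (any(sel)) {
    t2 <- table(factor(xi, levels = seq_len(bins)),
                factor(yi, levels = seq_len(bins)))
    counts <- matrix(as.integer(t2), bins, bins)
  }
  grid <- tidyr::expand_grid(
    x_mid = (xb[-1] + xb[-(bins + 1)]) / 2,
    y_mid = (yb[-1] + yb[-(bins + 1)]) / 2)
  grid$count <- as.integer(t(counts))
  out <- grid[, c("x_mid", "y_mid", "count")]
  attr(out, "x_breaks") <- xb
  attr(out, "y_breaks") <- yb
  attr(out, "n_in_range") <- sum(sel)
  attr(out, "features") <- c(x = x, y = y)
  out
}
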