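#' Tidy the fitted Golgi gates
#'
#' @param x A `golgi_gates` object from [fit_golgi_gates()].
#' @param ... Unused.
#' @return A tibble with one row per class: sample size, class centers and
#'   SDs on both gate axes.
#' @export
tidy.golgi_gates <- function(x, ...) {
  x$class_stats
}

#' One-row summary of the fitted Golgi gates
#'
#' @inheritParams tidy.golgi_gates
#' @return A tibble with the four gate boundaries, the exemplar count and
#'   the resubstitution accuracy.
#' @export
glance.golgi_gates <- function(x, ...) {
  tibble::tibble(
    x_intact_max = x$boundaries$x_intact_max,
    y_intact_max = x$boundaries$y_intact_max,
    x_full_min = x$boundaries$x_full_min,
    y_full_min = x$boundaries$y_full_min,
    n = x$resubstitution$n,
    resubstitution_accuracy = x$resubstitution$accuracy)
}

#' Tidy an RD feature ranking
#'
#' @param x An `rd_ranking` from [rank_features()].
#' @param ... Unused.
#' @return The ranking as a plain tibble with a `rank` column.
#' @export
tidy.rd_ranking <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' One-row summary of a gating result
#'
#' @param x A `gating_result` from [gate_cells()].
#' @param ... Unused.
#' @return A one-row tibble of counts through the gate hierarchy.
#' @export
glance.gating_result <- function(x, ...) {
  tibble::tibble(
    n_total = nrow(x),
    n_singlet = sum(x$singlet),
    n_focused = sum(x$focused),
    n_eligible = sum(x$eligible),
    n_g2m = sum(x$cycle == "G2M", na.rm = TRUE),
    n_apoptotic = sum(x$apoptotic, na.rm = TRUE),
    n_golgi_assigned = sum(x$golgi != "unassigned"))
}
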