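# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the iteration-resolved trace of a trial
#'
#' @param x An `actinf_trial`.
#' @param ... Unused.
#' @return Tibble: level, iteration_global, ms, factor, unit, firing.
#' @export
tidy.actinf_trial <- function(x, ...) {
  out <- x$trace
  out[, c("level", "block", "iteration_global", "ms", "factor", "unit", "firing")]
}

#' One-row summary of a trial
#'
#' @param x An `actinf_trial`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.actinf_trial <- function(x, ...) {
  tibble::tibble(n_epochs_top = x$n_epochs_top,
                 n_epochs_lower = x$n_epochs_lower,
                 total_ms = x$total_ms,
                 replayed = x$replayed,
                 seed = x$seed)
}

#' Per-model validation results
#' @param x An `actinf_validation`.
#' @param ... Unused.
#' @return Tibble with one row per micro-model.
#' @export
tidy.actinf_validation <- function(x, ...) x$models

#' One-row validation summary
#' @param x An `actinf_validation`.
#' @param ... Unused.
#' @return One-row tibble with the extreme statistics across models.
#' @export
glance.actinf_validation <- function(x, ...) {
  m <- x$models
  if (!nrow(m)) {
    return(tibble::tibble(n_models = 0L, max_abs_err = NA_real_,
                          max_F_rise = NA_real_, n_descent_violations = 0L,
                          min_epistemic = NA_real_,
                          max_decomposition_gap = NA_real_))
  }
  tibble::tibble(n_models = nrow(m),
                 max_abs_err = max(m$max_abs_err),
                 max_F_rise = max(m$max_F_rise),
                 n_descent_violations = sum(m$max_F_rise > 1e-6),
                 min_epistemic = min(m$min_epistemic),
                 max_decomposition_gap = max(m$max_decomposition_gap))
}

#' Latency table of a violation analysis
#' @param x A `reading_violation`.
#' @param ... Unused.
#' @return Tibble of per-condition, per-level latencies and amplitudes.
#' @export
tidy.reading_violation <- function(x, ...) x$latencies

#' One-row summary of a violation analysis
#' @param x A `reading_violation`.
#' @param ... Unused.
#' @return One-row tibble: mismatch and early-deflection latencies (ms) and
#'   the above-half-maximum support of the local and global differences.
#' @export
glance.reading_violation <- function(x, ...) {
  lat <- x$latencies
  pick <- function(cond, lv, col) {
    v <- lat[[col]][lat$condition == cond & lat$level == lv]
    if (length(v)) v[1] else NA_real_
  }
  tibble::tibble(
    mmn_latency_ms = pick("local", 1L, "latency_ms"),
    early_latency_ms = pick("standard_early", 1L, "latency_ms"),
    local_support_ms = pick("local", 1L, "half_max_support_ms"),
    global_support_ms = pick("global", 1L, "half_max_support_ms"),
    align_ms = x$align_ms)
}

#' Raster plot of a simulated trial
#'
#' Firing-rate rasters for both levels on the global millisecond clock (an
#' expectation of one plots dark), with saccadic epoch onsets marked.
#'
#' @param object An `actinf_trial`.
#' @param factors Named list mapping level to displayed factor
#'   (default word / sentence units for reading models).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.actinf_trial <- function(object,
                                  factors = list(`1` = NULL, `2` = NULL),
                                  ...) {
  ser <- dplyr::bind_rows(lapply(c(1L, 2L), function(lv)
    dplyr::mutate(trace_series(object, lv, factors[[as.character(lv)]]),
                  level = lv)))
  ser$row <- paste0("L", ser$level, " ", ser$factor, " ", ser$unit)
  onsets <- object$blocks$ms_start[object$blocks$level == 1L]
  ggplot2::ggplot(ser, ggplot2::aes(x = .data$ms, y = .data$row,
                                    fill = .data$firing)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "expectation") +
    ggplot2::geom_vline(xintercept = onsets, colour = "cyan3",
                        linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$level), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Difference-waveform plot of a violation analysis
#'
#' @param object A `reading_violation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reading_violation <- function(object, ...) {
  d <- object$differences
  d$trace <- paste(d$factor, d$unit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$peri_ms, y = .data$value,
                                  group = .data$trace,
                                  colour = factor(.data$level))) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_colour_manual(values = c(`1` = "blue3", `2` = "red3"),
                                 name = "level") +
    ggplot2::labs(x = "peristimulus time (ms)", y = "difference (a.u.)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
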