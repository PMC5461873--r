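# Simulated electrophysiology: expectation-unit firing collected on the
# global 16 ms iteration grid becomes rasters; band-pass filtered firing
# fluctuations stand in for (depolarisation-driven) local field potentials;
# condition differences aligned to the analysed perisaccadic epoch yield
# mismatch-negativity and P300-like difference waveforms.

#' Continuous firing-rate series for one level of a trial
#'
#' Expectation-unit (Bayesian model average, initial time step) firing on the
#' global iteration grid. While a level is suspended (the other level is
#' updating) its expectations are sustained at their last value.
#'
#' @param trial An `actinf_trial` with a recorded trace.
#' @param level Level index (1 = lowest).
#' @param factors Factor names to include (default: all factors of the level).
#' @return Tibble: `iteration_global`, `ms`, `factor`, `unit`, `firing`.
#' @export
trace_series <- function(trial, level, factors = NULL) {
  tr <- trial$trace
  stopifnot(!is.null(tr))
  n_it <- max(tr$iteration_global)
  msi <- trial$ms_per_iteration
  tr <- tr[tr$level == level, ]
  if (!is.null(factors)) tr <- tr[tr$factor %in% factors, ]
  out <- list()
  for (key in unique(paste(tr$factor, tr$unit, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- tr[tr$factor == parts[1] & tr$unit == as.integer(parts[2]), ]
    y <- rep(NA_real_, n_it)
    y[sub$iteration_global] <- sub$firing
    # sustain during suspension; before the level's first update, hold its
    # first (prior) value
    filled <- y
    last <- NA_real_
    for (i in seq_len(n_it)) {
      if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
    }
    first_val <- sub$firing[which.min(sub$iteration_global)]
    filled[is.na(filled)] <- first_val
    out[[key]] <- tibble::tibble(
      iteration_global = seq_len(n_it),
      ms = (seq_len(n_it) - 1) * msi,
      factor = parts[1], unit = as.integer(parts[2]), firing = filled)
  }
  dplyr::bind_rows(out)
}

#' Firing-rate raster for one level
#'
#' @inheritParams trace_series
#' @return A units x iterations matrix of firing rates in `[0, 1]`; row names
#'   `factor.unit`, with the global ms grid in `attr(, "ms")`.
#' @export
raster <- function(trial, level, factors = NULL) {
  ser <- trace_series(trial, level, factors)
  keys <- unique(paste(ser$factor, ser$unit, sep = "."))
  n_it <- max(ser$iteration_global)
  m <- matrix(NA_real_, length(keys), n_it, dimnames = list(keys, NULL))
  for (k in seq_along(keys)) {
    sub <- ser[paste(ser$factor, ser$unit, sep = ".") == keys[k], ]
    m[k, sub$iteration_global] <- sub$firing
  }
  attr(m, "ms") <- (seq_len(n_it) - 1) * trial$ms_per_iteration
  m
}

#' Band-pass filtered simulated local field potentials
#'
#' Each unit's firing series is linearly upsampled (default 4x, to a 4 ms
#' grid, so the printed 4-32 Hz band lies below Nyquist) and filtered with a
#' zero-phase (forward-backward) second-order Butterworth band-pass.
#'
#' @inheritParams trace_series
#' @param band_hz Band edges in Hz (default `c(4, 32)`).
#' @param upsample Integer upsampling factor (default 4).
#' @param condition Condition label attached to the waveforms.
#' @return Tibble: `time_ms`, `level`, `factor`, `unit`, `value`, `condition`
#'   (class `actinf_lfp`).
#' @export
lfp <- function(trial, level, factors = NULL, band_hz = c(4, 32),
                upsample = 4L, condition = "standard") {
  ser <- trace_series(trial, level, factors)
  msi <- trial$ms_per_iteration
  dt <- msi / upsample
  fs <- 1000 / dt
  if (band_hz[1] <= 0 || band_hz[2] >= fs / 2 || band_hz[1] >= band_hz[2])
    stop(sprintf("band-invalid: (%g, %g) Hz outside (0, %g) Hz",
                 band_hz[1], band_hz[2], fs / 2), call. = FALSE)
  bf <- signal::butter(2, band_hz / (fs / 2), type = "pass")
  # demean and reflect-pad before the zero-phase pass so that edges do not
  # inject step transients (filtfilt pads with zeros otherwise)
  bandpass <- function(y) {
    mu <- mean(y)
    y <- y - mu
    n <- length(y)
    pad <- min(n - 1L, 200L)
    yp <- c(rev(y[seq_len(pad) + 1L]), y, rev(y[n - seq_len(pad)]))
    as.numeric(signal::filtfilt(bf, yp))[pad + seq_len(n)]
  }
  out <- ser |>
    dplyr::group_by(.data$factor, .data$unit) |>
    dplyr::group_modify(function(d, key) {
      t_new <- seq(min(d$ms), max(d$ms), by = dt)
      y <- stats::approx(d$ms, d$firing, xout = t_new)$y
      tibble::tibble(time_ms = t_new, value = bandpass(y))
    }) |>
    dplyr::ungroup()
  out$level <- level
  out$condition <- condition
  class(out) <- c("actinf_lfp", class(out))
  out
}

#' Pointwise difference waveform between two conditions
#'
#' Subtracts the standard from the deviant condition per unit and time point.
#' Both waveform sets must come from identically scheduled (replayed) trials.
#' Applying it to two difference waveforms yields the interaction
#' (difference-of-differences).
#'
#' @param cond,standard `actinf_lfp` tibbles on the same time grid.
#' @return An `actinf_lfp` tibble whose `condition` records both parents.
#' @export
difference_waveform <- function(cond, standard) {
  keys <- c("time_ms", "level", "factor", "unit")
  if ("peri_ms" %in% names(cond) && "peri_ms" %in% names(standard))
    keys <- c(keys, "peri_ms")
  j <- dplyr::inner_join(cond, standard, by = keys,
                         suffix = c("_cond", "_std"))
  if (nrow(j) != nrow(cond) || nrow(j) != nrow(standard))
    stop("difference_waveform: misaligned waveforms", call. = FALSE)
  out <- tibble::tibble(
    time_ms = j$time_ms, level = j$level, factor = j$factor, unit = j$unit,
    value = j$value_cond - j$value_std,
    condition = paste(j$condition_cond, "-", j$condition_std))
  if ("peri_ms" %in% keys) out$peri_ms <- j$peri_ms
  class(out) <- c("actinf_lfp", class(out))
  out
}

#' Onset (ms) of the last saccadic epoch before the decision
#'
#' Returns the start time of the final lowest-level epoch of the trial: the
#' last saccade prior to the decision epochs, the alignment event for the
#' violation analyses.
#'
#' @param trial An `actinf_trial`.
#' @return Time in ms on the global clock.
#' @export
last_saccade_onset <- function(trial) {
  b <- trial$blocks[trial$blocks$level == 1L, ]
  if (!nrow(b)) stop("trial has no lower-level epochs", call. = FALSE)
  b$ms_start[which.max(b$block)]
}

#' Align waveforms to an event and window them
#'
#' @param wave An `actinf_lfp` tibble.
#' @param align_ms Event time on the global clock (t = 0 after alignment).
#' @param window_ms Peristimulus window kept, default `c(0, 400)` ms.
#' @return The windowed tibble with an added `peri_ms` column.
#' @export
align_waveform <- function(wave, align_ms, window_ms = c(0, 400)) {
  out <- wave
  out$peri_ms <- out$time_ms - align_ms
  out <- out[out$peri_ms >= window_ms[1] & out$peri_ms <= window_ms[2], ]
  class(out) <- class(wave)
  out
}

#' Latency and amplitude of the extremal deflection in a window
#'
#' Finds the extremal sample of the waveform within the window (over all
#' units pooled, or per unit); ties resolve to the earliest sample. No
#' sub-sample interpolation is performed.
#'
#' @param wave An `actinf_lfp` tibble carrying a `peri_ms` column (see
#'   [align_waveform()]); a plain `time_ms` column is used as-is otherwise.
#' @param window_ms Search window in (peristimulus) ms.
#' @param polarity `"absmax"` (default), `"max"` or `"min"`.
#' @param by_unit Return one row per unit instead of the pooled extremum.
#' @return Tibble with `latency_ms`, `amplitude` (and `factor`/`unit`).
#' @export
peak_latency <- function(wave, window_ms = c(0, 400),
                         polarity = c("absmax", "max", "min"),
                         by_unit = FALSE) {
  polarity <- match.arg(polarity)
  t <- if ("peri_ms" %in% names(wave)) wave$peri_ms else wave$time_ms
  keep <- t >= window_ms[1] & t <= window_ms[2]
  if (!any(keep)) stop("peak_latency: empty window", call. = FALSE)
  w <- wave[keep, ]
  tk <- t[keep]
  score <- switch(polarity, absmax = abs(w$value), max = w$value, min = -w$value)
  pick <- function(idx) {
    s <- score[idx]
    best <- idx[s == max(s)]
    best <- best[which.min(tk[best])]
    tibble::tibble(latency_ms = tk[best], amplitude = w$value[best],
                   factor = w$factor[best], unit = w$unit[best])
  }
  if (!by_unit) return(pick(seq_along(tk)))
  keys <- paste(w$factor, w$unit)
  dplyr::bind_rows(lapply(unique(keys), function(k) pick(which(keys == k))))
}

#' Duration of the above-half-maximum envelope of a waveform
#'
#' The envelope is the maximum absolute value across units at each time
#' point; the support is the total time it spends at or above half its
#' maximum. Used to compare how protracted global versus local violation
#' responses are.
#'
#' @inheritParams peak_latency
#' @return Duration in ms.
#' @export
half_max_support <- function(wave, window_ms = c(0, 400)) {
  t <- if ("peri_ms" %in% names(wave)) wave$peri_ms else wave$time_ms
  keep <- t >= window_ms[1] & t <= window_ms[2]
  w <- wave[keep, ]
  tk <- t[keep]
  env <- tapply(abs(w$value), tk, max)
  tt <- as.numeric(names(env))
  dt <- if (length(tt) > 1) min(diff(sort(tt))) else 0
  sum(env >= max(env) / 2) * dt
}
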