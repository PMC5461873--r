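# Scripted experiments: the exemplar reading trial, the violation battery
# (local / global / both, replayed on identical stimuli and actions), and the
# engine validation suite against an exact enumeration oracle.

#' Run the exemplar reading trial
#'
#' Simulates reading of sentence 1 (lower case except the designated
#' vertically flipped word) under the default priors, and summarises
#' behaviour: saccades per word, decision, feedback and total simulated time.
#'
#' @param config A [reading_config()].
#' @param seed Integer seed.
#' @param stimuli Optional stimuli (default: the exemplar of the config).
#' @param threshold_nats Optional override of the termination threshold.
#' @param out_dir If non-NULL, trial record, rasters and LFPs are written
#'   there as delimited text with a manifest.
#' @return List with `trial` (an `actinf_trial`), `summary` (one-row tibble),
#'   `saccades` (tibble) and `config`.
#' @export
run_reading_experiment <- function(config = reading_config(), seed = 1,
                                   stimuli = NULL, threshold_nats = NULL,
                                   out_dir = NULL) {
  model <- build_reading_model(config)
  rule <- termination_rule(threshold_nats %||% config$threshold_nats,
                           target = "word")
  stimuli <- stimuli %||% reading_stimuli(config)
  trial <- run_trial(model, stimuli = stimuli, rule = rule, seed = seed,
                     kappa = config$kappa)
  res <- list(trial = trial, summary = reading_summary(trial),
              saccades = saccade_log(trial), config = config)
  if (!is.null(out_dir))
    write_trial_record(trial, out_dir, experiment = "read", config = config)
  res
}

#' Run the violation battery and compute difference waveforms
#'
#' Runs the standard exemplar trial, replays it with exactly the same stimuli
#' and actions under each violated prior (local: vertical-flip prior reversed
#' for the last word; global: sentence-1 prior deflated; both), band-passes
#' the per-level firing traces, aligns them to the last saccade before the
#' decision, and returns difference waveforms, the interaction
#' (difference-of-differences), and a latency/amplitude table.
#'
#' @param config A [reading_config()].
#' @param kinds Violations to run (subset of `c("local", "global", "both")`).
#' @param seed Integer seed.
#' @param window_ms Peristimulus analysis window (default 0-400 ms).
#' @param display_factors Factors whose units are analysed per level
#'   (default: the three word units at level 1, six sentence units at
#'   level 2).
#' @param out_dir If non-NULL, waveforms and the latency table are written as
#'   delimited text with a manifest.
#' @return Object of class `reading_violation`: `summary`, `waveforms`
#'   (aligned, per condition), `differences`, `interaction`, `latencies`,
#'   `align_ms`, plus the standard and replayed trials.
#' @export
run_violation_experiment <- function(config = reading_config(),
                                     kinds = c("local", "global", "both"),
                                     seed = 1, window_ms = c(0, 400),
                                     display_factors = list(`1` = "word",
                                                            `2` = "sentence"),
                                     out_dir = NULL) {
  kinds <- intersect(kinds, c("local", "global", "both"))
  std <- run_reading_experiment(config, seed = seed)
  align <- last_saccade_onset(std$trial)
  trials <- list(standard = std$trial)
  for (k in kinds)
    trials[[k]] <- replay_trial(apply_violation(build_reading_model(config), k, config),
                                std$trial)

  wave_one <- function(trial, condition) {
    dplyr::bind_rows(lapply(c(1L, 2L), function(lv)
      lfp(trial, level = lv, factors = display_factors[[as.character(lv)]],
          band_hz = config$band_hz, condition = condition)))
  }
  waves <- lapply(names(trials), function(cn) wave_one(trials[[cn]], cn))
  names(waves) <- names(trials)

  aligned <- lapply(waves, align_waveform, align_ms = align, window_ms = window_ms)
  diffs <- list()
  for (k in kinds)
    diffs[[k]] <- difference_waveform(aligned[[k]], aligned$standard)
  interaction <- NULL
  if (all(c("local", "global", "both") %in% kinds)) {
    interaction <- difference_waveform(
      difference_waveform(aligned$both, aligned$global),
      diffs$local)
    interaction$condition <- "(both - global) - (local - standard)"
  }

  lat_rows <- list()
  for (k in names(diffs)) for (lv in c(1L, 2L)) {
    d <- diffs[[k]][diffs[[k]]$level == lv, ]
    pk <- peak_latency(d, window_ms = window_ms)
    lat_rows[[length(lat_rows) + 1]] <- tibble::tibble(
      condition = k, level = lv, latency_ms = pk$latency_ms,
      amplitude = pk$amplitude,
      half_max_support_ms = half_max_support(d, window_ms))
  }
  # early (N1-like) deflection of the standard first-level response
  n1 <- peak_latency(aligned$standard[aligned$standard$level == 1L, ],
                     window_ms = c(0, 150))
  lat_rows[[length(lat_rows) + 1]] <- tibble::tibble(
    condition = "standard_early", level = 1L, latency_ms = n1$latency_ms,
    amplitude = n1$amplitude, half_max_support_ms = NA_real_)
  latencies <- dplyr::bind_rows(lat_rows)

  out <- structure(list(
    summary = std$summary, trials = trials,
    waveforms = dplyr::bind_rows(aligned), differences = dplyr::bind_rows(diffs),
    differences_by_kind = diffs, interaction = interaction,
    latencies = latencies, align_ms = align, window_ms = window_ms,
    config = config, seed = seed), class = "reading_violation")
  if (!is.null(out_dir)) write_violation_outputs(out, out_dir)
  out
}

#' @export
print.reading_violation <- function(x, ...) {
  cat(sprintf("<reading_violation> conditions: %s; aligned at %g ms\n",
              paste(names(x$trials), collapse = ", "), x$align_ms))
  print(x$latencies)
  invisible(x)
}

random_micro_model <- function(n_states, n_modalities, n_out, horizon = 2L,
                               n_iterations = 16L, ms = 16) {
  A <- lapply(seq_len(n_modalities), function(m)
    normalize_columns(matrix(stats::runif(n_out * n_states) + 0.05,
                             nrow = n_out)))
  names(A) <- paste0("m", seq_len(n_modalities))
  B <- array(0, dim = c(n_states, n_states, 2L))
  B[, , 1] <- diag(n_states)
  B[, , 2] <- normalize_columns(matrix(stats::runif(n_states^2) + 0.05,
                                       nrow = n_states))
  D <- stats::runif(n_states) + 0.05
  D <- D / sum(D)
  level_model(
    factors = c(state = n_states),
    modalities = stats::setNames(rep(n_out, n_modalities), names(A)),
    A = lapply(A, function(a) array(a, dim = c(n_out, n_states))),
    B = list(state = B),
    D = list(state = D),
    policies = list(cbind(1L), cbind(2L)),
    horizon = horizon, n_iterations = n_iterations, ms_per_iteration = ms,
    name = "micro")
}

#' Validate the belief engine against an exact enumeration oracle
#'
#' Generates random single-factor micro-models (2-4 states, 1-2 modalities of
#' 2-4 outcomes), presents one sampled observation, and compares the engine's
#' converged single-epoch posterior with the exact Bayes posterior computed by
#' enumeration. Also audits free-energy descent across iterations, the
#' non-negativity of epistemic value, and the agreement of the risk+ambiguity
#' and epistemic+pragmatic decompositions of expected free energy.
#'
#' @param n_models Number of random micro-models (default 100).
#' @param seed Integer seed.
#' @param kappa Gradient step size (set deliberately large to exercise the
#'   descent detector).
#' @param n_iterations Iterations per epoch (default 16).
#' @return Object of class `actinf_validation`: a per-model tibble plus
#'   summary statistics; see [glance.actinf_validation()].
#' @export
validate_engine <- function(n_models = 100, seed = 1, kappa = 0.25,
                            n_iterations = 16L) {
  rows <- with_seed(seed, lapply(seq_len(n_models), function(i) {
    n_states <- sample(2:4, 1)
    n_mod <- sample(1:2, 1)
    n_out <- sample(2:4, 1)
    lvl <- random_micro_model(n_states, n_mod, n_out,
                              n_iterations = n_iterations)
    true_s <- sample.int(n_states, 1)
    obs <- lapply(seq_len(n_mod), function(m)
      sample_cat(lvl$A[[m]][, true_s]))
    names(obs) <- names(lvl$modalities)

    b <- init_beliefs(lvl)
    b <- set_observation(b, 1L, obs)
    up <- update_epoch(lvl, b, kappa = kappa, record_trace = TRUE)
    bf <- up$beliefs

    # exact enumeration: posterior over the single epoch's state
    post <- resolve_D_prior(lvl, "state", NULL)
    for (m in names(obs))
      post <- post * lvl$A[[m]][obs[[m]], ]
    post <- post / sum(post)
    err <- max(abs(bma_states(bf, tau = 1L)$state - post))

    favg <- tapply(up$trace$energies$F * up$trace$pi$prob,
                   up$trace$energies$iteration, sum)
    dF <- diff(as.numeric(favg))
    max_rise <- if (length(dF)) max(dF) else 0

    gaps <- epi_min <- numeric(0)
    for (p in seq_len(bf$n_pol)) {
      g <- expected_free_energy(lvl, bf, p)
      if (nrow(g$parts)) {
        gaps <- c(gaps, abs((g$parts$risk + g$parts$ambiguity) -
                              (-(g$parts$epistemic + g$parts$pragmatic))))
        epi_min <- c(epi_min, g$parts$epistemic)
      }
    }
    tibble::tibble(model = i, n_states = n_states, n_modalities = n_mod,
                   n_outcomes = n_out, max_abs_err = err,
                   max_F_rise = max_rise,
                   min_epistemic = min(epi_min),
                   max_decomposition_gap = max(gaps))
  }))
  tab <- dplyr::bind_rows(rows)
  structure(list(models = tab, n_models = n_models, seed = seed,
                 kappa = kappa, n_iterations = n_iterations),
            class = "actinf_validation")
}

#' @export
print.actinf_validation <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("<actinf_validation> %d micro-models (kappa = %g, %d iterations)\n",
              x$n_models, x$kappa, x$n_iterations))
  cat(sprintf("  max |posterior - oracle|   : %.2e\n", s$max_abs_err))
  cat(sprintf("  max free-energy rise       : %.2e (descent violations: %d)\n",
              s$max_F_rise, s$n_descent_violations))
  cat(sprintf("  min epistemic value        : %.2e\n", s$min_epistemic))
  cat(sprintf("  max decomposition gap      : %.2e\n", s$max_decomposition_gap))
  invisible(x)
}
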