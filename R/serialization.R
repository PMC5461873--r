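# Plain-text persistence: YAML for model and reading configurations (full
# round-trip), delimited text for traces, trial records, fixtures and
# waveforms, and a YAML manifest with parameter echoes and file checksums.

encode_array <- function(x) {
  list(dim = as.integer(dim(x) %||% length(x)), values = as.numeric(x))
}

decode_array <- function(e) {
  if (length(e$dim) > 1L) array(e$values, dim = e$dim) else as.numeric(e$values)
}

encode_level <- function(lvl) {
  list(
    name = lvl$name,
    factors = as.list(lvl$factors),
    modalities = as.list(lvl$modalities),
    A = lapply(lvl$A, encode_array),
    B = lapply(lvl$B, encode_array),
    C = lapply(lvl$C, as.numeric),
    D = lapply(lvl$D, function(d)
      list(parents = as.list(d$parents), table = encode_array(d$table))),
    policies = lapply(lvl$policies, function(p)
      list(dim = dim(p), values = as.integer(p))),
    horizon = lvl$horizon,
    n_iterations = lvl$n_iterations,
    ms_per_iteration = lvl$ms_per_iteration)
}

decode_level <- function(e) {
  level_model(
    factors = unlist(e$factors),
    modalities = unlist(e$modalities),
    A = lapply(e$A, decode_array),
    B = lapply(e$B, decode_array),
    C = lapply(e$C, as.numeric),
    D = lapply(e$D, function(d)
      list(parents = as.character(unlist(d$parents)),
           table = decode_array(d$table))),
    policies = lapply(e$policies, function(p)
      matrix(as.integer(unlist(p$values)), nrow = p$dim[[1]])),
    horizon = e$horizon,
    n_iterations = e$n_iterations,
    ms_per_iteration = e$ms_per_iteration,
    name = e$name)
}

#' Write / read a hierarchical model as a plain-text (YAML) config
#'
#' The full specification (factor and modality names and sizes, dense A/B/C/D
#' entries, policies, horizons, link and gate maps) round-trips exactly.
#'
#' @param model An `actinf_model`.
#' @param path File path.
#' @return `write_model_config` returns `path` invisibly; `read_model_config`
#'   returns the reconstructed `actinf_model`.
#' @export
write_model_config <- function(model, path) {
  obj <- list(levels = lapply(model$levels, encode_level),
              links = model$links,
              gates = model$gates)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- yaml::read_yaml(path)
  deep_model(levels = lapply(obj$levels, decode_level),
             links = lapply(obj$links, function(l)
               list(factor = l$factor, modality = l$modality)),
             gates = if (is.null(obj$gates)) NULL else
               lapply(obj$gates, function(g)
                 if (is.null(g)) NULL else
                   list(factor = g$factor, state = as.integer(g$state))))
}

#' Write / read a reading configuration as YAML
#'
#' @param config A [reading_config()].
#' @param path File path.
#' @return The path (write) or a `reading_config` (read).
#' @export
write_reading_config <- function(config, path) {
  obj <- unclass(config)
  obj$sentences <- lapply(obj$sentences, as.list)
  obj$happy_set <- NULL # derived
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_reading_config
#' @export
read_reading_config <- function(path) {
  obj <- yaml::read_yaml(path)
  reading_config(
    sentences = lapply(obj$sentences, function(s) as.character(unlist(s))),
    wrong_log_pref = obj$wrong_log_pref,
    right_log_pref = obj$right_log_pref,
    vflip_prior = as.numeric(unlist(obj$vflip_prior)),
    hflip_prior = as.numeric(unlist(obj$hflip_prior)),
    violation = obj$violation,
    global_factor = obj$global_factor,
    exemplar_sentence = obj$exemplar_sentence,
    exemplar_vflip_word = obj$exemplar_vflip_word,
    threshold_nats = obj$threshold_nats,
    kappa = obj$kappa,
    n_iterations = obj$n_iterations,
    ms_per_iteration = obj$ms_per_iteration,
    band_hz = as.numeric(unlist(obj$band_hz)))
}

manifest_entry <- function(files) {
  sums <- tools::md5sum(files)
  stats::setNames(as.list(unname(sums)), basename(files))
}

write_manifest <- function(dir, experiment, seed, parameters, conditions,
                           files) {
  manifest <- list(experiment = experiment, seed = seed,
                   parameters = parameters, conditions = as.list(conditions),
                   files = manifest_entry(files))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 17)
  invisible(path)
}

trial_parameters <- function(trial, config = NULL) {
  top <- trial$model$levels[[length(trial$model$levels)]]
  pars <- list(kappa = trial$kappa,
               threshold_nats = trial$rule$threshold_nats,
               n_iterations = top$n_iterations,
               ms_per_iteration = top$ms_per_iteration,
               horizons = lapply(trial$model$levels, function(l) l$horizon))
  if (!is.null(config))
    pars <- c(pars, list(band_hz = config$band_hz,
                         wrong_log_pref = config$wrong_log_pref,
                         right_log_pref = config$right_log_pref,
                         global_factor = config$global_factor))
  pars
}

#' Export a trial record as delimited-text tables plus a manifest
#'
#' Writes the iteration trace, epoch blocks, per-epoch free energies, true
#' states, the saccade log and behavioural summary (for reading models), and
#' a YAML manifest echoing all numeric parameters and the md5 checksum of
#' every file. Re-running the same experiment with the same manifest
#' reproduces identical checksums.
#'
#' @param trial An `actinf_trial`.
#' @param dir Output directory (created if needed).
#' @param experiment Experiment name recorded in the manifest.
#' @param condition Condition label.
#' @param config Optional [reading_config()] echoed into the manifest.
#' @param extra Optional named list of extra tibbles to write.
#' @return Invisibly, the manifest path.
#' @export
write_trial_record <- function(trial, dir, experiment = "trial",
                               condition = "standard", config = NULL,
                               extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(trace = trial$trace, blocks = trial$blocks,
               energies = trial$energies, true_states = trial$true_top)
  if (!is.null(config)) {
    tabs$saccades <- saccade_log(trial)
    tabs$summary <- reading_summary(trial)
  }
  tabs <- c(tabs, extra)
  files <- character(0)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], f)
    files <- c(files, f)
  }
  write_manifest(dir, experiment, trial$seed,
                 trial_parameters(trial, config), condition, files)
}

#' Export waveforms as delimited text
#'
#' @param waves An `actinf_lfp` tibble (or any tibble of waveforms).
#' @param path Output csv path.
#' @return The path, invisibly.
#' @export
export_waveforms <- function(waves, path) {
  readr::write_csv(waves, path)
  invisible(path)
}

write_violation_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(tab, nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tab, f)
    files <<- c(files, f)
  }
  add(res$waveforms, "waveforms")
  if (nrow(res$differences)) add(res$differences, "differences")
  if (!is.null(res$interaction)) add(res$interaction, "interaction")
  add(res$latencies, "latencies")
  add(res$summary, "summary")
  write_manifest(dir, "violation", res$seed,
                 trial_parameters(res$trials$standard, res$config),
                 names(res$trials), files)
}

#' Write a sampled trial fixture as delimited text
#'
#' One row per level/epoch/time/modality with the sampled outcome index, and
#' a companion state table; the substrate for regression fixtures.
#'
#' @param model An `actinf_model`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to [sample_trial()].
#' @return Invisibly, the manifest path.
#' @export
write_fixture <- function(model, dir, seed = 1, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- sample_trial(model, seed = seed, ...)
  f1 <- file.path(dir, "fixture_states.csv")
  f2 <- file.path(dir, "fixture_outcomes.csv")
  readr::write_csv(sm$states, f1)
  readr::write_csv(sm$outcomes, f2)
  write_manifest(dir, "sample-fixtures", seed, list(), "fixture", c(f1, f2))
}

#' Export an iteration trace in long delimited-text format
#'
#' One row per iteration, policy (or model average, `policy = NA`), time
#' step and unit, with firing and depolarisation.
#'
#' @param trace An `actinf_trace` from [update_epoch()].
#' @param path Output csv path.
#' @param level Optional level label column.
#' @return The path, invisibly.
#' @export
export_trace <- function(trace, path, level = NA_integer_) {
  u <- trace$units
  u$ms <- (u$iteration - 1) * trace$ms_per_iteration
  u$level <- level
  readr::write_csv(u[, c("level", "unit", "factor", "policy", "tau",
                         "iteration", "ms", "firing", "depolarisation")],
                   path)
  invisible(path)
}
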