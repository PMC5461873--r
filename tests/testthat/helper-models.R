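# Shared fixtures: all built in code, nothing on disk.

# one factor, two states, single "stay" policy; the canonical exact-Bayes toy:
# A = [[.9, .2], [.1, .8]], D = (1/2, 1/2)
two_state_level <- function(horizon = 1L, C = NULL, n_iterations = 16L) {
  level_model(
    factors = c(state = 2L),
    modalities = c(obs = 2L),
    A = list(obs = array(c(0.9, 0.1, 0.2, 0.8), dim = c(2, 2))),
    B = list(state = array(diag(2), dim = c(2, 2, 1))),
    C = C,
    D = list(state = c(0.5, 0.5)),
    policies = list(cbind(1L)),
    horizon = horizon,
    n_iterations = n_iterations,
    name = "two-state toy")
}

# degenerate single-state model: every message is trivially delta
one_state_level <- function() {
  level_model(
    factors = c(state = 1L),
    modalities = c(obs = 1L),
    A = list(obs = array(1, dim = c(1, 1))),
    B = list(state = array(1, dim = c(1, 1, 1))),
    D = list(state = 1),
    policies = list(cbind(1L)),
    horizon = 2L,
    name = "degenerate")
}

# flat model: uniform A, B, D; beliefs should sit at the uniform fixed point
uniform_level <- function(n = 3L, n_out = 3L) {
  level_model(
    factors = c(state = n),
    modalities = c(obs = n_out),
    A = list(obs = array(1 / n_out, dim = c(n_out, n))),
    B = list(state = array(1 / n, dim = c(n, n, 1))),
    D = list(state = rep(1 / n, n)),
    policies = list(cbind(1L)),
    horizon = 2L,
    name = "uniform")
}

# two hidden states, a controllable "gaze" factor: looking at location 1
# reveals the hidden state, looking at location 2 reveals nothing
peek_level <- function(C_obs = numeric(3)) {
  A_obs <- array(0, dim = c(3, 2, 2))
  A_obs[1, 1, 1] <- 1 # looking: outcome mirrors the hidden state
  A_obs[2, 2, 1] <- 1
  A_obs[3, , 2] <- 1  # looking away: uninformative third outcome
  B_gaze <- array(0, dim = c(2, 2, 2))
  B_gaze[1, , 1] <- 1
  B_gaze[2, , 2] <- 1
  level_model(
    factors = c(hidden = 2L, gaze = 2L),
    modalities = c(obs = 3L),
    A = list(obs = A_obs),
    B = list(hidden = array(diag(2), dim = c(2, 2, 1)), gaze = B_gaze),
    C = list(obs = C_obs),
    D = list(hidden = c(0.5, 0.5), gaze = c(1, 0)),
    policies = list(cbind(1L, 1L), cbind(1L, 2L)),
    horizon = 2L,
    name = "peek")
}

# minimal trial-shaped object for exercising the readout functions without a
# full simulation: one level, one factor, explicit firing series per unit
synthetic_trial <- function(firing, ms_per_iteration = 16) {
  n_it <- nrow(firing)
  tr <- do.call(rbind, lapply(seq_len(ncol(firing)), function(u)
    tibble::tibble(level = 1L, block = 1L, iteration_global = seq_len(n_it),
                   ms = (seq_len(n_it) - 1) * ms_per_iteration,
                   factor = "unit", unit = u, firing = firing[, u])))
  structure(list(
    trace = tr,
    ms_per_iteration = ms_per_iteration,
    blocks = tibble::tibble(block = 1L, level = 1L, epoch_above = 1L,
                            step = 1L, it_start = 1L, it_end = n_it,
                            ms_start = 0, ms_end = n_it * ms_per_iteration)),
    class = "actinf_trial")
}

# The exemplar trial and the violation battery are the expensive fixtures;
# compute each once per test run and share across files.
.fixture_cache <- new.env(parent = emptyenv())

exemplar_result <- function() {
  if (is.null(.fixture_cache$exemplar))
    .fixture_cache$exemplar <- run_reading_experiment(reading_config(), seed = 1)
  .fixture_cache$exemplar
}

violation_result <- function() {
  if (is.null(.fixture_cache$violation))
    .fixture_cache$violation <- run_violation_experiment(reading_config(), seed = 1)
  .fixture_cache$violation
}

# small conveniences mirrored from the package internals for test fixtures
one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

validation_result <- function() {
  if (is.null(.fixture_cache$validation))
    .fixture_cache$validation <- validate_engine(n_models = 100, seed = 7)
  .fixture_cache$validation
}
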