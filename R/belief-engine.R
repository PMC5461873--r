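# Single-level variational belief updating and policy selection.
#
# Beliefs are policy-conditioned categorical expectations s[policy][time][factor]
# together with their log-domain auxiliary ("depolarisation") variables v, so
# that s = softmax(v) unit-group-wise. Updating is a damped gradient flow
# v <- v + kappa * eps driven by state prediction errors; policy expectations
# are a softmax of (expected) free energy recomputed on every iteration; the
# quantities exchanged between levels are Bayesian model averages.

#' Initialise a belief state for one level
#'
#' @param level An `actinf_level`.
#' @param priors Named list of categorical vectors, one per factor: the
#'   empirical priors over initial states (descended from the level above, or
#'   the level's own unconditional `D`). Missing factors default to their `D`.
#' @return An object of class `actinf_beliefs` spanning a single time step.
#' @export
init_beliefs <- function(level, priors = NULL) {
  fs <- level$factors
  full <- lapply(names(fs), function(n) {
    p <- priors[[n]] %||% resolve_D_prior(level, n, NULL)
    p / sum(p)
  })
  names(full) <- names(fs)
  n_pol <- length(level$policies)
  depth <- max(vapply(level$policies, nrow, 1L))
  slot <- lapply(full, identity)
  b <- structure(list(
    level = level,
    priors = full,
    n_pol = n_pol,
    depth = depth,
    t_obs = 0L,
    T_b = 1L,
    s = rep(list(list(slot)), n_pol),
    v = rep(list(list(lapply(slot, ln_safe))), n_pol),
    pi = rep(1 / n_pol, n_pol),
    F = numeric(n_pol),
    G = numeric(n_pol),
    observed = list(NULL),
    actions = matrix(integer(0), nrow = 0, ncol = length(fs),
                     dimnames = list(NULL, names(fs)))
  ), class = "actinf_beliefs")
  b
}

#' @export
print.actinf_beliefs <- function(x, ...) {
  cat(sprintf("<actinf_beliefs> %d policies, %d/%d time steps observed, %d factors\n",
              x$n_pol, x$t_obs, x$T_b, length(x$level$factors)))
  invisible(x)
}

# Outcomes may be integer indices (one-hot) or probability vectors (soft
# evidence passed up from a lower level).
as_outcome_vec <- function(o, n) {
  if (length(o) == 1L && is.numeric(o)) one_hot(as.integer(o), n) else {
    stopifnot(length(o) == n)
    o / sum(o)
  }
}

#' Register the outcomes observed at the next time step
#'
#' @param beliefs An `actinf_beliefs`.
#' @param t Time index being observed (must be `t_obs + 1`).
#' @param outcomes Named list over modalities: integer outcome indices or
#'   probability vectors (soft evidence). Missing modalities are unobserved.
#' @return Updated beliefs spanning predictions one policy-step ahead.
#' @export
set_observation <- function(beliefs, t, outcomes) {
  lvl <- beliefs$level
  stopifnot(t == beliefs$t_obs + 1L, t <= lvl$horizon)
  outcomes <- lapply(names(outcomes), function(m)
    as_outcome_vec(outcomes[[m]], lvl$modalities[[m]])) |>
    stats::setNames(names(outcomes))
  beliefs$observed[[t]] <- outcomes
  beliefs$t_obs <- t
  beliefs$T_b <- min(lvl$horizon, t + beliefs$depth)
  for (p in seq_len(beliefs$n_pol)) {
    while (length(beliefs$s[[p]]) < beliefs$T_b) {
      k <- length(beliefs$s[[p]])
      beliefs$s[[p]][[k + 1L]] <- beliefs$s[[p]][[k]]
      beliefs$v[[p]][[k + 1L]] <- beliefs$v[[p]][[k]]
    }
  }
  beliefs
}

#' Record the action actually executed after the current time step
#' @param beliefs An `actinf_beliefs`.
#' @param action Named integer vector of control values, one per factor.
#' @return Updated beliefs.
#' @export
record_action <- function(beliefs, action) {
  beliefs$actions <- rbind(beliefs$actions, action[colnames(beliefs$actions)])
  beliefs
}

# action in force between tau and tau+1, under policy p: executed history
# where available, the policy's own steps beyond it.
action_at <- function(beliefs, p, tau) {
  if (tau <= nrow(beliefs$actions)) return(beliefs$actions[tau, ])
  pol <- beliefs$level$policies[[p]]
  step <- tau - nrow(beliefs$actions)
  pol[min(step, nrow(pol)), ]
}

# Prior-predictive chain used to (re)set depolarisations at epoch onset:
# tau = 1 is the empirical prior, later slots roll forward through B.
reset_depolarisation <- function(beliefs) {
  lvl <- beliefs$level
  fs <- names(lvl$factors)
  for (p in seq_len(beliefs$n_pol)) {
    for (tau in seq_len(beliefs$T_b)) {
      if (tau == 1L) {
        pred <- beliefs$priors
      } else {
        a <- action_at(beliefs, p, tau - 1L)
        prev <- beliefs$s[[p]][[tau - 1L]]
        pred <- lapply(seq_along(fs), function(n)
          as.vector(lvl$B[[n]][, , a[[n]]] %*% prev[[n]]))
        names(pred) <- fs
      }
      beliefs$v[[p]][[tau]] <- lapply(pred, ln_safe)
      beliefs$s[[p]][[tau]] <- lapply(pred, function(x) x / sum(x))
    }
  }
  beliefs
}

#' State prediction errors for one policy and time
#'
#' The error for each factor is the sum of the log messages that predict its
#' state (a likelihood message from any outcome observed at `tau`, and the
#' forward message through `B` from the preceding state - or the empirical
#' prior at `tau = 1`) minus the current log expectation. Marginal messages
#' over the other factors use the generalised dot product. Message passing is
#' a forward (filtering) scheme: each time step's marginal accumulates all
#' evidence observed so far through the forward chain, and it is that
#' converged current-time marginal that is read out, averaged and exchanged
#' between levels.
#'
#' @param level An `actinf_level`.
#' @param beliefs An `actinf_beliefs`.
#' @param policy Policy index.
#' @param tau Time index (1-based, within the belief span).
#' @return Named list of per-factor error vectors (nats).
#' @export
state_prediction_error <- function(level, beliefs, policy, tau) {
  if (tau < 1L || tau > beliefs$T_b) stop("state_prediction_error: tau out of range")
  fs <- level$factors
  s_tau <- beliefs$s[[policy]][[tau]]
  o_tau <- if (tau <= beliefs$t_obs) beliefs$observed[[tau]] else NULL
  eps <- vector("list", length(fs))
  names(eps) <- names(fs)
  for (n in seq_along(fs)) {
    msg <- numeric(fs[[n]])
    if (!is.null(o_tau)) {
      for (m in names(o_tau)) {
        vecs <- c(list(o_tau[[m]]), s_tau)
        vecs[[1L + n]] <- NULL
        vecs <- append(vecs, list(NULL), after = n)
        msg <- msg + ln_safe(as.vector(tensor_contract(level$A[[m]], vecs)))
      }
    }
    if (tau == 1L) {
      msg <- msg + ln_safe(beliefs$priors[[n]])
    } else {
      a <- action_at(beliefs, policy, tau - 1L)
      msg <- msg + ln_safe(as.vector(level$B[[n]][, , a[[n]]] %*%
                                       beliefs$s[[policy]][[tau - 1L]][[n]]))
    }
    eps[[n]] <- msg - ln_safe(s_tau[[n]])
  }
  eps
}

# per-state-combination outcome entropy of each A (Table-style H), cached on
# the level object lazily
conditional_entropy <- function(level, m) {
  A <- level$A[[m]]
  d <- dim(A)
  h <- -apply(A, seq_along(d)[-1], function(col) sum(col * ln_safe(col)))
  array(h, dim = d[-1])
}

# multiply a transition matrix into one axis of a joint distribution
apply_axis <- function(q, M, axis) {
  d <- dim(q) %||% length(q)
  if (length(d) == 1L) return(as.vector(M %*% q))
  perm <- c(axis, seq_along(d)[-axis])
  qp <- aperm(q, perm)
  m <- M %*% matrix(qp, nrow = d[axis])
  qp <- array(m, dim = d[perm])
  aperm(qp, order(perm))
}

#' Exact joint predictive distribution over hidden states
#'
#' Forward-filters the joint distribution over all of the level's factors
#' through the executed actions and observed outcomes (soft outcomes enter by
#' expected likelihood), then rolls it forward under the policy's actions to
#' `tau`. Policy evaluation uses this exact predictive (the state spaces are
#' small), so that the informativeness of outcomes reflects the correlations
#' among factors that a product of mean-field marginals discards.
#'
#' @inheritParams state_prediction_error
#' @return Array over the factor state spaces summing to 1.
#' @export
exact_predictive <- function(level, beliefs, policy, tau) {
  fs <- level$factors
  q <- Reduce(`%o%`, beliefs$priors)
  q <- array(q, dim = unname(fs))
  step <- function(q, t) {
    a <- action_at(beliefs, policy, t)
    for (n in seq_along(fs)) q <- apply_axis(q, level$B[[n]][, , a[[n]]], n)
    q
  }
  t_like <- min(beliefs$t_obs, tau)
  for (t in seq_len(t_like)) {
    o_t <- beliefs$observed[[t]]
    for (m in names(o_t)) {
      L <- tensor_contract(level$A[[m]], c(list(o_t[[m]]),
                                           rep(list(NULL), length(fs))))
      q <- q * array(L, dim = unname(fs))
    }
    q <- q / sum(q)
    if (t < tau) q <- step(q, t)
  }
  if (t_like < tau - 1L) for (t in seq.int(t_like + 1L, tau - 1L)) q <- step(q, t)
  q / sum(q)
}

#' Outcome prediction errors for one policy and time
#'
#' For each modality the error vector is `ln o_pred - C` plus the expected
#' conditional outcome entropy (ambiguity) of that modality under the current
#' state beliefs, added as a constant so that the inner product of the error
#' with the predicted outcomes equals that modality's contribution to the
#' expected free energy G(policy, tau).
#'
#' @inheritParams state_prediction_error
#' @return Named list of per-modality error vectors (nats).
#' @export
outcome_prediction_error <- function(level, beliefs, policy, tau) {
  q <- exact_predictive(level, beliefs, policy, tau)
  out <- vector("list", length(level$modalities))
  names(out) <- names(level$modalities)
  for (m in names(level$modalities)) {
    o_pred <- project_joint(level$A[[m]], q)
    Hm <- conditional_entropy(level, m)
    amb <- sum(Hm * q)
    out[[m]] <- ln_safe(o_pred) - level$C[[m]] + amb
  }
  out
}

# project a joint state distribution through a likelihood array: A has the
# outcome axis first and one axis per factor, matching q's dimensions
project_joint <- function(A, q) {
  d <- dim(A) %||% length(A)
  m <- matrix(A, nrow = d[1])
  as.vector(m %*% as.vector(q))
}

#' Variational free energy of one policy
#'
#' The expected state prediction error under current beliefs, summed over the
#' observed time steps and factors: at the variational fixed point of a
#' single-policy, single-epoch model this equals the negative log evidence.
#'
#' @inheritParams state_prediction_error
#' @return F(policy) in nats.
#' @export
policy_free_energy <- function(level, beliefs, policy) {
  if (beliefs$t_obs == 0L) return(0)
  f <- 0
  for (tau in seq_len(beliefs$t_obs)) {
    eps <- state_prediction_error(level, beliefs, policy, tau)
    for (n in names(eps))
      f <- f - sum(beliefs$s[[policy]][[tau]][[n]] * eps[[n]])
  }
  f
}

#' Expected free energy of one policy, with its two decompositions
#'
#' G(policy) sums, over the predicted (not yet observed) time steps, the inner
#' product of the predicted outcomes with the outcome prediction errors; the
#' predictive distributions come from [exact_predictive()] so that factor
#' correlations established by past outcomes are respected. The report carries
#' both readings: risk (divergence of predicted outcomes from preferences)
#' plus ambiguity (expected conditional outcome entropy), and equivalently the
#' negative of epistemic value (mutual information between hidden states and
#' outcomes, always non-negative) plus pragmatic value (expected log
#' preference).
#'
#' @inheritParams state_prediction_error
#' @return List with `G` (nats) and a tibble `parts` (tau, risk, ambiguity,
#'   epistemic, pragmatic).
#' @export
expected_free_energy <- function(level, beliefs, policy) {
  taus <- if (beliefs$t_obs < beliefs$T_b)
    seq.int(beliefs$t_obs + 1L, beliefs$T_b) else integer(0)
  G <- 0
  rows <- vector("list", length(taus))
  for (k in seq_along(taus)) {
    tau <- taus[k]
    q <- exact_predictive(level, beliefs, policy, tau)
    risk <- amb <- epi <- prag <- 0
    for (m in names(level$modalities)) {
      o <- project_joint(level$A[[m]], q)
      Hm <- sum(conditional_entropy(level, m) * q)
      risk <- risk + sum(o * (ln_safe(o) - level$C[[m]]))
      amb <- amb + Hm
      epi <- epi + (-sum(o * ln_safe(o)) - Hm)
      prag <- prag + sum(o * level$C[[m]])
    }
    G <- G + risk + amb
    rows[[k]] <- tibble::tibble(tau = tau, risk = risk, ambiguity = amb,
                                epistemic = epi, pragmatic = prag)
  }
  list(G = G, parts = dplyr::bind_rows(rows))
}

#' Posterior expectations over policies
#'
#' @param F Per-policy variational free energies (nats).
#' @param G Per-policy expected free energies (nats).
#' @param use_F If `FALSE` (the default, appropriate when policies differ only
#'   in their next action so past evidence is common to all), the posterior is
#'   `softmax(-G)`; otherwise `softmax(-F - G)`.
#' @return Categorical vector over policies.
#' @export
policy_posterior <- function(F, G, use_F = FALSE) {
  stopifnot(all(is.finite(F)), all(is.finite(G)))
  softmax(if (use_F) -F - G else -G)
}

#' Bayesian model average of state expectations over policies
#'
#' @param beliefs An `actinf_beliefs`.
#' @param tau Optional single time index (`"current"` selects the latest
#'   observed step, whose marginal carries all accumulated evidence);
#'   default all.
#' @return For a single `tau`, a named list of per-factor categorical vectors;
#'   otherwise a list over time of such lists.
#' @export
bma_states <- function(beliefs, tau = NULL) {
  if (identical(tau, "current")) tau <- max(beliefs$t_obs, 1L)
  one <- function(t) {
    out <- lapply(names(beliefs$level$factors), function(n) {
      acc <- 0
      for (p in seq_len(beliefs$n_pol))
        acc <- acc + beliefs$pi[p] * beliefs$s[[p]][[t]][[n]]
      acc
    })
    names(out) <- names(beliefs$level$factors)
    out
  }
  if (!is.null(tau)) return(one(tau))
  lapply(seq_len(beliefs$T_b), one)
}

#' Select the action of the most probable policy
#'
#' Deterministic argmax over the policy posterior; exact ties resolve to the
#' lowest policy index. A categorical sampling mode is available for
#' exploratory use.
#'
#' @param beliefs An `actinf_beliefs`.
#' @param level An `actinf_level` (defaults to the beliefs' level).
#' @param mode `"argmax"` (default) or `"sample"`.
#' @return List with `policy` (index) and `action` (named integer vector, the
#'   first-step control value per factor).
#' @export
select_action <- function(beliefs, level = beliefs$level, mode = c("argmax", "sample")) {
  mode <- match.arg(mode)
  k <- if (mode == "argmax") argmax1(beliefs$pi) else sample_cat(beliefs$pi)
  act <- level$policies[[k]][1L, ]
  names(act) <- names(level$factors)
  list(policy = k, action = act)
}

#' Run one epoch of belief updating
#'
#' Iterates the gradient flow `v <- v + kappa * eps`, `s <- softmax(v)` over
#' every policy, modelled time step and factor, recomputing the policy
#' posterior and Bayesian model averages after every iteration, and returns
#' the updated beliefs together with an iteration-resolved trace. At the start
#' of an epoch depolarisations are reset to the (log) prior-predictive chain,
#' producing the characteristic epoch-onset transients.
#'
#' Prediction errors drive depolarisation through a saturating transduction
#' `cap * tanh(eps / cap)`: the transform is sign-preserving and linear near
#' zero, so every variational fixed point is untouched, but the drive per
#' iteration is bounded (as postsynaptic currents are), which makes evidence
#' accumulation against a violated prior measurably slower - the origin of the
#' protracted mismatch responses.
#'
#' @param level An `actinf_level`.
#' @param beliefs An `actinf_beliefs` (observations already registered).
#' @param n_iterations Number of iterations (default: the level's setting).
#' @param kappa Gradient step size (default 0.25).
#' @param err_sat Saturation bound on the prediction-error drive, in nats
#'   (default `Inf`, i.e. no saturation; finite values slow evidence
#'   accumulation against strong messages without moving any fixed point).
#' @param reset Reset depolarisations to the prior-predictive chain first.
#' @param use_F Include variational free energy in the policy posterior.
#' @param record_trace Collect the per-iteration trace (default TRUE).
#' @return List with elements `beliefs` and `trace` (an `actinf_trace`: tibbles
#'   `units` with per-policy and model-averaged firing/depolarisation,
#'   `pi` and `energies` per iteration).
#' @export
update_epoch <- function(level, beliefs, n_iterations = level$n_iterations,
                         kappa = 0.25, err_sat = Inf, reset = TRUE,
                         use_F = FALSE, record_trace = TRUE) {
  if (reset) beliefs <- reset_depolarisation(beliefs)
  fs <- level$factors
  P <- beliefs$n_pol
  Tb <- beliefs$T_b
  n_units <- sum(fs)
  unit_factor <- rep(names(fs), fs)
  unit_index <- unlist(lapply(fs, seq_len), use.names = FALSE)

  fire_cols <- vector("list", n_iterations)
  dep_cols <- vector("list", n_iterations)
  bma_cols <- vector("list", n_iterations)
  pi_rows <- matrix(NA_real_, n_iterations, P)
  F_rows <- matrix(NA_real_, n_iterations, P)
  G_rows <- matrix(NA_real_, n_iterations, P)

  # G depends on the executed history and predictive roll-out only, so it is
  # fixed within an epoch
  for (p in seq_len(P))
    beliefs$G[p] <- expected_free_energy(level, beliefs, p)$G

  for (it in seq_len(n_iterations)) {
    for (p in seq_len(P)) {
      for (tau in seq_len(Tb)) {
        eps <- state_prediction_error(level, beliefs, p, tau)
        for (n in names(fs)) {
          drive <- if (is.finite(err_sat))
            err_sat * tanh(eps[[n]] / err_sat) else eps[[n]]
          v <- beliefs$v[[p]][[tau]][[n]] + kappa * drive
          if (!all(is.finite(v)))
            stop(sprintf("numerical-divergence at iteration %d (policy %d, tau %d, factor %s)",
                         it, p, tau, n), call. = FALSE)
          beliefs$v[[p]][[tau]][[n]] <- v
          beliefs$s[[p]][[tau]][[n]] <- softmax(v)
        }
      }
      beliefs$F[p] <- policy_free_energy(level, beliefs, p)
    }
    beliefs$pi <- policy_posterior(beliefs$F, beliefs$G, use_F)
    pi_rows[it, ] <- beliefs$pi
    F_rows[it, ] <- beliefs$F
    G_rows[it, ] <- beliefs$G
    if (record_trace) {
      fire_cols[[it]] <- unlist(lapply(seq_len(P), function(p)
        unlist(lapply(seq_len(Tb), function(tau)
          unlist(beliefs$s[[p]][[tau]], use.names = FALSE)), use.names = FALSE)),
        use.names = FALSE)
      dep_cols[[it]] <- unlist(lapply(seq_len(P), function(p)
        unlist(lapply(seq_len(Tb), function(tau)
          unlist(beliefs$v[[p]][[tau]], use.names = FALSE)), use.names = FALSE)),
        use.names = FALSE)
      bma <- bma_states(beliefs)
      bma_cols[[it]] <- unlist(lapply(seq_len(Tb), function(tau)
        unlist(bma[[tau]], use.names = FALSE)), use.names = FALSE)
    }
  }

  trace <- NULL
  if (record_trace) {
    block <- P * Tb * n_units
    idx <- tibble::tibble(
      policy = rep(seq_len(P), each = Tb * n_units),
      tau = rep(rep(seq_len(Tb), each = n_units), times = P),
      factor = rep(unit_factor, times = P * Tb),
      unit = rep(unit_index, times = P * Tb))
    units <- tibble::tibble(
      iteration = rep(seq_len(n_iterations), each = block),
      policy = rep(idx$policy, n_iterations),
      tau = rep(idx$tau, n_iterations),
      factor = rep(idx$factor, n_iterations),
      unit = rep(idx$unit, n_iterations),
      firing = unlist(fire_cols, use.names = FALSE),
      depolarisation = unlist(dep_cols, use.names = FALSE))
    bma_idx <- tibble::tibble(
      tau = rep(seq_len(Tb), each = n_units),
      factor = rep(unit_factor, Tb),
      unit = rep(unit_index, Tb))
    bma_units <- tibble::tibble(
      iteration = rep(seq_len(n_iterations), each = Tb * n_units),
      policy = NA_integer_,
      tau = rep(bma_idx$tau, n_iterations),
      factor = rep(bma_idx$factor, n_iterations),
      unit = rep(bma_idx$unit, n_iterations),
      firing = unlist(bma_cols, use.names = FALSE),
      depolarisation = NA_real_)
    trace <- structure(list(
      units = dplyr::bind_rows(units, bma_units),
      pi = tibble::tibble(iteration = rep(seq_len(n_iterations), each = P),
                          policy = rep(seq_len(P), n_iterations),
                          prob = as.vector(t(pi_rows))),
      energies = tibble::tibble(iteration = rep(seq_len(n_iterations), each = P),
                                policy = rep(seq_len(P), n_iterations),
                                F = as.vector(t(F_rows)),
                                G = as.vector(t(G_rows))),
      n_iterations = n_iterations,
      tau_current = max(beliefs$t_obs, 1L),
      ms_per_iteration = level$ms_per_iteration),
      class = "actinf_trace")
  }
  list(beliefs = beliefs, trace = trace)
}
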