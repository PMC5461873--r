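# Asynchronous scheduling of belief updating across hierarchical levels:
# empirical priors descend, the lower level runs to termination while the
# higher level is suspended, posterior expectations ascend as probabilistic
# outcomes, and every 16-iteration epoch at either level advances the shared
# simulated clock by 256 ms.

#' Define a termination rule for a subordinate level
#'
#' A lower-level sequence of actions terminates once the Shannon entropy (in
#' nats) of the Bayesian-model-averaged posterior over the monitored factor
#' (the factor prescribed by the level above) falls to the threshold or below.
#'
#' @param threshold_nats Positive entropy threshold (default 1/512 nats).
#' @param target Name of the monitored factor.
#' @return An object of class `actinf_rule`.
#' @export
termination_rule <- function(threshold_nats = 1 / 512, target) {
  stopifnot(threshold_nats > 0)
  structure(list(threshold_nats = threshold_nats, target = target),
            class = "actinf_rule")
}

#' Check a termination rule against current beliefs
#'
#' @param beliefs An `actinf_beliefs`.
#' @param rule An [termination_rule()] object.
#' @return `TRUE` if the monitored factor's posterior entropy is at or below
#'   the threshold.
#' @export
check_termination <- function(beliefs, rule) {
  p <- bma_states(beliefs, tau = "current")[[rule$target]]
  entropy_nats(p) <= rule$threshold_nats
}

#' Descend empirical priors to the level below
#'
#' For every factor of the lower level whose `D` is conditioned on
#' higher-level factors, contracts the link table with the higher-level
#' Bayesian model averages (generalised dot product); unconditional factors
#' keep their own `D`.
#'
#' @param lower An `actinf_level` (the receiving level).
#' @param higher_bma Named list of categorical vectors over the higher level's
#'   factors.
#' @return Named list of per-factor categorical priors.
#' @export
descend_priors <- function(lower, higher_bma) {
  out <- lapply(names(lower$factors), function(n)
    resolve_D_prior(lower, n, higher_bma))
  names(out) <- names(lower$factors)
  for (n in names(out)) {
    if (any(out[[n]] < -1e-8) || abs(sum(out[[n]]) - 1) > 1e-6)
      stop(sprintf("descend_priors: invalid prior for factor %s", n))
    out[[n]] <- pmax(out[[n]], 0)
    out[[n]] <- out[[n]] / sum(out[[n]])
  }
  out
}

#' Ascend converged posterior expectations as a probabilistic outcome
#'
#' Returns the Bayesian-model-averaged posterior over the linked factor given
#' every outcome of the run (the factor is static within a run, so the
#' converged current-time marginal is the posterior over its initial state),
#' to be consumed by the higher level's likelihood message as a soft outcome.
#'
#' @param beliefs Converged `actinf_beliefs` of the lower level.
#' @param factor Name of the linked factor.
#' @return Categorical vector.
#' @export
ascend_evidence <- function(beliefs, factor) {
  p <- bma_states(beliefs, tau = "current")[[factor]]
  p / sum(p)
}

# Generative-process interface: holds true states and produces outcomes /
# executes transitions by sampling the model's own A and B columns.
make_process <- function(level, true_states) {
  env <- new.env(parent = emptyenv())
  env$states <- true_states
  env$observe <- function() {
    s1 <- lapply(names(level$factors), function(f)
      one_hot(env$states[[f]], level$factors[[f]]))
    out <- lapply(names(level$modalities), function(m)
      sample_cat(likelihood_project(level$A[[m]], s1)))
    names(out) <- names(level$modalities)
    out
  }
  env$act <- function(action) {
    for (n in names(level$factors)) {
      p <- level$B[[n]][, env$states[[n]], action[[n]]]
      env$states[[n]] <- sample_cat(p)
    }
    invisible(env$states)
  }
  env
}

# After executing an action, rewrite the one-step-ahead prediction slot of
# every policy with the executed action, so that descending priors and
# subsequent forward messages condition on what was actually done.
roll_forward <- function(beliefs, action) {
  lvl <- beliefs$level
  t1 <- beliefs$t_obs + 1L
  if (t1 > beliefs$T_b) return(beliefs)
  for (p in seq_len(beliefs$n_pol)) {
    prev <- beliefs$s[[p]][[beliefs$t_obs]]
    pred <- lapply(names(lvl$factors), function(n)
      as.vector(lvl$B[[n]][, , action[[n]]] %*% prev[[n]]))
    names(pred) <- names(lvl$factors)
    beliefs$s[[p]][[t1]] <- lapply(pred, function(x) x / sum(x))
    beliefs$v[[p]][[t1]] <- lapply(pred, ln_safe)
  }
  beliefs
}

#' Run one level to termination
#'
#' Loops over epochs: observe, update beliefs for one epoch, check the
#' termination rule, and otherwise select (or replay) an action, advance the
#' generative process, and continue, up to the level horizon. If the horizon
#' is exhausted without reaching the termination threshold the run is flagged
#' `undecided` (no error).
#'
#' @param level An `actinf_level`.
#' @param priors Named list of per-factor initial-state priors.
#' @param process A process interface as built internally from true states
#'   (`$observe()`, `$act(action)`, `$states`).
#' @param rule An [termination_rule()] or `NULL` (run the full horizon).
#' @param kappa,use_F,n_iterations Passed to [update_epoch()].
#' @param replay Optional list with `n_steps`, `policies` (integer vector) and
#'   `outcomes` (list per step): clamp actions and outcomes to a recorded run.
#' @param record_trace Collect iteration traces.
#' @return List with `beliefs`, `n_steps`, `policies`, `actions`, `outcomes`,
#'   `traces` (list of `actinf_trace`), and `undecided`.
#' @export
run_level <- function(level, priors, process, rule = NULL,
                      kappa = 0.25, use_F = FALSE,
                      n_iterations = level$n_iterations,
                      replay = NULL, record_trace = TRUE) {
  beliefs <- init_beliefs(level, priors)
  t <- 1L
  policies <- integer(0)
  actions <- list()
  outcomes <- list()
  traces <- list()
  undecided <- FALSE
  repeat {
    o <- if (!is.null(replay)) replay$outcomes[[t]] else process$observe()
    outcomes[[t]] <- o
    beliefs <- set_observation(beliefs, t, o)
    up <- update_epoch(level, beliefs, n_iterations = n_iterations,
                       kappa = kappa, use_F = use_F, record_trace = record_trace)
    beliefs <- up$beliefs
    traces[[t]] <- up$trace
    done <- if (!is.null(replay)) t >= replay$n_steps else
      (!is.null(rule) && check_termination(beliefs, rule))
    if (done) break
    if (t >= level$horizon) {
      undecided <- !is.null(rule)
      break
    }
    if (!is.null(replay)) {
      k <- replay$policies[t]
      act <- level$policies[[k]][1L, ]
      names(act) <- names(level$factors)
    } else {
      sel <- select_action(beliefs, level)
      k <- sel$policy
      act <- sel$action
    }
    policies[t] <- k
    actions[[t]] <- act
    beliefs <- record_action(beliefs, act)
    beliefs <- roll_forward(beliefs, act)
    if (is.null(replay)) process$act(act) else {
      for (n in names(level$factors)) {
        p <- level$B[[n]][, process$states[[n]], act[[n]]]
        process$states[[n]] <- sample_cat(p)
      }
    }
    t <- t + 1L
  }
  list(beliefs = beliefs, n_steps = t, policies = policies, actions = actions,
       outcomes = outcomes, traces = traces, undecided = undecided)
}

resolve_true_states <- function(model, i, higher_true, overrides) {
  lvl <- model$levels[[i]]
  s <- integer(length(lvl$factors))
  names(s) <- names(lvl$factors)
  hb <- NULL
  if (!is.null(higher_true)) {
    hfs <- model$levels[[i + 1]]$factors
    hb <- lapply(names(hfs), function(f) one_hot(higher_true[[f]], hfs[[f]]))
    names(hb) <- names(hfs)
  }
  for (n in names(lvl$factors)) {
    if (!is.null(overrides) && n %in% names(overrides)) {
      s[n] <- as.integer(overrides[[n]])
    } else {
      s[n] <- sample_cat(resolve_D_prior(lvl, n, hb))
    }
  }
  s
}

#' Simulate a full trial of a two-level deep temporal model
#'
#' Runs the asynchronous deep loop: at every top-level epoch, empirical priors
#' descend to the level below (while the gate factor is in its sampling
#' state), the lower level runs to its termination threshold, its posterior
#' ascends as a probabilistic outcome, the top level updates for one epoch and
#' selects the next action. Iteration traces from both levels are concatenated
#' on one global millisecond clock (levels never update simultaneously).
#'
#' @param model A two-level `actinf_model`.
#' @param stimuli List: `top` named integer vector fixing top-level true
#'   states (missing factors are sampled from `D`), and optionally `lower`, a
#'   list indexed by top-level epoch of named integer overrides for lower
#'   free factors (e.g. spatial flips). Non-overridden lower factors are
#'   sampled from their links/priors.
#' @param rule Termination rule for the lower level.
#' @param seed Integer seed (all sampling is reproducible given it).
#' @param kappa Gradient step size for belief updating.
#' @param use_F Include variational free energy in policy posteriors.
#' @param replay Optional `actinf_trial`: clamp all actions, outcomes and
#'   scheduling to a previously recorded trial (beliefs are recomputed under
#'   `model`, which may carry different priors).
#' @param record_trace Collect iteration-resolved traces (default TRUE).
#' @return An object of class `actinf_trial`; see [tidy.actinf_trial()] and
#'   [glance.actinf_trial()].
#' @export
run_trial <- function(model, stimuli = list(), rule = NULL, seed = 1,
                      kappa = 0.25, use_F = FALSE, replay = NULL,
                      record_trace = TRUE) {
  stopifnot(length(model$levels) == 2L)
  with_seed(seed, {
    top <- model$levels[[2]]
    low <- model$levels[[1]]
    link <- model$links[[1]]
    gate <- model$gates[[1]] %||% NULL

    true_top <- resolve_true_states(model, 2L, NULL, stimuli$top)
    tb <- init_beliefs(top)

    blocks <- list(); trace_rows <- list(); energy_rows <- list()
    it_global <- 0L
    block_id <- 0L
    add_block <- function(level_id, epoch_above, step, trace) {
      block_id <<- block_id + 1L
      n_it <- trace$n_iterations
      blocks[[block_id]] <<- tibble::tibble(
        block = block_id, level = level_id, epoch_above = epoch_above,
        step = step, it_start = it_global + 1L, it_end = it_global + n_it,
        ms_start = it_global * trace$ms_per_iteration,
        ms_end = (it_global + n_it) * trace$ms_per_iteration)
      u <- trace$units
      u <- u[is.na(u$policy) & u$tau == trace$tau_current,
             c("iteration", "factor", "unit", "firing")]
      u$iteration_global <- it_global + u$iteration
      u$ms <- (u$iteration_global - 1L) * trace$ms_per_iteration
      u$level <- level_id
      u$block <- block_id
      trace_rows[[block_id]] <<- u
      e <- trace$energies
      e$iteration_global <- it_global + e$iteration
      e$level <- level_id
      e$block <- block_id
      energy_rows[[block_id]] <<- e
      it_global <<- it_global + n_it
    }

    lower_runs <- vector("list", top$horizon)
    top_outcomes <- vector("list", top$horizon)
    top_policies <- integer(0)
    true_top_log <- list()
    last_evidence <- NULL

    for (t2 in seq_len(top$horizon)) {
      true_top_log[[t2]] <- tibble::tibble(
        level = 2L, epoch_above = NA_integer_, step = t2,
        factor = names(true_top), state = unname(true_top))
      o_top <- list()
      gate_open <- is.null(gate) || true_top[[gate$factor]] == gate$state
      run_now <- if (!is.null(replay)) !is.null(replay$lower_runs[[t2]]) else gate_open
      if (run_now) {
        bma_now <- bma_states(tb, tau = min(t2, tb$T_b))
        priors_low <- descend_priors(low, bma_now)
        over <- if (!is.null(replay)) replay$lower_runs[[t2]]$true_states else
          stimuli$lower[[t2]] %||% NULL
        true_low <- resolve_true_states(model, 1L, true_top, over)
        proc <- make_process(low, true_low)
        rep_low <- if (!is.null(replay)) {
          lr0 <- replay$lower_runs[[t2]]
          list(n_steps = lr0$n_steps, policies = lr0$policies, outcomes = lr0$outcomes)
        } else NULL
        lr <- run_level(low, priors_low, proc, rule, kappa = kappa,
                        use_F = use_F, replay = rep_low,
                        record_trace = record_trace)
        if (record_trace)
          for (st in seq_along(lr$traces)) add_block(1L, t2, st, lr$traces[[st]])
        last_evidence <- ascend_evidence(lr$beliefs, link$factor)
        lower_runs[[t2]] <- list(
          epoch_above = t2, n_steps = lr$n_steps, policies = lr$policies,
          actions = lr$actions, outcomes = lr$outcomes,
          true_states = true_low, undecided = lr$undecided,
          priors = priors_low, evidence = last_evidence,
          bma_final = bma_states(lr$beliefs, tau = "current"))
      }
      # the linked modality is observed only when the level below actually ran
      # this epoch; afterwards (e.g. once a decision is made) it is simply
      # unobserved and its likelihood message is omitted
      if (run_now) o_top[[link$modality]] <- last_evidence
      s1 <- lapply(names(top$factors), function(f)
        one_hot(true_top[[f]], top$factors[[f]]))
      for (m in setdiff(names(top$modalities), link$modality))
        o_top[[m]] <- sample_cat(likelihood_project(top$A[[m]], s1))
      top_outcomes[[t2]] <- o_top

      tb <- set_observation(tb, t2, o_top)
      up <- update_epoch(top, tb, kappa = kappa, use_F = use_F,
                         record_trace = record_trace)
      tb <- up$beliefs
      if (record_trace) add_block(2L, NA_integer_, t2, up$trace)

      if (t2 < top$horizon) {
        if (!is.null(replay)) {
          k <- replay$top_policies[t2]
          act <- top$policies[[k]][1L, ]
          names(act) <- names(top$factors)
        } else {
          sel <- select_action(tb, top)
          k <- sel$policy
          act <- sel$action
        }
        top_policies[t2] <- k
        tb <- record_action(tb, act)
        tb <- roll_forward(tb, act)
        for (n in names(top$factors)) {
          p <- top$B[[n]][, true_top[[n]], act[[n]]]
          true_top[[n]] <- sample_cat(p)
        }
      }
    }

    n_lower_epochs <- sum(vapply(lower_runs, function(x)
      if (is.null(x)) 0L else x$n_steps, 1L))
    structure(list(
      model = model, rule = rule, seed = seed, kappa = kappa, use_F = use_F,
      replayed = !is.null(replay),
      blocks = dplyr::bind_rows(blocks),
      trace = if (record_trace) dplyr::bind_rows(trace_rows) else NULL,
      energies = if (record_trace) dplyr::bind_rows(energy_rows) else NULL,
      lower_runs = lower_runs,
      top_outcomes = top_outcomes,
      top_policies = top_policies,
      true_top = dplyr::bind_rows(true_top_log),
      beliefs_top = tb,
      n_epochs_top = top$horizon,
      n_epochs_lower = n_lower_epochs,
      total_ms = it_global * top$ms_per_iteration,
      ms_per_iteration = top$ms_per_iteration
    ), class = "actinf_trial")
  })
}

#' Replay a recorded trial under a (possibly modified) model
#'
#' Re-runs belief updating with exactly the stimuli, actions and scheduling of
#' a recorded trial, but under the supplied model (e.g. with violated priors),
#' so that condition differences reflect beliefs alone.
#'
#' @param model An `actinf_model` (same structure as the recorded trial's).
#' @param record An `actinf_trial` from [run_trial()].
#' @param ... Passed to [run_trial()].
#' @return An `actinf_trial`.
#' @export
replay_trial <- function(model, record, ...) {
  top_true1 <- record$true_top[record$true_top$step == 1L, ]
  top_fix <- stats::setNames(top_true1$state, top_true1$factor)
  run_trial(model, stimuli = list(top = top_fix), rule = record$rule,
            seed = record$seed, kappa = record$kappa, use_F = record$use_F,
            replay = record, ...)
}

#' @export
print.actinf_trial <- function(x, ...) {
  cat(sprintf("<actinf_trial> %d top epochs + %d lower epochs = %.0f ms simulated%s\n",
              x$n_epochs_top, x$n_epochs_lower, x$total_ms,
              if (x$replayed) " (replayed)" else ""))
  invisible(x)
}
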