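#' Normalise the columns of a non-negative tensor to categorical distributions
#'
#' A "column" is the slice along the first axis at a fixed combination of the
#' remaining indices, i.e. the outcome (or next-state) distribution for one
#' state combination. Each column is rescaled to sum to one.
#'
#' @param x A non-negative numeric vector, matrix or array. The first axis
#'   indexes the support of each distribution.
#' @return An object with the same dimensions whose columns each sum to 1.
#' @examples
#' normalize_columns(matrix(c(2, 2, 1, 3), nrow = 2))
#' @export
normalize_columns <- function(x) {
  if (any(x < 0)) stop("normalize_columns: negative entries", call. = FALSE)
  d <- dim(x) %||% length(x)
  m <- matrix(as.vector(x), nrow = d[1])
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    stop(sprintf("degenerate-column: all-zero column(s) at flat index %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- sweep(m, 2, tot, "/")
  out <- if (length(d) > 1L) array(as.vector(m), dim = d) else as.vector(m)
  dimnames(out) <- dimnames(x)
  out
}

is_categorical <- function(p, tol = 1e-8) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

#' Project state beliefs through a likelihood array
#'
#' Computes the predictive outcome distribution `o = A (x) s_1 (x) ... (x) s_N`
#' (a generalised dot product over every hidden factor).
#'
#' @param A Likelihood array: first axis outcomes, one further axis per factor.
#' @param state_beliefs List of categorical vectors, one per factor, in the
#'   order of `A`'s factor axes.
#' @return Categorical vector over outcomes.
#' @export
likelihood_project <- function(A, state_beliefs) {
  d <- dim(A) %||% length(A)
  if (length(state_beliefs) != length(d) - 1L)
    stop("likelihood_project: need one belief vector per factor axis", call. = FALSE)
  sizes <- vapply(state_beliefs, length, 1L)
  if (!all(sizes == d[-1]))
    stop("likelihood_project: belief dimensions do not match A", call. = FALSE)
  o <- tensor_contract(A, c(list(NULL), state_beliefs))
  as.vector(o)
}

#' Place ones at specified hidden-state/outcome combinations
#'
#' Builds a dense likelihood (or transition) tensor from a sparse description:
#' a one at each listed index combination, zeros elsewhere. Interactions among
#' hidden factors are therefore encoded directly.
#'
#' @param dims Integer vector of tensor dimensions (outcome axis first).
#' @param at Integer matrix, one row per non-zero entry, `length(dims)` columns.
#' @param values Values to place (default 1).
#' @return Array of dimension `dims`.
#' @export
sparse_ones <- function(dims, at, values = 1) {
  x <- array(0, dim = dims)
  at <- matrix(as.integer(at), ncol = length(dims))
  x[at] <- values
  x
}

#' Specify one level of a hierarchical generative model
#'
#' A level is defined by hidden-state factors, outcome modalities, and the
#' usual four parameter sets: likelihoods `A` (one per modality), transition
#' arrays `B` (one per factor, third axis = action), log prior preferences `C`
#' (one per modality, in nats), and initial-state priors/links `D` (one per
#' factor; a link is a table conditioned on named factors of the level above).
#'
#' @param factors Named integer vector of hidden-state space sizes.
#' @param modalities Named integer vector of outcome space sizes.
#' @param A Named list of likelihood arrays, `dim = c(modality, factors...)`.
#' @param B Named list of transition arrays, `dim = c(n, n, n_actions)`;
#'   columns map the current state to a distribution over the next state.
#' @param C Named list of numeric log-preference vectors (default all zero).
#' @param D Named list; each element either a categorical vector (unconditional
#'   prior) or a list `list(parents = <higher factor names>, table = <array>)`
#'   with `dim = c(n, parent sizes...)`.
#' @param policies List of integer matrices (steps x factors): the action each
#'   policy applies to each factor at each future step. One-step policies are
#'   single-row matrices.
#' @param horizon Maximum number of time steps (epochs) at this level.
#' @param n_iterations Belief-update iterations per time step (default 16).
#' @param ms_per_iteration Simulated milliseconds per iteration (default 16,
#'   so one epoch spans 256 ms).
#' @param name Optional level label.
#' @return An object of class `actinf_level`.
#' @export
level_model <- function(factors, modalities, A, B, C = NULL, D, policies,
                        horizon, n_iterations = 16, ms_per_iteration = 16,
                        name = "level") {
  if (is.null(C)) C <- lapply(modalities, function(n) numeric(n))
  D <- lapply(D, function(d) {
    if (is.list(d)) d else list(parents = character(0), table = as.vector(d))
  })
  policies <- lapply(policies, function(p) {
    p <- rbind(p)
    storage.mode(p) <- "integer"
    p
  })
  lvl <- structure(
    list(factors = factors, modalities = modalities, A = A, B = B, C = C,
         D = D, policies = policies, horizon = as.integer(horizon),
         n_iterations = as.integer(n_iterations),
         ms_per_iteration = ms_per_iteration, name = name),
    class = "actinf_level")
  lvl
}

#' Assemble levels into a deep (hierarchical) generative model
#'
#' Levels are ordered lowest first. Each non-top level is linked to the level
#' above in two ways: the conditioned `D` tables of its factors (their
#' `parents` name higher-level factors), and one designated pair
#' (`factor`, `modality`): after the lower level terminates, the posterior
#' over that factor at its initial time ascends as a probabilistic outcome of
#' the named higher-level modality.
#'
#' @param levels List of [level_model()] objects, lowest level first.
#' @param links List (one element per non-top level) of
#'   `list(factor =, modality =)` character pairs.
#' @param gates Optional list (one per non-top level) of
#'   `list(factor =, state =)`: the level below only runs while the named
#'   higher-level factor is in the given true state (e.g. "undecided").
#' @return An object of class `actinf_model`.
#' @export
deep_model <- function(levels, links, gates = NULL) {
  structure(list(levels = levels, links = links, gates = gates),
            class = "actinf_model")
}

#' @export
print.actinf_level <- function(x, ...) {
  cat(sprintf("<actinf_level '%s'> %d factor(s) [%s], %d modalit%s [%s], %d policies, horizon %d\n",
              x$name, length(x$factors),
              paste(names(x$factors), x$factors, sep = "=", collapse = ", "),
              length(x$modalities), if (length(x$modalities) == 1) "y" else "ies",
              paste(names(x$modalities), x$modalities, sep = "=", collapse = ", "),
              length(x$policies), x$horizon))
  invisible(x)
}

#' @export
print.actinf_model <- function(x, ...) {
  cat(sprintf("<actinf_model> %d levels (lowest first)\n", length(x$levels)))
  for (l in x$levels) print(l)
  invisible(x)
}

check_cat_columns <- function(tab, path, report, tol = 1e-8) {
  d <- dim(tab) %||% length(tab)
  m <- matrix(as.vector(tab), nrow = d[1])
  bad_sum <- which(abs(colSums(m) - 1) > tol)
  if (length(bad_sum))
    report[[length(report) + 1]] <- sprintf(
      "%s: column(s) %s do not sum to 1", path, paste(bad_sum, collapse = ","))
  if (any(m < 0))
    report[[length(report) + 1]] <- sprintf("%s: negative entries", path)
  report
}

#' Validate a hierarchical model against its structural invariants
#'
#' Checks every categorical-column invariant of the A/B/D arrays, counts
#' (one B and D per factor, one A and C per modality), tensor ranks, policy
#' action ranges, and the dimensional consistency of between-level links.
#'
#' @param model An `actinf_model` or a single `actinf_level`.
#' @return A tibble with columns `path` and `message`; zero rows means valid.
#' @export
validate_model <- function(model) {
  if (inherits(model, "actinf_level")) {
    model <- deep_model(list(model), links = list())
  }
  report <- list()
  n_levels <- length(model$levels)
  for (i in seq_len(n_levels)) {
    lvl <- model$levels[[i]]
    fs <- lvl$factors
    ms <- lvl$modalities
    pre <- sprintf("level %d", i)
    if (length(lvl$A) != length(ms))
      report[[length(report) + 1]] <- sprintf("%s: %d A arrays for %d modalities", pre, length(lvl$A), length(ms))
    if (length(lvl$C) != length(ms))
      report[[length(report) + 1]] <- sprintf("%s: %d C vectors for %d modalities", pre, length(lvl$C), length(ms))
    if (length(lvl$B) != length(fs))
      report[[length(report) + 1]] <- sprintf("%s: %d B arrays for %d factors", pre, length(lvl$B), length(fs))
    for (n in names(fs)) {
      if (!n %in% names(lvl$D)) {
        report[[length(report) + 1]] <- sprintf("%s: missing D for factor %s", pre, n)
      }
    }
    for (m in seq_along(lvl$A)) {
      a <- lvl$A[[m]]
      path <- sprintf("%s A[%s]", pre, names(lvl$A)[m] %||% m)
      d <- dim(a) %||% length(a)
      if (length(d) != 1L + length(fs)) {
        report[[length(report) + 1]] <- sprintf("%s: rank %d, expected %d", path, length(d), 1L + length(fs))
      } else if (d[1] != ms[[m]] || !all(d[-1] == unname(fs))) {
        report[[length(report) + 1]] <- sprintf("%s: dimensions do not match modality/factor sizes", path)
      } else {
        report <- check_cat_columns(a, path, report)
      }
    }
    for (n in seq_along(lvl$B)) {
      b <- lvl$B[[n]]
      path <- sprintf("%s B[%s]", pre, names(lvl$B)[n] %||% n)
      d <- dim(b)
      if (is.null(d) || length(d) != 3L || d[1] != d[2] || d[1] != fs[[n]]) {
        report[[length(report) + 1]] <- sprintf("%s: expected square %dx%d per-action matrices", path, fs[[n]], fs[[n]])
      } else {
        for (u in seq_len(d[3])) {
          sums <- colSums(b[, , u, drop = FALSE][, , 1])
          bad <- which(abs(sums - 1) > 1e-8)
          if (length(bad))
            report[[length(report) + 1]] <- sprintf(
              "%s action %d: column(s) %s do not sum to 1", path, u, paste(bad, collapse = ","))
        }
      }
    }
    for (m in seq_along(lvl$C)) {
      if (!all(is.finite(lvl$C[[m]])))
        report[[length(report) + 1]] <- sprintf("%s C[%s]: non-finite entries", pre, names(lvl$C)[m] %||% m)
    }
    for (n in names(lvl$D)) {
      d_ent <- lvl$D[[n]]
      path <- sprintf("%s D[%s]", pre, n)
      if (!n %in% names(fs)) {
        report[[length(report) + 1]] <- sprintf("%s: D for unknown factor", path)
        next
      }
      tab <- d_ent$table
      dd <- dim(tab) %||% length(tab)
      if (dd[1] != fs[[n]]) {
        report[[length(report) + 1]] <- sprintf("%s: first axis %d, expected %d", path, dd[1], fs[[n]])
      } else {
        report <- check_cat_columns(tab, path, report)
      }
      if (length(d_ent$parents)) {
        if (i == n_levels) {
          report[[length(report) + 1]] <- sprintf("%s: top level D cannot be conditioned", path)
        } else {
          hfs <- model$levels[[i + 1]]$factors
          if (!all(d_ent$parents %in% names(hfs))) {
            report[[length(report) + 1]] <- sprintf("%s: unknown parent factor(s)", path)
          } else if (length(dd) != 1L + length(d_ent$parents) ||
                     !all(dd[-1] == unname(hfs[d_ent$parents]))) {
            report[[length(report) + 1]] <- sprintf("%s: link dimensions do not match parent factors", path)
          }
        }
      }
    }
    for (k in seq_along(lvl$policies)) {
      p <- lvl$policies[[k]]
      if (ncol(p) != length(fs)) {
        report[[length(report) + 1]] <- sprintf("%s policy %d: %d action columns for %d factors", pre, k, ncol(p), length(fs))
        next
      }
      if (nrow(p) > lvl$horizon)
        report[[length(report) + 1]] <- sprintf("%s policy %d: longer than horizon", pre, k)
      for (n in seq_along(fs)) {
        n_act <- dim(lvl$B[[n]])[3]
        if (!is.null(n_act) && any(p[, n] < 1 | p[, n] > n_act))
          report[[length(report) + 1]] <- sprintf(
            "%s policy %d: action out of range for factor %s", pre, k, names(fs)[n])
      }
    }
    if (i < n_levels) {
      link <- model$links[[i]]
      upper <- model$levels[[i + 1]]
      if (is.null(link) || !link$factor %in% names(fs) ||
          !link$modality %in% names(upper$modalities)) {
        report[[length(report) + 1]] <- sprintf("%s: invalid link specification", pre)
      } else if (fs[[link$factor]] != upper$modalities[[link$modality]]) {
        report[[length(report) + 1]] <- sprintf(
          "%s: linked factor size %d != higher modality size %d",
          pre, fs[[link$factor]], upper$modalities[[link$modality]])
      }
    }
  }
  tibble::tibble(path = vapply(report, function(x) sub(":.*$", "", x), ""),
                 message = unlist(report) %||% character(0))
}

sample_cat <- function(p) sample.int(length(p), 1L, prob = p)

resolve_D_prior <- function(lvl, name, higher_beliefs = NULL) {
  d <- lvl$D[[name]]
  if (!length(d$parents)) return(as.vector(d$table))
  vecs <- c(list(NULL), higher_beliefs[d$parents])
  as.vector(tensor_contract(d$table, vecs))
}

#' Forward-sample states and outcomes from the generative process
#'
#' Runs the model in the generative direction: top-level initial states are
#' drawn from `D` (or fixed), states evolve under the supplied action
#' sequences, outcomes are drawn from `A` columns, and each lower level is
#' re-initialised from its `D` links for every higher-level epoch (one full
#' lower sequence per higher transition).
#'
#' @param model An `actinf_model`.
#' @param true_states Optional named integer vector fixing top-level initial
#'   states; also accepts a list with one named vector per level fixing
#'   non-linked lower factors (recycled across higher epochs) via elements
#'   named after levels' positions.
#' @param actions Optional list (one per level) of integer matrices
#'   (steps-1 x factors); defaults to action 1 for every factor.
#' @param horizons Optional integer vector of steps per level (default: the
#'   level horizons).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A list with tibbles `states` (level, epoch_above, time, factor,
#'   state) and `outcomes` (level, epoch_above, time, modality, outcome).
#' @export
sample_trial <- function(model, true_states = NULL, actions = NULL,
                         horizons = NULL, seed = 1) {
  with_seed(seed, {
    n_levels <- length(model$levels)
    if (is.null(horizons))
      horizons <- vapply(model$levels, function(l) l$horizon, 1L)
    fixed_top <- if (is.list(true_states)) true_states$top else true_states
    fixed_lower <- if (is.list(true_states)) true_states$lower else NULL
    st_rows <- list(); oc_rows <- list()

    sample_level <- function(i, higher_state, epoch_above) {
      lvl <- model$levels[[i]]
      fs <- lvl$factors
      Tn <- horizons[i]
      act <- if (!is.null(actions) && !is.null(actions[[i]])) actions[[i]] else
        matrix(1L, nrow = max(Tn - 1L, 0L), ncol = length(fs))
      s <- integer(length(fs)); names(s) <- names(fs)
      for (n in names(fs)) {
        if (i == n_levels && !is.null(fixed_top) && n %in% names(fixed_top)) {
          s[n] <- fixed_top[[n]]
        } else if (i < n_levels && !is.null(fixed_lower) && n %in% names(fixed_lower)) {
          s[n] <- fixed_lower[[n]]
        } else {
          hb <- NULL
          if (length(lvl$D[[n]]$parents)) {
            if (is.null(higher_state)) stop("sample_trial: conditioned D at top level")
            hb <- lapply(names(higher_state), function(f)
              one_hot(higher_state[[f]], model$levels[[i + 1]]$factors[[f]]))
            names(hb) <- names(higher_state)
          }
          p <- resolve_D_prior(lvl, n, hb)
          if (any(p < 0) || abs(sum(p) - 1) > 1e-6) stop("sample_trial: invalid D prior")
          s[n] <- sample_cat(p)
        }
      }
      for (t in seq_len(Tn)) {
        for (n in names(fs)) {
          st_rows[[length(st_rows) + 1]] <<- tibble::tibble(
            level = i, epoch_above = epoch_above, time = t, factor = n, state = unname(s[n]))
        }
        for (m in names(lvl$modalities)) {
          col <- tensor_contract(lvl$A[[m]], c(list(NULL), lapply(names(fs), function(f)
            one_hot(s[[f]], fs[[f]]))))
          o <- sample_cat(as.vector(col))
          oc_rows[[length(oc_rows) + 1]] <<- tibble::tibble(
            level = i, epoch_above = epoch_above, time = t, modality = m, outcome = o)
        }
        if (i > 1L) sample_level(i - 1L, as.list(s), epoch_above = t)
        if (t < Tn) {
          for (n in seq_along(fs)) {
            u <- act[min(t, nrow(act)), n]
            p <- model$levels[[i]]$B[[n]][, s[[n]], u]
            s[[n]] <- sample_cat(p)
          }
        }
      }
    }
    sample_level(n_levels, NULL, epoch_above = NA_integer_)
    list(states = dplyr::bind_rows(st_rows), outcomes = dplyr::bind_rows(oc_rows))
  })
}
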