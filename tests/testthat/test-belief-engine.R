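test_that("degenerate single-state models produce zero errors and zero F", {
  lvl <- one_state_level()
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 1L))
  eps <- state_prediction_error(lvl, b, 1, 1)
  expect_equal(eps$state, 0, tolerance = 1e-6)
  expect_equal(policy_free_energy(lvl, b, 1), 0, tolerance = 1e-6)
})

test_that("uniform models sit at a zero-error fixed point", {
  lvl <- uniform_level()
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 2L))
  eps <- state_prediction_error(lvl, b, 1, 1)
  # all messages are uniform: the error is constant across states (the
  # component the softmax can see is zero) and beliefs do not move
  expect_equal(max(eps$state) - min(eps$state), 0, tolerance = 1e-10)
  up <- update_epoch(lvl, b)
  expect_equal(bma_states(up$beliefs, 1)$state, rep(1 / 3, 3),
               tolerance = 1e-10)
})

test_that("the converged posterior matches exact Bayes on the two-state toy", {
  lvl <- two_state_level()
  exact <- c(0.45, 0.10) / 0.55 # D * A[1, ] renormalised
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 1L))
  up16 <- update_epoch(lvl, b, n_iterations = 16)
  expect_lt(max(abs(bma_states(up16$beliefs, 1)$state - exact)), 1e-2)
  up128 <- update_epoch(lvl, b, n_iterations = 128)
  expect_equal(bma_states(up128$beliefs, 1)$state, exact, tolerance = 1e-4)
  # at convergence -F is the log evidence p(o) = 0.55
  expect_equal(policy_free_energy(lvl, up128$beliefs, 1), -log(0.55),
               tolerance = 1e-4)
})

test_that("F is zero when beliefs equal the prior and nothing is observed", {
  lvl <- two_state_level()
  b <- init_beliefs(lvl)
  expect_equal(policy_free_energy(lvl, b, 1), 0)
})

test_that("outcome prediction errors reduce to ln o_pred for flat preferences", {
  lvl <- level_model(
    factors = c(state = 2L), modalities = c(obs = 2L),
    A = list(obs = array(diag(2), dim = c(2, 2))),
    B = list(state = array(diag(2), dim = c(2, 2, 1))),
    D = list(state = c(0.3, 0.7)),
    policies = list(cbind(1L)), horizon = 2L)
  b <- init_beliefs(lvl)
  eps <- outcome_prediction_error(lvl, b, 1, 1)
  # deterministic A: zero ambiguity, so the error is the log expected outcome
  expect_equal(eps$obs, log(c(0.3, 0.7)), tolerance = 1e-6)
})

test_that("expected free energy matches the hand-computed 2 - ln 2 example", {
  # predicted outcomes (1/2, 1/2) under a deterministic likelihood with
  # C = (0, -4): G = sum o (ln o - C) = 2 - ln 2
  lvl <- level_model(
    factors = c(state = 2L), modalities = c(obs = 2L),
    A = list(obs = array(diag(2), dim = c(2, 2))),
    B = list(state = array(diag(2), dim = c(2, 2, 1))),
    C = list(obs = c(0, -4)),
    D = list(state = c(0.5, 0.5)),
    policies = list(cbind(1L)), horizon = 2L)
  b <- init_beliefs(lvl)
  g <- expected_free_energy(lvl, b, 1)
  expect_equal(g$G, 2 - log(2), tolerance = 1e-4)
  # decomposition identity: risk + ambiguity = -(epistemic + pragmatic)
  expect_equal(g$parts$risk + g$parts$ambiguity,
               -(g$parts$epistemic + g$parts$pragmatic), tolerance = 1e-6)
})

test_that("a perfectly observed, indifferent world has G = 0 for all policies", {
  lvl <- peek_level()
  lvl$D$hidden$table <- c(1, 0) # no residual uncertainty
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 1L))
  up <- update_epoch(lvl, b)
  expect_equal(up$beliefs$G, c(0, 0), tolerance = 1e-5)
})

test_that("an informative policy has strictly lower G than an uninformative one", {
  lvl <- peek_level()
  lvl$D$gaze$table <- c(0, 1) # start looking away
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 3L)) # looked away: learned nothing
  up <- update_epoch(lvl, b)
  G <- up$beliefs$G
  expect_lt(G[1], G[2]) # policy 1 peeks at the revealing location
})

test_that("policy posteriors are a softmax of negative (expected) free energy", {
  expect_equal(policy_posterior(c(0, 0), c(1, 1)), c(0.5, 0.5))
  expect_equal(policy_posterior(c(0, 0), c(0, log(2))), c(2 / 3, 1 / 3))
  expect_equal(policy_posterior(0, 0), 1)
  # use_F folds the variational term in
  expect_equal(policy_posterior(c(0, log(2)), c(0, 0), use_F = TRUE),
               c(2 / 3, 1 / 3))
})

test_that("bma_states averages policy-conditioned beliefs", {
  lvl <- peek_level()
  b <- init_beliefs(lvl)
  b$pi <- c(0.5, 0.5)
  b$s[[1]][[1]]$hidden <- c(1, 0)
  b$s[[2]][[1]]$hidden <- c(0, 1)
  expect_equal(bma_states(b, 1)$hidden, c(0.5, 0.5))
  # random 3-policy mixture against a direct weighted sum
  set.seed(3)
  lvl3 <- peek_level()
  lvl3$policies <- list(cbind(1L, 1L), cbind(1L, 2L), cbind(1L, 1L))
  b3 <- init_beliefs(lvl3)
  w <- runif(3); b3$pi <- w / sum(w)
  for (p in 1:3) {
    x <- runif(2)
    b3$s[[p]][[1]]$hidden <- x / sum(x)
  }
  direct <- Reduce(`+`, lapply(1:3, function(p)
    b3$pi[p] * b3$s[[p]][[1]]$hidden))
  expect_equal(bma_states(b3, 1)$hidden, direct)
})

test_that("select_action takes the most probable policy, ties to lowest index", {
  lvl <- peek_level()
  b <- init_beliefs(lvl)
  b$pi <- c(0.9, 0.1)
  expect_equal(select_action(b, lvl)$policy, 1L)
  b$pi <- c(0.5, 0.5)
  expect_equal(select_action(b, lvl)$policy, 1L)
  b$pi <- c(0.1, 0.9)
  sel <- select_action(b, lvl)
  expect_equal(sel$policy, 2L)
  expect_equal(unname(sel$action[["gaze"]]), 2L)
})

test_that("exact_predictive respects factor correlations that marginals lose", {
  lvl <- peek_level()
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 1L)) # reveals hidden state 1
  q <- exact_predictive(lvl, b, 1, 1)
  expect_equal(sum(q), 1, tolerance = 1e-10)
  expect_equal(q[2, 1], 0, tolerance = 1e-6) # hidden state 2 excluded
  expect_equal(q[1, 1], 1, tolerance = 1e-6)
})

test_that("saturating transduction changes the path but not the fixed point", {
  lvl <- two_state_level()
  exact <- c(0.45, 0.10) / 0.55
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 1L))
  sat <- update_epoch(lvl, b, n_iterations = 256, err_sat = 2)
  expect_equal(bma_states(sat$beliefs, 1)$state, exact, tolerance = 1e-4)
  # with the bound active, early iterations move more slowly
  sat16 <- update_epoch(lvl, b, n_iterations = 2, err_sat = 0.05)
  free16 <- update_epoch(lvl, b, n_iterations = 2)
  gap <- function(up) abs(bma_states(up$beliefs, 1)$state[1] - 0.5)
  expect_lt(gap(sat16), gap(free16))
})

test_that("free energy descends, epistemic value is non-negative and the two
           G decompositions agree on random micro-models", {
  v <- validate_engine(n_models = 25, seed = 42)
  s <- glance(v)
  expect_lt(s$max_abs_err, 1e-2)
  expect_identical(s$n_descent_violations, 0L)
  expect_gte(s$min_epistemic, -1e-8)
  expect_lt(s$max_decomposition_gap, 1e-6)
})

test_that("an absurd gradient step is caught by the descent audit", {
  v <- validate_engine(n_models = 10, seed = 42, kappa = 10)
  expect_gt(glance(v)$n_descent_violations, 0L)
})

test_that("every s, pi and BMA stays categorical across an epoch", {
  set.seed(5)
  lvl <- peek_level()
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 1L))
  up <- update_epoch(lvl, b)
  tr <- up$trace
  pi_by_it <- tapply(tr$pi$prob, tr$pi$iteration, sum)
  expect_equal(unname(as.numeric(pi_by_it)), rep(1, 16), tolerance = 1e-10)
  u <- tr$units[!is.na(tr$units$policy), ]
  sums <- stats::aggregate(firing ~ iteration + policy + tau + factor,
                           data = u, FUN = sum)
  expect_equal(sums$firing, rep(1, nrow(sums)), tolerance = 1e-8)
})

test_that("iteration traces have one entry per iteration and unit", {
  lvl <- two_state_level()
  b <- init_beliefs(lvl)
  b <- set_observation(b, 1L, list(obs = 1L))
  up <- update_epoch(lvl, b, n_iterations = 16)
  u <- up$trace$units
  per_policy <- u[!is.na(u$policy), ]
  expect_identical(nrow(per_policy), 16L * 1L * up$beliefs$T_b * 2L)
  expect_true(all(is.finite(per_policy$depolarisation)))
})
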