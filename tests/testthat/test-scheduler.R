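test_that("check_termination compares posterior entropy to the threshold", {
  lvl <- level_model(
    factors = c(word = 3L), modalities = c(obs = 3L),
    A = list(obs = array(diag(3), dim = c(3, 3))),
    B = list(word = array(diag(3), dim = c(3, 3, 1))),
    D = list(word = rep(1 / 3, 3)),
    policies = list(cbind(1L)), horizon = 2L)
  b <- init_beliefs(lvl)
  rule <- termination_rule(1 / 512, target = "word")
  # delta posterior terminates for any positive threshold
  b$s[[1]][[1]]$word <- c(1, 0, 0)
  expect_true(check_termination(b, rule))
  # uniform over 3 words: entropy ln 3 >> 1/512
  b$s[[1]][[1]]$word <- rep(1 / 3, 3)
  expect_false(check_termination(b, rule))
  # (0.999, 0.001, 0): entropy ~ 0.0079 nats, below a 0.01 threshold
  b$s[[1]][[1]]$word <- c(0.999, 0.001, 0)
  expect_false(check_termination(b, rule))
  expect_true(check_termination(b, termination_rule(0.01, target = "word")))
  expect_error(termination_rule(0, "word"))
})

test_that("descend_priors contracts link tables with higher-level averages", {
  m <- build_reading_model(reading_config())
  low <- m$levels[[1]]
  # delta higher beliefs pick out the corresponding D column
  hb <- list(sentence = one_hot(1, 6), position = one_hot(3, 4),
             decision = one_hot(1, 3))
  pr <- descend_priors(low, hb)
  expect_equal(pr$word, one_hot(2, 3)) # sentence 1, word 3 is feed
  # uniform sentences at position 1: support only on flee and wait
  hb$sentence <- rep(1 / 6, 6)
  hb$position <- one_hot(1, 4)
  pr1 <- descend_priors(low, hb)
  expect_equal(pr1$word[2], 0) # no sentence starts with feed
  expect_gt(pr1$word[1], 0)
  expect_gt(pr1$word[3], 0)
  # random beliefs against the direct weighted sum on the vflip link
  set.seed(9)
  w <- runif(4); w <- w / sum(w)
  hb$position <- w
  pr2 <- descend_priors(low, hb)
  expect_equal(pr2$vflip, as.vector(low$D$vflip$table %*% w))
})

test_that("ascend_evidence returns the linked factor's averaged posterior", {
  lvl <- level_model(
    factors = c(word = 3L), modalities = c(obs = 3L),
    A = list(obs = array(diag(3), dim = c(3, 3))),
    B = list(word = array(diag(3), dim = c(3, 3, 1))),
    D = list(word = rep(1 / 3, 3)),
    policies = list(cbind(1L)), horizon = 2L)
  b <- init_beliefs(lvl)
  b$s[[1]][[1]]$word <- c(1, 0, 0)
  expect_equal(ascend_evidence(b, "word"), c(1, 0, 0))
  b$s[[1]][[1]]$word <- rep(1 / 3, 3)
  expect_equal(ascend_evidence(b, "word"), rep(1 / 3, 3))
})

test_that("run_level stops immediately once the posterior is sharp", {
  lvl <- level_model(
    factors = c(word = 2L), modalities = c(obs = 2L),
    A = list(obs = array(diag(2), dim = c(2, 2))),
    B = list(word = array(diag(2), dim = c(2, 2, 1))),
    D = list(word = c(0.5, 0.5)),
    policies = list(cbind(1L)), horizon = 4L)
  proc <- deepactive:::make_process(lvl, c(word = 1L))
  res <- withr::with_seed(1, run_level(lvl, list(word = c(0.5, 0.5)), proc,
                                      termination_rule(1 / 512, "word")))
  expect_identical(res$n_steps, 1L)
  expect_false(res$undecided)
  expect_equal(ascend_evidence(res$beliefs, "word"), c(1, 0),
               tolerance = 1e-4)
})

test_that("run_level flags horizon exhaustion without termination", {
  # uninformative outcomes: uncertainty never drops, no exception raised
  lvl <- level_model(
    factors = c(word = 2L), modalities = c(obs = 2L),
    A = list(obs = array(0.5, dim = c(2, 2))),
    B = list(word = array(diag(2), dim = c(2, 2, 1))),
    D = list(word = c(0.5, 0.5)),
    policies = list(cbind(1L)), horizon = 3L)
  proc <- deepactive:::make_process(lvl, c(word = 1L))
  res <- withr::with_seed(1, run_level(lvl, list(word = c(0.5, 0.5)), proc,
                                      termination_rule(1 / 512, "word")))
  expect_identical(res$n_steps, 3L)
  expect_true(res$undecided)
})

test_that("the exemplar trial reproduces the reported reading behaviour", {
  s <- exemplar_result()$summary
  expect_identical(
    c(s$saccades_word1, s$saccades_word2, s$saccades_word3, s$saccades_word4),
    c(1L, 2L, 2L, 2L))
  expect_identical(s$decision, "happy")
  expect_identical(s$feedback, "right")
  expect_false(s$undecided)
  # word 1 resolves in one fixation; word 2 needs a second saccade
  runs <- exemplar_result()$trial$lower_runs
  expect_identical(runs[[1]]$n_steps, 1L)
  expect_identical(runs[[2]]$n_steps, 2L)
})

test_that("an infinite threshold collapses every word to a single fixation", {
  cfg <- reading_config()
  res <- run_reading_experiment(cfg, seed = 1, threshold_nats = 1e6)
  s <- res$summary
  expect_identical(
    c(s$saccades_word1, s$saccades_word2, s$saccades_word3, s$saccades_word4),
    c(1L, 1L, 1L, 1L))
})

test_that("trials are deterministic given the seed", {
  cfg <- reading_config()
  t1 <- run_reading_experiment(cfg, seed = 3)$trial
  t2 <- run_reading_experiment(cfg, seed = 3)$trial
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$top_policies, t2$top_policies)
  expect_identical(t1$total_ms, t2$total_ms)
})

test_that("scheduling is literally asynchronous on one global clock", {
  trial <- exemplar_result()$trial
  b <- trial$blocks
  # blocks tile the timeline without overlap, in 256 ms epochs
  expect_equal(b$ms_start, c(0, head(b$ms_end, -1)))
  expect_equal(b$ms_end - b$ms_start, rep(256, nrow(b)))
  # no level-2 iteration falls inside a level-1 epoch's span and vice versa
  tr <- trial$trace
  for (i in seq_len(nrow(b))) {
    inside <- tr$ms >= b$ms_start[i] & tr$ms < b$ms_end[i]
    expect_true(all(tr$level[inside] == b$level[i]))
  }
  # global timestamps advance strictly in ms_per_iteration steps
  ms <- sort(unique(tr$ms))
  expect_equal(diff(ms), rep(16, length(ms) - 1))
})

test_that("messages crossing level interfaces are categorical", {
  trial <- exemplar_result()$trial
  for (r in trial$lower_runs) {
    if (is.null(r)) next
    for (p in r$priors) {
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-8)
    }
    expect_equal(sum(r$evidence), 1, tolerance = 1e-8)
    expect_true(all(r$evidence >= 0))
  }
})

test_that("replaying a trial under the unmodified model reproduces it", {
  cfg <- reading_config()
  std <- exemplar_result()$trial
  rep <- replay_trial(build_reading_model(cfg), std)
  expect_equal(rep$trace$firing, std$trace$firing, tolerance = 1e-10)
  expect_identical(rep$total_ms, std$total_ms)
})

test_that("unflipped sampled trials are reported correctly whenever feedback
           is right", {
  cfg <- reading_config()
  model <- build_reading_model(cfg)
  rule <- termination_rule(cfg$threshold_nats, "word")
  for (sent in c(2L, 4L, 6L)) {
    st <- reading_stimuli(cfg, sentence = sent, vflip = rep(1L, 4L),
                          hflip = c(1L, 2L, 1L, 2L))
    tr <- run_trial(model, stimuli = st, rule = rule, seed = 20 + sent)
    sm <- reading_summary(tr)
    post <- bma_states(tr$beliefs_top, tau = "current")$sentence
    if (sm$feedback == "right") {
      expect_identical(which.max(post), as.integer(sent))
      expect_gt(max(post), 0.9)
    }
    # the model never reports while uncertain about the category
    if (sm$decision != "undecided") expect_identical(sm$feedback, "right")
  }
})
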