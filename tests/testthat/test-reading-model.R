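test_that("word layouts obey the letter-placement rules", {
  # flee: cat in quadrant 1, bird in quadrant 2, rest empty
  expect_equal(word_layout("flee"), c("cat", "bird", "null", "null"))
  # wait: bird and seed on a diagonal; vertical flip leaves 1 and 4 empty
  w <- word_layout("wait")
  expect_setequal(which(w != "null"), c(1, 4))
  wv <- word_layout("wait", vflip = TRUE)
  expect_equal(wv[c(1, 4)], c("null", "null"))
  # vertical flip swaps rows
  expect_equal(word_layout("flee", vflip = TRUE),
               word_layout("flee")[c(3, 4, 1, 2)])
  # horizontal flip swaps columns
  expect_equal(word_layout("feed", hflip = TRUE),
               word_layout("feed")[c(2, 1, 4, 3)])
  expect_error(word_layout("sing"), "unknown word")
})

test_that("every layout is letter-identifiable", {
  combos <- expand.grid(word = c("flee", "feed", "wait"),
                        v = c(FALSE, TRUE), h = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  seen <- character(0)
  for (i in seq_len(nrow(combos))) {
    lay <- word_layout(combos$word[i], combos$v[i], combos$h[i])
    expect_identical(sum(lay == "bird"), 1L)
    if (combos$word[i] == "flee") {
      expect_identical(sum(lay == "cat"), 1L)
      expect_identical(sum(lay == "seed"), 0L)
    } else {
      expect_identical(sum(lay == "seed"), 1L)
      expect_identical(sum(lay == "cat"), 0L)
    }
    # horizontal flips preserve the multiset of row-wise letter pairs
    hlay <- word_layout(combos$word[i], combos$v[i], !combos$h[i])
    rows <- function(x) sort(c(paste(sort(x[1:2]), collapse = "|"),
                               paste(sort(x[3:4]), collapse = "|")))
    expect_identical(rows(lay), rows(hlay))
    seen <- c(seen, paste(lay, collapse = "-"))
  }
  # all twelve (word, flips) scenes are distinct, so four fixations always
  # disambiguate them
  expect_identical(anyDuplicated(seen), 0L)
})

test_that("reading_config derives the happy set and enforces the inventory", {
  cfg <- reading_config()
  expect_length(cfg$sentences, 6)
  expect_identical(cfg$sentences[[1]], c("flee", "wait", "feed", "wait"))
  expect_true(1L %in% cfg$happy_set)
  expect_length(cfg$happy_set, 3)
  for (i in seq_along(cfg$sentences)) {
    s <- cfg$sentences[[i]]
    expect_true(s[1] %in% c("flee", "wait"))
    expect_true(s[2] %in% c("flee", "wait"))
    happy <- !"flee" %in% s[3:4]
    expect_identical(i %in% cfg$happy_set, happy)
  }
  expect_error(reading_config(sentences = c(list(c("feed", "wait", "feed", "wait")),
                                            reading_config()$sentences[-1])),
               "flee or wait")
})

test_that("the built model is valid and encodes the stated preferences", {
  cfg <- reading_config()
  m <- build_reading_model(cfg)
  expect_identical(nrow(validate_model(m)), 0L)
  C_fb <- m$levels[[2]]$C$feedback
  # wrong is at least exp(4) ~ 54 times less probable a priori than neutral
  expect_gte(exp(C_fb[1] - C_fb[3]), 54)
  # word likelihood matches the sentence inventory
  A_word <- m$levels[[2]]$A$word
  for (s in 1:6) for (p in 1:4) {
    w <- match(cfg$sentences[[s]][p], c("flee", "feed", "wait"))
    expect_equal(A_word[, s, p, 1], one_hot(w, 3))
  }
  # level-1 priors: gaze starts at quadrant 1, strong belief in no vflip
  expect_equal(m$levels[[1]]$D$where$table, one_hot(1, 4))
  expect_equal(m$levels[[1]]$D$vflip$table[, 1], c(7, 1) / 8)
})

test_that("violations edit exactly the stated priors", {
  cfg <- reading_config()
  m <- build_reading_model(cfg)
  loc <- apply_violation(m, "local", cfg)
  expect_equal(loc$levels[[1]]$D$vflip$table[, 1:3],
               m$levels[[1]]$D$vflip$table[, 1:3])
  expect_equal(loc$levels[[1]]$D$vflip$table[, 4], c(1, 7) / 8)
  expect_identical(loc$levels[[2]]$D$sentence, m$levels[[2]]$D$sentence)

  glo <- apply_violation(m, "global", cfg)
  expect_equal(glo$levels[[2]]$D$sentence$table[1], (1 / 8) / (1 / 8 + 5))
  expect_equal(sum(glo$levels[[2]]$D$sentence$table), 1)
  expect_identical(glo$levels[[1]]$D$vflip, m$levels[[1]]$D$vflip)

  both <- apply_violation(m, "both", cfg)
  expect_equal(both$levels[[1]]$D$vflip$table[, 4], c(1, 7) / 8)
  expect_equal(both$levels[[2]]$D$sentence$table[1], (1 / 8) / (1 / 8 + 5))

  expect_identical(apply_violation(m, "none", cfg), m)
  expect_error(apply_violation(m, "sideways", cfg))
})

test_that("the model supports the printed perceptual deductions", {
  cfg <- reading_config()
  m <- build_reading_model(cfg)
  lvl <- m$levels[[1]]
  priors <- list(word = c(4, 0, 2) / 6, where = one_hot(1, 4),
                 vflip = c(7, 1) / 8, hflip = c(1, 1) / 2)
  # seeing a cat in quadrant 1 implies flee
  b <- init_beliefs(lvl, priors)
  b <- set_observation(b, 1L, list(letter = 2L, eye = 1L))
  up <- update_epoch(lvl, b)
  expect_gt(bma_states(up$beliefs, "current")$word[1], 0.99)
  # two empty quadrants on the {1,4} diagonal imply wait under the
  # sentence-constrained prior: a fact of the model posterior, checked on the
  # exact joint (the engine itself prefers the discriminating quadrant 2)
  b2 <- init_beliefs(lvl, priors)
  b2 <- set_observation(b2, 1L, list(letter = 4L, eye = 1L))
  b2 <- record_action(b2, c(word = 1L, where = 4L, vflip = 1L, hflip = 1L))
  b2 <- set_observation(b2, 2L, list(letter = 4L, eye = 4L))
  q <- exact_predictive(lvl, b2, 1, 2)
  word_marg <- apply(q, 1, sum)
  expect_gt(word_marg[3] / sum(word_marg), 0.99)
})

test_that("exemplar stimuli flip exactly the designated word", {
  cfg <- reading_config()
  st <- reading_stimuli(cfg)
  expect_identical(st$top[["sentence"]], 1L)
  vflips <- vapply(st$lower, function(x) x[["vflip"]], 1L)
  expect_identical(vflips, c(1L, 2L, 1L, 1L))
  # sampled stimuli are reproducible
  s1 <- reading_stimuli(cfg, sample = TRUE, seed = 5)
  s2 <- reading_stimuli(cfg, sample = TRUE, seed = 5)
  expect_identical(s1, s2)
})

test_that("the saccade log matches the exemplar narrative", {
  sc <- exemplar_result()$saccades
  expect_identical(nrow(sc), 7L)
  # first fixation of the trial sees the cat in quadrant 1
  expect_identical(sc$letter[sc$word_position == 1], "cat")
  # word 2 (vertically flipped wait) shows nothing on the first fixation
  w2 <- sc[sc$word_position == 2, ]
  expect_identical(w2$letter[1], "null")
  expect_identical(w2$quadrant[1], 1L)
})
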