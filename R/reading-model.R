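# The two-level reading model: six candidate sentences of four words generate
# words (flee / feed / wait), each word is a 2x2 scene of letters (bird, cat,
# seed or nothing) subject to vertical/horizontal spatial flips, and letters
# are sampled by saccades to quadrants. The subject's task is to categorise
# the sentence as a happy or sad narrative and report it for feedback.

READING_WORDS <- c("flee", "feed", "wait")
READING_LETTERS <- c("bird", "cat", "seed", "null")
READING_DECISIONS <- c("undecided", "happy", "sad")
READING_FEEDBACK <- c("nothing", "right", "wrong")

# Canonical (no-flip) quadrant contents; quadrant order is upper-left,
# upper-right, lower-left, lower-right. flee: cat next to bird in a row;
# feed: bird next to seed in a row; wait: bird and seed in diagonal quadrants
# (so the vertically flipped form leaves quadrants 1 and 4 empty).
CANONICAL_LAYOUTS <- list(
  flee = c("cat", "bird", "null", "null"),
  feed = c("bird", "seed", "null", "null"),
  wait = c("bird", "null", "null", "seed")
)

#' Quadrant contents of a word under spatial flips
#'
#' @param word One of `"flee"`, `"feed"`, `"wait"`.
#' @param vflip,hflip Logical: swap rows / columns of the 2x2 scene.
#' @return Character vector of length 4 over
#'   `c("bird", "cat", "seed", "null")`, quadrant order upper-left,
#'   upper-right, lower-left, lower-right.
#' @examples
#' word_layout("flee")            # cat, bird in the upper row
#' word_layout("wait", vflip = TRUE)  # occupied {2,3} diagonal; 1 and 4 empty
#' @export
word_layout <- function(word, vflip = FALSE, hflip = FALSE) {
  if (!word %in% READING_WORDS) stop("unknown word: ", word, call. = FALSE)
  lay <- CANONICAL_LAYOUTS[[word]]
  if (isTRUE(vflip)) lay <- lay[c(3L, 4L, 1L, 2L)]
  if (isTRUE(hflip)) lay <- lay[c(2L, 1L, 4L, 3L)]
  lay
}

sentence_category <- function(words) {
  if (any(utils::tail(words, 2L) == "flee")) "sad" else "happy"
}

#' Configuration of the reading model
#'
#' Defaults reproduce the study conditions: six four-word sentences (all
#' beginning, and continuing at the second word, with flee or wait; sentence 1
#' is flee-wait-feed-wait), happy narratives are those without a flee in the
#' final two words, "wrong" feedback carries a -4 nat prior preference (about
#' 54 times less likely than neutral), a strong prior that text is not
#' vertically flipped (lower case), an uninformative prior over horizontal
#' flips, 16 belief-update iterations of 16 ms per epoch, and a 1/512 nat
#' termination threshold on word uncertainty.
#'
#' @param sentences List of six character vectors of four words each.
#' @param wrong_log_pref Log preference (nats) for "wrong" feedback.
#' @param right_log_pref Log preference (nats) for "right" feedback: the
#'   instruction to confirm a decision once confident.
#' @param vflip_prior,hflip_prior Length-2 categorical priors (no, yes).
#' @param violation One of `"none"`, `"local"`, `"global"`, `"both"`.
#' @param global_factor Factor by which a global violation deflates the prior
#'   probability of sentence 1.
#' @param exemplar_sentence,exemplar_vflip_word The exemplar trial: which
#'   sentence is shown and which single word is vertically flipped (upper
#'   case).
#' @param threshold_nats Termination threshold on word-posterior entropy.
#' @param kappa Belief-update gradient step size.
#' @param n_iterations,ms_per_iteration Temporal granularity of updating.
#' @param band_hz Band edges (Hz) for simulated local field potentials.
#' @return An object of class `reading_config`.
#' @export
reading_config <- function(sentences = list(
                             c("flee", "wait", "feed", "wait"),
                             c("wait", "flee", "flee", "feed"),
                             c("wait", "wait", "feed", "feed"),
                             c("flee", "wait", "feed", "flee"),
                             c("flee", "wait", "wait", "flee"),
                             c("flee", "flee", "wait", "wait")),
                           wrong_log_pref = -4,
                           right_log_pref = 1,
                           vflip_prior = c(7, 1) / 8,
                           hflip_prior = c(1, 1) / 2,
                           violation = c("none", "local", "global", "both"),
                           global_factor = 8,
                           exemplar_sentence = 1L,
                           exemplar_vflip_word = 2L,
                           threshold_nats = 1 / 512,
                           kappa = 0.25,
                           n_iterations = 16L,
                           ms_per_iteration = 16,
                           band_hz = c(4, 32)) {
  violation <- match.arg(violation)
  stopifnot(length(sentences) == 6L,
            all(vapply(sentences, length, 1L) == 4L),
            all(unlist(sentences) %in% READING_WORDS))
  if (!all(vapply(sentences, function(s) s[1] %in% c("flee", "wait"), TRUE)))
    stop("every sentence must begin with flee or wait", call. = FALSE)
  if (!identical(sentences[[1]], c("flee", "wait", "feed", "wait")))
    stop("sentence 1 must be flee, wait, feed, wait", call. = FALSE)
  happy_set <- which(vapply(sentences, sentence_category, "") == "happy")
  structure(list(
    sentences = sentences, happy_set = happy_set,
    wrong_log_pref = wrong_log_pref, right_log_pref = right_log_pref,
    vflip_prior = vflip_prior / sum(vflip_prior),
    hflip_prior = hflip_prior / sum(hflip_prior),
    violation = violation, global_factor = global_factor,
    exemplar_sentence = as.integer(exemplar_sentence),
    exemplar_vflip_word = as.integer(exemplar_vflip_word),
    threshold_nats = threshold_nats, kappa = kappa,
    n_iterations = as.integer(n_iterations),
    ms_per_iteration = ms_per_iteration, band_hz = band_hz
  ), class = "reading_config")
}

#' @export
print.reading_config <- function(x, ...) {
  cat("<reading_config>\n")
  for (i in seq_along(x$sentences))
    cat(sprintf("  sentence %d: %s (%s)\n", i,
                paste(x$sentences[[i]], collapse = ", "),
                if (i %in% x$happy_set) "happy" else "sad"))
  cat(sprintf("  C: wrong %+g, right %+g nats; P(no vflip) = %.3f; violation = %s\n",
              x$wrong_log_pref, x$right_log_pref, x$vflip_prior[1], x$violation))
  invisible(x)
}

#' Build the two-level reading model
#'
#' Level 2 (narrative) factors: sentence (6), word position (4), decision
#' (undecided/happy/sad); modalities: the word passed up from the level below,
#' word-location proprioception, and feedback. Level 1 (lexical) factors:
#' word, letter location, vertical and horizontal flip; modalities: letter
#' and letter-location proprioception. Likelihoods encode the hidden-state
#' interactions by placing ones at the consistent state combinations.
#'
#' @param config A [reading_config()].
#' @return An `actinf_model` (passes [validate_model()]).
#' @export
build_reading_model <- function(config = reading_config()) {
  nW <- 3L; nQ <- 4L; nS <- 6L; nP <- 4L; nD <- 3L; nL <- 4L

  ## --- level 1: lexical -------------------------------------------------
  A_letter <- array(0, dim = c(nL, nW, nQ, 2L, 2L))
  A_eye <- array(0, dim = c(nQ, nW, nQ, 2L, 2L))
  for (w in seq_len(nW)) for (v in 1:2) for (h in 1:2) {
    lay <- word_layout(READING_WORDS[w], v == 2L, h == 2L)
    for (q in seq_len(nQ)) {
      A_letter[match(lay[q], READING_LETTERS), w, q, v, h] <- 1
      A_eye[q, w, q, v, h] <- 1
    }
  }
  B_where <- array(0, dim = c(nQ, nQ, nQ))
  for (u in seq_len(nQ)) B_where[u, , u] <- 1
  ident <- function(n) array(diag(n), dim = c(n, n, 1L))

  D_word <- array(0, dim = c(nW, nS, nP))
  for (s in seq_len(nS)) for (p in seq_len(nP))
    D_word[match(config$sentences[[s]][p], READING_WORDS), s, p] <- 1
  D_vflip <- matrix(rep(config$vflip_prior, nP), nrow = 2L,
                    dimnames = NULL)

  level1 <- level_model(
    factors = c(word = nW, where = nQ, vflip = 2L, hflip = 2L),
    modalities = c(letter = nL, eye = nQ),
    A = list(letter = A_letter, eye = A_eye),
    B = list(word = ident(nW), where = B_where,
             vflip = ident(2L), hflip = ident(2L)),
    C = list(letter = numeric(nL), eye = numeric(nQ)),
    D = list(word = list(parents = c("sentence", "position"), table = D_word),
             where = one_hot(1L, nQ),
             vflip = list(parents = "position", table = D_vflip),
             hflip = config$hflip_prior),
    policies = lapply(seq_len(nQ), function(u) cbind(1L, u, 1L, 1L)),
    horizon = 4L,
    n_iterations = config$n_iterations,
    ms_per_iteration = config$ms_per_iteration,
    name = "lexical")

  ## --- level 2: narrative ----------------------------------------------
  A_word <- array(0, dim = c(nW, nS, nP, nD))
  A_head <- array(0, dim = c(nP, nS, nP, nD))
  A_fb <- array(0, dim = c(3L, nS, nP, nD))
  for (s in seq_len(nS)) for (p in seq_len(nP)) {
    w <- match(config$sentences[[s]][p], READING_WORDS)
    happy <- s %in% config$happy_set
    for (d in seq_len(nD)) {
      A_word[w, s, p, d] <- 1
      A_head[p, s, p, d] <- 1
      A_fb[, s, p, d] <- switch(d,
        one_hot(1L, 3L),
        if (happy) one_hot(2L, 3L) else one_hot(3L, 3L),
        if (happy) one_hot(3L, 3L) else one_hot(2L, 3L))
    }
  }
  B_pos <- array(0, dim = c(nP, nP, 3L))
  for (p in seq_len(nP)) {
    B_pos[min(p + 1L, nP), p, 1L] <- 1   # continue reading: advance
    B_pos[p, p, 2L] <- 1                 # reporting: stay
    B_pos[p, p, 3L] <- 1
  }
  B_dec <- array(0, dim = c(nD, nD, 3L))
  for (u in 1:3) {
    B_dec[, 1L, u] <- one_hot(u, nD)     # from undecided: act selects state
    B_dec[2L, 2L, u] <- 1                # happy / sad are absorbing
    B_dec[3L, 3L, u] <- 1
  }
  C_fb <- c(0, config$right_log_pref, config$wrong_log_pref)

  level2 <- level_model(
    factors = c(sentence = nS, position = nP, decision = nD),
    modalities = c(word = nW, head = nP, feedback = 3L),
    A = list(word = A_word, head = A_head, feedback = A_fb),
    B = list(sentence = ident(nS), position = B_pos, decision = B_dec),
    C = list(word = numeric(nW), head = numeric(nP), feedback = C_fb),
    D = list(sentence = rep(1 / nS, nS),
             position = one_hot(1L, nP),
             decision = one_hot(1L, nD)),
    policies = list(cbind(1L, 1L, 1L),   # read the next word
                    cbind(1L, 2L, 2L),   # stop and report happy
                    cbind(1L, 3L, 3L)),  # stop and report sad
    horizon = 6L,
    n_iterations = config$n_iterations,
    ms_per_iteration = config$ms_per_iteration,
    name = "narrative")

  model <- deep_model(
    levels = list(level1, level2),
    links = list(list(factor = "word", modality = "word")),
    gates = list(list(factor = "decision", state = 1L)))
  if (config$violation != "none")
    model <- apply_violation(model, config$violation, config)
  model
}

#' Apply a local and/or global prior violation to a reading model
#'
#' A local violation reverses the vertical-flip prior for, and only for, the
#' last word (so upper case becomes the expected default there); a global
#' violation deflates the prior probability of sentence 1 by `global_factor`
#' and renormalises. Stimuli and actions are never modified: replay the same
#' trial under the violated model to obtain difference waveforms.
#'
#' @param model A reading `actinf_model`.
#' @param kind `"none"`, `"local"`, `"global"` or `"both"`.
#' @param config The [reading_config()] used to build the model.
#' @return The modified model.
#' @export
apply_violation <- function(model, kind = c("none", "local", "global", "both"),
                            config = reading_config()) {
  kind <- match.arg(kind)
  if (kind %in% c("local", "both")) {
    tab <- model$levels[[1]]$D$vflip$table
    tab[, 4L] <- rev(tab[, 4L])
    model$levels[[1]]$D$vflip$table <- tab
  }
  if (kind %in% c("global", "both")) {
    d <- model$levels[[2]]$D$sentence$table
    d[1L] <- d[1L] / config$global_factor
    model$levels[[2]]$D$sentence$table <- d / sum(d)
  }
  model
}

#' Exemplar (or sampled) stimuli for a reading trial
#'
#' The exemplar trial presents the configured sentence in lower case except
#' one vertically flipped (upper case) word, with no horizontal flips. With
#' `sample = TRUE`, the sentence and per-word flips are drawn from the model's
#' own priors instead.
#'
#' @param config A [reading_config()].
#' @param sentence Sentence index (default: the exemplar sentence).
#' @param vflip,hflip Integer vectors of flip states per word (1 = no,
#'   2 = yes); defaults: the exemplar pattern and no horizontal flips.
#' @param sample Draw sentence and flips from the generative priors.
#' @param seed Seed used when sampling.
#' @return A `stimuli` list for [run_trial()].
#' @export
reading_stimuli <- function(config = reading_config(),
                            sentence = config$exemplar_sentence,
                            vflip = NULL, hflip = NULL,
                            sample = FALSE, seed = 1) {
  if (sample) {
    with_seed(seed, {
      sentence <- sample.int(6L, 1L)
      vflip <- sample.int(2L, 4L, replace = TRUE, prob = config$vflip_prior)
      hflip <- sample.int(2L, 4L, replace = TRUE, prob = config$hflip_prior)
    })
  }
  if (is.null(vflip)) {
    vflip <- rep(1L, 4L)
    vflip[config$exemplar_vflip_word] <- 2L
  }
  if (is.null(hflip)) hflip <- rep(1L, 4L)
  list(top = c(sentence = as.integer(sentence), position = 1L, decision = 1L),
       lower = lapply(seq_len(4L), function(p)
         c(vflip = vflip[p], hflip = hflip[p])))
}

#' Behavioural summary of a reading trial
#'
#' @param trial An `actinf_trial` from [run_trial()] on a reading model.
#' @return A one-row tibble: saccade counts per word, decision, feedback,
#'   epochs, total simulated ms, and whether the trial ended undecided.
#' @export
reading_summary <- function(trial) {
  runs <- trial$lower_runs
  pos <- trial$true_top[trial$true_top$factor == "position", ]
  dec <- trial$true_top[trial$true_top$factor == "decision", ]
  sacc <- rep(NA_integer_, 4L)
  for (r in runs) {
    if (is.null(r)) next
    p <- pos$state[pos$step == r$epoch_above]
    if (is.na(sacc[p])) sacc[p] <- 0L
    sacc[p] <- sacc[p] + r$n_steps
  }
  fb_idx <- vapply(trial$top_outcomes, function(o) {
    f <- o[["feedback"]]
    if (length(f) == 1L) as.integer(f) else which.max(f)
  }, 1L)
  fb <- setdiff(unique(READING_FEEDBACK[fb_idx]), "nothing")
  dec_state <- dec$state[which(dec$state != 1L)[1]]
  undecided <- all(dec$state == 1L) ||
    any(vapply(runs, function(r) !is.null(r) && isTRUE(r$undecided), TRUE))
  tibble::tibble(
    saccades_word1 = sacc[1], saccades_word2 = sacc[2],
    saccades_word3 = sacc[3], saccades_word4 = sacc[4],
    word_transitions = sum(!is.na(sacc)),
    decision = if (is.na(dec_state)) "undecided" else READING_DECISIONS[dec_state],
    feedback = if (length(fb)) fb[1] else "nothing",
    n_epochs_top = trial$n_epochs_top,
    n_epochs_lower = trial$n_epochs_lower,
    total_ms = trial$total_ms,
    undecided = undecided)
}

#' Saccade log of a reading trial
#'
#' One row per fixation: the word position being read, the fixation index
#' within that word, the quadrant fixated and the letter observed there.
#'
#' @param trial An `actinf_trial` on a reading model.
#' @return A tibble.
#' @export
saccade_log <- function(trial) {
  pos <- trial$true_top[trial$true_top$factor == "position", ]
  rows <- list()
  for (r in trial$lower_runs) {
    if (is.null(r)) next
    p <- pos$state[pos$step == r$epoch_above]
    q <- unname(r$true_states[["where"]])
    for (st in seq_len(r$n_steps)) {
      if (st > 1L) q <- unname(r$actions[[st - 1L]][["where"]])
      o <- r$outcomes[[st]][["letter"]]
      o <- if (length(o) == 1L) as.integer(o) else which.max(o)
      rows[[length(rows) + 1]] <- tibble::tibble(
        epoch = r$epoch_above, word_position = p, fixation = st,
        quadrant = q, letter = READING_LETTERS[o])
    }
  }
  dplyr::bind_rows(rows)
}
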