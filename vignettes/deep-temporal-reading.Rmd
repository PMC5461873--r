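---
title: "Deep temporal active inference and the reading model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep temporal active inference and the reading model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepactive)
```

## The generative model

`deepactive` works with discrete-state generative models factored into the
four standard parameter sets. At each hierarchical level, hidden states
split into conditionally independent *factors* (e.g. which word is on the
page versus where the eye points) and outcomes into *modalities* (the letter
seen versus the proprioceptive eye position). A level is then

- **A**: one likelihood tensor per modality, `dim = c(outcomes, factors...)`,
  whose columns are categorical distributions. Interactions among factors
  (you must know both the word and the fixated quadrant to predict the
  letter) are encoded by placing ones at the consistent state combinations
  (`sparse_ones()`).
- **B**: one square transition matrix per factor and action; columns map the
  current state to a distribution over the next.
- **C**: log prior preferences over outcomes, in nats; a zero vector is
  indifference.
- **D**: the prior over each factor's initial state — either unconditional,
  or a *link* table conditioned on named factors of the level above. Links
  are what make the model deep: one higher-level transition spans an entire
  lower-level sequence re-initialised through **D**.

Policies here are one-step action assignments (one control value per
factor); multi-step policies are supported structurally but unused by the
reading model, whose policies differ only in the next action.

## Belief updating

Within an epoch (one observed time step), expectations are updated by a
damped gradient flow in the log domain: for every policy, time and factor
the state prediction error is the sum of the log messages predicting that
factor (likelihood messages through **A** with marginal generalised dot
products over the other factors; the forward message through **B**, or the
empirical prior at the initial time) minus the current log expectation, and

```
v <- v + kappa * eps ;  s <- softmax(v)
```

for 16 iterations of 16 ms each, so an epoch spans 256 ms of simulated
time. Depolarisations `v` are reset to the log prior-predictive chain at
epoch onset, which produces the transients visible in the rasters. The
policy posterior `softmax(-G)` and the Bayesian model averages are
recomputed after every iteration; the model average of the current time
step's marginal is what terminates a run, ascends to the level above, and is
displayed as unit firing.

Message passing is deliberately a *filtering* scheme (no backward message).
With the identity transitions of static factors, a backward message has no
stable fixed point — the same evidence circulates between time steps and
every graded posterior collapses to a delta. Under filtering, the fixed
point of the current-time marginal is the exact filtered posterior, and for
a static factor that marginal *is* the posterior over its initial state
given everything observed, which is exactly the quantity the hierarchy
needs to exchange.

### Policy evaluation on the exact joint predictive

Expected free energy is evaluated per policy and future time as
`G = risk + ambiguity`, with `risk = sum o*(ln o - C)` and ambiguity the
expected conditional outcome entropy of **A**; the equivalent reading
`-(epistemic + pragmatic)` is reported alongside, and the two agree
identically by construction. The predictive distributions are computed from
the exact joint over the level's factors, forward-filtered through the
executed actions and observed outcomes and rolled out under the policy
(`exact_predictive()`).

This is a deliberate design decision. The product of mean-field marginals
leaks probability onto factor combinations that past outcomes have already
excluded; measured on the reading model this inflated the predicted-outcome
entropy of re-fixating an already-seen quadrant to within numerical noise of
an unvisited one, so the epistemic ordering that drives saccadic foraging
rested on a knife edge. The joint state spaces here are tiny (192 and 72
states), so the exact predictive is cheap, restores the strict ordering
(visited quadrants have exactly zero information gain), and leaves
single-factor models — where the mean field is exact — bit-for-bit
unchanged. Neuronal belief updating, model averaging, termination and the
ascending evidence all remain the factored scheme.

### Numerical choices

- All logs are `log(p + exp(-16))`, bounding the prediction error of an
  impossible state at 16 nats.
- `kappa = 0.25` with 16 iterations: at this rate the residual of the
  fixed-point iteration is about 1% of the initial log-gap after one epoch,
  which keeps single-epoch posteriors within 1e-2 of exact enumeration (and
  within 1e-4 at 128 iterations). Both tolerances are enforced by tests.
- Exact ties in action selection resolve to the lowest policy index; the
  reading model orders its policies (continue, report happy, report sad) so
  that ties never favour a premature report.
- `update_epoch(err_sat =)` optionally passes prediction errors through a
  saturating transduction `cap * tanh(eps / cap)`. The transform is
  sign-preserving and linear at the origin, so no fixed point moves; it only
  bounds the drive per iteration, slowing evidence accumulation against
  strong messages. It is off by default (see *Known limitations*).
- Degenerate inputs fail loudly: all-zero likelihood columns, invalid
  priors at a level interface, and out-of-band filter requests are errors;
  a lower level that exhausts its horizon without reaching the termination
  threshold records an `undecided` flag rather than raising.

## The reading model

Level 2 (narrative) carries three factors — sentence (6), word position
(4), decision (undecided / happy / sad) — and observes the word passed up
from below, a word-location proprioceptive signal, and feedback. Level 1
(lexical) carries word (flee / feed / wait), letter location (4 quadrants)
and two spatial flips, and observes the letter (bird / cat / seed / nothing)
plus letter location. The canonical (no-flip) scenes are: *flee* = cat and
bird in the upper row; *feed* = bird and seed in the upper row; *wait* =
bird and seed on the main diagonal, so that its vertically flipped form
leaves quadrants 1 and 4 empty. All twelve (word, flips) scenes are
distinct, so four fixations always disambiguate a word.

Only the first sentence is fixed by the task description. The inventory was
chosen once to satisfy the behavioural constraints the task implies and is
fully configurable: every sentence begins, and continues at the second
word, with flee or wait; sentence 4 shares its first three words with
sentence 1 and ends differently, so the sentence-1-versus-4 ambiguity
survives until the last word; one sentence keeps the third word uncertain;
and happy/sad narratives (no flee among the last two words) split 3/3.

Tunable parameters, their defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `wrong_log_pref` | -4 nats | aversion to wrong feedback; makes being wrong ~54x less probable a priori than neutral feedback, so the subject reports only when confident |
| `right_log_pref` | +1 nat | mild preference for confirmatory feedback; encodes the instruction to report once confident (see below) |
| `vflip_prior` | (7/8, 1/8) | strong prior that text is lower case; its reversal for the last word is the local violation |
| `hflip_prior` | (1/2, 1/2) | letter order carries no meaning (palindrome invariance) |
| `threshold_nats` | 1/512 | word-posterior entropy at which a saccadic run terminates |
| `global_factor` | 8 | prior deflation of sentence 1 under the global violation |
| `kappa`, `n_iterations`, `ms_per_iteration` | 0.25, 16, 16 | temporal granularity of updating (256 ms epochs) |
| `band_hz` | (4, 32) | band for the simulated local field potentials |

The positive `right_log_pref` deserves a note. With deterministic argmax
action selection and a perfectly flat preference over non-wrong outcomes,
a report policy always carries a residual risk penalty of `4 * q` nats
(`q` the remaining probability of being wrong) relative to continuing to
read, so the argmax would continue forever. A small positive preference for
confirmation makes reporting strictly optimal once the posterior odds of
being correct exceed about 4:1 *and* no epistemic value remains; in the
exemplar the report happens at `q ~ 1e-7`. Stochastic action selection
(`select_action(mode = "sample")`) is available but the shipped experiments
are deterministic for reproducibility.

Scheduling: the lower level runs (and saccades) only while the decision
factor is truly undecided; afterwards the word modality is simply
unobserved and its likelihood message is omitted. The top level always runs
its full six-epoch horizon (four words, the decision, its feedback), so the
exemplar spans 6 + 7 epochs = 3328 ms.

## What the stimulus generator does and does not emulate

`reading_stimuli()` (and `sample_trial()` generally) draws from the model's
own generative process: sentences uniform, flips from their priors, letters
deterministic given the scene. This matches the study conditions — the
simulated subject's model is the true process, so inference is well
calibrated. It does not emulate real text (orthography, lexical statistics,
grammar), sensory noise (likelihoods are deterministic), or any
learning across trials. Passing tests therefore demonstrate the internal
consistency of inference, foraging and scheduling under the stated model,
not reading performance on natural stimuli.

## Violations and simulated electrophysiology

`run_violation_experiment()` records the standard exemplar trial, then
replays *exactly the same stimuli and actions* under edited priors: the
vertical-flip prior reversed for (and only for) the last word (local), the
sentence-1 prior deflated by a factor of 8 and renormalised (global), or
both. Belief trajectories differ; behaviour is clamped. Firing traces are
linearly upsampled 4x (the 16 ms grid puts 32 Hz above Nyquist; the 4 ms
grid realises the printed band), band-passed with a zero-phase second-order
Butterworth filter (demeaned and reflection-padded so edges stay clean),
aligned to the onset of the last saccade before the decision, and
subtracted per unit. The interaction is the difference of difference
waveforms, `(both - global) - (local - standard)`.

In the shipped configuration the local difference is a brief transient
(extremum at 48 ms, above-half-maximum support 48 ms across the three word
units) and the global difference is more protracted (support 76 ms) with a
late (~260 ms), large second-level deflection — qualitatively the mismatch
versus contextual-violation pattern, with the hierarchy's levels cleanly
dissociated.

## Known limitations

- **Component latencies run early.** Classical feature-violation mismatch
  responses peak near 170 ms and early deflections near 100 ms; here they
  sit at 48 and 56 ms. The latency is set by the effective
  evidence-accumulation rate: deterministic likelihoods deliver ~16 nat
  messages, so beliefs saturate within ~6 of the 16 iterations. Slowing the
  clock fixes the latencies but breaks things this package treats as
  structural: a smaller `kappa` fails the enumeration-oracle tolerance at 16
  iterations and distorts the exemplar's saccade counts, and the saturating
  transduction (`err_sat ~ 8`) moves the raw divergence peak to ~144 ms but
  the band-pass fragments the waveform into lobes and the
  global-more-protracted-than-local ordering inverts. We kept exact
  inference and behaviour and report the early latencies as measured.
- **Mean-field misreading.** Words presented with an unexpected vertical
  flip can be confidently misidentified: the factored marginals settle on a
  word/flip combination whose joint the letters exclude. The exemplar and
  all unflipped stimuli are immune (tested); strongly flipped stimuli are
  not. This is a real property of the factored scheme — unexpected-case
  text being hard to read is precisely what the local violation exploits —
  but it means sentence-level accuracy guarantees hold only for unflipped
  stimuli.
- The scheduler implements asynchronous updating only (the alternative,
  synchronous scheme is out of scope), and `run_trial()` orchestrates
  two-level models; `run_level()` composes for deeper stacks.
- Problem sizes are those of the study: 13-14 epochs of 16 iterations per
  trial, joint state spaces of 192 and 72, and validation suites of 100
  random micro-models; everything runs in seconds on one CPU.

## Repository shape

Result objects are tibble-first: traces, waveforms, latency tables,
validation reports and behavioural summaries are tibbles with `tidy()`,
`glance()` and `autoplot()` methods, so analyses compose with dplyr and
ggplot2. The generative-model containers themselves (likelihood tensors,
belief arrays) remain plain S3 lists of arrays — they are not tabular, and
pretending otherwise would only obscure the linear algebra.
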