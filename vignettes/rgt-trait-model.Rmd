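---
title: "A trait-modulated reinforcement-learning model of the Rat Gambling Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A trait-modulated reinforcement-learning model of the Rat Gambling Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the question

The Rat Gambling Task (RGT) confronts a rat, for a single one-hour session,
with four nose-poke options. Two options (A, B) deliver two food pellets but
are followed, with probability 1/2 and 1/4, by long time-outs (444 s and
222 s) during which no food can be earned; two options (C, D) deliver one
pellet with short, rare time-outs (12 s at probability 1/4, 6 s at
probability 1/2). Because a pellet takes about nine seconds to obtain and
consume, a time-out is equivalent to an immediate loss of
`timeout / 9` pellets: -50, -25, -4/3 and -2/3 pellets for A-D. Options C
and D therefore maximise long-run payoff (2/3 of a pellet per trial each,
against -23 and -4.25), and the percentage of C/D choices during the final
20 minutes classifies an individual as a good (> 70%), poor (< 30%) or
undecided decision maker.

Healthy rats split reproducibly into these phenotypes. The question this
package operationalises is whether a small set of stable behavioural
traits — reward seeking, risk seeking and cognitive inflexibility — is
sufficient to generate both phenotypes from a single learning mechanism,
and whether those traits can be estimated per individual from nothing but
the binned choice record.

## The learning model

Each individual is a temporal-difference learner over the four response
holes, with Q-values initialised at zero and updated after every trial:

    Q[h] <- Q[h] + alpha(t) * (signal - Q[h])

Three traits shape the learning signal and its dynamics:

* **Reward seeking** (`omega >= 0`): the delivered pellets are re-weighted
  multiplicatively, `omega * r`. Penalties are *not* re-weighted —
  penalty-only task variants show intact penalty sensitivity in poor
  decision makers — so over-valuation inflates gains only.
* **Risk seeking** (`rho`, any sign): an additive bonus
  `rho * sd(penalties experienced at this hole)`, where the spread is the
  population standard deviation over *all* trials at that hole,
  zero-penalty trials included, maintained as running statistics (Welford
  recursion; zero while the hole has at most one visit). Positive `rho`
  makes volatile options attractive; the asymptotic spreads under the
  canonical table are 25 (A), 25·sqrt(3)/4 ≈ 10.8 (B), 0.58 (C), 0.33 (D),
  so risk appetite disproportionately inflates the disadvantageous pair.
* **Cognitive inflexibility** (`alpha0`, `tau0`): the learning rate decays
  exponentially, `alpha(t) = alpha0 * exp(-t / tau0)`, with `t` the elapsed
  session time in seconds. A small `tau0` freezes learning early; the time
  integral of `alpha` (the "area under alpha") summarises overall
  flexibility and is increasing in both parameters.

The full signal for a trial is `omega * pellets + penalty + rho * risk`,
with the penalty statistics updated *before* the value update so the
current trial's penalty informs its own risk bonus. Actions follow a
softmax with temperature `epsilon` (max-shifted, stable to |Q|/epsilon of
1e3 and beyond); the first 10 minutes impose uniform forced exploration,
implemented as the infinite-temperature limit. There is no temporal
discounting and no state splitting.

## Time accounting: two clocks

The package exposes two session clocks, and the distinction matters:

* **Episode clock** (default). A trial advances the session by 9 s per
  pellet consumed; the time-out is charged entirely through its
  pellet-equivalent penalty. A session is then a fixed hour of
  consumption-equivalent time (roughly 200-400 trials), the forced
  10-minute phase contains ~65 trials — enough to sample every option and
  seed the running risk statistics — and the pellet cap is irrelevant by
  construction (it defaults to `Inf` on this clock).
* **Behavioural clock**. Realized time-outs also consume session time, as
  in the operant chamber, and the 250-pellet satiety cap applies (an
  all-advantageous agent reaches it before the hour). Use this clock to
  emulate the procedure's timing, e.g. when writing realistic session
  logs.

All model analyses in this package run on the episode clock. Under the
behavioural clock a uniform forced phase contains only ~6 trials (a single
penalized draw of A consumes 7+ minutes), single early penalties trap
options at strongly negative values before any risk estimate exists, and
the poor phenotype emerges only sporadically; the conversion of time-outs
into pellet units exists precisely so that learning operates on a uniform
episode time base.

A related choice concerns the reversal session (options A/B spatially
exchanged with C/D; values are indexed by hole, so learned preferences
meet new outcomes). The learned values and penalty statistics carry over;
the bin clock restarts; and by default the *decay clock does not restart*:
an agent whose learning rate has collapsed cannot relearn the swapped
contingencies, and no second forced-exploration phase is imposed. This is
what lets inflexibility measured in the RGT predict reversal behaviour at
all — resetting the decay clock (available via `reset_decay_clock = TRUE`)
makes every agent relearn during the reversal's forced phase and erases
the phenotype. Flexibility is scored as the percentage of final-20-minute
reversal trials that still obtain the previously preferred contingency
(> 60 flexible, 40-60 undecided, < 40 inflexible; an alternative < 35
inflexibility cut appears in some descriptions of the behavioural data —
the 40/60 bands are implemented).

## Estimation

The estimator is simulation-based maximum likelihood on the binned
profile `x10..x60` (percentage of advantageous choices per 10-minute bin).
For a candidate parameter vector, `n_runs = 50` sessions are simulated
with fixed per-run seeds (common random numbers — the objective is a
deterministic function of the master seed), the per-bin advantageous
probability is the Laplace-smoothed pooled fraction `(adv + 1)/(tot + 2)`,
and the observed counts contribute independent binomial terms. Bins empty
on either side are dropped; profiles carrying only percentages fall back
to an assumed 30 trials per bin, with a warning. The search is a coarse
grid over the free parameters (log-spaced where natural; bounds
`alpha0` 0.01-1, `tau0` 60 s-Inf via the decay rate, `omega` 0.5-4, `rho`
-1-2, `epsilon` 0.05-5) followed by Nelder-Mead refinement from the best
candidate; the reported optimum is the best parameter vector actually
evaluated. Joint RGT + reversal fits sum the two sessions' bin terms,
simulating each run's reversal from its own end-of-RGT state.

Model variants pin inactive traits at neutral values (`omega = 1`,
`rho = 0`, `tau0 = Inf`); the free-parameter count is 2 (always `alpha0`,
`epsilon`) plus one per active trait, so the full model has five. When a
cohort is fitted across variants, the nested optima seed the full model's
refinement, which guarantees — under the shared per-rat seeds — that the
full likelihood dominates every nested one, as the likelihood-ratio test
presumes. Cohort BIC is the sum of per-rat BICs with `n_obs` the number
of likelihood bins per rat (6, or 12 for joint fits), and LRT degrees of
freedom scale with the number of individuals; these conventions are this
package's choices.

Two practical facts shape what a single session can identify:

* The simulated log-likelihood carries seed-to-seed evaluation noise of
  several units at the 50-run budget (measured SD roughly 3-15 at the
  generating parameters). Differences on that scale are not evidence.
* Saturated profiles are flat along whole parameter directions. An
  all-advantageous profile says nothing about `omega` (the softmax is
  scale-degenerate between `omega` and `epsilon` once penalties stop
  being sampled), and an all-disadvantageous profile lets `omega` and
  `rho` trade off freely.

For these reasons every fit also reports a *grid-posterior-mean* trait
summary: the likelihood-weighted average of the coarse-grid points under
a uniform prior on the search box, with weights tempered as
`exp(logL / 5)` so that noise-scale differences do not collapse the
average onto an arbitrary plateau point. The ML point is kept for
likelihood machinery (LRT, BIC, dominance checks); the posterior mean is
the recommended per-individual trait estimate and is what the recovery
analyses correlate with the ground truth. An optional weak MAP shrinkage
toward neutral traits exists but is off by default.

## The synthetic cohort

No animal data ship with this package; every downstream analysis runs on
a generated cohort with known ground truth. Two archetypes are sampled
uniformly within frozen ranges: good decision makers with `omega` in
0.8-1.2, `rho` in -0.3-0.1, `alpha0` in 0.2-0.6, `tau0` from 1200 s to
infinity (uniform on the decay-rate scale) and `epsilon` in 0.3-1; poor
decision makers with `omega` in 1.5-3, `rho` in 0.5-1.5, the same
`alpha0`, `tau0` in 120-600 s and the same `epsilon`. Under these ranges
the trait-inflated asymptotic values make the disadvantageous pair
dominate for the poor archetype (e.g. `omega = 2`, `rho = 1` gives A ≈ 4
and B ≈ 8.55 against C ≈ 2.2 and D ≈ 2), and generated rats classify as
their archetype essentially always.

Behavioural battery measures are emulated as monotone transforms of the
generating traits with lognormal noise (coefficient of variation 0.3 by
default): reward-collection latency proportional to `1/omega`; emergence
latency and risk-assessment count proportional to `exp(-rho)`;
anticipatory/perseverative press counts proportional to `exp(rho)`; the
flexibility percentage is taken from the simulated reversal session
itself. These transforms emulate the *ordering* structure of the
behavioural battery, not its mechanisms — passing recovery tests shows
the estimator works under the model's own assumptions, not that real
operant measures behave this way.

For model comparison a *heterogeneous* cohort is used instead, with
traits sampled independently over broad ranges (`omega` 0.8-3, `rho`
-0.3-1.5, `tau0` 120 s-Inf), so that each trait carries explanatory
power not already implied by the others.

## Statistics

The bespoke statistics mirror the analysis pipeline: a Monte-Carlo
permutation test for correlations (two-sided, with the `(1 + hits)/
(n_perm + 1)` correction, so p-values are valid at any permutation
budget and bounded below by `1/(n_perm + 1)`); a group correlation that
first reduces each score to ±1 around its own median (ties count as
high, matching the convention used for the trait profile tables) and
correlates the sign vectors; a sum-of-ranks global index across trait
scores, oriented so higher means more poor-like, with average ranks for
ties and missing cells ranked on the available individuals and flagged;
and median-split trait profiles counting high marks per individual. The
chi-squared reference for the LRT is kept although the likelihood is
simulated — the result carries a caveat flag.

## Problem sizes and numerical choices

The analysis scripts and tests run at desk scale, chosen so the full
suite completes in minutes on one core: 20 seeded sessions per archetype;
a 12-rat cohort for recovery (joint fits, 50 runs per evaluation); a
10-rat heterogeneous cohort, 20 runs per evaluation and three master
seeds for model comparison; 10^4 draws for Monte-Carlo frequency checks;
199-10^4 permutations depending on context. Degenerate inputs fail
loudly: empty sessions, profiles without observed bins, zero-variance
correlation inputs and non-bijective location maps all raise errors
rather than returning defaults. Softmax ties are broken by the uniform
draw, never by option order; the C++ simulation core and the pure-R
reference loop consume the RNG identically and are tested bit-identical.

## Known limitations

* With choice data summarised as advantageous fractions, `omega` is only
  weakly identified: its marginal contribution to the cohort likelihood
  (about two units over ten rats) is smaller than any BIC penalty, so
  model selection prefers the risk + inflexibility two-trait model on
  synthetic data even when the data were generated with reward seeking
  active. Recovering a clear reward-seeking signature would require
  richer data summaries (e.g. the A/B split within disadvantageous
  choices, or trial-level likelihoods).
* Parameter recovery is rank-level, not value-level: per-rat estimates of
  weakly identified parameters can sit far from the truth even when the
  cohort ordering is preserved.
* The generator emulates one RGT and one reversal session per individual;
  session-to-session stability, retraining between sessions and satiety
  dynamics are not modelled.
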