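---
title: "Markov sequence design, performance and strategy metrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov sequence design, performance and strategy metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqstrat)
```

## The task and the stimulus models

`seqstrat` supports prediction experiments over probabilistic symbol
sequences: an observer watches a stream of items drawn from an alphabet of
four (A–D, mapped to arbitrary glyphs at presentation time via the
`permutation` argument of `build_model()`), and at the end of each stream
predicts the next item. The sources are order-*k* Markov models,

$$P(s_i \mid s_{i-1}, \dots, s_1) = P(s_i \mid s_{i-1}, \dots, s_{i-k}),$$

with the *k*-tuple of preceding items called the *context* and the next
item the *target*. Three levels are built in:

* **Level 0** — memoryless occurrence probabilities
  (0.18, 0.72, 0.05, 0.05): two dominant symbols, two rare ones.
* **Level 1** — each single-item context allows exactly two successors at
  0.8/0.2, arranged cyclically (A→{B: .8, C: .2}, B→{C, D}, C→{D, A},
  D→{A, B}).
* **Level 2** — contexts are ordered item pairs, again with two successors
  at 0.8/0.2 per context.

The two-successor structure keeps memory-conditional uncertainty equal
across the conditional levels, so the levels differ only in context
length. All probabilities are configurable; the defaults above are the
package's reference design.

### Why the level-2 design has eight contexts

A natural first guess for the order-2 design is a small set of six
recurrent contexts. That is impossible for a four-symbol source in which
every context allows exactly two successors. Write a context as an ordered
pair $(x, y)$. Emitting target $t$ moves the chain to context $(y, t)$, so
every context ending in $y$ needs at least two in-set contexts beginning
with $y$; summing over the (necessarily four, if all symbols recur)
letters that end contexts gives at least $2 \times 4 = 8$ recurrent
contexts. The package therefore uses the minimal ergodic design: the eight
pairs realisable under the level-1 successor skeleton. To make the source
genuinely second-order, the 0.8/0.2 assignment within a context $(x, y)$
depends on $x$: it is flipped when $x \to y$ was itself the
high-probability edge. The induced context chain is ergodic with uniform
stationary weights, and conditional rows for contexts sharing a final item
differ — an order-1 fit cannot represent the source.

### Sequence generation and the initial context

`generate_sequence()` draws the first $k$ items from the stationary
context distribution (computed by `stationary_context_distribution()` as
the fixed point of the induced context chain), then iterates the
conditional rows. Starting at stationarity removes burn-in bias from the
empirical statistics of finite sequences, which matters because sequence
selection scores exactly those statistics.

## Selecting presentation sets by KL divergence

Long-run statistics of a finite stochastic sequence fluctuate; to present
observers with streams that are *representative* of their generating
model, `select_sequences()` draws a large candidate pool (default 10,000
sequences of 672 items) and keeps the `n_select` (default 50) sequences
with the smallest Kullback–Leibler divergence between the ideal model Q
and the sequence's empirical conditional distribution P:

$$\mathrm{KL} = \sum_{c} Q(c) \sum_{t} Q(t \mid c)
   \log \frac{Q(t \mid c)}{P(t \mid c)},$$

with $Q(c)$ the stationary context weights (for $k = 0$ this reduces to
the unconditional divergence). Ties are broken by generation order (stable
sort). Training streams of 8–14 items are cut as contiguous random windows
from the selected sequences, 56 trials per block with every length equally
represented; test runs hold 10 structured and 10 random (uniform i.i.d.)
streams of 10 items in counterbalanced block order.

### Numerical conventions

* **Logarithms** are natural (nats) throughout; every KL-based function
  takes a `base` argument for bits.
* **Smoothing.** Empirical distributions in KL denominators are
  epsilon-smoothed and renormalized, $P' = (P + \varepsilon)/(1 +
  4\varepsilon)$ with $\varepsilon = 10^{-6}$; a context absent from the
  data enters as the smoothed uniform floor. The printed divergence
  formulas are undefined at zeros, and $\varepsilon$ at this scale moves
  full-support divergences by well under 1% (asserted in the tests).
  Numerator zeros contribute $0 \log 0 = 0$ exactly.
* **Determinism.** All randomness flows through R's RNG; every simulation
  entry point either inherits the caller's `set.seed()` state or (for
  observers and cohorts) takes an explicit seed and restores the caller's
  RNG state on exit.

## The performance index and its chance baselines

Responses are scored distributionally per block (the unit at which
observers receive feedback): for each context, the *performance index* is
the minimum overlap between the response histogram and the
presented-target histogram,

$$\mathrm{PI}(c) = \sum_s \min\!\big(P_{\text{resp}}(s \mid c),\,
   P_{\text{pres}}(s \mid c)\big),$$

averaged over contexts weighted by context frequency. PI equals
$1 - \tfrac12\sum_s |p_s - q_s|$ (one minus total-variation distance), is
1 exactly when the distributions coincide, and is symmetric.

Design choices a user should know:

* **Presented-target distribution.** By default it is estimated from all
  within-stream context→next-item transitions of the scope's streams,
  which is well defined and data-rich (~600 transitions per 56-trial
  block); `presented = "model"` uses the exact model rows instead.
* **Null responses** (timeouts) never enter either distribution; they are
  counted and reported separately.
* **Context mismatch.** A context present in only one of the two tables is
  dropped and the weights renormalized; the dropped count is reported.
* **Session scores** are means of block scores.

### Analytic and simulated baselines

A uniform random guesser achieves
$\mathrm{PI}_{\text{rand}} = \sum_c \pi_c \sum_s \min(P(s \mid c), 0.25)$:
0.53 for the level-0 row and 0.45 for every 0.8/0.2 row, hence 0.45 at
both conditional levels. `normalized_pi()` subtracts this baseline; the
0.70 training criterion thus corresponds to 0.25 above conditional-design
chance.

`random_baseline_pi(mode = "simulated")` provides the finite-sample
counterpart: the mean PI of a uniform responder over simulated blocks.
Because that responder is context-free by definition, the estimator pools
its responses across contexts by default, which keeps the finite-sample
estimate within about 0.005 of the closed form at 56-trial blocks.
Stratifying the estimate by context (`pool_responses = FALSE`) instead
injects per-context small-sample noise into the overlap, which biases it
downward — an effect worth knowing when comparing published chance values:
at one-session samples (~280 trials, ~35 per level-2 context) the
stratified estimate sits near 0.44, i.e. about 0.01 below the analytic
0.45, and at single-block samples it falls to ~0.41. The package's tests
compute both regimes. Observed block-level PI of real (or synthetic)
observers is subject to the same small-sample bias, so comparisons of
observed PI against a simulated baseline should match scope and estimator.

## Strategy: matching versus maximization

Two baseline response profiles are derived from the generating model by
`baseline_models()`: *matching* equals the model's conditional rows;
*maximization* puts all mass on each context's modal target (exact ties —
impossible under 0.8/0.2, possible for custom models — split mass
equally). The response table R estimated from a window of trials is
compared with each baseline by

$$\mathrm{KL}(M \,\|\, R) = \sum_c M(c) \sum_t M(t \mid c)
   \log \frac{M(t \mid c)}{R(t \mid c)},$$

with the model in the numerator, the model's stationary context weights as
$M(c)$, and R smoothed as above. (A `direction` flag offers the reversed
divergence for sensitivity analyses; the default orientation is the one
under which the two baselines are exactly representable.)

The *strategy choice* statistic is
$\Delta\mathrm{KL} = \mathrm{KL}(\text{matching}\|R) -
\mathrm{KL}(\text{maximization}\|R)$, oriented so that larger values mean
responding closer to maximization. An exact matcher scores the negative
constant $-\mathrm{KL}(\text{max}\|\text{match})$ (`matcher_reference()`),
an exact maximizer a large positive value bounded by the smoothing floor.

The *strategy curve* evaluates $\Delta$KL in consecutive non-overlapping
windows. The window defaults to 56 trials — one block, the same estimation
unit as PI — because a window must contain enough trials per context to
estimate R (at level 2, 56 trials give ~7 per context; much smaller
windows make the smoothed KL erratic). The *integral curve difference*
(ICD) is the trapezoidal integral of the curve over the window axis
normalized to $[0,1]$, minus the integral of the constant matcher
reference; a single window degenerates to a plain difference. By
construction the ICD of an exact matcher is 0 to machine precision — both
integrals are computed by the identical floating-point path — and the
index grows positive toward maximization. Indices for the two conditional
levels may be averaged (`pooled_context_index()`) into a single
context-based-statistics index when they are strongly correlated across
observers.

## Synthetic observers

No generative observer model is implied by the metrics themselves, so the
package ships the simplest generator whose limits are exactly the two
baseline strategies: a decayed-count Dirichlet learner. Counts $C(c, t)$
start at `prior_count` (default 1, a uniform Dirichlet prior), are
multiplied by `decay` (default 1 = no forgetting) each trial, and are
incremented by every within-stream transition of the presented stream —
the same transition set the scoring uses, so the generator and the
analysis share one definition of "what was presented". The response to the
trial's final context is:

* with probability `null_rate` (default 0.01): no response (timeout);
* else with probability `lapse` (default 0.02): uniform at random;
* else with probability `lambda_max`: the arg-max of the posterior-mean
  row (maximization);
* otherwise: a sample from the posterior-mean row (matching).

The defaults are modest, realistic noise rates for a trained adult
observer in a 2-s response window; they are deliberately small so that
λ, not noise, dominates the strategy continuum. A λ = 0 observer's
response table converges to the model rows (probability matching); a
λ = 1 observer converges to the maximization baseline.

`simulate_cohort()` runs heterogeneous observers (λ drawn uniformly unless
specified) through the training protocol — per level, three to five
sessions of five 56-trial blocks, i.e. 840–1400 trials — with a documented
seed-splitting scheme: per-(observer, level) base seeds are drawn from R's
RNG seeded by the master seed; trial assembly uses the base seed and
observer behavior uses base + 1, so any slice of a cohort can be
regenerated in isolation.

### What the generator does and does not emulate

It reproduces the statistical structure the metrics assume: incremental
learning of conditional distributions, a matching↔maximization continuum,
lapses, timeouts, and the session/block protocol. It does **not** model
reaction times, fatigue or session-to-session consolidation, strategy
switching over time, or biased priors — so passing recovery tests
validates the *metrics* (that the ICD orders and tracks the generating
blend), not any claim about human learning dynamics.

## Parameter recovery as the validation surface

Because individual participant statistics cannot be reproduced without raw
data, the package's quantitative validation is a recovery experiment
(`recovery_experiment()`): blends λ ∈ {0, 0.25, 0.5, 0.75, 1}, 20 seeded
replicates each, 1120 training trials (the protocol's mid-range) on the
level-1 design. Under these conditions the mean ICD is strictly increasing
in λ and Spearman's ρ(λ, index) exceeds 0.9 (typically ≈ 0.97). Note the
sampled-matcher subtlety: a λ = 0 observer's *estimated* window tables
carry sampling noise, so its mean ICD is slightly positive; the exact zero
point of the scale is defined by the noise-free matcher profile, which the
tests assert separately.

## Problem sizes and runtime

Full-scale sequence selection (10,000 × 672 items, three levels) runs in
seconds thanks to a vectorized transition-count path (verified in the
tests against a per-sequence brute-force oracle); the recovery experiment
(100 simulated observers × 1120 trials plus scoring) takes well under a
minute. The unit-test suite uses reduced pools (30–500 candidates,
sequences of 100–300 items) wherever the property under test does not
depend on scale; the acceptance-grade checks in
`tests/testthat/test-acceptance.R` and the `analysis/` scripts run the
full design sizes.

## Known limitations

* The level-2 topology, while the minimal ergodic two-successor design, is
  one of several valid 8-context assignments; alternatives can be supplied
  by constructing a `markov_model` with a custom table.
* PI-based session termination is exposed only as the
  `reached_criterion()` predicate; multi-day scheduling is out of scope.
* The strategy index inherits the smoothing floor: exact maximizers score
  $\approx \log(1/\varepsilon)$-sized values, so indices are comparable
  only at a fixed ε (default $10^{-6}$).
* File formats are deliberately plain CSV/YAML with items as letters A–D;
  glyph rendering, timing and response-hardware concerns live outside the
  package.
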