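---
title: "Modeling reciprocity motives in multiplier trust games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reciprocity motives in multiplier trust games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

In a Trust Game the Investor sends part of a 10-token endowment to the
Trustee; the investment is multiplied before arrival, and the Trustee
freely decides how much to return. Because Trustees typically return about
half of the multiplied amount, two different motives — a preference for
equal payoffs and an aversion to disappointing the Investor's expectation —
predict the same behavior and are confounded. The hidden-multiplier variant
(HMTG) breaks the confound by secretly varying the true multiplier (×2, ×4
or ×6, with the Investor believing ×4 throughout; a raised variant uses
×4/×6/×8 with believed ×6), and the false-belief variant (FBMTG) inverts
this by varying the Investor's believed multiplier around a fixed true ×4.
`trustmotives` implements the task structures, the competing utility
models, the fitting and model-comparison machinery, the parameter-space
classification of motives, the stability statistics, and a synthetic-agent
generator that makes the whole pipeline testable end to end.

## Models and assumptions

All quantities are per single-shot trial; there is no learning or belief
updating across trials. For investment $I$, true multiplier $M_2$ and
believed multiplier $E_1(M_1)$, the Trustee chooses an integer
back-transfer $S_2 \in \{0,\dots,I M_2\}$. Utility sources:

$$\pi_2 = \frac{I M_2 - S_2}{I M_2}, \qquad
Guilt_2 = \left(\frac{\tfrac12 E_1(M_1) I - S_2}{E_1(M_1)\, I}\right)^2,
\qquad
Inequity_2 = \left(\frac{I M_2 - S_2}{10 - I + I M_2} - \tfrac12\right)^2.$$

The second-order expectation is fixed at half the believed amount for every
participant — a deliberate homogeneity assumption that buys generality at
the cost of ignoring individual differences in expectations. The moral
strategy (MS) model combines the terms as

$$U_2(S_2) = \Theta\,\pi_2 - (1-\Theta)\,
\min(Guilt_2 + \Phi,\; Inequity_2 - \Phi),$$

so that $\Theta$ trades payoff against moral concern and $\Phi$ biases the
min operator toward the guilt obligation ($\Phi < 0$) or the inequity
obligation ($\Phi > 0$); at $\Phi \approx 0$ the model follows whichever
obligation is cheaper per condition, which is exactly the morally
opportunistic pattern. The unitary models are GR ($U = \pi_2$),
IA ($U = \pi_2 - \Theta\,Inequity_2$) and GA ($U = \pi_2 - \Theta\,Guilt_2$).
Predictions are exhaustive argmaxes over the discrete strategy space; no
continuous relaxation is involved, so the prediction operator is exact.

### A note on the inequity exponent

The guilt term is unambiguously squared; the inequity term is implemented
squared as well, mirroring the guilt term's form (and the quadratic
Fehr–Schmidt-style loss it descends from). With a linear inequity term the
MS min-operator would compare a quadratic against a linear loss on
different scales, which breaks the interpretation of $\Phi$ as a symmetric
bias. Symmetric advantageous/disadvantageous inequity weights are out of
scope.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| endowment | tokens | 10 | the task's standard endowment |
| n_trials | trials/block | 80 | the task's standard block length; 25/50/25 condition split realized as exact counts 20/40/20 |
| MS $\Theta$ | – | fit on $[0, 0.5]$ | the classification grid's domain; $\Theta = 1$ would reduce MS to greed, but beyond 0.5 behavior is already greed-dominated |
| MS $\Phi$ | – | fit on $[-0.1, 0.1]$ | the classification grid's domain; the guilt/inequity terms live in $[0, 0.25]$, so $\pm 0.1$ spans full regime reversal |
| GA/IA $\Theta$ | – | fit on $[0, 200]$ | see below |
| n_restarts | – | 1000 | dense multi-start for a piecewise-constant objective; tests use 40–400 with fixed seeds |
| SSE exclusion threshold | squared tokens | 10 (strict) | AIC needs $\log(SSE)$; near-perfect fits are excluded from comparison but kept for classification |
| grid resolution | – | 101 × 101 | 10,201 simulation points |
| noise_sd | tokens | 1 | see the generator section |
| zone margin | grid steps | 3 | agents sampled at least 3 steps inside a zone so the generating label is unambiguous |

The GA/IA loss weight lives on a different scale from the MS $\Theta$
because it multiplies a squared normalized fraction. The bound must be
large enough that, at the bound, a one-token deviation from the moral
optimum costs more than the linear payoff gain on every stimulus;
the worst case over investments 1–10 and multipliers 2–8 requires a weight
of about 100, so the bound is 200. With a bound of 20 the fitted models
could never reach their theoretical limit patterns (e.g. the GA argmax at
weight 20 is 18/19/19 across the ×2/×4/×6 conditions at full investment,
not the expectation 20/20/20), which would distort both the standard-game
confound and model comparison.

## Numerical choices

- **Tie-breaking.** Among utility-maximizing back-transfers the smallest is
  returned: the Trustee keeps more among equally good options. This makes
  predictions deterministic; it matters at $\Theta = 0$, where payoff has
  zero weight and plateaus of exactly equal utility appear.
- **Zero investment.** $I = 0$ makes the payoff and guilt denominators
  vanish. Such trials are rejected by the utility operators and excluded
  from fitting; the generator never produces them (investments are drawn
  from 1–10).
- **Optimizer.** The SSE objective is piecewise constant in the parameters
  (argmax predictions change only at finitely many breakpoints), so
  gradient-based refinement is useless. `fit_model()` evaluates uniform
  random starts inside the bounds and refines the best five by a
  shrinking-step compass search (initial step 1/8 of the range, halved on
  failure down to 1/4096), keeping the overall best. Restart sampling is
  prefix-stable: the first $m$ starts of an $n$-restart run ($m<n$, same
  seed) are identical to an $m$-restart run, so more restarts can only
  improve the solution.
- **Archetype rounding.** Canonical patterns round half-integer targets
  *down*, matching the argmax tie-break (both neighbors of a half-integer
  optimum are equally good, and the tie goes to the smaller).
- **Stuart–Maxwell degeneracy.** When the marginal-difference covariance is
  singular (e.g. an empty strategy category) the test falls back to a
  Moore–Penrose generalized inverse with rank-based degrees of freedom and
  reports the fallback.
- **Seeds.** All stochastic stages take a single top-level seed;
  per-record and per-model child seeds are derived deterministically so any
  subset of fits or simulations is reproducible in isolation.

## The strategy map

The map is built from model simulations only — never from participant
data — so maps for different task variants are directly comparable. The MS
model is simulated at all 10,201 grid points over all combinations of
investment (1–10) and multiplier condition; grid points are clustered by
Euclidean distance between their simulated behavior vectors using Ward
linkage (compact, contiguous zones; the linkage is configurable since the
canonical choice is not uniquely determined); clusters are labeled by their
nearest theoretical archetype; and clusters sharing a label are merged.

Cutting at five clusters and merging yields the four motive zones in all
three task variants, but which regime splits differs: in the ×2/×4/×6 HMTG
and the FBMTG the moral-opportunism regime occupies two clusters (its
guilt-obligation and inequity-obligation halves), whereas in the ×4/×6/×8
HMTG the greed regime splits along its payoff gradient before the small IA
zone separates. A direct four-cluster cut is therefore not achievable for
the raised multiplier set under any of the standard linkages we examined
(Ward, average, complete; raw or normalized behavior vectors) — the
same-label merge makes the recipe uniform instead. Exact zone boundary
shapes depend on the linkage and are not a claim of this package; the
orientation of the zones (high $\Theta$ greed, low $\Phi$ guilt aversion,
high $\Phi$ inequity aversion, $\Phi \approx 0$ opportunism) is asserted by
the tests.

Participants are classified by the label of the nearest grid point to
their fitted $(\Theta, \Phi)$, with exact ties resolved toward lower
$\Theta$, then lower $\Phi$.

## What the generator emulates — and what it does not

`sample_population()` draws agents from a 40% IA / 10% GA / 40% MO / 10%
GR mixture (the distribution reported for student samples on this
paradigm), placing each agent's $(\Theta, \Phi)$ uniformly on grid points
at least three steps inside its strategy's zone. Zone boundaries shift
between multiplier contexts, so for multi-block studies the sampler takes
the maps of all blocks and samples from the intersection of the zones:
an agent only *embodies* a strategy across contexts if its fixed
parameters express that strategy in every context. Schedules realize the
condition counts exactly, draw investments uniformly from 1–10 (the
empirical investment distribution of the original studies is not public;
uniform support keeps all strategy-space regions identifiable), and
reuse the same investment sequence across blocks, mirroring the
within-participant design. Decision noise is additive Gaussian on the
returned amount (default sd 1 token), rounded and clipped to the feasible
range — a choice that keeps SSE-based fitting well-posed; a
softmax-choice noise model is deliberately out of scope.

Passing tests on these synthetic populations demonstrates internal
consistency of the pipeline — that parameters, labels, and their
population distribution are recoverable when the generating process *is*
the MS model. Real data differ in ways the generator does not emulate:
heterogeneous second-order expectations, non-Gaussian and
context-dependent decision noise, investment distributions concentrated
away from the identifiable range, and participants whose behavior no
utility model captures. Recovery rates here are therefore upper bounds on
what field data can support.

## Problem sizes

The test suite runs the full pipeline at reduced scale: 30 agents per
strategy group for model-comparison patterns and 100 agents across two
blocks for cross-context recovery, each with 100 restarts per fit;
Stuart–Maxwell calibration uses 10,000 simulated 4×4 tables of 200 pairs
drawn from a symmetric joint distribution (diagonal mass 0.6, uniform
symmetric exchange 0.4), a design chosen in advance for adequate
chi-square asymptotics. The oracle-equivalence check covers all four
models, all investments 1–10, every multiplier pair used across the task
variants, and a 21×21 parameter subgrid.

## Known limitations

- The classification depends on the clustering linkage near zone
  boundaries; only the zone orientation and recovery behavior are stable
  claims.
- AIC is undefined at SSE = 0; noise-free simulated participants are
  excluded from model comparison by the SSE < 10 rule, exactly as
  near-perfect human participants would be.
- The MS model nests the unitary patterns, so on noise-free unitary
  behavior MS ties the generating model on SSE and model selection rests
  on the complexity penalty alone.
- Cross-context label stability holds for agents sampled in zone
  intersections; agents near a context-dependent boundary genuinely change
  label between multiplier sets, which is a property of the model family,
  not a pipeline defect.

## A minimal session

```{r example}
library(trustmotives)

cfg <- make_hmtg_config(c(2, 4, 6), believed = 4, n_trials = 80)
map <- build_strategy_map(cfg, n_clusters = 5)

agents <- sample_population(12, map, noise_sd = 1, seed = 42)
study <- generate_study(agents, list(hmtg = cfg), seed = 42)

labels <- classify_study(study$behavior, map, n_restarts = 200, seed = 7)
table(
  truth = agents$strategy[match(labels$participant_id, agents$agent_id)],
  recovered = labels$label
)
```
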