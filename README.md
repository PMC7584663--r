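# trustmotives

Why do people return money in a trust game? Returning half of a windfall is
consistent with at least two very different psychological motives: avoiding
unequal payoffs (**inequity aversion**) and avoiding the guilt of
disappointing a partner's expectations (**guilt aversion**). In the standard
Trust Game these motives predict identical behavior and cannot be told
apart. `trustmotives` implements the analysis pipeline for two task variants
that break this confound — the **Hidden Multiplier Trust Game** (HMTG),
where the true multiplier applied to the investment varies while the
Investor believes it fixed, and the **False-Belief Multiplier Trust Game**
(FBMTG), where the Investor's believed multiplier varies while the true one
is fixed — and for classifying each Trustee's *reciprocity motive*: greed
(GR), guilt aversion (GA), inequity aversion (IA), or context-dependent
moral opportunism (MO).

It is intended for behavioral and decision scientists who want to fit and
compare Trustee utility models, classify participants' motives, test the
stability of motive distributions, or run simulation-based recovery studies
of this paradigm.

## The models

On a trial the Investor invests *I* of a 10-token endowment; the Trustee
receives *I·M₂* tokens (*M₂* the true multiplier) and returns an integer
*S₂ ∈ {0, …, I·M₂}*. The Investor believes the multiplier is *E₁(M₁)*, and
the Trustee assumes the Investor expects half of the believed amount back,
*E₂(E₁(S₂)) = ½·E₁(M₁)·I*. Three utility sources are defined:

- payoff: π₂ = (I·M₂ − S₂) / (I·M₂)
- guilt: Guilt₂ = ((E₂(E₁(S₂)) − S₂) / (E₁(M₁)·I))²
- inequity: Inequity₂ = ((I·M₂ − S₂) / (10 − I + I·M₂) − ½)²

Four decision models map these to utility:

| model | utility | free parameters |
|-------|---------|-----------------|
| MS (moral strategy) | Θ·π₂ − (1−Θ)·min(Guilt₂ + Φ, Inequity₂ − Φ) | Θ ∈ [0, 0.5], Φ ∈ [−0.1, 0.1] |
| GA (guilt aversion) | π₂ − Θ·Guilt₂ | Θ ∈ [0, 200] |
| IA (inequity aversion) | π₂ − Θ·Inequity₂ | Θ ∈ [0, 200] |
| GR (greed) | π₂ | none |

Predicted behavior is the exhaustive argmax Ŝ₂ = argmax U₂(S₂) over the
discrete strategy space. Models are fit per participant by multi-restart
bounded least squares and compared with AIC = n·ln(SSE/n) + 2k. Motives are
classified by simulating the MS model at 10,201 (101×101) equidistant
points of the Θ–Φ space, hierarchically clustering the simulated behavior,
labeling clusters by their nearest theoretical archetype, and locating each
participant's fitted (Θ, Φ) in the resulting zones. Stability analyses
include test–retest Pearson correlations, inter-participant parameter-space
distances, the Stuart–Maxwell test of marginal homogeneity on strategy
transitions, and prevalence chi-square comparisons.

## Worked example

Build the ×2/×4/×6 HMTG, derive its strategy map, simulate a small agent
population with one token of decision noise, and recover each agent's
motive end to end:

```r
library(trustmotives)

cfg <- make_hmtg_config(c(2, 4, 6), believed = 4, n_trials = 80)
map <- build_strategy_map(cfg, n_clusters = 5)
map
#> <strategy_map: 10201 grid points (101 x 101), HMTG game>
#>
#>   GR   GA   IA   MO
#> 2723 1160 1859 4459
```

The map partitions the parameter space into the four motive zones (grid
points per zone shown above). Simulate twelve agents and fit all four
models to the first one:

```r
agents <- sample_population(12, map, noise_sd = 1, seed = 42)
study  <- generate_study(agents, list(hmtg = cfg), seed = 42)

fits <- fit_models(study$behavior[study$behavior$participant_id == "agent001", ],
                   n_restarts = 200, seed = 1)
fits[, c("model", "theta", "phi", "sse", "aic")]
#> # A tibble: 4 × 5
#>   model  theta     phi   sse   aic
#>   <chr>  <dbl>   <dbl> <dbl> <dbl>
#> 1 MS     0.246 -0.0464    44 -43.8
#> 2 GA     2.66  NA        120  34.4
#> 3 IA     3.48  NA        386 128.
#> 4 GR    NA     NA       4882 329.
```

The integrative MS model fits this (morally opportunistic) agent far
better than any unitary model even after the two-parameter AIC penalty.
Classifying all twelve agents recovers every generating motive:

```r
labels <- classify_study(study$behavior, map, n_restarts = 200, seed = 7)
table(truth = agents$strategy[match(labels$participant_id, agents$agent_id)],
      recovered = labels$label)
#>      recovered
#> truth GR GA IA MO
#>    GR  1  0  0  0
#>    GA  0  1  0  0
#>    IA  0  0  5  0
#>    MO  0  0  0  5
```

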