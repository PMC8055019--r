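---
title: "Hawk-dove conflict under power asymmetry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hawk-dove conflict under power asymmetry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hawkdovenet)
```

## The model

`hawkdovenet` simulates repeated games of conflict in a population of `N`
agents who differ in competitive ability. Two agents contesting a resource
simultaneously play *hawk* (aggressive) or *dove* (deferential). With
payoffs ordered `hd > dd > dh > hh` and all non-negative, the stage game
between a higher-ranked agent *i* and a lower-ranked agent *j* is

|            | j: hawk   | j: dove |
|------------|-----------|---------|
| **i: hawk**| `f`, `hh` | `hd`, `dh` |
| **i: dove**| `dh`, `hd`| `dd`, `dd` |

The only place rank enters is the hawk-hawk cell: the ranking agent wins
the entire contested reward `f` (a rank-order contest, not graded by rank
distance) while the outranked agent receives `hh`. `f = 0` recovers the
symmetric baseline game in which rank is irrelevant; `f = 1 = hd` means a
ranking agent can extract the maximum payoff by fighting. If the two
contestants have exactly equal payoff accumulators (possible in the
dynamic-ranks variant, essentially only in early rounds) each receives
`f/3` — an even chance at the resource minus a conflict cost.

Defaults are `dh = 0.4`, `dd = 0.6`, `hd = 1`, `hh = 0`. The first two are
the canonical values for this model family; `hd` and `hh` are natural
normalizations (the full resource worth 1, the defeated aggressor getting
nothing) consistent with the required ordering and with the interpretation
of `f` ranging over `[0, 1]`.

### Roles, learning, and the round loop

Each round every agent visits exactly one other agent; an agent can host
any number of visitors (0 to `N − 1`). Agents condition behavior on their
role: they keep separate hawk/dove reinforcement weights for hosting
(`w_H, w_D`) and visiting (`w_h, w_d`), plus a vector of outgoing network
weights (`w_i1, ..., w_iN`, `w_ii = 0`) governing whom they visit. Choice
probabilities follow the Roth-Erev rule with a tremble,

$$\Pr(s) = (1-\epsilon)\,\frac{w_s}{\sum_{s'} w_{s'}} + \frac{\epsilon}{|S|},$$

and at the end of each round every weight is discounted by `(1 − δ)` while
chosen actions gain their realized payoff (network ties gain `v · payoff`,
where `v` rescales the speed of partner-choice learning relative to
strategy learning). Updates are simultaneous: all payoffs are computed
from pre-round weights and applied once. Visitors update their visiting
strategy and the tie they used; hosts update only their hosting strategy —
an agent controls whom it visits but not who visits it. Payoffs earned in
one role never touch the other role's weights.

Strategy weights start at 1; network weights start uniform at
`L/(N − 1)`, so with the default `L = 19` and `N = 20` every tie starts at
weight 1 and the in-weight variance is exactly 0.

### The three variants

* **`random_interaction`** — the network is frozen at its uniform
  initialization; partners are effectively uniform draws. Ranks are a
  fixed random permutation.
* **`partner_choice`** — outgoing ties learn by reinforcement; the
  interaction network coevolves with behavior. Ranks fixed.
* **`dynamic_ranks`** — partner choice plus ranks recomputed every
  `rank_update_interval` rounds (default 1,000, which averages out
  tremble noise) from accumulated payoffs, so wealth confers power.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|-----------|---------|-------|---------|
| `f` | — | payoff | reward to the ranking agent in hawk-hawk contests |
| `dh`, `dd`, `hd`, `hh` | 0.4, 0.6, 1, 0 | payoff | stage-game payoffs |
| `delta` | 0.01 | /round | geometric discount of all weights |
| `epsilon` | 0.01 | prob. | tremble (exploration/error) rate |
| `v` | 1 | — | network-learning speed multiplier |
| `L` | 19 | weight | initial total outgoing network weight |
| `N` | 20 | agents | population size |
| `rank_update_interval` | 1000 | rounds | rank refresh cadence (dynamic) |

The tremble must be positive: exploration by error is what lets ranking
agents discover that aggression pays and lets others learn to avoid them.
We fix `epsilon = 0.01` once, a conventional choice for Roth-Erev
simulations. Outcome *fractions* (conflict shares, convention prevalence)
are insensitive to moderate changes of `epsilon`, but the count of agents
classified as "pure hawks" at the 0.8-likelihood threshold is not:
diagnostics with `epsilon` in {0.001, 0.005, 0.01, 0.02} at `f = 0.7`
yield pure-hawk fractions of roughly 51%, 36%, 25%, 21%. Comparisons of
pure-hawk counts against external reference values should be read with
this sensitivity in mind.

## The rank accumulator: raw, not discounted

In the dynamic-ranks variant, ranks are recomputed from a per-agent payoff
accumulator. Two readings are defensible: the raw cumulative sum of
payoffs, or a discounted accumulator `C ← (1 − δ)C + π` that tracks
recent income. We implement both (`discount_rank_accumulator`) and default
to the **raw sum**, for three reasons established during development:

1. With a discounted accumulator (memory ≈ `1/δ` = 100 rounds), rank order
   is dominated by short-run luck in visitor arrivals; ranks churn
   stochastically even below the critical asymmetry where the hierarchy
   should be quiescent. With the raw sum, rank order freezes once
   accumulated stocks separate.
2. Rank-strategy-network cycle lengths under the raw sum decrease cleanly
   and monotonically in `f` (at 500k rounds: ≈83k, 57k, 25k, 15k rounds
   for `f` = 0.4, 0.6, 0.8, 1.0), matching the qualitative account of
   shorter cycles under stronger asymmetry; the discounted version
   compresses all cycles toward the rank-update cadence and blurs this
   ordering.
3. The raw sum is the literal meaning of ranking agents "based on
   cumulative payoffs", and makes the economic story coherent: a bully's
   hoard is overtaken only when isolated long enough for cooperators'
   steady income to outgrow it — which is exactly what sets the cycle
   timescale.

Exact accumulator ties are then possible in principle (payoffs are sums of
a few rational values), and are resolved by the `f/3` rule in hawk-hawk
meetings and by a stable sort (previous rank order preserved) at rank
updates. In practice ties vanish after the first few rounds.

## Analytic layer

Under random matching, an agent of rank `r` outranks a uniformly random
opponent with probability `R = (N − r)/(N − 1)`, and faces an *expected*
2×2 game identical to the stage game except for the hawk-hawk entry
`R·f + (1 − R)·hh`. Hawk strictly dominates dove in that expected game iff
`R·f + (1 − R)·hh ≥ dh` (the hawk-vs-dove column already favors hawk since
`hd > dd`). Hence:

* the set of dominance-solvable ranks is empty iff `f < dh` (for
  `hh < dh`), becomes `{1}` exactly at `f = dh`, and grows downward from
  the top as `f` rises — independent of `N` and of every other parameter;
* for an outranked agent facing opponents who play hawk with probability
  `P`, dove is the better reply in both roles once
  `P > (hd − dd) / ((dh − dd) − (R·f − hd))`.

This single critical point `f = dh` is the phase transition of all three
simulation variants: below it conventions cover the whole population;
above it the top-ranked agent(s) break off; and in the dynamic variant it
is where cycles first emerge.

## Summary metrics

* **Strategy classes** — from tremble-free probabilities
  (`p = w_hawk/(w_hawk + w_dove)` per role) at the 0.8-likelihood
  threshold: `pure_hawk` (hawk at home and away — the conservative bully
  definition), `pure_dove`, `ownership` (hawk at home, dove away),
  `host_guest` (dove at home, hawk away), else `mixed`. A population
  convention label requires a strict majority of non-pure-hawk agents in
  one convention class.
* **Network centralization** — the sample variance (denominator `N − 1`)
  of the in-weight column sums of the row-normalized visit matrix,
  tremble excluded. The sample variance and the tremble-free
  normalization are forced by the two benchmarks the measure must
  reproduce: 0 for the uniform initial network and 17.95 for the `N = 20`
  star (19 spokes visiting the hub with probability 1).
* **Interaction fractions** — the partition of interactions in a window
  into hawk-hawk, host-guest (visitor hawk/host dove), ownership
  (visitor dove/host hawk), and dove-dove.
* **Cycle length** — per agent, the lag of the first local maximum of the
  autocorrelation of the rank time series (at rank-update resolution)
  that exceeds the white-noise band `1.96/√T`, averaged over agents;
  agents without such a peak carry a no-cycle marker. The estimator is
  deterministic and parameter-light, and recovers the exact period of
  noiseless synthetic signals and periods within one rank-update interval
  under 10%-of-range noise. Because the autocorrelation is scale-free, a
  pair of mid-hierarchy neighbours slowly leapfrogging can register as a
  "cycle" for those two agents even when the hierarchy as a whole is
  quiescent; population-level statements should therefore use the
  *fraction of agents* with a detected period (≲ 25% below the critical
  `f`, ≳ 90% above it in our runs) and evaluate the estimator on the
  post-transient half of the rank history.
* **Welfare and inequality** — total of undiscounted cumulative payoffs,
  and their Gini coefficient (0 = perfect equality; the variance is also
  reported as an alternative dispersion measure).

## Numerical and reproducibility choices

* **RNG order is frozen**: initial rank permutation; then per round,
  visit targets for agents 1..N, visitor actions 1..N, host actions
  grouped by host index ascending (visitors ascending within a host). All
  draws come from R's global RNG, so a run is fully reproducible from
  `(config, seed)`.
* **Two engines, one trajectory**: the production loop is C++ (Rcpp); a
  straight-line loop-per-agent R reference implements the identical
  arithmetic in the identical order, and the test suite asserts
  bit-for-bit equality of trajectories for all three variants. The
  compiled engine runs a 200k-round, `N = 20` simulation in well under a
  second.
* **Degenerate cases**: an all-zero weight vector (reachable only with
  `epsilon = 0`) falls back to uniform choice; an all-zero payoff vector
  has Gini 0 by definition; rank updates require at least 3 recorded
  updates before cycle estimation.
* **Self-visits are structurally impossible**: the self-tie weight is
  identically 0 and the tremble mass is spread over the other `N − 1`
  agents only.

## What the simulations do and do not show

All quantitative claims shipped with the package are computed at desk
scale: 200k rounds per run (500k where slow network learning needs longer
to converge), with 6–20 seeds per condition; the full-scale study design
(1M rounds × 200 seeds per grid point) is reproduced in miniature, not
replicated. At this scale the phase structure, convention selection,
conflict fractions, welfare/inequality ordering, and cycle phenomenology
are stable, but (a) quantities tied to the exact critical point `f = dh`
are marginal — weak dominance at `R·f = dh` means the first bully's
emergence time diverges at the boundary, so supercritical behavior is
checked at `f ≥ 0.5`; and (b) seed-to-seed variability of maximum
centralization at low `f` is large (homogeneous-to-star outcomes coexist),
so the location of the centralization peak on a 0.1-grid of `f` is the
least stable reported quantity.

The model emulates none of the following features of real social systems:
payoff noise, population turnover, communication or coalition formation,
partner rejection by hosts, or costs of maintaining ties. Conclusions
transfer to real data only insofar as those omissions are acceptable.

## A worked example

```{r, eval = FALSE}
cfg <- sim_config("dynamic_ranks", N = 20, rounds = 200000,
                  payoffs = payoff_params(f = 0.6), seed = 1)
traj <- run_simulation(cfg)
summarize_run(traj, window = c(0.5, 1))
estimate_cycle_length(traj$rank_history, cfg$rank_update_interval)
```
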