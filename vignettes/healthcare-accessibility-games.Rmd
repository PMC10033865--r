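---
title: "Modelling healthcare accessibility as a congestion game with belief learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling healthcare accessibility as a congestion game with belief learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elfarolcare)
```

## The model in one page

A tertiary hospital is a congested shared resource: a visit is worth making
only while total attendance stays within the hospital's effective capacity.
`elfarolcare` stacks three model layers.

**Layer 1 — the attendance game.** In the generalized El Farol bar game,
each of $N$ players picks an action $j \in \{0,\dots,k-1\}$; action 0 always
pays 0, and action $j \ge 1$ pays $w_{ij}H$ if the sum of all actions is at
most the capacity $c$ and $-w_{ij}L$ otherwise, with $H, L > 0$. Viewing the
opponents as independent mixed strategies, a player's expected payoff from
attending is $H - (H+L)\,P(\text{opponent demand} \ge c)$, so the best
response is to attend exactly when that Poisson-binomial tail probability is
at or below the indifference level $u = H/(H+L)$. Fictitious play tracks the
empirical frequency of every player's past actions and best-responds to it;
its rest points are the pure Nash equilibria, which for this game are
exactly the profiles whose actions sum to $c$ (with $k$ actions, the
per-player equilibrium actions $j(i)$ satisfy $\sum_i j(i) = c$).

**Layer 2 — daily belief learning.** A representative patient holds a
belief $p_t$ that the hospital is accessible, updated from the observed
daily visit series by the balance equation
$$p_t = (1-\omega)\,p_{t-1} + \omega\, s_t,$$
where $s_t \in [0,1]$ is a reward signal computed from the most recent $d$
days of counts and $\omega \in (0,1]$ is the learning rate (equivalently,
how fast older experience is discounted). Because the update is a convex
combination, unrolling it gives hard envelopes
$(1-\omega)^{t-1}p_1 \le p_t \le 1-(1-\omega)^{t-1}(1-p_1)$, attained on
all-unfavourable and all-favourable histories; every simulated trajectory
is asserted against this envelope in the test suite.

**Layer 3 — the payoff of attending.** Service quality enters through a
composite index: each indicator is standardised as the ratio of the
hospital's value to the national value, mapped to a signed comprehensive
index, and summed within a gain category ($H$) and a loss category ($L$).
The expected net benefit of a visit at belief $p$ is the affine map
$E = Hp - L(1-p)$, with slope $H+L$ and extremes $-L$ (at $p=0$) and $H$
(at $p=1$). With the packaged indicator table ($H = 1.55$, $L = -0.72$;
note the loss-side sum is legitimately negative and the formula is applied
to the signed values) the minimum of $E$ over $p \in [0,1]$ is
$\min(H, -L) = 0.72 > 0$: attending retains positive expected value even
under maximal pessimism, and $E$ is perfectly positively correlated with
$p$ since $H + L = 0.83 > 0$. A first-stage hospital-versus-pharmacy game
consumes this $E$ through `pharmacy_game_matrix()`, whose four cells are
$0$, $e$, $E$, and $E+e$; the pipeline stops at constructing that matrix.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `threshold` (c) | daily visit count at or below which a day is favourable | 1250 | round figure near the annual mean (≈1239) of the modelled outpatient year |
| `learning_rate` (ω) | weight on the newest signal | 0.2 | slow enough to average a week-scale history, fast enough to track months |
| `initial_p` | prior belief before any observation | 0.5 | uninformative prior |
| `window_days` (d) | days of counts consulted per update | 1 | the one-day observer; sweeps use 1–7 |
| `signal_rule` | how a window becomes a signal | `fraction` | see below |

A day is favourable when its count is **at or below** the threshold (the
weak inequality mirrors the game's "at most capacity" payoff rule), and
"days with $p$ above one half" counts strict exceedances.

**Why `fraction` is the default window rule.** How a multi-day observation
window should enter the one-signal update is a genuinely open design
choice. Three rules are provided: `fraction` (share of window days at or
below threshold), `all` (1 only if every window day is favourable), and
`mean` (window mean compared to threshold). `fraction` is the default
because it is the only rule for which setting the threshold at the
empirical median provably balances the signal: the long-run mean signal is
then one half for every window length, so the long-run mean belief settles
at $0.5 \pm 0.03$ for windows of 1–7 days — the median-threshold
invariance that the acceptance analysis checks. The conjunctive `all` rule
breaks that invariance by construction (its signal mean decays with window
length), so the decline of the mean belief with longer observation windows
on real crowded data is treated as a data-dependent effect, not an
identity.

**Warm-up and reporting conventions.** The prior sits at day 0 and is never
reported; the first reported belief is $p_1$, after one observed day. Early
days use however many days exist (no days are dropped), so a 366-day series
yields 366 reported beliefs. Reported table means are conventionally
rounded to 3 decimals; raw values are returned.

**Emergency mode.** Emergency patients are modelled as committed attenders:
prior $p = 1$, one-day window, and the threshold set to the annual mean of
the emergency series rounded to the nearest integer. The packaged monthly
reference table of emergency beliefs ranges over $[0.8, 1]$ with annual
mean 0.898 (to 3 decimals).

## The synthetic data generator

The confidential daily outpatient series the model was designed around is
not shippable, so `default_outpatient_config()` emulates its published
statistical signature: 366 days starting 2020-01-01, annual mean near
1,238.9 visits/day, median near 1,350, strong weekday structure with Monday
the busiest day (specialist scheduling plus weekend backlog) and deep
weekend lows, a February trough with a 7-day festival dip, and mild
negative-binomial overdispersion. Counts are Gamma-Poisson: day $t$ draws a
Poisson count around a Gamma-mixed rate with mean
$\lambda \cdot m_{\text{month}} \cdot w_{\text{weekday}}$ and variance
$\mu(1+\phi\mu)$; $\phi = 2\times 10^{-4}$ keeps day-to-day noise at a
realistic few-percent scale. The weekday/weekend asymmetry makes the count
distribution left-skewed, which is exactly why the median (1,350) sits
above the mean (1,239) — the generator reproduces that ordering by
construction, and the calibration is verified across ten seeds in the test
suite. The emergency preset uses a base rate of 150 visits/day — a
realistic emergency load for a tertiary hospital, an order of magnitude
below outpatient volume (no published figure constrains it) — with a flat
weekday profile, since emergency arrivals do not follow specialist
scheduling.

What the generator does **not** emulate: epidemic waves and lockdown
regimes (the modelled year is pandemic-shaped only through seasonality
knobs), autocorrelated shocks, and patient-level heterogeneity. Passing
tests on this synthetic data therefore demonstrate the model's internal
properties (envelopes, monotonicities, median invariance), not agreement
with any particular hospital's numbers.

## Numerical choices

- **Poisson-binomial tail.** Exact dynamic-programming convolution,
  $O(m^2)$; verified against full $2^m$ enumeration for $m \le 10$.
- **Tie-breaking.** In the binary game the attendance tie (tail exactly
  equal to $u$) goes to attending, matching the weak best-response
  inequality; in the generalized argmax, ties break toward the lowest
  action index. Both are deterministic; at $k = 2$ they can disagree only
  on an exact tie, which has measure zero in the simulations used.
- **Weak capacity inequality everywhere.** "At most $c$ wins" is used in
  payoffs, best responses, and the generalized expected payoff
  $u_{ij} = w_{ij}(H+L)\,(u - P(Y_i \ge c-j+1))$.
- **Simultaneous updating.** All players update each step from the same
  snapshot of frequencies. A consequence worth knowing: from symmetric or
  generic initial beliefs the players' best responses coincide, their
  frequencies synchronize, and the play cycles (e.g. alternating
  everyone-attends / no-one-attends) instead of sorting into an
  equilibrium. Pure equilibria are absorbing and locally attracting — play
  started at or near a profile whose actions sum to $c$ converges to it —
  and that is the property the tests assert for the generalized game. The
  binary game with heterogeneous starts does sort itself into $c$
  attendees.
- **Convergence flag.** `has_converged()` flags a trajectory when no
  frequency moves by more than $10^{-6}$ over 100 steps — a scale suited to
  the $10^3$–$10^4$-step horizons used here.
- **Degenerate inputs.** Frequencies at $t = 0$ are undefined (division by
  $t$), so initial beliefs are supplied explicitly and counts accumulate
  from the first step. Thresholds may be half-integers so that an empirical
  median of an even-length series can be used verbatim.
- **Problem sizes.** The test suite uses horizons up to $10^4$ for the
  binary game, $1.5\times 10^3$ for the generalized game, exhaustive Nash
  scans to $N = 10$, and 1,000 randomized belief trajectories of 10–40
  days; everything runs in seconds on one CPU.

## Known limitations

- One representative belief per day: no patient-level heterogeneity or
  mixing of observation strategies within a population.
- The mapping from standardised indicators to comprehensive indices
  (the aggregative weighting) is taken as given in the packaged table; in
  computed mode the user supplies signed weights
  (index = weight × standard value). The package does not estimate weights.
- The published gain-side total 1.55 differs from its own column sum 1.56;
  both are exposed (`healthcare_payoff_index()` returns the published pair
  and attaches the recomputed sums as attributes).
- No queueing or waiting-time component, and no policy optimisation over
  the belief process; the hospital-pharmacy game is constructed but not
  analysed beyond its payoff matrix.
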