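---
title: "A barrier-probability model of vaccine-technology coverage impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A barrier-probability model of vaccine-technology coverage impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaximpact)
```

## The model and its assumptions

`vaximpact` estimates the vaccination-coverage change from replacing a
deployed vaccine presentation with a technologically improved one. The
population model is deliberately simple: an individual is vaccinated if and
only if they overcome every *technology-addressable* barrier, once per
required dose. Each barrier `i` has a population prevalence `p_i` — the
probability of failing it with no technological help — and each presentation
a technology score `v_i` — the fraction of that failure probability the
presentation removes. The per-trial pass probability is `1 − p_i(1 − v_i)`,
and with `D` doses the uncalibrated coverage is
`U = (∏_i [1 − p_i(1 − v_i)])^D`.

Three assumptions are load-bearing:

* **Independence.** Barriers are independent of one another, and doses are
  independent repetitions. This is hard-coded into the analytic path; real
  barriers surely co-occur (remote populations face both cold-chain and
  staffing gaps). The Monte-Carlo simulator (`simulate_agents()`) carries a
  correlation knob precisely so the direction of this bias can be probed —
  positively coupled failures *raise* true coverage above the independent
  product, because failures pile onto the same individuals. The knob exists
  only in the simulator; the analytic model never uses it.
* **Linear calibration.** Uncalibrated coverage ignores every barrier
  technology cannot touch, so `U` is mapped to observed coverage through
  `C = S·U + β`, a line through two anchors: the perfect presentation
  (`U = 1` ↦ `M`, the maximum coverage attainable through technology alone)
  and a *calibration vaccine* already deployed in the population
  (`U_c` ↦ its observed coverage `C_c`). The calibration soaks up
  non-technology barriers and some of the independence error, but linearity
  over wide `U` ranges is itself an approximation; choosing a calibration
  vaccine similar to the test presentation keeps the extrapolation short.
* **Proportional help.** A technology score removes the same *fraction* of a
  barrier everywhere: `v = 0.8` helps a population where the barrier is rare
  exactly as proportionally as one where it is ubiquitous.

The reported estimate is `C_t = M − k·x_t` with headroom `k = M − C_l` and
residual failure probability `x_t = 1 − (U_t − U_l)/(1 − U_l)`, where the
`l` subscript denotes the least-desirable presentation (all scores 0,
worst-case dose count `d_worst`). Expanding these definitions shows
`C_t = S·U_t + β` identically: the decomposition into headroom and residual
is for interpretation and auditing, and `d_worst` **cancels out of the final
estimate** — it shifts `C_l`, `k` and `x_t` in compensating ways. A
sensitivity sweep over `d_worst` therefore returns constant estimates; the
package still validates it (it must be at least the calibration vaccine's
dose count, or the "least desirable" presentation would outperform a real
one, which is rejected as a mis-specification).

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `p_i` | barrier prevalence, probability in [0, 1] | from indicators | resolved per region from prioritized proxies |
| `v_i` | technology score in [0, 1] | from rubric | five-level rubric, shipped scores below |
| `D` | doses required for full protection | per presentation | integer ≥ 1; non-integer "expected doses" are not accepted |
| `d_worst` | doses of the least-desirable presentation | 4 | worst multi-dose schedule in routine programs; cancels from `C_t` |
| `M` | max coverage via technology alone | per region input | e.g. the best observed coverage of any vaccine in the program |
| `C_c` | observed calibration-vaccine coverage | per region input | must not exceed `M` |
| channel shares | population served by routine vs campaign delivery | per region input | no public source defines them; user-supplied |

The shipped rubric (`default_rubric()`) maps the five levels Low → High to
scores per barrier, e.g. temperature storage `0, 0.25, 0.50, 0.80, 1` and
administration `0, 0.40, 0.70, 0.90, 1`. These are expert judgement, not
estimates from data, which is why they ship as a CSV
(`inst/extdata/rubric_default.csv`) that users can replace — `read_rubric()`
validates five levels per barrier, scores in [0, 1], monotone from Low to
High. Acceptability has two coexisting variants (a generic scale and one
specific to the presence of a pork product); no rule selects between them
automatically, so each presentation spec names its variant.

Population scores resolve through a priority hierarchy: the best-priority
non-missing proxy wins, and provenance (priority used, source) is logged per
region and barrier. Missingness is an explicit marker — a recorded 0 means
the barrier is absent. Indicators recorded with opposite polarity
(probability of *overcoming*, e.g. skilled birth attendance) set
`complement = 1` and are flipped on resolution rather than guessed.

## Channels, aggregation, equity

Routine immunization and supplementary immunization activities (SIAs) can
face different barrier sets: a barrier not applicable in a channel is
treated as absent from that channel's population (`p_i = 0`) — a population
property, not a technology property, though the product is numerically the
same either way. The full estimate runs per channel and the final coverages
are blended by population share. Averaging the final `C_t` (rather than
intermediate quantities) is a deliberate choice; with both channels facing
all barriers it provably collapses to the single-channel estimate, which the
tests assert.

Multi-country aggregates are birth-cohort-weighted means over *valid*
regions. Validity implements an extreme-value rule: when `M` and `C_c` are
far apart the scaling factor is large and `C_t` can exceed 100% — the model
is then overstating what technology can do (often the calibration vaccine is
under-deployed rather than under-teched). Such estimates are flagged, never
clamped (clamping would hide the misuse signal), excluded from aggregation,
and the excluded share of the birth cohort is always reported. Note
`C_t ≤ M` algebraically, so this can only trigger when `M > 1`; the package
deliberately accepts `M > 1` because administrative coverage reports do
exceed 100%, and rejecting them would make the exclusion rule unreachable.
`C_c > M` is rejected as an input error, and a calibration vaccine with
`U_c = 1` (no barriers faced) leaves the line undefined and is an error
rather than an infinite slope.

For subnational analyses the equity index
`E = 1 − Σ_i (max(c) − c_i)/(r − 1)` summarizes dispersion of the `r`
regional estimates: 1 means perfectly even coverage; each unit of average
shortfall from the best region subtracts proportionally.

## Numerical choices

* Probabilities are fractions in [0, 1] end to end; percent formatting (one
  decimal) happens only in reports (`format_percent()`).
* Channel shares must sum to 1 within 1e−9.
* Test tolerances: anchor identities of the calibration line hold to 1e−12;
  composed end-to-end identities to 1e−9; the enumeration cross-check to
  1e−12 (the oracle derives per-trial pass probabilities by outcome
  enumeration, whose operation order differs from the model's expression, so
  exact bit equality is not claimed).
* Ties in the gain ranking break lexicographically by region id, for
  deterministic output.
* Scenario runs have no hidden state: identical inputs give identical
  outputs, and every region's audit row carries `U_c`, `U_l`, `U_t`, `S`,
  `β`, `C_l`, `k`, `x_t`.

## The synthetic-data generator

Real inputs — coverage rates, survey-based barrier proxies, birth cohorts —
come from sources that cannot be redistributed here, so
`synthetic_spec()`/`generate_dataset()` emulate their *structure*: a
73-country dataset by default, uniform barrier prevalences in [0.01, 0.5],
calibration coverage in [0.4, 0.95] (the range seen for first-dose
measles-containing vaccine in low-income settings), a technology headroom of
`M − C_c` drawn from [0.02, 0.15] capped at `M = 1`, birth cohorts of
5×10⁴–5×10⁶, routine-channel shares in [0.6, 1], and 30% missingness at
priority 1 with priority 2 always present (so every barrier resolves, via a
jittered coarse fallback mimicking sub-regional averages). Uniform draws are
used throughout because nothing justifies a more opinionated distribution
and uniform covers edges well. Generation is seeded and byte-reproducible.

What the generator does *not* emulate: spatial and cross-barrier correlation
between countries, real marginal distributions, reporting biases, or any
country's actual values. Tests passing on synthetic data therefore
demonstrate the *machinery* — identities, monotonicity, exclusion handling,
exact recovery of planted calibration lines — not agreement with any
published multi-country figure, whose country-level inputs are not public.

The simulator `simulate_agents()` draws, per agent, every barrier-dose trial
and checks the empirical vaccinated fraction against the analytic product
(binomial-error agreement at correlation 0; bias direction at correlation
> 0 via a single shared Gaussian latent factor — a one-parameter testing
device chosen for simplicity, not a claim about real dependence structure).

## Problem sizes

The test suite exercises: 10,000 random calibration settings for the
identity checks; the full 5-point grid of `p` and `v` on 1–3 barriers with
1, 2 and 4 doses against the enumeration oracle; 18 Monte-Carlo cells of
100,000 agents; and 73-country synthetic scenarios end to end. These sizes
were chosen so each property is tested across its whole domain while the
entire suite stays comfortably interactive.

## Known limitations

* Independence of barriers is assumed, not tested against data; calibration
  only partially compensates.
* Rubric scores are expert guesses; revising them changes results and no
  uncertainty is propagated.
* Observed calibration coverage is attributed entirely to one presentation's
  technology scores, though multiple presentations usually co-circulate.
* The method cannot distinguish technology impact from incomplete rollout of
  the calibration vaccine — the exclusion rule flags the extreme cases but
  milder confounding passes through.
* No uncertainty intervals on aggregates; sensitivity sweeps (up to three
  parameters, Cartesian grids) are the supported what-if mechanism.
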