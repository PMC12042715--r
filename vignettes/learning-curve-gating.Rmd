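---
title: "Major-mistake learning curves and the Poisson dispersion gate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Major-mistake learning curves and the Poisson dispersion gate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcgate)
```

## The problem

Simulation-based surgical training produces a sequence of scored attempts.
Two performance signals are routinely recorded per attempt: the task
completion time (TCT, seconds) and a mistake score in which minor technical
errors contribute 1 point and critical, non-repairable errors 5 points. An
attempt whose total score reaches 5 is classified as containing a *major
mistake*; in the raw-data convention such attempts are aborted and carry a
total time of zero with absent stage times. `lcgate` asks two questions of
such a sequence:

1. How does the rate of major mistakes evolve with practice (the learning
   curve), and how fast does it fall in each phase of training?
2. When do the residual mistakes stop carrying information about skill —
   i.e. when do they become statistically indistinguishable from a random
   (Poisson) process?

The answer to the second question is an operational *efficient skill
threshold*: past it, further errors are attributed to chance rather than to
technical deficiency.

## The MMA learning curve

The headline index is the cumulative **major mistake average**,

$$\mathrm{MMA}(n) \;=\; \frac{\#\{\text{major-mistake attempts among } 1..n\}}{n},$$

i.e. a cumulative proportion accumulated from the first attempt of the
trial. The cumulative form is deliberate: the published worked values
(1/6 at attempt 6, 5/19 at the attempt-19 peak, 6/36 at attempt 36, 10/85
at attempt 85) are consistent only with accumulation from attempt 1, not
with per-period ratios. `mma_series()` computes it exactly (a ratio of
integers in double precision); presentation rounding — half away from zero,
3 decimals for MMA and 3–4 for drop rates — happens only in `print`
methods and `round_half_up()`, never inside the arithmetic.

`segment_periods()` partitions attempts into user-supplied periods (the
breakpoints are the last attempt of each period). For period $k$ ending at
attempt $e_k$, the starting reference is $\mathrm{MMA}(e_{k-1})$ (the
previous period's endpoint; for the first period, the curve's value at its
own first attempt), the ending value is $\mathrm{MMA}(e_k)$, the *absolute
drop* is their difference and the *drop rate* divides it by the period's
attempt count. Defined this way the drops telescope across any partition —
a property the test suite checks on random partitions. The default
breakpoints `c(5, 12, 19, 36, 85)` encode the six-period structure of a
132-attempt single-operator trial; no automatic change-point detection is
performed, because segmenting by inspection of the MMA trend is part of the
method being packaged, not a claim we add to.

Trend fits (`fit_trend()`) are ordinary least squares: `linear` for the TCT
series and `exponential` (least squares of $\log y$ on $x$) for the MMA
curve, with $R^2$ for the exponential model evaluated on the original scale
from back-transformed fitted values so the two models are comparable. A
constant response yields `r_squared = NA` rather than an arbitrary number.

## The Poisson dispersion gate

Per-attempt indicators are Bernoulli, and a Bernoulli variable is
structurally *under*-dispersed relative to Poisson (variance $\le$ mean),
so testing the raw indicators would be meaningless. The gate therefore
counts major mistakes in consecutive non-overlapping blocks of
`block_size` attempts (default 4 — one training session comprised roughly
four attempts). A trailing short block is dropped, not pooled, so block
counts are identically distributed under a constant hazard. The block size
is a genuine judgment call — the source analysis does not state its
blocking — and is therefore fully configurable and always reported.

Two conformity tests are provided, both reporting statistic, degrees of
freedom and threshold explicitly:

* `dispersion_test()` — the classical index of dispersion
  $D = (n-1)\,s^2/\bar{x}$ over $n$ blocks, referred to the upper tail of
  $\chi^2_{n-1}$. Overdispersion signals systematic error, so the default
  is one-sided. A *positive* verdict (failure to reject at level `alpha`,
  default 0.05, implied by the published 3.841 threshold) is read as
  "mistakes occur randomly".
* `gof_test()` — a binned chi-squared goodness of fit against
  Poisson($\hat\lambda$) with classes $\{0, 1, \ge 2\}$, merged downward
  from the top while an expected count is below 1 but never below two
  classes, with degrees of freedom (classes − 2) floored at 1.

`detect_plateau()` applies the chosen test to every period in order,
labels periods too short to bin as `untestable` (never silently skipping
them) and returns the first Poisson-positive period as the plateau.
All-zero periods are degenerate: trivially positive, and flagged as such.
The reported per-period `lambda` is always the per-attempt rate
(majors/attempts); published per-period lambda values match no single
consistent unit, so we document ours and leave it at that.

Two calibration caveats, both measured by the test suite rather than
assumed:

* The index-of-dispersion test is conservative when the expected total
  count is small: at $\lambda = 0.5$–$1$ per block with only 5 blocks its
  type-I error is roughly 0.013–0.027 at nominal 0.05 (the chi-squared
  approximation to the discrete statistic breaks down). From about 10
  blocks, or mean counts of a few per block, the nominal level is
  accurate.
* Binned Bernoulli counts are themselves slightly under-dispersed
  (binomial variance $np(1-p) < np$), which pushes the gate further toward
  conservatism — it errs on the side of *not* declaring randomness, the
  safe direction for a skill gate.

## The synthetic-data generator

`simulate_attempts()` emulates the assumed structure of a training
sequence: a three-phase per-attempt major-mistake hazard — constant
`p_unstable` in an unstable early phase, exponential decay
$p_{\mathrm{pl}} + (p_0 - p_{\mathrm{pl}})e^{-k(t - t_1 - 1)}$ in the
learning phase, constant $p_{\mathrm{pl}}$ in the plateau — plus a mean TCT
declining exponentially toward a floor with multiplicative lognormal noise.
The unstable phase is modelled as a constant hazard because the early
periods are described only as unstable, with no structure to copy; that
choice is an invention of this package and labelled as such. Minor-mistake
scores are generated independently of majors (minor errors were found
confounded and excluded from the headline index).

Defaults mirror the 132-attempt trial the method was developed on: phase
bounds (19, 85); `p_unstable = 5/19` (the observed unstable-phase
frequency); `p_plateau = 0.04` (≈ 2 majors in the 47 plateau attempts);
`p0 = 0.12`, `decay = 0.05` (a learning phase passing through the observed
5 majors in attempts 20–85); TCT from 2,523 s toward a 1,200 s floor
(`tct_decay = 0.03`, `tct_cv = 0.25`, matching the first/last-period
averages and the heavy observed scatter); minor-score probabilities
(0.45, 0.40, 0.15) and stage-time proportions (0.25, 0.25, 0.50) read off
the published 18-row raw-data sample; major mistakes assigned to stages
with probabilities (2/11, 8/11, 1/11), the observed stage breakdown. One
master seed deterministically derives separate sub-streams for mistakes
and times, so altering the time-noise model cannot perturb a simulated
mistake sequence.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: session effects (attempts after long breaks
being slower and more error-prone), any dependence between completion time
and error probability, specimen-difficulty variation, and non-exponential
learning shapes. It is a calibration instrument for the statistics, not a
behavioural model of a trainee.

`operating_characteristics()` reports negative-verdict rates on a
plateau-length segment under stationary, decaying (hazard halving at equal
mean) and step-change hazards, with replicates paired through shared
per-replicate seeds. `recover_parameters()` fits
$(p_0, p_{\mathrm{pl}}, k)$ by direct Nelder–Mead maximisation of the
exact Bernoulli log-likelihood under the transform
$p_{\mathrm{pl}} = \mathrm{logit}^{-1}(a)$,
$p_0 = p_{\mathrm{pl}} + (1 - p_{\mathrm{pl}})\,\mathrm{logit}^{-1}(b)$,
$k = e^{c}$ (which enforces $0 \le p_{\mathrm{pl}} \le p_0 \le 1$,
$k \ge 0$), starting from moment-based values with three decay starts to
cope with the flat ridge that appears when the hazard is near-constant. On
truly constant data the parameters $(p_0 - p_{\mathrm{pl}}, k)$ are not
separately identified — single fits may return a visible amplitude with a
fast decay — but the fitted hazard *path* collapses onto the constant
truth and the likelihood gain over the constant model stays at chance
level, which is the property the tests assert. Data with no majors at all
return a flagged boundary estimate rather than an optimiser failure.

## Numerical and design notes

* Absent cells (`"-"`) are absent, never zero; zero total time is itself
  meaningful. Thousands separators (`"1,159"`) are parsed.
* Lenient validation trusts `total_score` over stage sums (archival tables
  contain rows where they disagree); strict mode is for new data.
* Attempt numbering is 1-based throughout; dates are informational only.
* All internal arithmetic is full precision; rounding is presentation-only.
* Exit codes of the `lcgate` CLI: 0 success, 2 input/schema error, 3
  statistical preconditions unmet (e.g. every period untestable).

Problem sizes used by the test suite — chosen to estimate each property
comfortably: 200 random sequences (length ≤ 1,000) for the MMA oracle;
2,000 Poisson replicates per point of a 3×3 $(\lambda, n)$ grid for type-I
calibration; 1,500 paired replicates for the decaying-hazard power
ordering; 60 replicate fits at $n = 2{,}000$ attempts for the
parameter-recovery interval study.

## Limitations

The gate's verdict depends on the blocking; per-session blocks would be
preferable when session boundaries are recorded. No multiple-testing
correction is applied across periods (none is part of the method), and the
plateau decision is a first-crossing rule, not a change-point model. The
method was developed on a single operator; nothing in this package
addresses between-operator variability.
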