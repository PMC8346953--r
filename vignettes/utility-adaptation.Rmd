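---
title: "Measuring utility adaptation to reward distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring utility adaptation to reward distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utiladapt)
```

## The problem

When the range of rewards on offer changes, do the preferences inferred
from risky choice stay put, or do they re-anchor to the new range?
`utiladapt` implements the computational chain used to ask that question
with binary-choice data: a decision-maker repeatedly chooses between a
safe reward and an equiprobable two-outcome gamble while the *reward
distribution* — the interval of magnitudes in play — is held fixed for a
block of sessions and then switched (canonically `low` 0–0.5 ml, `high`
0.5–1.0 ml, `full` 0–1.0 ml, with a wide variant 0.1–1.3 ml).  Utility is
anchored at 0 at the block's minimum and 1 at its maximum, so curves
estimated in different blocks can be compared on the normalized unit
square.  Because trial-level data of this kind are not publicly
deposited, the package ships a synthetic-agent module that generates
choice data with exactly the structure the analysis assumes; every stage
is exercised end to end on simulated agents with known ground truth.

## The model

Choices follow a logit discrete choice model.  For options with outcome
magnitudes $m$ (normalized to the block's range) and probabilities $p$,

$$EU = \sum_i p_i \, U(m_i), \qquad
P(\text{left}) = \frac{1}{1 + e^{-\lambda (EU_L - EU_R) - \theta}},$$

with temperature $\lambda \ge 0$ (larger = more deterministic) and side
bias $\theta$ (positive favours the left option; the sign convention
follows the logit expression literally).  Probabilities are objective:
all gambles are equiprobable, where probability distortion is negligible,
so option value is plain expected utility.

Five parametric utility families are available, all mapping $[0,1]$ onto
$[0,1]$:

| family | form | parameters |
|---|---|---|
| `power1` | $m^\alpha$ | $\alpha$ |
| `tversky1` | $m^\gamma / (m^\gamma + (1-m)^\gamma)^{1/\gamma}$ | $\gamma$ |
| `prelec2` | $e^{-\beta(-\ln m)^\alpha}$ | $\alpha, \beta$ |
| `scdf2` | two-sided-power CDF with knot $\beta$ | $\alpha, \beta$ |
| `power3` | anchored piecewise power around $\gamma$ | $\alpha, \beta, \gamma$ |

Two reconstructions deserve flags.  The one-parameter `tversky1` form is
known in this literature only by name; it is implemented here as the
standard one-parameter inverse-S curve transplanted from probability
weighting to normalized magnitude, and the exact intended form cannot be
confirmed.  For `scdf2` the package implements the standard
CDF of the two-sided power distribution,
$U(m) = \beta (m/\beta)^\alpha$ for $m \le \beta$ and
$1 - (1-\beta)\left((1-m)/(1-\beta)\right)^\alpha$ above, and treats the
documented curvature behaviour ($\alpha > 1$ S-shaped with inflection at
the knot, $\alpha < 1$ inverse-S) as the authoritative contract — the
test suite verifies both claims.  `power3` is not intrinsically anchored,
so the raw piecewise curve is affinely rescaled to $U(0)=0$, $U(1)=1$;
since all magnitudes here are gains, its loss-aversion weight $\beta$ is
fixed at 1 during fitting by default (`fix_beta = FALSE` frees it).

Parameter bounds (exponents in $[0.05, 20]$, Prelec elevation in
$[0.05, 20]$, knots inside the unit interval, Tversky exponent $\ge 0.3$)
keep every curve monotone, finite and identifiable; the Tversky lower
bound matters because the canonical form loses monotonicity below
$\gamma \approx 0.28$.

## Certainty equivalents and the fractile ladder

A gamble's certainty equivalent (CE) is read from the psychometric
function fitted to the proportion of safe choices across a ladder of safe
magnitudes spaced 0.05 ml apart:

$$P(\text{choose safe}) =
  \frac{1}{1 + e^{-(\text{safe}_{ml} - x_0)/\sigma}},$$

whose inflection $x_0$ is the safe magnitude of indifference — the CE —
and $\sigma$ its temperature in ml.  The default objective is binomial
maximum likelihood on the per-magnitude counts (fitted as a logit GLM,
which is an exact reparametrization and weights magnitudes by their trial
counts); a count-weighted least-squares mode on the raw ratios is kept
behind `method = "ls"` for studies that fit the sigmoid that way.
Fits require at least three distinct safe magnitudes
each tested at least four times; flat or non-increasing response profiles
and temperatures above ten times the tested range are flagged degenerate
and yield no CE.

The fractile (bisection) procedure chains CEs into a utility ladder: the
CE of the min/max equiprobable gamble carries utility 0.5 (its expected
utility under any anchored curve, $0.5 \cdot 0 + 0.5 \cdot 1$); gambles
built between the minimum and that CE, and between the CE and the
maximum, yield utilities 0.25 and 0.75 (their trials interwoven in one
sequence); a third step yields 0.125 and 0.875.  CEs are taken from the
continuous fitted inflection rather than snapped to the 0.05 ml grid.  A
simulated CE landing within half a ladder step of a distribution bound
cannot seed a meaningful next-step gamble, so the session is flagged and
excluded from fractile bookkeeping; sessions yielding fewer than three
utility levels are discarded, mirroring the design's reliability filter.

## Fitting and model selection

`fit_dcm()` estimates each family's parameters plus $\lambda$ and
$\theta$ by bounded maximum likelihood (`L-BFGS-B`) from one heuristic
start plus Latin-hypercube draws within the bounds; the best converged
start is kept.  Likelihood contributions are clamped away from 0/1 by
$10^{-12}$; convergence uses a relative tolerance of about $10^{-10}$ on
the objective.  Utilities are evaluated once per unique normalized
magnitude (fractile ladders repeat few distinct values) and the smooth
one- and two-parameter families use analytic gradients, which makes a
full-session fit take milliseconds.

Models are compared by $BIC = k \ln n + 2\,(-LL)$ with $k$ counting the
utility parameters plus $\lambda$ and $\theta$ (counting the choice
parameters in `k` is a convention; `k` is recorded on every fit so the
alternative convention can be recomputed), and by 10-fold
cross-validation: folds are random, seeded and stratified by sequence
tag, refits warm-start from the full-data solution, and the score is the
mean held-out negative log-likelihood.  Implausible daily fits are
excluded by the pooled ln-parameter rule: any utility parameter whose log
lies more than three pooled standard deviations from the pooled mean
excludes that day; a zero-SD pool excludes nothing, and non-positive
parameters (log undefined) are excluded with an explicit reason.

## Adaptation metrics

Per distribution, daily fits are summarized by the **parameter-wise
median** curve (not the pointwise median of curves — the two differ for
non-linear families; the parameter-wise convention matches the daily
summary the analysis is built on).  Two shape summaries feed the
adaptation metrics:

* the **inflection**: the unique interior magnitude where curvature
  reverses.  For the kinked families this is the knot itself; for the
  smooth families it is found by bracketing the sign change of a
  central-difference second derivative ($h = 10^{-4}$, magnitudes below
  $10^{-5}$ treated as zero so float noise cannot masquerade as a
  curvature reversal) and refining with `uniroot` to $10^{-6}$.  Pure
  power curves have none.
* the **curvature ratio** (CR): the integral of $U$ over $[0,1]$,
  computed by the composite trapezoid rule on 10,001 points (error
  $\sim 10^{-8}$ for these smooth curves, well inside the package-wide
  $10^{-5}$ quadrature tolerance).  CR $> 0.5$ means net concavity (risk
  aversion).

**SAC**, the sequential adaptation coefficient, is the relative CR change
between consecutive distributions' curves,
$(CR_n - CR_{n-1})/CR_{n-1}$, computed on the normalized domain (both
curves are anchored there, making the integrals directly comparable):
zero under full adaptation, negative when preferences turn more
risk-seeking.

**GAC**, the general adaptation coefficient, positions a narrow
distribution's curve between two anchors built from the full
distribution's curve on the narrow sub-interval $[a, b]$ of normalized
full space, with image anchors $c = U_{full}(a)$, $d = U_{full}(b)$:

$$GAC = \frac{\int U_{partial} - \int U_{full}}
             {\int U_{adapt} - \int U_{full}},$$

where $U_{adapt}(x) = c + (d - c)\,U_{full}\!\left(\frac{x-a}{b-a}\right)$
is the fully rescaled template and $U_{partial}$ maps the narrow curve
into full space with the same convention.  GAC is exactly 1 when the
narrow curve has the full curve's normalized shape and exactly 0 when it
is the full curve's own segment.  When the full curve is linear — or a
pure power law on a lower half-range, which is scale-free at the origin —
template and segment coincide and the GAC is reported as undefined
(condition class `utiladapt_undefined_gac`) rather than forced to 0 or 1.
GAC requires the narrow range to be nested inside the full one and
refuses non-nested pairs.

Inflection predictions under full adaptation preserve relative position
when mapped between ranges; predictions falling outside the target range
are clipped to its bounds and flagged.  The map is self-consistent:
0.3 ml in the full range sits at relative position 0.3 and maps to
0.15 ml in the low range exactly (and 0.3 ml in the low range, at
relative 0.6, maps to 0.6 ml in the full range); the round trip without
clipping is the identity to machine precision.

## The synthetic agent

`agent_config()` builds a seeded logit decision-maker from a ground-truth
curve, $\lambda$, $\theta$ and an adaptation mode: `full` re-anchors the
curve to every session's range, `none` keeps it anchored to a fixed
reference range (a narrow session then exercises only a segment), and
`partial` interpolates the anchors with a weight — the construction that
makes intermediate GAC values testable.  Sessions derive their RNG stream
from the master seed as `(seed + 131071 * (day + 1) + 7919 * salt) mod
(2^31 - 1)`, so any single day regenerates bitwise-identically in
isolation.

The fractile generator reproduces the task structure: safe ladders on
every 0.05 ml multiple of the range (the ladder spans the whole range, a
design choice — only the 0.05 ml increment is prescribed by the task),
each gamble/safe pairing repeated a configurable number of times (default
4, chosen to satisfy the minimum-repeats filter exactly), steps chained
through psychometric fits of the simulated
choices, and step-2/3 gamble pairs interwoven in one randomized sequence.
Validation sessions pair the four equivariant gambles (spread 30% of the
range, centers at 25/45/65/85%) against the same ladder.
`generate_choice_trials()` provides an unstructured safe-vs-gamble
schedule spanning the whole domain for recovery studies, where
identifiability matters more than fidelity to the fractile presentation
order.

What the generator deliberately does not emulate: reaction times, error
trials and timeouts, satiety and motivation drifts, within-session
learning, or any left/right presentation constraints beyond uniform
sampling.  Passing recovery tests therefore show that the estimation
chain is correct and well-calibrated for logit choosers under the task's
trial structure — not that real choice data satisfy the logit model.

## Study sizes used by the test suite

The automated checks run at sizes chosen to make their conclusions
statistically meaningful while staying desk-scale; they are the package's
own design choices and are fixed by seeds:

* parameter recovery: Prelec$(\alpha=2,\beta=1)$, $\lambda = 10$, 100
  replicates of 5000 trials (median recovery well within 10%), plus
  40-replicate error curves at 200/1000/5000 trials;
* model recovery: 10 sessions per generating family, 800 trials each,
  $\lambda = 20$.  A recovery study needs conditions under which the
  design can discriminate: several of these families mimic each other
  within choice noise at small sizes (`power1` is nested exactly inside
  `prelec2`, so their cross-validated scores differ only by overfitting
  noise), which is why the success criterion is that the generating
  family wins in the majority of the 50 sessions overall rather than
  within every family;
* Monte-Carlo null: 200 replicates over 3-day low and high templates,
  $\lambda = 30$; the non-adapting agent's median simulated GAC sits
  within $\pm 0.1$ of 0 and the fully adapting control within $\pm 0.1$
  of 1, with no overlap between 50 + 50 replicate experiments.

## A short worked example

```{r, eval = FALSE}
library(utiladapt)
cfg <- list(
  agent = list(family = "prelec2", params = c(2, 1), lambda = 30,
               theta = 0, adaptation_mode = "partial", adapt_weight = 0.5,
               reference = "full", seed = 7),
  schedule = list(blocks = list(list(distribution = "low", n_days = 3),
                                list(distribution = "full", n_days = 3),
                                list(distribution = "high", n_days = 3))),
  fitting = list(families = c("power1", "prelec2"), n_starts = 5),
  validation = list(enabled = TRUE))
res <- run_pipeline(cfg, out_dir = "pipeline_out")
res$report
```

The report collects per-distribution median curves, inflections and CRs,
consecutive-pair SACs, per-narrow-distribution GACs and the clipped
full-adaptation inflection predictions; `pipeline_out/` holds the trial,
CE, fit, adaptation and validation tables plus a human-readable summary.

## Known limitations

* The `tversky1` functional form is a reconstruction (see above).
* GAC is undefined, by construction, for linear or origin-scale-free full
  curves and refuses non-nested range pairs.
* The inferential statistics that a study would run on the pipeline's
  outputs (ANOVAs, rank tests on daily metrics) are out of scope; the
  package produces the quantities those tests would consume.
* Bootstrap confidence bands on median curves are not implemented.
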