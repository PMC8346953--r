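# utiladapt

Tools for measuring how utility functions inferred from risky choice
adapt to the distribution of experienced rewards.

## The problem

In binary-choice experiments a decision-maker repeatedly chooses between
a safe reward and an equiprobable two-outcome gamble while the *reward
distribution* — the interval of magnitudes in play (canonically `low`
0–0.5 ml, `high` 0.5–1.0 ml, `full` 0–1.0 ml) — stays fixed for a block
of sessions and then switches.  If preferences re-anchor to the new
range, the utility curve estimated from choices keeps its shape on the
normalized domain; if they do not, the narrow-range curve is just a
segment of a fixed wider curve.  `utiladapt` implements the full
computational chain for quantifying where behaviour falls between those
poles, for researchers in behavioural economics and neuroeconomics
working with trial-level choice data (or simulating it).

## The method

* **Certainty equivalents** come from the logistic psychometric function
  `P(safe) = 1 / (1 + exp(-(safe_ml - x0) / sigma))`, fitted to
  safe-choice proportions across a 0.05 ml ladder by binomial maximum
  likelihood; the inflection `x0` is the gamble's CE.  The stepwise
  fractile procedure chains CEs into utility levels 0.5, 0.25/0.75 and
  0.125/0.875.
* **Discrete-choice fitting**: a logit model on expected-utility
  differences, `P(left) = 1 / (1 + exp(-λ(EU_L − EU_R) − θ))` with
  `EU = Σ p·U(m)` on range-normalized magnitudes, fit per session by
  bounded maximum likelihood for five utility families (`power1`,
  `tversky1`, `prelec2`, `scdf2`, `power3`); model selection by
  `BIC = k·ln(n) + 2·(−LL)` and seeded 10-fold cross-validation, with a
  pooled 3-SD ln-parameter outlier rule.
* **Adaptation metrics**: inflection points and curvature ratios
  (CR = area under the normalized curve; 0.5 = linear), the sequential
  adaptation coefficient `SAC = (CR_n − CR_{n−1}) / CR_{n−1}` (0 under
  full adaptation), and the general adaptation coefficient
  `GAC = (∫U_partial − ∫U_full) / (∫U_adapt − ∫U_full)` positioning a
  narrow-range curve between the full curve's own segment (GAC 0) and its
  rescaled template (GAC 1), plus a Monte-Carlo null that pushes
  non-adapting and fully adapting synthetic agents through the whole
  estimation chain.
* **Out-of-sample validation**: equivariant gambles (spread 30% of the
  range, centers at 25/45/65/85%) whose `CE − EV` risk attitudes are
  regressed on `EV − inflection`.

A seeded synthetic-agent module generates fractile, validation and
recovery schedules from logit agents with known ground truth, so the
entire pipeline runs end to end without any experimental data.  See the
methods vignette (`vignettes/utility-adaptation.Rmd`) for the model
details and design decisions.

## A worked example

```r
library(utiladapt)
cfg <- list(
  agent = list(family = "prelec2", params = c(2, 1), lambda = 30,
               theta = 0, adaptation_mode = "partial", adapt_weight = 0.5,
               reference = "full", seed = 7),
  schedule = list(blocks = list(list(distribution = "low",  n_days = 3),
                                list(distribution = "full", n_days = 3),
                                list(distribution = "high", n_days = 3))),
  fitting = list(families = c("power1", "prelec2"), n_starts = 5),
  validation = list(enabled = TRUE))
res <- run_pipeline(cfg, out_dir = "pipeline_out")
res$report
```

which prints (seed 7, half-adapting S-shaped agent):

```
selected family by median BIC: prelec2
<adaptation_report>
  distribution inflection_ml curvature_ratio n_days
1          low     0.3276685       0.4028068      3
2         full     0.3693371       0.5487290      3
3         high     0.5687484       0.6609901      3
SAC:
  from   to       sac
1  low full 0.3622633
2 full high 0.2045840
GAC:
  distribution       gac undefined
1          low 0.3508103     FALSE
2         high 0.3015261     FALSE
```

Reading it: the agent's inflection (the magnitude where risk attitude
flips) climbs from 0.33 ml in the low range to 0.57 ml in the high
range, but not as far as full re-anchoring would predict; the positive
SACs say each switch to a richer range made revealed preferences more
risk-averse on the normalized domain; and GACs around 0.3–0.35 place the
narrow-range utilities between the no-adaptation pole (0) and the
full-adaptation pole (1), as built into this half-adapting agent.
`pipeline_out/` holds `trials.csv`, `cepoints.csv`, `fits.jsonl`,
`adaptation.json`, `validation.csv` and a `report.md` summary.

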