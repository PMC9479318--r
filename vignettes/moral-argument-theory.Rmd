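---
title: "The moral argument theory of opinion dynamics: models, scoring, and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The moral argument theory of opinion dynamics: models, scoring, and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralargs)
```

## The scientific question

Public opinion on moral issues (abortion, sexual behavior, civil rights,
gun rights, the death penalty, ...) tends to liberalize over decades. The
moral argument theory explains this as the cumulative outcome of everyday
political discussions. Its premises:

1. People are regularly exposed to arguments for both sides of moral
   issues.
2. Arguments appealing to **harm, violence, fairness, or liberty (HVFL)**
   are acceptable to liberals and conservatives alike; other kinds
   (purity, loyalty, authority) move mainly conservatives.
3. On any given issue, one opinion is easier to justify with HVFL
   arguments than its opposite. That side has the *HVFL argument
   advantage*.
4. A listener is more likely to switch opinions when the argument is of a
   kind relevant to their own moral judgments.

Together these imply that discussion systematically pushes opinions —
liberals' opinions first — toward the advantaged side, and they yield five
testable predictions about survey data: (P1) advantaged opinions are more
popular among liberals than conservatives; (P2) opinions drift toward the
advantaged side at a speed increasing in the advantage; (P3) among
liberals, frequent discussers hold advantaged opinions more often; (P4)
that discussion-frequency effect grows with the size of the advantage;
(P5) among conservatives there is little or no discussion-frequency
effect, and always a smaller one than among liberals.

This package implements the full chain: scoring the advantage from
argument-endorsement data, an agent-based model that produces P1–P5,
survey preparation, the regression models that test the predictions, and
a synthetic-data generator with known ground truth so that every stage is
verifiable without access to survey microdata.

## Scoring the HVFL argument advantage

A judge considers one item, answers yes/no, and ticks which argument
kinds justify each side. The four HVFL kinds per side give eight dummies,
and the judge's advantage score for the "yes" opinion is

$$\frac{\textit{yes:harm} + \textit{yes:violence} + \textit{yes:fairness}
+ \textit{yes:liberty}}{4} -
\frac{\textit{no:harm} + \textit{no:violence} + \textit{no:fairness} +
\textit{no:liberty}}{4} \in [-1, 1].$$

A judge who ticks fairness and harm for "yes" and liberty for "no" scores
$1/2 - 1/4 = 0.25$:

```{r}
participant_advantage(c(yes_fairness = 1, yes_harm = 1, yes_violence = 0,
                        yes_liberty = 0, no_liberty = 1, no_harm = 0,
                        no_violence = 0, no_fairness = 0))
```

`item_advantage()` averages judges' scores per item and reports the
standard error of the mean (sample SD, $n-1$ denominator). Authority,
loyalty and purity dummies are carried but never scored. Judges labelled
`other` enter the overall mean but neither the liberal-based nor the
conservative-based sub-mean; `ideology_split_reliability()` correlates
the two sub-means (with a Fisher-z interval) to check that liberals and
conservatives agree about which arguments bear on which opinions.
`threshold_filter()` keeps items whose $|$advantage$| \ge 0.1$
(inclusive), the regime where the advantaged side is considered reliably
identified, and records each kept item's coding direction.

## The agent-based model

`run_simulation()` evolves `n_agents` agents, each with a fixed ideology
(liberal/conservative), a fixed discussion-frequency class, and a binary
opinion on one issue whose advantage is $A$. Per time step:

* every agent initiates a discussion with probability equal to its class
  rate $f$;
* the partner is drawn from the initiator's own ideological group with
  probability $b(f)$ (ingroup bias), otherwise from the other group,
  uniformly within group;
* both parties argue for their current opinion. An argument is of an HVFL
  kind with probability $(1+A)/2$ when the advocated opinion is the
  advantaged one and $(1-A)/2$ otherwise — so $A$ is exactly the expected
  difference between the sides in HVFL argument supply;
* a listener holding the opposite opinion switches with probability $s$
  if the argument kind is relevant to it: liberals are moved only by HVFL
  arguments, conservatives by any kind. Both parties are evaluated on
  pre-encounter opinions and all switches apply simultaneously.

Liberal–liberal encounters therefore drift toward the advantaged opinion
at a rate proportional to $A$, conservative–conservative encounters have
no net drift, and conservatives move only through their contact with
liberals. In the dilute-contact limit the expected one-step change of the
liberal prevalence $x$ is

$$E[\Delta x] = 2 \, c \, s A \, x(1-x),$$

with $c$ the per-agent within-group encounter rate
(`liberal_drift_oracle()`). This closed form is exact to first order in
$c$: at high contact rates an agent can be the listener in several
encounters of one step, coincident switch triggers collapse into a single
switch, and the realized drift falls below the formula (about 9% at
$c = 0.5$). The simulator-vs-oracle tests are therefore run at the
package's default dilute rates, where the first-order form is the correct
expectation.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `n_agents` | 2000 | population size |
| `prop_liberal` | 0.5 | share of liberal agents |
| `advantage` ($A$) | 0.2 | HVFL argument advantage of opinion 1 |
| `persuade_prob` ($s$) | 0.5 | switch probability given a relevant argument |
| class rates ($f$) | 0.01 / 0.05 | per-step initiation probability, infrequent/frequent, 50/50 within each ideology |
| `bias` | calibrated | ingroup bias per class |
| `horizon` | 500 | time steps |
| `n_replicates` | 200 | independent runs |

The time unit is deliberately abstract. The class rates were chosen so
that the advantaged opinion's rise spans the default 500-step horizon: at
much faster rates the population reaches near-consensus early and the
terminal comparisons between conditions degenerate. With two classes at
0.01/0.05 a frequent discusser initiates a discussion every 20 steps on
average, five times as often as an infrequent one, and the mid-horizon
state shows clearly separated frequency classes.

### Calibrated ingroup bias and Prediction 5

`calibrate_ingroup_bias()` sets $b(f) = 1 - \kappa/f$ with $\kappa$ the
smallest class rate, which makes the *cross*-ideology contact rate
$f(1-b(f)) = \kappa$ identical across classes. Conservatives' opinions
move only through cross-ideology contact (their within-group discussions
carry no net drift), so under calibration a conservative's discussion
frequency has exactly zero expected effect on its opinion — the sharp
form of P5. Under a constant bias instead, frequent conservatives meet
liberals more often and acquire a small frequency effect, but always a
smaller one than liberals, which is the relaxed form of P5 the model
also reproduces.

`summarize_df_effect()` reports the frequent-minus-infrequent prevalence
gap per ideology at a chosen time, averaged over replicates, with a
bootstrap percentile confidence interval of the replicate-mean gap (a
percentile interval of single-replicate gaps would not tighten with more
replicates, so the bootstrap-of-the-mean is used).

## The synthetic survey generator

`survey_dgp()`/`gen_survey()` mirror the pooled estimation model as a
data-generating process. For respondent $i$ (group $g$, wave $w$) and
issue $k$:

$$\mathrm{logit}\, P(\textit{Opinion}_{ik}=1) = \beta_{0k} + u_i + u_k +
u_{kw} + \beta_{1,g}\,DF_i + \beta_2\,A10_k + \beta_{3,g}\,DF_i\,A10_k +
\beta X_i + \dots$$

* $DF$ is drawn as integer days 0–7 ("how many days in the past week"),
  independent of ideology (the joint distribution of discussion frequency
  and ideology is not otherwise constrained by evidence; independence is
  the flagged default), and standardized over the generated sample before
  the slopes apply.
* $A10$ is the issue advantage centered at the item mean and multiplied
  by 10, so one unit is 0.1 advantage — the same scale the M2 fit uses.
* Random intercepts are independent mean-zero Gaussians on the log-odds
  scale (the conventional GLMM choice) for individual, issue, and
  issue-wave.
* Covariates are standard normals plus binary dummies whose effects
  default to zero — they are controls, not quantities of interest.
* Issue advantages default to draws from $N(0, 0.16)$ truncated to
  $[-1,1]$, matching the observed spread of item advantages.
* Optional terms used by the end-to-end pipeline: an ideology–advantage
  alignment effect (produces P1), an advantage-proportional time trend
  (P2), and a discussion-frequency moderation of that trend (the
  split-sample slope contrast of `fig5_slope_difference()`). $\beta_3$
  and the trend moderation accept per-group
  values because the theory locates the moderation among liberals; a
  global moderation would, after recoding to advantaged-opinion coding,
  manufacture a discussion-frequency effect for conservatives and
  contradict P5.
* The `truth` sidecar echoes every parameter so recovery tests never
  reverse-engineer ground truth from file names.

What the generator does **not** emulate: survey nonresponse and weighting
design (weights default to 1), panel attrition, item-specific response
scales (opinions are generated already dichotomized), correlation between
discussion frequency and ideology, and measurement error in
self-reports. Passing recovery tests on these data therefore shows that
the estimators are correct for the assumed model, not that the model is
a complete account of real survey data.

## Estimation

All models are logistic regressions of holding the advantaged opinion
(coded 1), with Wald 95% intervals and survey weights as pseudo-likelihood
prior weights normalized to mean 1 (unit weights reproduce the unweighted
fit exactly; a weight of 2 equals row duplication; a zero weight equals
deletion).

* `fit_issue_logistic()` — one issue, one group:
  $\mathrm{logit}(\textit{Opinion}) = \beta_0 + \beta_1 DF + \beta X$
  with controls education, woman, age, black/other (vs white), media
  use, and standardized year for repeated-wave designs. $\beta_1$ is in
  log-odds per SD of discussion frequency; `odds_factor()` exponentiates
  it (0.12 ↦ 1.13).
* `fit_pooled_m1()` — pools a group across issues and waves with crossed
  random intercepts for individual, issue-wave, and issue
  (`lme4::glmer`).
* `fit_pooled_m2()` — adds the advantage main effect and its interaction
  with discussion frequency on the $A10$ scale.
* `fit_change_rate()` — per-issue trend: logit of holding the advantaged
  opinion on time in decades; the slope is the change rate in log odds
  per 10 years.

Numerical choices:

* **Likelihood approximation.** `glmer` with `nAGQ = 0` (penalized
  iteratively reweighted least squares) is the default and is recorded in
  `FitResult$method`; `nAGQ = 1` (Laplace) is available. At the recovery
  suite's problem sizes the two differ in the discussion-frequency
  coefficient by about 0.005 (a fifth of its standard error) while
  nAGQ=0 is roughly five times faster; the contract for the fitting
  method is the zero-variance degeneracy oracle (GLMM with all RE
  variances zero equals plain logistic ML) plus parameter recovery, not
  a named algorithm. Derivative-based convergence checking is disabled
  (`calc.derivs = FALSE`) for speed; convergence messages are captured
  into the fit's metadata.
* **Fallback.** `method = "glm_cluster"` fits a pooled logistic model
  with cluster-robust (by individual) standard errors, clearly labeled
  in the result, for settings where GLMM fitting fails.
* **Separation.** A fit whose coefficients diverge beyond 10 in absolute
  log-odds (or a single-valued outcome) is flagged and its estimates are
  reported as missing rather than as arbitrary large numbers.
* **Degenerate grouping.** With a single wave per issue the issue-wave
  intercept is collinear with the issue intercept and is dropped with a
  warning; likewise the issue terms under a single issue.
* **Standardization** of continuous predictors happens within each fit's
  estimation sample (group × issue set), so a group-specific fit
  re-standardizes discussion frequency within that group.

## Prediction tests

* `test_prediction1()` counts items whose advantage sign matches the
  sign of the liberal-minus-conservative prevalence of the stated
  opinion, pooled over waves; exact ties count as non-aligned and are
  reported.
* `test_prediction2()` gives the Pearson correlation between advantage
  and change rate with a Fisher-z interval.
* `test_df_effects()` reads the pooled DF coefficients per group: P3 is
  a liberal CI above zero, P5 a conservative CI covering zero plus the
  magnitude ordering $|\beta_{1,\mathrm{cons}}| < \beta_{1,\mathrm{lib}}$.
* `fig5_slope_difference()` regresses change rates on advantage within
  the frequent and infrequent liberal subsamples (median split of
  standardized DF — the split rule is a package choice and configurable
  by splitting upstream) and reports the slope difference with a
  heteroskedasticity-robust (HC3) interval from the stacked interaction
  regression. Items are unweighted in this regression; weighting by
  change-rate precision is possible upstream but not the default.

`run_pipeline()` chains all stages on synthetic data — scoring from
simulated judgments, thresholding, survey generation, group fits, change
rates, and the five tests — and writes a JSON report plus CSV tables.
The analysis uses the *estimated* advantages (not the generator's truth),
as a real analysis would.

## Problem sizes used by the test suite

The recovery suite fits the pooled model on 5,000 respondents × 20
issues over 50 generator seeds, the degeneracy oracle on 3,000 × 10, the
simulator prediction suite on 2,000 agents × 500 steps × 200 replicates
per condition, the drift oracle on 100,000 agents × 60 one-step
replicates, and the scoring recovery on 98 judges × 200 seeds — the
endorsement-study scale. The end-to-end pipeline defaults to 40 issues,
98 judges, and 2,000 respondents.

## Known limitations

* The simulator covers exactly two ideologies, no network topology, and
  one issue per run; issues are simulated independently.
* The drift oracle is a first-order (dilute-contact) approximation, as
  described above.
* Mixed-model weights enter at the observation level only; design-based
  (replicate-weight) variance estimation is out of scope.
* The split-sample slope-difference contrast is very noisy at small
  sample sizes; its interval reflects that, and the pipeline reports it
  with its uncertainty rather than as a point claim.
* Discussion-frequency items differing across survey waves must be
  harmonized before pooling; standardizing within wave before pooling is
  the package's stated choice, applied by preparing each wave's extract
  separately.
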