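---
title: "Methods: design, simulation and estimation of the OCS risk-benefit DCE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, simulation and estimation of the OCS risk-benefit DCE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocsdce)
```

# The scientific problem

Oral corticosteroids (OCS) are the standard treatment for asthma attacks,
but carry temporary side effects (anxiety, insomnia, indigestion) and,
cumulatively, permanent ones (weak bones, heart disease, diabetes).
Whether — and by how much — patients and healthcare professionals (HCPs)
would trade treatment benefit against those harms is an empirical question
about preferences.  A discrete choice experiment (DCE) answers it by asking
respondents to choose repeatedly between two hypothetical, unlabelled
treatments ("treatment A" / "treatment B") described on six attributes:

| attribute | levels | reference |
|---|---|---|
| chance of further GP treatment within 28 days | 5 / 10 / 15% | 15% |
| chance of hospital treatment within 28 days | 5 / 10 / 15% | 15% |
| symptom improvement within 7 days | 100 / 50 / 25% | 25% |
| peak-flow improvement within 7 days | 40 / 20 / 0% | 0% |
| risk of permanent side effects | None / High | High |
| risk of temporary side effects | None / High | High |

`ocsdce` implements the full analysis pipeline for this experiment: design
generation, synthetic respondents, estimation and post-estimation
inference.  All containers are plain data frames; all randomness flows
through named integer seeds.

# Random-utility model

Choices follow a multinomial logit (MNL): the utility of alternative $j$ in
a choice task is $U_j = V_j + \varepsilon_j$ with i.i.d. extreme-value
errors, so

$$P(j) = \frac{e^{V_j}}{\sum_k e^{V_k}},$$

where $V_j = x_j'\beta$ and $x_j$ dummy-codes the non-reference levels of
the alternative.  A coefficient $\beta_\ell$ is the log odds ratio of
choosing an alternative carrying level $\ell$ over one carrying the
reference level, all else equal.  Because only utility *differences* are
identified, reference levels are pinned at zero; because the error scale is
arbitrary, only coefficient *ratios* (marginal rates of substitution) are
scale-free.

# Experimental design

`optimize_design()` searches for a Bayesian D-efficient set of
two-alternative tasks.  The D-error of a design at coefficients $\beta$ is
$\det\{I(\beta)^{-1}\}^{1/K}$, with $I(\beta)$ the MNL Fisher information
for one pass through the tasks and $K$ the number of coefficients; the
Bayesian criterion averages this over draws from a normal prior on $\beta$.
Choices that were genuinely open, and how they were resolved:

* **Search algorithm.** Random-swap exchange: replace one alternative of
  one randomly chosen task by a random candidate profile, keep the move if
  the criterion improves; 10,000 iterations by default.  The accepted-value
  trace is non-increasing by construction and the whole search is
  reproducible from its seed.
* **Prior.** Pilot-study priors behind the original design are unpublished,
  so the default is a weakly informative $N(0, 0.5^2)$ per coefficient,
  fully configurable via `design_spec()`.
* **Prior draws.** 100 quasi-random draws (randomly shifted Halton points
  through the normal quantile function).  Quasi-random points cut the
  integration error well below the plain-Monte-Carlo error at the same
  draw count; the test suite checks the 100-draw value against a large
  independent Monte-Carlo oracle.
* **Dominance filter.** A task in which one alternative is at least as good
  on every attribute (in the a priori preference direction: lower risk
  better, more benefit better, no side effects better) carries no
  trade-off and is excluded.  Toy systems in the test suite use *tied*
  preference ranks to switch the filter off where exhaustive enumeration
  is wanted.
* **Identification and ties.** With two alternatives the information matrix
  has rank at most the number of tasks, so at least $K$ tasks are needed;
  unidentified designs have infinite D-error, detected with a reciprocal
  condition number below $10^{-10}$.  While the search is still in the
  unidentified region, moves are ranked by a ridge-regularised surrogate
  ($I + 10^{-4}\mathrm{Id}$) so it can walk towards identification.
* **Duplicates.** Identical (unordered) tasks are forbidden within a
  design, and the two alternatives of a task must differ.
* **Blocking.** `block_design()` splits tasks into equal blocks minimising
  the sum over attribute levels and blocks of squared deviations of
  within-block level counts from perfect balance, by deterministic
  steepest-descent pairwise swaps from a round-robin start.  On toy
  designs this attains the exhaustive minimum.

The published 24 tasks themselves are in that study's supplement, not its
main text, so exact reproduction of the original design is out of reach;
the package targets criterion-level equivalence (a well-conditioned,
identified, blocked design under the same constraints).

# Synthetic respondents

The original survey data are available only on request, so
`sample_roster()` and `simulate_choices()` generate data with the
statistical structure the analysis assumes, calibrated to the published
sample margins.

* **ACT scores.** The Asthma Control Test is an integer 5–25 instrument
  reported only as mean 18.4 (SD 5.1).  The generator draws a latent
  normal, rounds and clips to the instrument range, with the latent mean
  and SD solved (analytically, over the integer grid) so the *clipped*
  distribution hits the target moments.  The implied share with
  ACT $\le 15$ is then ~28%, matching the published margin without being
  separately imposed.
* **Other covariates.** Ever hospitalised 48%, university degree 56%,
  non-white 12%, UK 45% for patients; care-setting and gender margins for
  HCPs.  Covariates are drawn independently: the published tables give
  only marginals, and inventing a copula would fabricate structure.  Age
  is a truncated normal (mean 56, SD 15 on 18–86; the source reports mean
  and range only), giving roughly a quarter of patients over 65.
* **Preference truth.** `published_truth()` returns the published
  full-sample odds ratios, log-transformed, as base utilities, plus the
  published subgroup interaction ratios (e.g. poorly controlled asthma
  scales the no-permanent-side-effects weight by 0.67).  The interactions
  are applied jointly in one generating model; whether the published
  ratios came from one joint model or one-at-a-time models is not stated,
  so parameter-recovery studies use the homogeneous truth
  (`include_interactions = FALSE`), under which the full-sample refit
  target *is* the generating value.
* **Choices.** Direct categorical draws from the logit probabilities —
  mathematically identical to Gumbel-error maximisation with fewer random
  numbers.  The narrative-arm label is attached with zero generating
  effect, mirroring the null finding it is meant to let you test.

What the generator does **not** emulate: respondent dropout, inattentive or
bot responses, fatigue across tasks, covariate correlation, and any
preference heterogeneity beyond the published interaction set.  Passing
recovery tests therefore show the estimator is correct *under the model*,
not that the model captures every feature of real survey behaviour.

# Estimation

`fit_mnl()` maximises the exact log-likelihood
$\sum_n w_n (V_{\text{chosen}} - \log \sum_j e^{V_j})$ by Newton–Raphson
with the analytic gradient and Hessian and step-halving, starting from
zero, declaring convergence at gradient max-norm below $10^{-8}$.
Rank-deficient model matrices and apparent separation are reported as
errors naming the problem.  The default covariance is the inverse negative
Hessian; a respondent-clustered sandwich is always computed and available
via `vcov(fit, "clustered")` — the provenance of the published intervals is
unstated, so both options exist and the default is a documented choice, not
a claim about the original analysis.  Under correct specification the two
agree (tested); the independent cross-check against conditional logistic
regression (`survival::clogit`) agrees to five decimals on matched data.

Weighted fits (`fit_weighted()`, `calibration_weights()`) reproduce the
post hoc reweighting of graduates to the 30% population share; unit
weights reproduce the unweighted fit exactly.  `test_arm_equivalence()`
compares a pooled model against a fully arm-interacted one by likelihood
ratio on $K(\text{arms}-1)$ degrees of freedom; under the null its
rejection rate is ~5% at the 0.05 line (tested at 200 replicates).

# Post-estimation

* **Failure slope.** The per-percentage-point disutility of treatment
  failure is taken from each channel's 5%-vs-15% contrast divided by 10 —
  the widest, hence best-estimated, contrast — and a one-point increase in
  failure is split equally between the GP and hospitalisation channels
  (their mean).  This equal split is the package default because it is the
  natural reading of a composite "GP re-treatment or hospitalisation"
  endpoint; `channel = "gp"` / `"hospital"` are sensitivity options.
  Applied to the published HCP odds ratios this arithmetic yields
  $\ln(5.79) / \{(\ln 2.09 + \ln 1.86)/20\} \approx 25.9$ percentage
  points, i.e. the published 26% figure.
* **MRS/MCID intervals.** Krinsky–Robb by default: 10,000 draws from the
  estimated multivariate-normal coefficient distribution, percentile
  interval, seeded; the delta method is the closed-form alternative.  If
  the denominator changes sign in more than 2.5% of draws the result is
  flagged unstable rather than reported as a silently huge number.
* **Forecasting.** `forecast()` scores scenario profiles (shipped:
  OCS-equivalent vs placebo-equivalent) through the logit formula, with
  simulation standard errors.  From the published full-sample
  coefficients, patients prefer the placebo-equivalent (no side effects)
  alternative and HCPs the OCS-equivalent one ($\approx 0.66$), matching
  the published ordering.  The exact published figures (57/43 patients,
  69/31 HCPs) came from subgroup models whose coefficients are only in
  that study's supplement, so they are reproducible in direction and rough
  magnitude, not digit-for-digit — a documented gap, not patched.
* **Subgroup for the patient MCID.** The protocol defines the relevant
  patient group by poor symptom control; the roster's `act_le_15` flag
  (the published 28% margin) is the subgroup filter.  The instrument is
  integer-valued, so the `<15` / `≤15` boundary reading differs only in
  whether score 15 is included; the package uses the flag consistent with
  the published margin.
* **Scale invariance.** `scale_invariance_check()` asserts the defining
  symmetry: rescaling all coefficients moves forecasts but cannot move any
  MRS.

# Problem sizes and numerical tolerances

Test-suite and acceptance-script runs use 400 exchange iterations and 100
prior draws for the 24-task design search, 10 seeded replicates for the
study-scale recovery studies (824 patients / 171 HCPs, 12 tasks each), and
200 replicates for the null-calibration study at reduced scale — sizes
chosen so the whole suite runs in about a minute while keeping Monte-Carlo
error well inside the asserted tolerances.  Gradient checks use central
differences at $10^{-5}$; oracle equivalences are asserted at $10^{-6}$
relative; grid-search comparisons at the grid resolution.

# Known limitations

* MNL only: no mixed logit, latent-class or Bayesian posterior estimation
  (the original primary analysis is MNL; heterogeneity enters via explicit
  interaction terms).
* No opt-out alternative and no labelled designs.
* No monetary attribute, hence no willingness-to-pay in currency units.
* The design search is stochastic hill-climbing: it attains exhaustive
  optima on toy systems, but on the full 324-profile system it guarantees
  only a monotone improvement path, not the global optimum.
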