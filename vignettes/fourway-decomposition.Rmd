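---
title: "Four-way decomposition of disparities in incident dementia: models and methods"
author: "fwdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-way decomposition of disparities in incident dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwdecomp)
```

## The scientific question

Minoritized racialized groups in the United States (non-Hispanic Black and
Hispanic adults) experience a substantially higher 6-year incidence of
dementia than non-Hispanic white adults. One candidate biological pathway is
systemic inflammation: chronic exposure to the stressors of racism is
hypothesized to raise circulating C-reactive protein (CRP), and elevated CRP
has been linked to dementia risk. `fwdecomp` quantifies how much of the
observed disparity operates *through* high CRP (mediation), how much arises
because minoritized group membership *modifies* the effect of high CRP on
dementia (interaction), and how much is left as a controlled direct effect
of the racialization process through all other pathways.

The exposure $A$ is membership in a minoritized group (coded 1) versus the
non-Hispanic white reference (coded 0); three contrasts are supported
(minoritized combined, non-Hispanic Black only, Hispanic only, each versus
the same reference arm). The mediator $M$ is high systemic inflammation,
CRP $\geq$ 4.73 µg/mL (the 75th percentile of the source biomarker
distribution); a standardized log-CRP variant is provided for sensitivity
analysis. The outcome $Y$ is incident dementia over up to three biennial
follow-up waves, with person-time $t \in \{2, 4, 6\}$ years.

## Cohort construction

Cognitive status uses the Langa-Weir classification of the 27-point
cognitive composite: scores 0–6 are dementia, 7–11 cognitive impairment
non-dementia (CIND), 12–27 cognitively normal. Participants enter free of
dementia (normal or CIND at baseline) and are followed until the first wave
whose classification is dementia, or censored administratively at 6 years
with $Y = 0$. Participants with a missing intermediate wave but an observed
later dementia classification are counted at the first *observed* dementia
wave; since follow-up in the emulated design stops at the first dementia
classification, this is the only coherent reading. Deaths and attrition are
treated as administratively censored at 6 years — the design we emulate
does not model competing risks, and neither do we (see Limitations). A
sensitivity outcome (`outcome_mode = "impairment"`) counts dementia-or-CIND
as the event for participants who were cognitively normal at baseline.

The default mediator cutoff is the *absolute* value 4.73 µg/mL rather than
a recomputed percentile, because the published cutoff derives from a larger
biomarker sample than any analytic subsample; a percentile mode
(type-7, linear-interpolation quantile — the R default, chosen so the
threshold is reproducible from the documented convention) is provided for
synthetic data. Analysis is complete-case: rows with any missing covariate,
mediator, or usable follow-up are excluded and tallied.

Four frozen adjustment sets mirror the sequential modelling strategy:
`unadjusted`; `demographic` (age, sex, education, *APOE*-ε4 carrier status,
enrollment wave); `risk_factors` (plus smoking, alcohol, body-mass index);
and `chronic` (plus the 0–8 chronic-condition count), the default for
decomposition.

## The outcome and mediator models

Incidence is modelled with Poisson regression with log link and
$\log t$ offset, so coefficients are log incidence-rate ratios:

$$\log \mathbb{E}[Y \mid A, M, C] = \log t + \beta_0 + \beta_A A + \beta_M M +
\beta_{AM} A M + \gamma' C.$$

The exposure–mediator product term is essential: the decomposition exists
precisely to separate its contribution. The binary mediator is modelled with
logistic regression, $\operatorname{logit} P(M = 1 \mid A, C) = \alpha_0 +
\alpha_A A + \alpha'C$; the continuous variant with a Gaussian linear model
whose residual variance $\hat\sigma^2$ (mean squared error with
degrees-of-freedom correction) enters the closed-form integrals below.
Sequential IRR and odds-ratio tables (`sequential_irr_suite`,
`mediator_or_suite`) report Wald 95% intervals, the standard epidemiologic
presentation; the decomposition itself never uses Wald intervals.

## The four-way decomposition

For each person $i$ with covariates $C_i$, the fitted models give
counterfactual 6-year cumulative rates
$\hat\mu(a, m, C_i) = T \exp(\hat\beta_0 + \hat\beta_A a + \hat\beta_M m +
\hat\beta_{AM} a m + \hat\gamma'C_i)$ with common offset $T = 6$ years, and
mediator probabilities $\hat\pi_a(C_i)$. Standardizing over the empirical
covariate distribution of the full analytic sample (direct counterfactual
imputation — *not* evaluation at covariate means, which we reject because
the rate model is nonlinear) gives $E[Y(a, m)]$ and the natural-mediator
means $E[Y(a, M_{a^*})]$. With $\theta = E[Y(0, M_0)]$ and reference
mediator level $m^* = 0$ (low CRP, matching the high-vs-low framing;
configurable), the total excess relative risk decomposes *exactly* into

$$\frac{E[Y(1,M_1)] - \theta}{\theta} =
\underbrace{\textstyle\frac{1}{\theta}\,\overline{\mu_{10} - \mu_{00}}}_{\text{CDE}} +
\underbrace{\textstyle\frac{1}{\theta}\,\overline{\Delta \cdot \pi_0}}_{\text{INT}_{\mathrm{ref}}} +
\underbrace{\textstyle\frac{1}{\theta}\,\overline{\Delta \cdot (\pi_1 - \pi_0)}}_{\text{INT}_{\mathrm{med}}} +
\underbrace{\textstyle\frac{1}{\theta}\,\overline{(\mu_{01} - \mu_{00})(\pi_1 - \pi_0)}}_{\text{PIE}},$$

where $\Delta = \mu_{11} - \mu_{10} - \mu_{01} + \mu_{00}$ is the additive
interaction contrast and overbars average over persons. The identity is
algebraic, so the implementation asserts additivity to $10^{-12}$ rather
than "approximately". Derived measures are shares of the total:
$\%\mathrm{CDE}, \%\mathrm{INT}_{\mathrm{ref}}, \%\mathrm{INT}_{\mathrm{med}},
\%\mathrm{PIE}$ (summing to 1 exactly), percent mediated
$\mathrm{PM} = \%\mathrm{INT}_{\mathrm{med}} + \%\mathrm{PIE}$, percent due
to interaction $\mathrm{PAI} = \%\mathrm{INT}_{\mathrm{ref}} +
\%\mathrm{INT}_{\mathrm{med}}$, and percent eliminated
$\mathrm{PE} = 1 - \%\mathrm{CDE}$. Proportions are always computed from
unrounded components; rounding to two decimals happens only at display.
When $|$total excess$| < 10^{-10}$ the proportions are reported as
undefined with a diagnostic instead of as enormous ratios.

Note one property that surprises many users: the interaction components
live on the *additive* scale, so a log-linear model with
$\hat\beta_{AM} = 0$ still has
$\Delta \propto (e^{\beta_A} - 1)(e^{\beta_M} - 1) \neq 0$. Multiplicative
and additive no-interaction are different claims; the components vanish
exactly when the *cells* satisfy $\mu_{11} = \mu_{10} + \mu_{01} -
\mu_{00}$, when the exposure has no outcome effect at all, or (for the
mediated components) when $\pi_1 = \pi_0$.

All ratio-scale quantities are invariant to the common offset $T$ (it
cancels between numerator and $\theta$); the test suite exercises
$T \in \{1, 6, 100\}$.

### Continuous mediator

For standardized log-CRP, the Gaussian mediator law integrates against the
log-linear outcome in closed form via the normal moment-generating
function: with $k_a = \beta_M + a\,\beta_{AM}$,

$$E\!\left[e^{k_a M} \mid A = a^*, C\right] =
\exp\!\left(k_a\,\bar m_{a^*}(C) + k_a^2 \hat\sigma^2 / 2\right).$$

The controlled direct effect needs a fixed mediator level; following the
convention of setting the standardized mediator's reference at the mean
(0) and evaluating one standard deviation above it, the CDE is computed at
`m_cde = 1` by default (the source description of this choice is ambiguous
between 0 and 1; we expose both `m_ref` and `m_cde`, and the reference
interaction is defined as the natural-direct-effect remainder so additivity
holds for any choice). The $\hat\sigma \to 0$ limit collapses to the
binary-style computation with $M$ degenerate at its conditional mean, a
property the tests verify, and the closed form is cross-checked against
Monte-Carlo integration over the fitted Gaussian law.

## The randomized-analog (interventional) estimator

*APOE*-ε4 carrier status and education are plausibly affected by the
exposure (in the emulated study design, racialized categories are paired
with genetic ancestry, and schooling in the United States has been
racially segregated), which breaks the identification of natural indirect
effects: they are mediator–outcome confounders affected by exposure, $L$.
The randomized-analog estimator replaces the natural mediator with a draw
from its marginal-over-$L$ law under the index exposure, independently of
the $L$ entering the outcome:

$$\tilde\mu(a, m, C) = \sum_l \hat\mu(a, m, C, l)\,\hat P(l \mid a, C),
\qquad
\tilde\pi_a(C) = \sum_l \hat\pi(a, C, l)\,\hat P(l \mid a, C),$$

plugged into the same four formulas. The joint $L$ law is factorized
sequentially — *APOE*-ε4 first (logistic), then education given *APOE*-ε4
(multinomial logit, reference high-school-or-less) — an order that must be
declared because the source framework leaves it unstated; it is
configurable in the sense that either variable can be dropped from `lset`.
The $L$ state space has $2 \times 3 = 6$ cells, so exact enumeration is
the default; a Monte-Carlo mode (`analog_mode = "monte_carlo"`) exists for
extensibility to larger $L$ spaces and is tested for agreement with
enumeration. When every fitted $L$ coefficient in the outcome and mediator
models is zero, the analog estimate reduces to the regression-based one
identically, a collapse the tests assert at $10^{-10}$.

## Inference

Confidence intervals are nonparametric percentile bootstrap with
$B = 1000$ resamples by default: rows are resampled unconditionally (not
stratified by arm — matching the default of the standard implementation of
this estimator), *every* model (outcome, mediator, and both $L$ models for
the analog estimator) is refitted per resample, and the 2.5th/97.5th
empirical quantiles are reported. Two-sided bootstrap p-values are
$2\min(\#\{\hat q_b \le q_0\}, \#\{\hat q_b \ge q_0\})/B$ with null
$q_0 = 0$ for excess components and proportions and $q_0 = 1$ for the
indirect-effect risk ratio. Resamples in which a model fails to converge
are dropped and counted; more than 10% failures marks the inference
unreliable. All randomness flows from a single seed; identical (data,
seed, $B$) reproduce identical intervals byte-for-byte.

Bootstrap refits warm-start from the full-data estimates (the same maximum
likelihood optimum, reached in fewer iterations), and the education
multinomial refits use an in-package Newton–Raphson solver started at the
full-data solution; the tests confirm agreement with the reference fitter
at the optimum.

## Mediational E-values

The indirect-effect risk ratio is
$\mathrm{RR}_{\mathrm{NIE}} = E[Y(1, M_1)] / E[Y(1, M_0)]$ (total natural
indirect effect; the source phrasing is ambiguous between this and the
pure indirect effect, so the PIE variant is exposed behind
`target = "pure_indirect"`). Its E-value,
$\mathrm{RR} + \sqrt{\mathrm{RR}(\mathrm{RR} - 1)}$ applied to
$\max(\mathrm{RR}, 1/\mathrm{RR})$, is the minimum strength of association
an unmeasured mediator–outcome confounder would need with both high CRP
and dementia to explain the indirect effect away; a second E-value for the
bootstrap confidence limit nearer the null (set to 1 when the interval
already crosses it) gives the strength needed to make the interval include
the null. Both are computed from the fitted decomposition, never copied
from published values, which depend on restricted data.

## The synthetic cohort generator

Because the real cohort requires registered access, the package ships a
generator (`sim_config()`, `generate_cohort()`) whose defaults *are* the
study conditions the package is validated under:

* three racialized groups at prevalences 5462/813/633 out of 6908;
* age $\mathcal N(67.11, 9.91^2)$, 61% female, two enrollment waves;
* education (3 levels) and *APOE*-ε4 carrier status drawn conditionally on
  group — these are the exposure-affected $L$; carrier prevalence is higher
  in the non-Hispanic Black group (0.38 vs 0.255/0.26), encoding the
  ancestry-pairing premise with magnitudes that are free parameters;
* smoking 45/43/12% never/former/current; alcohol zero-inflated
  exponential (55% zeros, positive mean 1.58, matching the printed mean
  0.71 and SD 1.30); BMI $\mathcal N(28.5, 5.79^2)$; chronic conditions
  Binomial(8, 0.235) for a mean of 1.88 — distribution families are our
  choice since only moments are published;
* CRP lognormal (chosen for positivity and right skew; the published
  density is displayed on the log scale) with scale 1.20 and group-by-sex
  locations derived from target means 6.8/6.0 (non-Hispanic Black
  female/male), 4.8/4.0 (Hispanic), 4.6/3.4 (non-Hispanic white), plus
  small negative loadings for *APOE*-ε4 carriage and higher education.
  These reproduce the group means 6.5/4.5/4.1 µg/mL, the overall mean
  ≈ 4.4, and put the 75th percentile within ±0.5 µg/mL of 4.73 without
  further tuning;
* a yearly dementia log-rate with group-specific direct effects (0.60
  non-Hispanic Black, 0.36 Hispanic — calibrated so 6-year cumulative
  incidences land near 21%, 16%, and 9.5%, about 11.5% overall), a common
  high-CRP effect $\beta_M = 0.175$ and a common positive interaction
  $\beta_{AM} = 0.25$, age, education, *APOE*-ε4, lifestyle, and
  chronic-condition loadings; events arise interval-censored with
  probability $1 - e^{-2\lambda}$ per 2-year wave, which makes person-time
  exact under the piecewise-constant hazard.

The interaction coefficient is deliberately *common* across minoritized
groups: the estimators fit a single product term per contrast, and a
group-varying interaction would make the pooled-contrast model structurally
misspecified, confounding validation of the estimator with validation of
the model. Group-specific *direct* effects are harmless because a single
exposure coefficient absorbs their prevalence-weighted mixture.

`true_decomposition_oracle()` computes the ground-truth components for
either estimand directly from the structural coefficients: it draws
covariate/$L$ profiles by Monte Carlo, evaluates the exact per-profile
counterfactual rates and mediator probabilities (a probit in the log-CRP
threshold), and averages. For the pooled contrast the exposed-side group is
a prevalence-weighted mixture, conditioned on $L$ for the regression
estimand and marginalized over $P(l \mid a)$ for the interventional one.
For covariate-free configurations every profile is identical and the
oracle is exact, which is how the hand-computed worked instance — risks
$(0.10, 0.20, 0.15, 0.40)$, mediator prevalences $(0.25, 0.50)$, components
$(0.4, 0.3, 0.3, 0.2)$, total excess $1.2$ — is wired into the tests.

### What the generator does and does not emulate

It reproduces the marginal structure the validation needs: group
prevalences and incidences, the inflammation hierarchy and its sex
gradient, exposure-graded $L$, and interval censoring. It does not emulate
survey weights, mortality or other competing risks, item-level cognition,
proxy respondents, or measurement error in CRP. Passing tests therefore
demonstrate estimator correctness under a faithful-but-idealized mechanism,
not robustness to those real-data features.

## Validation design and problem sizes

The test suite validates at sizes chosen to balance Monte-Carlo error
against wall-clock time, stated here as the package's own choices:
parameter recovery at $n = 20{,}000$ (regression) and $n = 50{,}000$
(analog, with active $A \to L$ paths) against oracles at $2 \times 10^5$
profiles; bootstrap coverage over 200 replicates of $n = 5{,}000$ with
$B = 200$ on a covariate-free mechanism (where the saturated-cell closed
form is provably identical to the full estimator, so the study isolates
bootstrap calibration); exact-additivity sweeps over 100 randomized
mechanisms; and a full demo pipeline at $n = 6908$, $B = 1000$, three
contrasts and both estimators, run twice to assert byte-identical output.
Under the default conditions the sampling standard deviation of the
percent-due-to-interaction at $n = 20{,}000$ is a few hundredths, so
recovery checks at fixed tolerances are run at the package's default seed.

## Numerical choices and degenerate inputs

* Convergence: IRLS to relative deviance change $10^{-8}$, at most 100
  iterations; non-convergence is an error, never a silent result.
* Rank-deficient designs error; possible separation in logistic fits warns
  and flags the fit.
* $\theta \le 0$ (or $\tilde\theta \le 0$) is an error — excess relative
  risks are undefined without a positive reference mean.
* Degenerate contrasts (an empty exposure arm) error at dataset
  construction.
* The percentile-mode mediator threshold uses type-7 quantiles; ties at
  the threshold are classified high (the $\geq$ convention).
* Bootstrap quantiles are type-7 on the retained (converged) draws.

## Known limitations

Competing risks and differential attrition are not modelled; if mortality
removes high-CRP minoritized participants before dementia can be observed,
all estimators here inherit that selection. The decomposition's causal
reading requires the usual confounding assumptions plus, for the
regression-based estimator, no exposure-affected mediator–outcome
confounding — the analog estimator relaxes exactly that one assumption and
answers a slightly different (interventional) question. A single baseline
CRP measurement cannot capture inflammation trajectories. The continuous
sensitivity analysis conditions on a correctly specified Gaussian law for
standardized log-CRP. Survey design weights are intentionally out of scope.
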