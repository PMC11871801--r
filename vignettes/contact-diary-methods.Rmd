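---
title: "Models and methods for period-stratified contact-diary analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for period-stratified contact-diary analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactdiaries)
```

## The problem

Diary-based social-contact surveys record, for each participant and each
survey day, every "close contact" (a skin-to-skin interaction, or a
non-physical exchange of three or more words) together with the contacted
person's age, sex, residential region, the relationship, location, duration,
frequency and physical type of the interaction. Such diaries are the raw
material for the age-grouped contact matrices that parameterise
infectious-disease transmission models.

`contactdiaries` implements the full analysis chain for a two-week winter
survey design in which every calendar day belongs to one of four exclusive
periods: semester weekdays (I), vacation weekdays (II), weekends (III) and
the Lunar New Year holidays (IV). Holidays take precedence over weekends, so
a holiday falling on a Saturday is period IV; this keeps the four periods a
partition of the 14 survey days (5 + 3 + 2 + 4 under the default calendar).
The default holiday block (2024-02-09 to 2024-02-12, including the
substitute holiday) is a configuration input of `survey_calendar()`, not a
hard-coded fact, because statutory holiday sets are jurisdiction- and
year-specific.

## The count model

Daily contact counts are overdispersed: across participant-days the variance
is several times the mean. We model the count $y_{it}$ of participant $i$ on
day $t$ as

$$y_{it} \sim \mathrm{NegBinomial}(\mu_{it}, \phi), \qquad
\log \mu_{it} = \alpha + \beta_{\text{age}(i)} + \beta_{\text{hh}(i)} +
\beta_{\text{period}(t)} + \beta_{\text{sex}(i)} + b_i, \qquad
b_i \sim \mathcal{N}(0, \tau),$$

with mean $\mu$ and variance $\mu + \mu^2/\phi$; the Poisson model is the
$\phi \to \infty$ limit. The participant intercept $b_i$ is constant across
the 14 diary days and absorbs the repeated-measures correlation. Treatment
contrasts use age 0–4, household size 1, period I and female as reference
levels, so each $e^\beta$ is directly a rate ratio against those groups.
The date effect is a period-level categorical effect (four levels), matching
how the estimates are reported; a day-of-week design can be emulated by
supplying a custom calendar.

Priors are weakly informative and overridable via `prior_spec()`:
Normal(0, 2.5) on coefficients, Normal($\log \bar y$, 1.5) on the intercept,
half-Normal(0, 1) on $\tau$ and Exponential(0.1) on $\phi$. They are this
package's defaults, chosen by standard practice; analyses that must match a
particular published prior set should pass it explicitly.

### Fitting

Two engines share the model frame:

* **`fit_map()`** — deterministic penalised maximisation. For each $\tau$ on
  a profile grid, coefficients and $\log\phi$ are maximised by penalised
  Fisher scoring alternating with per-participant Newton steps for the
  effects. Profiling $\tau$ at the joint mode alone is degenerate (the joint
  posterior density is unbounded as $\tau \to 0$), so the profile criterion
  is the Laplace approximation to the effect-marginalised posterior: the
  joint maximum plus $\tfrac12\sum_i \log 2\pi/\mathcal{I}_i$, with
  $\mathcal{I}_i$ the curvature of effect $i$ at its conditional mode. The
  default grid spans 0.001–1.5; convergence is a coefficient change below
  `tol` between outer sweeps.

* **`fit_mcmc()`** — a self-contained Metropolis-within-Gibbs sampler with
  four block moves per iteration: (1) the full coefficient vector via a
  Gamerman-style one-step-Newton (penalised IRLS) Gaussian proposal with
  exact Metropolis–Hastings correction; (2) an exact Gibbs recentering of
  each participant-level coefficient against the mean of its participants'
  effects (the flat "ridge" direction of hierarchical models, sampled in
  closed form because it is conditionally Gaussian); (3) a vectorised
  independent random-walk sweep over all participant effects; (4) log-scale
  random walks for $\tau$ and $\phi$. Random-walk scales adapt towards 44%
  acceptance during warmup and are frozen afterwards. Chains initialise with
  overdispersed jitter around a short penalised-likelihood mode.

Convergence is declared when every scalar parameter's split $\hat R$ is at
or below 1.01; the fit carries the full diagnostic table either way. The
default settings (4 chains × 20,000 iterations, half warmup) mirror the
survey analysis they emulate; the package's own tests use scaled-down chains
(hundreds to low thousands of iterations on diaries of 100–1,000
participants) that reach $\hat R \le 1.05$ and, at the
acceptance-experiment sizes, $\hat R \approx 1.01$.

Model comparison uses WAIC and a basic importance-sampling LOO
(`waic()`, `loo_is()`) computed from a thinned set of joint posterior draws;
IS-LOO carries a heavy-tail warning instead of Pareto smoothing, which is
deliberately out of scope.

## The synthetic diary generator

The raw survey data are not redistributable, so the generator
(`generator_config()`, `generate_survey()`) is a first-class, tested
component that emulates the survey's statistical structure:

* **Design**: 1,987 participants by default, quota-like sampling weights for
  age (the published participant margins over ten analysis bins), household
  class, sex and the 17 provincial regions; 14 diary days over the
  two-window calendar.
* **Counts**: exactly the NB random-intercept model above, with default
  coefficients equal to the logs of the published crude rate ratios.
* **Calibration**: the intercept is solved in closed form so the marginal
  mean is 4.81 contacts/participant/day, and $\phi$ is solved so the
  marginal variance is 16.57 (variance-to-mean ratio ≈ 3.4), using
  $E[y] = e^{\alpha + \tau^2/2}\prod_c \sum_l w_{cl} e^{\beta_{cl}}$ and
  $\mathrm{Var}[y] = E[\mu] + E[\mu^2]/\phi + \mathrm{Var}[\mu]$ under
  independent covariate margins. $\tau = 0.4$ is the package's choice of a
  realistic repeated-measures correlation for contact diaries (giving
  roughly a 2.2-fold ratio between the 84th and 50th percentile
  participants); it is not a published value.
* **Attributes**: per-period categorical kernels for relation, location,
  duration, frequency and physical type. The defaults qualitatively encode
  the survey's period contrasts — educational contacts halve in the vacation
  week, coworker and educational contacts collapse at weekends, and the
  holiday period boosts extended-family, infrequent, long-duration, physical
  and cross-region contacts. Contact ages use a two-component kernel:
  assortative mass $s_p$ on the participant's own age bin plus a background
  draw from the population age distribution, with $s_p$ lower in period IV.
  A small configured fraction of contact ages, sexes and regions is masked
  `unknown`, because real diaries contain unknowns and each analysis stage
  must own its exclusion rule.

What the generator does **not** emulate: reporting fatigue across the
fortnight, household-size/age dependence (margins are independent, with a
config hook), occupation-dependent behaviour, day-of-week texture within
periods, and multi-location repeated contacts with the same person. Tests
passing on synthetic data therefore validate the estimators under the
model's assumptions, not the survey's field quality.

`expected_contact_matrix()` returns the generator-implied expectation of the
raw contact matrix in closed form; it is the ground truth for
bootstrap-coverage experiments.

## Contact matrices

`m[i, j]` is the average number of daily contacts a participant in group `j`
reports with persons in group `i`: total tallied contacts divided by the
number of group-`j` participants and by the number of stratum days, so every
matrix is in contacts/participant/day whatever the stratum width. Location
matrices ignore the date and normalise over all 14 days. Contacts with
unknown age (or region, for region matrices) are excluded before
normalisation and counted.

Reciprocity at the population level requires `m[i,j] G[j] = m[j,i] G[i]`;
`reciprocity_correct()` averages the two flows and renormalises,
which is exact, linear, idempotent and conserves total population contacts.
Uncertainty comes from a participant-level bootstrap (the participant is the
sampling unit of a clustered diary; whether to resample participants or
participant-days is not specified by the emulated design, and
participant-level resampling is the standard choice) with 2,000 replicates
by default and central 95% percentile intervals. Replicates that empty an
age group are redrawn up to a capped budget and then fail loudly; silent
NaNs would hide bias.

The next-generation comparison (`dominant_eigenvalue()`, `r0_ratio()`)
assumes equal age-specific transmissibility, under which relative basic
reproduction numbers across periods equal ratios of the matrices' spectral
radii. Power iteration with a dense-eigensolver fallback covers reducible
matrices; period I is the default reference, and corrected matrices are
used. A pre-pandemic comparator matrix is deliberately not bundled — it is
external data the user may supply.

## Numerical choices and degenerate inputs

* NB pmf through log-gamma, valid for non-integer $\phi$; out-of-support
  parameters make `log_posterior()` return $-\infty$ by contract.
* WAIC/LOO use log-sum-exp throughout; a single draw gives a zero
  complexity penalty.
* `split_rhat()` returns 1 for constant chains by convention and requires at
  least four iterations.
* Half-open integer age bins `[lo, hi+1)`, open-ended top bin; the analysis
  preset is the ten published covariate groups, the recruitment preset the
  eight decades.
* Household sizes of five or more merge into `5+`.
* Unknown attribute levels survive reading and validation; exclusion happens
  per stage.
* Ties in `sample()`-based categorical draws are governed solely by the
  seeded RNG, so every generator output is byte-reproducible under a fixed
  seed.

## Problem sizes used by the test-suite experiments

Recovery and coverage experiments are run at sizes the package chooses for
statistical informativeness: a single n = 1,000 diary for point-estimate
recovery (MAP within 15%, scaled-down MCMC within 20% relative error on all
rate ratios), 50 replicate diaries of n = 120 with short two-chain runs for
credible-interval coverage, and 15 replicate diaries of n = 200 with four
wide age groups and B = 400 for bootstrap coverage of the
reciprocity-corrected true matrix. The wide-bin design keeps every group
populated in essentially all bootstrap replicates, which is what the
percentile interval assumes.

## Known limitations

* IS-LOO without tail smoothing is unreliable for highly influential
  observations; the heavy-tail warning flags, not fixes, this.
* The MAP $\tau$ is selected on a finite grid; its resolution (not its
  range) bounds the precision of the reported $\tau$.
* The bootstrap's empty-group redraw slightly biases intervals towards
  diaries that retain all groups; with the recommended group widths the
  redraw rate is well below 1%.
* Region-matrix population sizes default to allocating the national total by
  the participants' regional shares (quota sampling matches the regional
  margins); pass census counts via `G` for exact regional reciprocity
  weights.
* The sampler is random-walk based in its effect block; posteriors from very
  long chains are exchangeable with gradient-based samplers, but effective
  sample sizes per iteration are lower.
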