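# contactdiaries

Analysis of diary-based social-contact surveys for infectious-disease
modelling: descriptive contact-rate summaries, a Bayesian negative-binomial
random-intercept regression of daily contact counts, reciprocity-corrected
bootstrapped contact matrices stratified by survey period, location or
residential region, and next-generation-matrix eigenvalue ratios across
periods. The package targets two-week winter survey designs whose days
partition into four exclusive periods — semester weekdays (I), vacation
weekdays (II), weekends (III) and Lunar New Year holidays (IV) — and ships a
seeded synthetic diary generator that emulates that design, so the entire
pipeline is testable without access to restricted survey microdata.

It is written for epidemiologists and biostatisticians who work with
POLYMOD-style contact diaries and want a reproducible, scriptable route from
raw participant/contact tables to period-stratified mixing matrices.

## The models at the core

**Daily counts.** For participant *i* on day *t*,

```
y_it ~ NegBinomial(mu_it, phi)        Var(y) = mu + mu^2 / phi
log mu_it = alpha + beta_age(i) + beta_hh(i) + beta_period(t)
            + beta_sex(i) + b_i,      b_i ~ Normal(0, tau)
```

with treatment contrasts (reference: age 0–4, household 1, period I,
female), so `exp(beta)` is a rate ratio. Fitting is by penalised MAP
(`fit_map()`, deterministic, Laplace-profiled `tau`) or by a self-contained
adaptive-Metropolis MCMC sampler (`fit_mcmc()`) with split R-hat
diagnostics, WAIC and importance-sampling LOO.

**Contact matrices.** `m[i, j]` is the mean daily number of contacts a
participant in age group *j* reports with persons in group *i*
(`m = x / (g_j * days)`). Reciprocity correction enforces the
population-level symmetry `m[i,j] G_j = m[j,i] G_i` via
`C = (m_ij G_j + m_ji G_i) / 2`, and uncertainty comes from a
participant-level bootstrap (2,000 replicates by default, central 95%
percentile intervals). Dominant-eigenvalue ratios of period matrices give
relative basic reproduction numbers under equal age-specific
transmissibility.

## Worked example

```r
library(contactdiaries)

# a synthetic survey with the design's published margins and rates
cfg   <- generator_config(n_participants = 1987, seed = 1)
diary <- generate_survey(cfg)
diary
#> <survey_diary>
#>   participants: 1987
#>   contact records: 135880
#>   diary days: 14
#>   mean contacts/participant/day: 4.88

round(dispersion_check(diary), 2)
#>    mean variance ratio
#> 1  4.88     16.8  3.44

marginal_means(diary, "period")[, c("level", "marginal_mean", "crude_ratio")]
#>   level marginal_mean crude_ratio
#> 1 I              5.60       1
#> 2 II             4.96       0.886
#> 3 III            3.69       0.659
#> 4 IV             4.53       0.810

m4 <- bootstrap_matrix(diary, period = "IV", B = 200, seed = 1)
autoplot(m4)                       # heatmap, contacts/participant/day

r0_ratio(lapply(setNames(period_levels(), period_levels()), function(p)
  bootstrap_matrix(diary, period = p, B = 200, seed = 1)), reference = "I")
#>   stratum dominant_eigenvalue ratio_to_reference
#> 1 I                      6.33              1
#> 2 II                     5.69              0.899
#> 3 III                    3.96              0.626
#> 4 IV                     4.74              0.749
```

The daily mean (4.88) and variance-to-mean ratio (3.44) sit at the survey's
published operating point (4.81 and ≈3.4); the period crude ratios track the
configured rate ratios (0.89, 0.67, 0.81); and the eigenvalue ratios show
how much lower the transmission potential of weekend and holiday mixing is
than semester-weekday mixing. Note the period IV eigen ratio (0.75) falls
below its rate ratio (0.81): holiday mixing is less age-assortative, which
lowers the spectral radius beyond the drop in contact volume.

A full pipeline run — simulate, summarise, fit, matrices, eigen report, plus
a machine-readable manifest — is one call:

```r
run_pipeline(list(
  calendar  = list(window_a = c("2023-12-06", "2023-12-12"),
                   window_b = c("2024-02-07", "2024-02-13"),
                   holidays = as.character(seq(as.Date("2024-02-09"),
                                               as.Date("2024-02-12"), "day"))),
  generator = list(n_participants = 500, seed = 1),
  model     = list(method = "map"),
  matrix    = list(boot = 500, seed = 1),
  output_dir = "out"))
```

Real data enter through `read_diary()` (participants/contacts/population
CSVs, documented schema, row-level validation); `write_diary()` round-trips
byte-identically.

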