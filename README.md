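# relpseudo

Direct regression modelling of the **crude probability of death** (CPr) from
cancer and from other causes, and of the **number of life years lost** (LYL)
per cause, when the cause of death is unknown or unreliable — the *relative
survival* setting of population-based cancer registries.

## Who this is for

Cancer epidemiologists and biostatisticians working with registry cohorts
(follow-up time, vital status, demographics, covariates — no death
certificates) plus a population life table. Net survival answers "how does
survival compare across populations if the cancer were the only cause?";
the two indicators modelled here answer the complementary "real-world"
questions: the probability of dying *from the cancer* by time *t* in the
presence of competing mortality, and how many of the first τ life years are
lost to each cause.

## The method

The observed hazard is assumed to split additively into an excess
(cancer-related) part and the known expected hazard of the matched general
population:

    λ_O(t; X_i) = λ_C(t; X_i) + λ_P(t; z_i),

with λ_P read from a life table by attained age × calendar year × sex.
Nonparametric estimates on the cohort are

    F̂_C(t) = ∫₀ᵗ Ŝ(u⁻) dΛ̂_C(u),   F̂_P(t) = ∫₀ᵗ Ŝ(u⁻) dΛ̂_P(u),
    dΛ̂_P(u) = Σᵢ Yᵢ(u) dΛ_P(u; zᵢ) / Y(u),   dΛ̂_C = dN/Y − dΛ̂_P,

with Ŝ the Kaplan–Meier estimator (so Ŝ + F̂_C + F̂_P = 1 exactly), and
L̂_C(0,τ) = ∫₀^τ F̂_C, L̂_P(0,τ) = ∫₀^τ F̂_P. Each subject's incompletely
observed outcome is replaced by its leave-one-out **pseudo-observation**

    θ̃_i = n·θ̂ − (n−1)·θ̂^{−i}

computed at m timepoints (CPr) or at the horizon τ (LYL), and modelled by a
GEE g(E[θ̃ | X]) = β'X* with independence working covariance and
cluster-robust sandwich variance. Link choices: `cloglog` (coefficients are
log subdistribution-hazard ratios), `log` (log relative risks), `identity`
(risk differences / additional life years lost).

A subdistribution-hazard simulator (Generalized Weibull baseline with
covariate effects, population mortality for the competing cause, drop-out
and administrative censoring, closed-form truths retained) and a Monte-Carlo
study harness (bias, empirical/model SE, RMSE, coverage, least-false
parameters) validate parameter recovery; see the methods vignette
(`vignettes/pseudo-observations-relative-survival.Rmd`).

## Worked example

```r
library(relpseudo)

rt     <- synth_ratetable()                  # Gompertz-like life table
cfg    <- sim_config(n = 1000, ratetable = rt)
cohort <- simulate_cohort(cfg, seed = 1)

crude <- crude_probabilities(cohort, rt)
crude
#> Crude probabilities of death (relative survival), n = 1000
#>   grid: 4426 points on (0, 10] years
#>   at t = 10:  S = 0.3115,  F_C (cancer) = 0.3974,  F_P (other) = 0.2911

round(lyl(crude, tau = 10), 3)
#> cancer  other  total
#>  3.211  1.638  4.850
```

By 10 years, an estimated 39.7% of the cohort has died of the cancer and
29.1% of other causes; of the first 10 years, 3.21 are lost to cancer and
1.64 to other causes (4.85 in total, i.e. mean survival 5.15 years).

```r
ps  <- pseudo_cpr(cohort, rt, timepoints = select_timepoints(cohort, m = 5))
fit_pseudo_gee(ps, link = "cloglog", cause = "cancer")
#> Pseudo-observation GEE (cloglog link, independence working covariance)
#> cause: cancer, indicator: cpr, 1000 subjects x 5 timepoint(s)
#>             estimate     se   lower   upper
#> (Intercept)  -2.5251 0.1339 -2.7875 -2.2626
#> t=0.6082      0.7245 0.0843  0.5592  0.8898
#> t=1.574       1.0986 0.0987  0.9052  1.2921
#> t=3.129       1.3663 0.1063  1.1580  1.5746
#> t=5.969       1.5060 0.1122  1.2861  1.7259
#> age_c         0.1501 0.0492  0.0536  0.2466
#> sex           0.3754 0.1296  0.1213  0.6295
#> year_c       -0.0785 0.0713 -0.2183  0.0613
#> converged: TRUE in 10 iterations (score norm 2.6e-09)
```

`age_c` is age in decades centred at the cohort mean, so 0.1501 is the log
subdistribution-hazard ratio per 10 years of age (generating value 0.2);
`sex` = 0.3754 is the male-vs-female contrast (generating value 0.3); the
null year effect is correctly near zero. The same cohort's life years lost
to cancer:

```r
pl <- pseudo_lyl(cohort, rt, tau = 10)
fit_pseudo_gee(pl, link = "identity", cause = "cancer")
#>             estimate     se   lower  upper
#> (Intercept)   2.6941 0.2190  2.2649 3.1232
#> age_c         0.3548 0.1032  0.1525 0.5571
#> sex           1.0906 0.3281  0.4477 1.7336
#> year_c       -0.1853 0.1810 -0.5401 0.1696
```

— each decade of age costs an additional 0.35 years (95% CI 0.15–0.56) of
the first ten, and men lose 1.09 years more than women, within this single
simulated cohort.

## Command line

A thin CLI over the same functions lives at
`inst/scripts/relpseudo-cli.R` with subcommands `ratetable-synth`,
`simulate`, `estimate`, `pseudo`, `fit`, `study`; every run writes a JSON
manifest (seed, package version, input digests, outputs). Example chain:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts","relpseudo-cli.R",package="relpseudo"))')
Rscript $CLI ratetable-synth --out rt.csv
printf 'n: 1000\n' > sim.yaml
Rscript $CLI simulate --config sim.yaml --seed 4 --out cohort.csv
Rscript $CLI pseudo   --cohort cohort.csv --ratetable rt.csv \
                      --indicator cpr --cause cancer --m 5 --out pseudo.csv
Rscript $CLI fit      --pseudo pseudo.csv --link cloglog \
                      --covariates age_c,sex,year_c --out fit.csv
```

A study config for the `study` subcommand mirrors `study_config()`:

```yaml
sim: {n: 300}
n_reps: 10
cpr_links: [identity]
causes: [cancer]
indicators: [cpr]
```

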