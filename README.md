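# emaprofiles

Latent suicide-risk profiling of sparse smartphone EMA streams, with a
pre-lockdown vs lockdown prevalence contrast.

## What this package is for

Ecological momentary assessment (EMA) programmes for patients at high risk of
suicide deliver a 32-item questionnaire — wish to die / wish to live, sleep,
negative feelings, appetite — through a *turn-over* design: each patient
answers only 2–4 randomly chosen questions per day, prompted at random times
between 10:00 and 22:00. Every daily observation vector is therefore ~90%
missing by design. `emaprofiles` is for analysts of such streams who want to

1. standardise raw answers onto a worse-is-higher unit scale,
2. discover latent **risk profiles** with an Indian buffet process (IBP)
   latent-feature model whose Gaussian likelihood is evaluated over observed
   entries only (no imputation, no row dropping),
3. assign every observation vector to a profile, compute per-profile
   **signatures** (probability of scoring positive on each item), and
4. contrast profile prevalence between two calendar periods with
   continuity-corrected χ² tests, percent changes, and exact
   (Clopper–Pearson) binomial intervals for pooled rare profiles.

The model is `x_nd = mu_d + (ZA)_nd + eps_nd`, with `Z ~ IBP(alpha)` binary
ownership, Gaussian weights `A`, per-item intercepts `mu`, and
`eps ~ N(0, sigma_X^2)` evaluated only at observed cells; inference is an
uncollapsed Gibbs sampler with conjugate weight/intercept/concentration draws
and a reversible-jump singleton move (see the methods vignette,
`vignettes/risk-profiling.Rmd`). A **profile** is a distinct
feature-activation pattern; rows are labelled by their conditional posterior
mode given the highest-probability retained state.

Because the motivating cohort data are not redistributable, the package
includes a first-class synthetic generator (`simulate_ema_stream()`) that
emulates the study conditions: 36 patients, 2–4 questions/day, 960
pre-lockdown (2019-10-01..2020-03-13) and 214 lockdown (2020-03-14..
2020-04-14) observation vectors, and a 4-profile latent structure whose
mixture shifts between periods.

## Worked example

Period contrasts from published-style prevalence summaries (totals 960 and
214; per-profile prevalences in percent):

```r
library(emaprofiles)
contrast_from_prevalences(960, 214,
                          c(43.0, 17.8, 26.7, 11.8),
                          c(52.8, 10.3, 34.6, 2.3))
#>   profile n_in_pre n_in_lockdown prev_pre_pct prev_lockdown_pct   chi2 p_value pct_change
#> 1       1      413           113         43.0              52.8  6.382   0.012     22.791
#> 2       2      171            22         17.8              10.3  6.689   0.010    -42.135
#> 3       3      256            74         26.7              34.6  5.037   0.025     29.588
#> 4       4      113             5         11.8               2.3 16.200   0.000    -80.508
```

Reading: profile 1 (no risk feature active) rose from 43.0% of the 960
pre-lockdown vectors to 52.8% of the 214 lockdown vectors, a 22.8% relative
increase, significant at χ² = 6.38 (Yates-corrected, 1 df), p = 0.012.
Profiles pooled as "rare" get an exact binomial interval; 7 of 960 gives

```r
clopper_pearson_ci(7, 960)
#>     lower     upper
#> 0.2936507 1.4965592   # percent: 95% CI 0.3-1.5%
```

An end-to-end synthetic run — simulate, fit, profile, compare — is one call:

```r
res <- run_pipeline("out", seed = 1)
res$report
#> Period comparison: 960 pre-lockdown vs 214 lockdown observations
#>   profile 1: 50.5% -> 60.7% (20.2% increase); chi2 = 6.93, p = 0.008
#>   profile 2: 23.5% -> 28.5% (21.1% increase); chi2 = 2.07, p = 0.150
#>   profile 3: 17.9% -> 7.9% (55.7% decrease); chi2 = 12.16, p < 0.001
#>   profile 4: 8.0% -> 2.8% (65.0% decrease); chi2 = 6.48, p = 0.011
```

Here profile 1 is the recovered baseline profile, profiles 2 and 3 are the
negative-emotions and somatic/death-wish axes, and profile 4 combines both;
`match_profiles_to_templates()` aligns recovered signatures with the
generating templates (pooled correlation 0.998 on this run). The fit takes
about two minutes on one core. A thin command-line wrapper with
`simulate` / `fit` / `compare` / `run` subcommands is installed at
`inst/scripts/ema_pipeline.R`.

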