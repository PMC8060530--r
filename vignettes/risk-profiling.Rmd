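---
title: "Latent risk profiling of sparse EMA streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent risk profiling of sparse EMA streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Smartphone ecological momentary assessment (EMA) of psychiatric patients at
high risk of suicide delivers a 32-item questionnaire — wish to die / wish to
live (2 items), sleep (10), negative feelings (13) and appetite (7) — under a
*turn-over* design: to limit burden, each patient is prompted with only two to
four randomly chosen questions per day, at random times between 10:00 and
22:00. The result is a long stream of answers in which every daily observation
vector has roughly 90% of its entries missing *by design*. The scientific
questions are (i) whether a small number of latent risk profiles organises
these sparse vectors, and (ii) whether the prevalence of those profiles shifts
between two calendar periods — here a pre-lockdown window (2019-10-01 to
2020-03-13) and a lockdown window (2020-03-14 to 2020-04-14).

`emaprofiles` implements the full chain: standardisation, latent-feature
discovery with an Indian buffet process (IBP) model whose likelihood touches
only observed entries, profile assignment and signatures, and the
epidemiological period contrast. Because the underlying patient data cannot be
redistributed, the package ships a synthetic generator with the same design
(cohort size, turn-over missingness, period-dependent profile mixture), so
every stage is testable end to end.

## Standardisation

Each raw answer is mapped linearly onto $[0,1]$ over its item's range, with
polarity flipped for positively phrased items ("wish to live", sleep quality,
appetite level) so that **higher always means worse**:

$$s = \frac{x - x_{\min}}{x_{\max} - x_{\min}} \quad\text{or}\quad
  s = 1 - \frac{x - x_{\min}}{x_{\max} - x_{\min}}.$$

A score *scores positive* when $s \ge 0.5$ (inclusive). The threshold is the
midpoint of a worse-is-higher unit scale and is configurable everywhere it is
used. Item wording is not part of the package; the instrument is defined
entirely by a config-driven schema (`default_schema()`, 32 items on 0–10
scales with the domain cardinalities above), and schema order fixes the column
order of every downstream matrix.

Sessions default to one observation vector per patient per calendar day; when
the same question is answered twice in a session the later answer wins (the
count of superseded answers is reported). Sessions outside both period
windows are excluded and counted, never silently dropped.

## The latent-feature model

Let $X$ be the $N \times 32$ matrix of standardised scores with observed-entry
mask $O$. The model is the canonical linear-Gaussian IBP factorisation,
extended with a per-item mean:

$$x_{nd} = \mu_d + (ZA)_{nd} + \varepsilon_{nd}, \qquad
  \varepsilon_{nd} \sim \mathcal N(0, \sigma_X^2),$$

with $Z \in \{0,1\}^{N \times K}$ drawn from an IBP with concentration
$\alpha$ ($K$ unbounded a priori), weights $A_{kd} \sim \mathcal N(0,
\sigma_A^2)$ and intercepts $\mu_d \sim \mathcal N(0, \sigma_\mu^2)$. The
likelihood is a product over *observed* cells only — this is the model's whole
answer to turn-over missingness: no imputation, no row dropping; a row with
three observed items contributes exactly three Gaussian factors.

The intercept deserves a note, because a plain linear-Gaussian IBP omits it.
Standardised scores have a strictly positive baseline (an unaffected patient
still answers around 0.1–0.2, not at 0). Without $\mu$, the most prevalent
feature is recruited as a surrogate intercept: it ends up owned by most rows
and the all-zero "no active feature" pattern loses its meaning. With $\mu$
absorbing item baselines, features model *deviations* — the configuration the
profile interpretation needs. Setting `intercept = FALSE` in `run_gibbs()`
recovers the textbook model; the test-suite comparisons against the collapsed
(weights-integrated) likelihood and against exhaustive enumeration run in that
mode, where the closed forms are exact.

### Inference

`run_gibbs()` is an uncollapsed Gibbs sampler. Per sweep:

1. **Rows.** For each row, each feature shared with another row is resampled
   from its exact Bernoulli conditional — prior odds $m_{-i,k}/(N - m_{-i,k})$
   times the Gaussian likelihood ratio over the row's observed entries. The
   row's singleton features are then replaced through a reversible-jump move:
   a truncated-Poisson$(\alpha/N)$ count of fresh features is proposed and
   accepted with ratio $\tilde p(x_i \mid k_{\text{new}})/\tilde p(x_i \mid
   k_{\text{old}})$, both marginals integrating the affected weight rows out
   analytically; accepted weight rows are drawn from their exact conditional.
   The truncation (cap 4 per step, configurable) is applied to the proposal
   density itself, not by clamping a Poisson draw, so the acceptance ratio
   stays exact.
2. **Weights.** Each column of $A$ is drawn from its conjugate Gaussian
   conditional using only the rows observed at that item; an item nobody
   answered falls back to the prior.
3. **Intercept.** Conjugate draw of each $\mu_d$ from the observed residuals.
4. **Concentration.** $\alpha \sim \Gamma(a + K_+,\, b + H_N)$ with
   $H_N = \sum_{n \le N} 1/n$ (Gamma$(1,1)$ prior, resampling on by default).

Defaults: $\sigma_X = 0.25$, $\sigma_A = 0.5$, $\sigma_\mu = 0.5$,
$\alpha_0 = 1$; 2000 sweeps, 1000 burn-in, thinning 5. These are sized to
$D = 32$ unit-scale items: $\sigma_X$ matches the generator-scale response
noise plus model mismatch, $\sigma_A$ comfortably covers the observed
0.5–0.6 deviations of affected items. Everything is seeded and reruns are
bit-identical. The joint log-probability (IBP class prior + priors +
masked likelihood) is traced each sweep and must stay finite; the retained
state with the highest value (`map_state`) feeds the downstream analysis. A
single concrete state is used — rather than posterior averages — because
label switching and varying $K$ across samples make averaged feature matrices
ill-defined, and the substantive output (profiles) needs one concrete feature
set.

### Correctness checks worth knowing about

The test suite pins the sampler against independent oracles rather than
against itself: the collapsed likelihood is checked against a dense
linear-algebra evaluation and against Monte-Carlo integration over $A$; the
full kernel is checked against exhaustive enumeration of every feature matrix
with at most two columns on a three-row toy (class frequencies agree to well
under 0.02); a prior-only run reproduces $E[K_+] = \alpha H_N$; and the
conjugate steps are checked against their analytic limits (flat prior →
least squares, no data → prior).

## From features to profiles

A **profile** is a distinct feature-activation pattern (a subset of the $K$
features; at most $2^K$ exist, and the all-zero pattern is the baseline
profile). Profiles are numbered by descending prevalence, ties broken by the
pattern read as a binary integer.

Row labels are by default the *conditional posterior mode*: for each row,
the pattern maximising the IBP prior ($m_k/N$ per feature) times the masked
likelihood under the MAP state (`assign_profiles(..., method =
"map_pattern")`). The alternative — reading labels off the sampled rows of
$Z$ — is available as `"sampled_pattern"`, but under turn-over missingness a
sampled row activates any feature its 2–4 observed items say nothing about
with probability $m_k/N$, which is large for prevalent features. That noise
does not average out in prevalence estimates; the posterior-mode rule is
deterministic, and on synthetic data it is what recovers the generating
mixture. Rows whose observations are entirely uninformative collapse to the
prior-preferred pattern (the baseline, for any feature owned by a minority),
which slightly inflates the baseline profile's prevalence — a visible,
documented bias in place of an invisible random one.

A profile's **signature** is its empirical vector of positive-score
probabilities: for each item, the fraction of the profile's rows with an
observed positive score. Cells never observed within a profile are reported
missing, not zero. Signatures are deliberately empirical rather than derived
from $A$, so they stay meaningful under any likelihood.

## Period comparison

For each leading profile (default: top 4) the package forms the 2×2 table of
profile membership against period and applies the continuity-corrected
(Yates) $\chi^2$ test,

$$\chi^2 = \frac{n\,(|ad - bc| - n/2)_+^2}{(a{+}b)(c{+}d)(a{+}c)(b{+}d)},$$

with the correction floored so the statistic is never negative, plus the
signed percent change $100\,(p_{\text{lock}} - p_{\text{pre}})/p_{\text{pre}}$.
Profiles beyond the top group are pooled into a "rare" row with an exact
Clopper–Pearson binomial interval (beta-quantile inversion, lower bound 0 at
zero successes). The Yates variant and the exact interval are the
conventions under which the published statistics of the motivating study are
reproduced from its printed prevalences; reconstructing integer counts from
printed percentages uses round-half-away-from-zero. P-values come from the
upper $\chi^2_1$ tail and are reported to three decimals (`< 0.001` below
that). Rows are treated as independent in these tests although they are
nested within patients; this mirrors the original analysis and is a known
limitation, not an oversight.

## The synthetic generator

`simulate_ema_stream()` emulates the study conditions: 36 patients followed
over both windows; per patient-day a latent profile drawn from the period's
mixture; 2–4 distinct questions per day at uniform times in 10:00–22:00;
answers equal to the profile's per-item severity mean plus
$\mathcal N(0, 0.15)$ noise, clipped to $[0,1]$ and mapped back to the raw
scale; uniform thinning of patient-days to 960 pre-lockdown and 214 lockdown
vectors, emulating partial compliance.

The default latent structure is compositional: a death-wish/somatic axis and
a negative-emotions axis combine into four profiles (neither / somatic only /
affective only / both), with default period mixtures (0.430, 0.178, 0.267,
0.118, 0.007-rare) pre-lockdown and (0.528, 0.103, 0.346, 0.023, 0)
lockdown. Severity means are 0.18 for unaffected and 0.78 for affected
items, chosen once so that the implied positive-score probabilities sit
clearly inside the qualitative bands of the motivating description (affected
items ≈ 0.97, unaffected ≈ 0.02) with the default noise. The residual mass
is spread over four low-distinctiveness templates (mild +0.37 bumps over
8-item blocks). Profiles are redrawn i.i.d. per patient-day; a `sticky`
parameter allows within-patient persistence but defaults to 0, since the
motivating design describes dynamic features without specifying dynamics.

What the generator does **not** emulate: response-style heterogeneity
between patients, autocorrelated symptom trajectories, informative
(symptom-dependent) non-compliance, item-level floor/ceiling clumping, and
drift in item baselines. Passing recovery tests on this generator therefore
demonstrates that the pipeline's inference is sound under its own stated
assumptions — not that real EMA streams satisfy those assumptions.

## Problem sizes and runtime

The shipped configuration fits 1174 observation vectors × 32 items with
~3500 observed entries in about two minutes on one core (2000 sweeps). The
oracle comparisons use deliberately tiny problems — a 3×2 toy for
enumeration (≈50k sweeps) and $10^6$ Monte-Carlo draws for the integral
check — where exhaustive computation is feasible. These sizes are the
package's chosen trade-off between statistical resolution and a test suite
that runs in minutes.

## Known limitations

- Row independence in the $\chi^2$ contrasts ignores within-patient
  clustering (36 patients produce all 1174 rows).
- The Gaussian observation model on clipped unit-interval scores is an
  approximation; a Bernoulli/noisy-OR variant on binarized data is a natural
  extension and is out of scope here.
- The posterior-mode assignment inflates the baseline profile with rows
  whose observed items are uninformative; with 2–4 items per day this is
  unavoidable for any assignment rule and should be kept in mind when
  interpreting absolute prevalences (prevalence *contrasts* between periods
  are less affected, as the bias applies to both).
- MAP-state selection discards posterior uncertainty about $K$ and the
  feature set itself.
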