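---
title: "Personalized emotion networks: models, simulator, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized emotion networks: models, simulator, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the estimators and
their assumptions, what the synthetic-cohort generator emulates and what it
does not, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The estimation model

### Per-participant VAR(1)

Each participant's EMA item series live on an equidistant assessment grid
(e.g. 2/day, 12 h apart). For a subset of $k$ items (default $k = 5$), we fit
one OLS regression per item:

$$x_j(t) = c_j + \sum_{m=1}^{k} \beta_{jm}\, x_m(t-1) + \varepsilon_j(t).$$

Assumptions inherited from the estimator:

* **Stationarity** — constant mean, variance, and dynamics over the study.
  The companion assumption in participants undergoing rapid clinical change
  is not tested by this package.
* **Equidistant lags** — a "lag" is exactly one grid step. If slot $t-1$ is
  missing, slot $t$ contributes *no* regression row; a 12-h design never
  silently produces 24-h or 36-h lags, because those estimate a different
  quantity. Missed assessments therefore stay in the grid as missing rows.
* **Listwise deletion per equation** — a row enters equation $j$ when the
  outcome $x_j(t)$ and all $k$ lagged predictors are observed. No imputation.
  Each equation needs at least $k + 2$ complete lagged pairs.
* **No penalization** — edges are raw OLS coefficients. Aggregating over
  thousands of subnetworks (and over participants for exemplar networks)
  plays the role regularization would otherwise play; shrinking edges toward
  zero would bias the signed sums that are the quantity of interest.

### The two networks and connectivity

The **directed network** is the $k \times k$ coefficient matrix (diagonal =
inertia). Its connectivity is the signed sum of all $k^2$ entries — the
diagonal is included because the $k^2$ coefficients *are* the edge set of
this network.

The **contemporaneous network** summarizes same-moment dependence after
removing temporal structure. The residual series of the $k$ equations are
aligned on their common rows and either

* `partial` (default): $\omega_{jm} = -P_{jm} / \sqrt{P_{jj} P_{mm}}$ with
  $P$ the inverse of the residual covariance matrix, or
* `zero_order`: plain Pearson correlations of residual pairs.

Both modes exist because the two natural readings of "association between
residuals" (partial vs. zero-order) genuinely differ and the field uses both;
the default is the partial-correlation reading, which matches the standard
graphical-model interpretation of contemporaneous networks. Connectivity is
the signed sum of the $k(k-1)/2$ unique off-diagonal entries.

### Preparation

Within-person z-scoring (default on) makes signed sums comparable across
participants and across response scales (Likert −3..+3 vs. VAS 0–100). A
per-item linear detrend is available but off by default: with 8-week windows
the stationarity assumption, not trend removal, is the operative modeling
choice, and both flags are exposed because reasonable pipelines differ here.
Neither transform ever changes the missingness pattern.

## 2. Enumeration and outcome association

All $\binom{n}{k}$ subsets of the item pool are enumerated in lexicographic
order (4,368 for 16 items, 462 for 11). For each subset, connectivity is
computed per participant; failed fits become missing cells (never zeros,
which would bias sums toward null). Per-person average connectivity is the
mean over subsets with a successful fit.

For each subset–outcome analysis, participants at $\ge 3$ SD from the mean on
*either* variable (z computed on that analysis's own sample) are removed
jointly, then Pearson's $r$ with a two-sided $p$ from the $t$ distribution on
$n-2$ df. The removal is deliberately per analysis, so `n_used` varies across
subsets. No multiple-testing correction is applied: the summary quantities
(median $r$, IQR, proportion of $p < .05$) describe the raw distribution over
mutually dependent subnetworks and must be read as descriptive, not as a
family of independent confirmatory tests.

## 3. Stability and cross-sample comparison

The exemplar network is the entrywise mean of per-participant edge matrices.
The CS coefficient follows the standard case-dropping bootstrap convention:
for each drop fraction $f$ in $\{0.05, \dots, 0.75\}$, drop a random fraction
$f$ of the unit, re-estimate, and correlate vectorized non-redundant edges
($k^2$ for directed, unique off-diagonal for contemporaneous) with the
full-data exemplar; CS($0.7$) is the largest $f$ whose 5th-percentile
correlation is still $\ge 0.7$ ("95% of replicates correlate at 0.7"). Both
drop units are exposed: *participants* (the natural unit for exemplar
stability) and *assessments* (which, with the consecutive-lag rule above,
destroys lag pairs and is therefore the strictest probe of directed
networks). Replicates whose data cannot be refit are discarded and counted; a
fraction with > 50% discards is flagged unreliable and cannot carry the CS.
`B` defaults to 500 (a desk-scale compromise; raise for publication runs).

## 4. The synthetic-cohort generator

The generator exists so that every downstream stage has a testable ground
truth. It emulates the statistical structure the analysis *assumes*:

* stationary per-person VAR(1) dynamics over $n$ items (default 16: 9
  negative, 7 positive), with a 200-step burn-in discarded;
* a between-person **connectivity gradient**: one multiplier
  $\gamma_i \sim U(0, \gamma_{max})$ scales both the off-diagonal lag
  couplings and the innovation partial correlations, so directed and
  contemporaneous connectivity track the same gradient (the innovation
  precision is $K(\gamma) = I - \gamma W$, making the true innovation partial
  correlations exactly $\gamma W$);
* design presets matching the two field designs: 2/day × 56 d at 12 h
  (Likert −3..+3) and 3/day × 30 d at 6 h (VAS 0–100, with a held-out
  "gloomy"-style item for the proxy-variability analysis);
* whole-assessment MCAR missingness (you miss a prompt, not half a prompt;
  default rate 0.1, consistent with cohorts that pass a 75% completion
  screen);
* weekly depression scores coupled to negative affect:
  $D_w = \mathrm{round}(\mathrm{clip}(a + b\,\bar{x}^{neg}_w + \eta_w,\,0,\,60))$,
  with the baseline generated the same way from one pre-study week.

Parameter choices and why:

* **Autoregression** diagonal $\sim U(0.25, 0.35)$ — typical EMA inertia.
* **Sign structure**: negative–negative and positive–positive couplings
  positive; cross-valence couplings negative at a **quarter** of the
  within-valence magnitude. Empirical exemplar networks show strong positive
  within-valence partials and much weaker negative cross-valence ones, and a
  stronger cross-valence weight would cancel most of the signed subset sums,
  leaving the gradient invisible to the very statistic under study.
* **Lag vs. innovation coupling ratio 0.6** — with equal ratios one of the
  two stationarity constraints (spectral radius of the lag matrix $\le 0.95$;
  minimum eigenvalue of $K$ $\ge 0.05$) binds long before the other, wasting
  the gradient range of one channel; 0.6 lets both channels approach their
  caps at a similar $\gamma_{max}$ (found by bisection, capped at 2).
* **Depression link** $a = 0$, $b = 25$, $\eta \sim N(0, 1)$ — the offset
  sits at the scale floor on purpose: community depression sum scores are
  right-skewed with floor effects, and it is precisely this skew that couples
  the *mean* of a floor-censored score to its *variance*. That coupling is
  the severity–variability confound the control analyses exist to dissect;
  with an offset far from the floor the synthetic world would contain no
  confound and the control analysis would have nothing to do. $b = 25$ maps
  the weekly mean of negative items onto a realistic 0–15 range of weekly
  scores with SDs of roughly 1–12 across the gradient.

What the generator does **not** emulate — and hence what a green test does
not establish: non-stationary or treatment-driven change, time-varying
networks, MNAR missingness (e.g. mood-dependent skipping), reactivity or
fatigue effects, item-level measurement models (depression is generated from
the latent weekly mean, not from 20 scored items), circadian structure
beyond the fixed grid, and person-level trait differences in mean affect
(intercepts are common). Recovery results on synthetic cohorts validate the
*estimator and pipeline*, not the substantive theory.

## 5. Weekly connectivity and lagged models

Weekly contemporaneous networks are computed from the **full-series** VAR
residuals partitioned by study week (week $w$ = days $7(w-1)$..$7w-1$), not
from per-week VAR refits: ~14 assessments cannot support a 5-predictor
regression, while a week of residual rows can support a 5×5 covariance
(minimum $k+2$ rows, else that week is missing for that subset). This is a
declared interpretation of an ambiguous construct, exposed as its own
function rather than buried in a pipeline.

The lagged model pairs connectivity in week $w$ with depression in week
$w+1$ ("before") or $w-1$ ("after", baseline counting as week 0), z-scores
both over the pooled observations, person-mean-centers the predictor, and
fits OLS with per-person fixed-effect intercepts. A random-intercept variant
would be a reasonable substitute; fixed effects were chosen as the more
assumption-lean default given that the within-person effect is the estimand.
Coefficients from this model should be read directionally.

## 6. Numerical conventions and degenerate inputs

* OLS via QR (`.lm.fit`) in the reference path; the compiled enumeration
  kernel solves normal equations with a symmetric positive-definite solver.
  The two paths agree to ~1e−10 on test problems and the suite enforces it.
* Exact rank deficiency (duplicated predictors) is an error naming the
  subset; regression controls refuse designs with condition number > 1e8.
* Partial correlations require a non-singular residual covariance; the
  singular case is an error (or a counted discard inside bootstrap
  replicates and enumeration cells).
* Likert discretization rounds half away from zero, then clips to −3..+3;
  VAS maps the −3..+3 range affinely onto 0..100 and clips. Exactness-
  sensitive tests run on the continuous scale, where the variance-of-sum
  identity holds to 1e−10 by algebra.
* Inclusion threshold comparisons are inclusive (≥ 75%, ≥ 7 of 9), and
  completion counts assessments with at least one answered item — the most
  permissive reading of "completed an assessment"; partial answers count.
* The SD-of-depression outcome includes the baseline administration (up to 9
  scores); a flag excludes it. Week-8 depression means the week-8 score
  specifically, never last-observation-carried-forward.
* All stochastic functions take explicit seeds, derive any internal streams
  from them, and restore the caller's RNG state.

## 7. Known limitations

Pearson-based subnetwork summaries inherit the usual sensitivity to
outliers; the 3-SD rule is the declared mitigation, not a cure. The
proportion of $p < .05$ over dependent subnetworks has large sampling
variance in any single cohort (the test suite estimates the null rejection
rate by averaging over independent outcome draws for exactly this reason).
CS coefficients are grid-valued (resolution 0.05) and depend on the chosen
drop unit. The CLI covers the standard pipeline but not every keyword
argument of the underlying functions.
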