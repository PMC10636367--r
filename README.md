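# emanet

Personalized emotion networks from ecological momentary assessment (EMA)
data, and their relation to depression severity and depression *variability*.

## The scientific problem

Network theories of psychopathology treat emotions as interacting nodes of a
dynamical system: in densely connected networks a perturbation of one emotion
(say, sadness) propagates to others (guilt, irritability), so the system is
less resilient. A long-standing prediction is that people with more connected
emotion networks are more vulnerable to depression. A system-theoretic
refinement says connectivity should relate not to the *level* of depression
but to its *changeability over time*: high covariance among components
mechanically inflates the variance of any sum score built from them.

`emanet` implements the analysis pipeline used to test this prediction on
intensive longitudinal data — EMA items rated 2–3 times per day for weeks,
alongside weekly depression sum scores (CES-D style, 0–60) — for
psychologists and methodologists working with idiographic (per-participant)
network models. Because raw study data are not bundled, the package includes
a fully specified synthetic-cohort generator whose ground truth makes every
stage testable.

## The model

For participant *i* and a subset of *k* = 5 items, a lag-1 vector
autoregression (VAR(1)) is fit by ordinary least squares, one equation per
item:

    x_j(t) = c_j + Σ_m β_jm · x_m(t−1) + ε_j(t),   j = 1..k

* **Directed (temporal) network** — the k×k matrix of coefficients β
  (25 edges for k = 5; the diagonal is each emotion's inertia). No
  penalization or thresholding is applied.
* **Contemporaneous network** — partial correlations of the residuals
  ε across equations (zero-order residual correlations are available as an
  option), a symmetric k×k matrix with zero diagonal.
* **Connectivity** — the signed sum of edges: all k² entries for directed
  networks, the k(k−1)/2 unique off-diagonal entries for contemporaneous
  ones.

The pipeline enumerates **all** C(n, k) item subsets (4,368 for a 16-item
pool; 462 for 11 items), computes every participant's connectivity in every
subnetwork, averages to a per-person connectivity score, and correlates
connectivity with depression outcomes per subnetwork (with joint 3-SD outlier
removal per analysis). Case-dropping bootstrap CS coefficients quantify
exemplar-network stability, and weekly lagged models test whether
connectivity precedes or follows depression changes.

## Worked example

```r
library(emanet)

# a synthetic cohort: 60 participants, 8 affect items (5 negative),
# twice-daily assessments for 8 weeks, weekly depression scores
spec <- make_spec(n_items = 8, n_negative = 5, seed = 2024)
sim  <- simulate_cohort(spec, n_participants = 60, seed = 2024)
#> <simulated_cohort> 60 participants, gamma in [0.001, 1.947]

# inclusion rules: >= 75% completed assessments, >= 7 of 9 depression scores
inc <- apply_inclusion(sim$cohort)

# within-person standardization, then all C(8,5) = 56 five-node subnetworks
cohort  <- prepare_cohort(inc$cohort)
subsets <- enumerate_subsets(spec$item_names, k = 5, spec$item_valence)
cm      <- connectivity_matrix(cohort, subsets, "contemporaneous")
#> <connectivity_matrix> 60 participants x 56 subsets (contemporaneous), 0 failed fits

# per-person average connectivity vs depression outcomes
ppm <- per_participant_mean(cm)
oc  <- compute_outcomes(cohort)
correlate(ppm, setNames(oc$sd_depression, oc$participant))
#> $r 0.3911556   $p 0.00239683   $n_used 58
correlate(ppm, setNames(oc$baseline, oc$participant))
#> $r -0.007724144   $p 0.9541106   $n_used 58

# severity association controlled for variability
regression_control(ppm, data.frame(baseline = oc$baseline,
                                   sd_depression = oc$sd_depression))
#> <regression_control> n = 60
#>       predictor   beta    se     t       p
#> 1      baseline -0.188 0.137 -1.37 0.17553
#> 2 sd_depression  0.434 0.137  3.17 0.00243

# distribution of per-subnetwork associations + node valence
assoc <- subset_outcome_associations(cm, setNames(oc$sd_depression,
                                                  oc$participant))
#> <subset_association> 56 subsets: median r = 0.284 (IQR 0.205, 0.372), 57.14% of p < 0.05
valence_association(cm$subsets, assoc)$r
#> [1] 0.5819136

# exemplar network stability (case-dropping bootstrap)
st <- correlation_stability(cohort, subsets[[1]], "contemporaneous",
                            "participants", B = 100, seed = 1)
#> <stability_result> contemporaneous network, dropping participants: CS(0.7) = 0.25 (B = 100)
```

Reading the output: connectivity correlates with the 8-week SD of depression
(r = 0.39) but not with baseline severity (r = −0.01), and the depression-SD
coefficient survives a joint regression while baseline does not — the
variability, not severity, signature. Subnetworks containing more
negative-valence items show stronger associations (valence r = 0.58). The
CS(0.7) of 0.25 says the exemplar network in this *small* cohort tolerates
dropping 25% of participants while staying correlated ≥ 0.7 with the
full-data network in 95% of bootstrap replicates.

Real data enter through two CSV formats: a long EMA table
(`participant, assessment_index, item, value`) read by `read_ema_table()`,
and a weekly depression table (`participant, week, score`) read by
`read_depression_table()`. A command-line interface wrapping the same
pipeline is installed as `exec/emanet` (subcommands `simulate`, `preprocess`,
`fit`, `enumerate`, `stability`, `analyze`, `temporal`; see
`emanet help`).

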