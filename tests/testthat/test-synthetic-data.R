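test_that("make_spec produces stationary, valence-structured templates", {
  # no coupling: diagonal lag matrix, spectral radius = max autoregression
  s0 <- make_spec(n_items = 4, base_coupling = 0, seed = 1)
  expect_true(all(s0$A0[row(s0$A0) != col(s0$A0)] == 0))
  expect_lt(max(diag(s0$A0)), 1)
  expect_equal(emanet:::spectral_radius(s0$A0), max(diag(s0$A0)))

  # full pool: stationarity at gamma_max, checked by power iteration
  s <- make_spec(n_items = 16, base_coupling = 0.05, seed = 2)
  A <- emanet:::lag_matrix(s, s$gamma_range[2])
  expect_lt(oracle_spectral_radius(A), 1)
  S <- emanet:::innovation_cov(s, s$gamma_range[2])
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)

  # valence sign structure: same-valence couplings positive, cross negative
  neg <- which(s$item_valence == "negative")
  pos <- which(s$item_valence == "positive")
  off <- s$A0; diag(off) <- NA
  expect_true(all(off[neg, neg] > 0, na.rm = TRUE))
  expect_true(all(off[pos, pos] > 0, na.rm = TRUE))
  expect_true(all(off[neg, pos] < 0))

  # single item: autoregression only
  s1 <- make_spec(n_items = 1, base_coupling = 0.05, seed = 3)
  expect_equal(dim(s1$A0), c(1L, 1L))
  expect_lt(s1$A0[1, 1], 1)
})

test_that("simulate_participant is deterministic and respects the process", {
  spec <- make_spec(n_items = 4, base_coupling = 0.05, seed = 4,
                    scale = "continuous", missing_rate = 0)

  p1 <- simulate_participant(spec, 0.3, T = 50, seed = 9)
  p2 <- simulate_participant(spec, 0.3, T = 50, seed = 9)
  expect_identical(p1$values, p2$values)

  expect_error(simulate_participant(spec, spec$gamma_range[2] + 1, T = 50),
               "gamma")

  # gamma = 0: lag-1 cross-correlations vanish (scale-free 3/sqrt(T) bound)
  T <- 5000
  p0 <- simulate_participant(spec, 0, T = T, seed = 10)
  v <- p0$values
  for (i in 1:3) for (j in (i + 1):4) {
    cc <- cor(v[-1, i], v[-T, j])
    expect_lt(abs(cc), 3 / sqrt(T))
  }

  # known A(gamma) recovered by an independent lag-1 OLS at T = 10,000
  sp <- sim_panel(n_items = 5, T = 10000, gamma_frac = 0.5, seed = 20)
  v <- sp$panel$values
  X <- cbind(1, v[-nrow(v), ])
  Ahat <- t(vapply(1:5, function(i) oracle_ols(X, v[-1, i])[-1], numeric(5)))
  expect_lt(max(abs(Ahat - sp$A)), 0.03)
})

test_that("likert and vas discretization stay within scale bounds", {
  spec_l <- make_spec(n_items = 3, base_coupling = 0.05, seed = 5,
                      scale = "likert", missing_rate = 0)
  vl <- simulate_participant(spec_l, 0.2, T = 300, seed = 6)$values
  expect_true(all(vl >= -3 & vl <= 3))
  expect_true(all(vl == round(vl)))
  spec_v <- make_spec(n_items = 3, base_coupling = 0.05, seed = 5,
                      scale = "vas", missing_rate = 0)
  vv <- simulate_participant(spec_v, 0.2, T = 300, seed = 6)$values
  expect_true(all(vv >= 0 & vv <= 100))
})

test_that("simulate_cohort couples depression to negative affect", {
  # b = 0, noise_sd = 0: every score is the constant round(clip(a))
  spec <- make_spec(n_items = 4, base_coupling = 0.05, seed = 7,
                    depression_link = list(a = 12.4, b = 0, noise_sd = 0),
                    design = list(assessments_per_day = 2, n_days = 14,
                                  hours_between = 12))
  sim <- simulate_cohort(spec, 3, seed = 8)
  for (d in sim$cohort$depression) {
    expect_true(all(d$scores[1:3] == 12))
  }

  # gamma gradient drives SD of depression (n = 200, full design)
  spec <- make_spec(seed = 11)
  sim <- simulate_cohort(spec, 200, seed = 12)
  oc <- compute_outcomes(sim$cohort)
  expect_gt(cor(sim$true_gamma, oc$sd_depression), 0.3)

  # ground truth is consistent with the generative parameters
  g1 <- sim$true_gamma[[1]]
  expect_equal(sim$true_networks[[1]]$A,
               emanet:::lag_matrix(spec, g1))

  # MCAR missingness hits the requested rate
  spec_m <- make_spec(seed = 13, missing_rate = 0.25)
  sim_m <- simulate_cohort(spec_m, 200, seed = 14)
  obs <- vapply(sim_m$cohort$panels, function(p) mean(!is.na(p$values)),
                numeric(1))
  expect_lt(abs(mean(1 - obs) - 0.25), 0.03)
})

test_that("variance-of-sum identity holds exactly on continuous panels", {
  for (seed in 1:3) {
    sp <- sim_panel(n_items = 6, T = 400, gamma_frac = 0.7, seed = seed)
    v <- sp$panel$values
    expect_equal(var(rowSums(v)), sum(cov(v)), tolerance = 1e-12)
  }
})

test_that("long-run moments are stationary and connectivity tracks gamma", {
  spec <- make_spec(n_items = 5, base_coupling = 0.05, seed = 30,
                    scale = "continuous", missing_rate = 0)
  T <- 10000
  p <- simulate_participant(spec, 0.8 * spec$gamma_range[2], T = T, seed = 31)
  v <- p$values
  half <- seq_len(T / 2)
  for (j in 1:5) {
    se <- sd(v[, j]) / sqrt(T / 2)
    expect_lt(abs(mean(v[half, j]) - mean(v[-half, j])), 4 * se)
  }

  # monotone contemporaneous connectivity across gamma = 0, mid, max
  gam <- c(0, spec$gamma_range[2] / 2, spec$gamma_range[2])
  sub <- node_subset(spec$item_names, spec$item_valence)
  conn <- vapply(seq_along(gam), function(i) {
    pp <- simulate_participant(spec, gam[i], T = T, seed = 40 + i)
    contemporaneous_from_residuals(fit_var(pp, sub))$connectivity
  }, numeric(1))
  expect_true(all(diff(conn) > 0))
})
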