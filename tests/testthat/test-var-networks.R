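test_that("fit_var matches an independent normal-equations solver", {
  for (seed in 1:3) {
    k <- sample(3:5, 1)
    panel <- toy_panel(T = 60 + 10 * seed,
                       items = paste0("it", seq_len(k)), seed = seed)
    sub <- node_subset(panel$item_names, panel$item_valence)
    fit <- fit_var(panel, sub)
    expect_equal(length(fit$directed$edges), k * k)

    v <- panel$values
    X <- cbind(1, v[-nrow(v), ])
    for (i in seq_len(k)) {
      cf <- oracle_ols(X, v[-1, i])
      expect_equal(unname(fit$directed$edges[i, ]), unname(cf[-1]),
                   tolerance = 1e-8)
      expect_equal(unname(fit$directed$intercepts[i]), unname(cf[1]),
                   tolerance = 1e-8)
    }
    # connectivity is exactly the signed sum of all k^2 edges
    expect_identical(fit$directed$connectivity, sum(fit$directed$edges))
  }
})

test_that("a 5-node fit yields exactly 25 directed edges", {
  panel <- toy_panel(T = 60, items = paste0("it", 1:5))
  fit <- fit_var(panel, node_subset(panel$item_names, panel$item_valence))
  expect_identical(dim(fit$directed$edges), c(5L, 5L))
})

test_that("lag pairs use consecutive slots only and missing rows drop out", {
  panel <- toy_panel(T = 30, items = c("x", "y"))
  panel$values[10, ] <- NA  # kills lag pairs (9->10) and (10->11)
  fit <- fit_var(panel, node_subset(c("x", "y"), panel$item_valence))
  expect_equal(unique(fit$directed$n_lag_pairs_used), 29 - 2)
  expect_true(all(is.na(fit$residuals[c(9, 10), ])))
})

test_that("white-noise and known-A panels are recovered", {
  sp0 <- sim_panel(n_items = 4, T = 10000, gamma_frac = 0, seed = 5)
  fit0 <- fit_var(sp0$panel, node_subset(sp0$panel$item_names,
                                         sp0$panel$item_valence))
  off <- fit0$directed$edges[row(fit0$directed$edges) !=
                             col(fit0$directed$edges)]
  expect_lt(max(abs(off)), 0.03)

  sp <- sim_panel(n_items = 5, T = 10000, gamma_frac = 0.8, seed = 6)
  fit <- fit_var(sp$panel, node_subset(sp$panel$item_names,
                                       sp$panel$item_valence))
  expect_lt(max(abs(fit$directed$edges - sp$A)), 0.03)
})

test_that("fit_var errors on insufficient or collinear data", {
  panel <- toy_panel(T = 6, items = paste0("it", 1:5))
  expect_error(fit_var(panel, node_subset(panel$item_names,
                                          panel$item_valence)),
               "insufficient data")

  p2 <- toy_panel(T = 40, items = c("x", "y", "z"))
  p2$values[, "y"] <- 2 * p2$values[, "x"]
  expect_error(fit_var(p2, node_subset(c("x", "y", "z"), p2$item_valence)),
               "collinear")
})

test_that("contemporaneous partial correlations match the brute-force oracle", {
  for (k in 3:5) {
    set.seed(k)
    R <- matrix(rnorm(200 * k), 200, k)
    R[, 2] <- R[, 2] + 0.5 * R[, 1]
    if (k > 3) R[, 4] <- R[, 4] - 0.3 * R[, 2]
    colnames(R) <- paste0("it", seq_len(k))
    net <- contemporaneous_from_residuals(R, mode = "partial")
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      expect_equal(net$edges[i, j], oracle_partial_cor(R, i, j),
                   tolerance = 1e-10)
    }
    expect_identical(net$edges, t(net$edges))
    expect_true(all(diag(net$edges) == 0))
    expect_identical(net$connectivity, sum(net$edges[upper.tri(net$edges)]))

    # zero-order mode is the plain Pearson correlation
    net0 <- contemporaneous_from_residuals(R, mode = "zero_order")
    C <- cor(R); diag(C) <- 0
    expect_equal(net0$edges, C, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("independent residuals give a near-empty contemporaneous network", {
  set.seed(9)
  R <- matrix(rnorm(20000 * 3), ncol = 3, dimnames = list(NULL, letters[1:3]))
  net <- contemporaneous_from_residuals(R)
  expect_lt(max(abs(net$edges)), 0.03)
})

test_that("connectivity arithmetic and error handling", {
  d <- structure(list(edges = matrix(c(0.4, -0.2, 0.1, 0.3), 2, 2)),
                 class = "directed_network")
  expect_equal(connectivity(d), 0.6)

  e <- matrix(0, 3, 3)
  e[upper.tri(e)] <- c(0.5, -0.2, 0.1)
  e <- e + t(e)
  cn <- structure(list(edges = e), class = "contemporaneous_network")
  expect_equal(connectivity(cn), 0.4)

  z <- structure(list(edges = matrix(0, 4, 4)), class = "directed_network")
  expect_equal(connectivity(z), 0)

  d$edges[1, 1] <- NaN
  expect_error(connectivity(d), "non-finite")
})

test_that("connectivity is invariant to node ordering within the subset", {
  panel <- toy_panel(T = 80, items = paste0("it", 1:5), seed = 3)
  items <- panel$item_names
  f1 <- fit_var(panel, node_subset(items, panel$item_valence))
  f2 <- fit_var(panel, node_subset(rev(items), panel$item_valence))
  expect_equal(f1$directed$connectivity, f2$directed$connectivity,
               tolerance = 1e-12)
  expect_equal(contemporaneous_from_residuals(f1)$connectivity,
               contemporaneous_from_residuals(f2)$connectivity,
               tolerance = 1e-12)
})

test_that("compiled batch kernel equals the pure-R path cell by cell", {
  spec <- make_spec(n_items = 6, seed = 44, missing_rate = 0.2)
  panel <- prepare_series(simulate_participant(spec, 0.7 * spec$gamma_range[2],
                                               T = 112, seed = 45))
  cohort <- ema_cohort(list(panel))
  subs <- enumerate_subsets(panel$item_names, 5, panel$item_valence)
  for (ty in c("directed", "contemporaneous")) {
    a <- connectivity_matrix(cohort, subs, ty, engine = "cpp")
    b <- connectivity_matrix(cohort, subs, ty, engine = "r")
    expect_equal(a$values, b$values, tolerance = 1e-10)
  }
  zo_a <- connectivity_matrix(cohort, subs, "contemporaneous",
                              mode = "zero_order", engine = "cpp")
  zo_b <- connectivity_matrix(cohort, subs, "contemporaneous",
                              mode = "zero_order", engine = "r")
  expect_equal(zo_a$values, zo_b$values, tolerance = 1e-10)
})
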