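test_that("subset enumeration matches binomial coefficients", {
  pool16 <- paste0("it", 1:16)
  s16 <- enumerate_subsets(pool16, 5)
  expect_length(s16, 4368)
  expect_length(enumerate_subsets(paste0("it", 1:11), 5), 462)
  expect_length(enumerate_subsets(paste0("it", 1:5), 5), 1)
  expect_error(enumerate_subsets(paste0("it", 1:4), 5), "exceeds")

  # deterministic lexicographic order, no duplicates
  labs <- vapply(s16, function(s) paste(s$items, collapse = "+"), character(1))
  expect_identical(anyDuplicated(labs), 0L)
  expect_identical(s16[[1]]$items, pool16[1:5])
  expect_identical(s16[[4368]]$items, pool16[12:16])

  # property: counts match choose(n, k) for assorted (n, k)
  for (n in c(6, 9, 12)) for (k in c(2, 4, min(5, n))) {
    expect_length(enumerate_subsets(paste0("x", 1:n), k), choose(n, k))
  }

  # valence tagging
  val <- setNames(rep(c("negative", "positive"), each = 8), pool16)
  s <- enumerate_subsets(pool16, 5, val)
  expect_identical(s[[1]]$n_negative, 5L)
  expect_identical(s[[4368]]$n_negative, 0L)
})

test_that("connectivity_matrix fills cells and reports failures", {
  items <- paste0("it", 1:5)
  good <- lapply(1:3, function(i) toy_panel(T = 60, items = items,
                                            seed = i, id = paste0("p", i)))
  short <- toy_panel(T = 6, items = items, seed = 9, id = "p4")
  cohort <- ema_cohort(c(good, list(short)))
  subs <- enumerate_subsets(items, 5)

  cm <- connectivity_matrix(cohort, subs, "contemporaneous")
  expect_identical(dim(cm$values), c(4L, 1L))
  expect_true(all(is.finite(cm$values[1:3, ])))
  expect_true(is.na(cm$values[4, 1]))
  expect_identical(cm$failures$participant, "p4")
  expect_match(cm$failures$reason, "insufficient")
})

test_that("per_participant_mean averages non-missing cells", {
  cm <- structure(list(values = matrix(c(1, 2, 3, NA, 4, 5), 2, 3,
                                       dimnames = list(c("a", "b"), NULL))),
                  class = "connectivity_matrix")
  m <- per_participant_mean(cm)
  expect_equal(unname(m["a"]), mean(c(1, 3, 4)))
  expect_equal(unname(m["b"]), mean(c(2, 5)))

  # permuting subset columns leaves means unchanged
  cm2 <- cm; cm2$values <- cm$values[, c(3, 1, 2)]
  expect_equal(per_participant_mean(cm2), m)

  cm$values[2, ] <- NA
  expect_error(per_participant_mean(cm), "b")
})

test_that("subset_outcome_associations: identity, outliers, p-values", {
  items <- paste0("it", 1:6)
  panels <- lapply(1:30, function(i) toy_panel(T = 60, items = items,
                                               seed = 100 + i,
                                               id = sprintf("p%02d", i)))
  cohort <- ema_cohort(panels)
  subs <- enumerate_subsets(items, 5)
  cm <- connectivity_matrix(cohort, subs, "contemporaneous")

  # outcome identical to a subset's connectivity gives r = 1 there
  for (s in c(1, 4)) {
    outc <- setNames(cm$values[, s], rownames(cm$values))
    a <- subset_outcome_associations(cm, outc)
    expect_equal(a$per_subset$r[s], 1, tolerance = 1e-12)
    expect_lt(a$per_subset$p[s], 1e-12)
  }

  # r and p match cor.test on the jointly outlier-cleaned sample
  set.seed(7)
  outc <- setNames(rnorm(30), rownames(cm$values))
  a <- subset_outcome_associations(cm, outc)
  x <- cm$values[, 2]
  keep <- abs(x - mean(x)) / sd(x) < 3 & abs(outc - mean(outc)) / sd(outc) < 3
  ct <- cor.test(x[keep], outc[keep])
  expect_equal(a$per_subset$r[2], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(a$per_subset$p[2], ct$p.value, tolerance = 1e-12)
  expect_equal(a$per_subset$n_used[2], sum(keep))
  expect_true(all(abs(a$per_subset$r) <= 1))
})

test_that("a single far-out participant drops n_used by 1 in every subset", {
  # bounded (uniform) connectivity values cannot produce natural 3-SD outliers
  set.seed(17)
  ids <- sprintf("p%02d", 1:30)
  vals <- matrix(runif(30 * 4), 30, 4, dimnames = list(ids, paste0("s", 1:4)))
  cm <- structure(list(values = vals,
                       subsets = enumerate_subsets(paste0("it", 1:4), 2)[1:4]),
                  class = "connectivity_matrix")
  outc <- setNames(runif(30), ids)
  outc[1] <- mean(outc[-1]) + 10 * sd(outc[-1])
  a <- subset_outcome_associations(cm, outc)
  expect_true(all(a$per_subset$n_used == 29))
})

test_that("correlate and subset_outcome_associations agree on one pair", {
  set.seed(11)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40)
  names(x) <- names(y) <- sprintf("p%02d", 1:40)
  cm <- structure(list(values = matrix(x, ncol = 1,
                                       dimnames = list(names(x), "s")),
                       subsets = list(node_subset(c("a", "b")))),
                  class = "connectivity_matrix")
  a <- subset_outcome_associations(cm, y)
  cl <- correlate(x, y)
  expect_equal(a$per_subset$r[1], cl$r, tolerance = 1e-12)
  expect_equal(a$per_subset$p[1], cl$p, tolerance = 1e-12)
  expect_equal(a$per_subset$n_used[1], cl$n_used)
})
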