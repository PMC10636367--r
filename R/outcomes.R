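# Depression outcomes and their association with per-participant connectivity.

#' Per-participant depression and variability outcomes
#'
#' Computes, per participant: baseline depression (week 0), week-8 depression
#' (index 8 only, no carry-forward), the SD of all available depression
#' scores including baseline (the study's variability outcome; sample SD,
#' n - 1 denominator, only when at least `min_scores` administrations are
#' present), an optional proxy variability outcome (the SD of one designated
#' held-out EMA item, for designs without weekly questionnaires), and the
#' mean within-person variance across EMA items (the item-variance control
#' covariate; the holdout item is excluded).
#'
#' @param cohort An [ema_cohort].
#' @param holdout_item Item label held out from all network analyses whose SD
#'   serves as the variability proxy, or `NULL`.
#' @param pool Optional item pool used for network enumeration; supplying a
#'   `holdout_item` that is inside this pool is an error (circularity guard).
#' @param min_scores Minimum depression administrations for `sd_depression`
#'   (default 2).
#' @param include_baseline Include the baseline score in `sd_depression`?
#'   Default `TRUE`.
#' @return data.frame of class `outcome_set` with one row per participant:
#'   `participant`, `baseline`, `week8`, `sd_depression`, `proxy_sd`,
#'   `mean_item_variance`.
#' @export
compute_outcomes <- function(cohort, holdout_item = NULL, pool = NULL,
                             min_scores = 2, include_baseline = TRUE) {
  stopifnot(inherits(cohort, "ema_cohort"))
  if (!is.null(holdout_item) && !is.null(pool) && holdout_item %in% pool) {
    stop("holdout item '", holdout_item,
         "' is inside the enumeration pool (circularity)", call. = FALSE)
  }
  ids <- participant_ids(cohort)
  out <- data.frame(participant = ids, baseline = NA_real_, week8 = NA_real_,
                    sd_depression = NA_real_, proxy_sd = NA_real_,
                    mean_item_variance = NA_real_, stringsAsFactors = FALSE,
                    row.names = ids)
  for (id in ids) {
    d <- cohort$depression[[id]]
    if (!is.null(d)) {
      s <- d$scores
      out[id, "baseline"] <- s[1]
      out[id, "week8"] <- s[9]
      use <- if (include_baseline) s else s[-1]
      use <- use[!is.na(use)]
      if (length(use) >= min_scores) out[id, "sd_depression"] <- sd(use)
    }
    panel <- cohort$panels[[id]]
    items <- panel$item_names
    if (!is.null(holdout_item)) {
      if (holdout_item %in% items) {
        x <- panel$values[, holdout_item]
        x <- x[!is.na(x)]
        if (length(x) >= 2) out[id, "proxy_sd"] <- sd(x)
      }
      items <- setdiff(items, holdout_item)
    }
    vars <- apply(panel$values[, items, drop = FALSE], 2, var, na.rm = TRUE)
    out[id, "mean_item_variance"] <- mean(vars, na.rm = TRUE)
  }
  class(out) <- c("outcome_set", "data.frame")
  out
}

#' Pearson correlation with joint 3-SD outlier removal
#'
#' The subject-level association used throughout: participants at least
#' `outlier_sd` SDs from the mean on either variable (z computed on this
#' analysis's own sample) are removed jointly, then Pearson r with a
#' two-sided t-based p-value.
#'
#' @param x,y Aligned per-participant numeric vectors.
#' @param outlier_sd Outlier threshold in SD units (default 3).
#' @return List `(r, p, n_used)`.
#' @export
correlate <- function(x, y, outlier_sd = 3) {
  if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
  if (sum(!is.na(x) & !is.na(y)) < 4) stop("need >= 4 aligned pairs",
                                           call. = FALSE)
  cl <- remove_joint_outliers(x, y, outlier_sd)
  if (sd(cl$x) == 0 || sd(cl$y) == 0) stop("zero variance", call. = FALSE)
  pr <- pearson_with_p(cl$x, cl$y)
  list(r = pr$r, p = pr$p, n_used = cl$n_used)
}

#' Standardized multiple regression (control analysis)
#'
#' Z-scores the dependent variable and every predictor on the complete cases,
#' then ordinary least squares with intercept. With a single predictor the
#' standardized coefficient equals the Pearson correlation. Used for the
#' severity-vs-variability control (connectivity ~ baseline + SD depression)
#' and the item-variance control.
#'
#' @param dv Named per-participant numeric vector (dependent variable).
#' @param ivs Named list or data.frame of per-participant predictors.
#' @param condition_limit Design-matrix condition-number limit above which
#'   predictors are declared collinear (default 1e8).
#' @return Object of class `regression_control`: `coefficients` data.frame
#'   (predictor, beta, se, t, p) and `n`.
#' @export
regression_control <- function(dv, ivs, condition_limit = 1e8) {
  ivs <- as.data.frame(ivs)
  stopifnot(nrow(ivs) == length(dv))
  cc <- complete.cases(cbind(dv, ivs))
  n <- sum(cc)
  if (n < ncol(ivs) + 3) stop("need >= n_ivs + 3 complete cases", call. = FALSE)
  z <- function(v) (v - mean(v)) / sd(v)
  y <- z(dv[cc])
  Xz <- as.data.frame(lapply(ivs[cc, , drop = FALSE], z))
  kappa_x <- kappa(cbind(1, as.matrix(Xz)), exact = TRUE)
  if (!is.finite(kappa_x) || kappa_x > condition_limit) {
    stop("collinear predictors (condition number ", format(kappa_x), ")",
         call. = FALSE)
  }
  fit <- lm(y ~ ., data = cbind(y = y, Xz))
  sm <- summary(fit)$coefficients[-1, , drop = FALSE]
  structure(
    list(coefficients = data.frame(predictor = names(Xz),
                                   beta = sm[, 1], se = sm[, 2],
                                   t = sm[, 3], p = sm[, 4],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
         n = n),
    class = "regression_control"
  )
}

#' @export
print.regression_control <- function(x, ...) {
  cat(sprintf("<regression_control> n = %d\n", x$n))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Does node valence drive the connectivity-outcome association?
#'
#' Pearson correlation, across subnetworks, between the number of
#' negative-valence items in each subset and that subset's
#' connectivity-outcome correlation coefficient.
#'
#' @param subsets The subsets used (list of [node_subset] with valence tags),
#'   aligned to `associations`.
#' @param associations A [subset_outcome_associations()] result.
#' @return List `(r, p, n)`.
#' @export
valence_association <- function(subsets, associations) {
  stopifnot(inherits(associations, "subset_association"))
  n_neg <- vapply(subsets, `[[`, integer(1), "n_negative")
  r <- associations$per_subset$r
  keep <- !is.na(r) & !is.na(n_neg)
  if (length(unique(n_neg[keep])) < 2) {
    stop("degenerate valence distribution: all subsets share one negative count",
         call. = FALSE)
  }
  pr <- pearson_with_p(n_neg[keep], r[keep])
  list(r = pr$r, p = pr$p, n = pr$n)
}
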