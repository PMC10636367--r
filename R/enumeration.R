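# Exhaustive k-node subnetwork enumeration and cross-participant summaries.

#' Enumerate all k-node subsets of an item pool
#'
#' All `choose(n, k)` combinations in deterministic lexicographic order
#' (order of `item_pool`), each tagged with its count of negative-valence
#' items. A 16-item pool yields 4,368 5-node subsets; an 11-item pool 462.
#'
#' @param item_pool Ordered item labels.
#' @param k Subset size (default 5).
#' @param item_valence Optional named valence vector for negative-item counts.
#' @return List of [node_subset] objects.
#' @export
enumerate_subsets <- function(item_pool, k = 5, item_valence = NULL) {
  n <- length(item_pool)
  if (k > n) stop("k = ", k, " exceeds pool size ", n, call. = FALSE)
  idx <- combn(n, k)
  lapply(seq_len(ncol(idx)), function(j) {
    node_subset(item_pool[idx[, j]], item_valence)
  })
}

subset_labels <- function(subsets) {
  vapply(subsets, function(s) paste(s$items, collapse = "+"), character(1))
}

#' Connectivity of every participant in every subnetwork
#'
#' Fits the lag-1 VAR of each subset for each participant and records the
#' signed-sum connectivity. Failed fits (insufficient lagged pairs, singular
#' designs) become `NA` cells and are reported, never zeros. The default
#' engine is the compiled batch kernel; `engine = "r"` routes every cell
#' through [fit_var()] / [contemporaneous_from_residuals()] (identical
#' results, used for cross-validation of the two paths).
#'
#' @param cohort A prepared [ema_cohort].
#' @param subsets List of [node_subset], e.g. from [enumerate_subsets()].
#' @param network_type `"contemporaneous"` (default) or `"directed"`.
#' @param mode Contemporaneous edge mode, `"partial"` or `"zero_order"`.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return Object of class `connectivity_matrix`: `values` (participants x
#'   subsets), `subsets`, `network_type`, `mode`, `failures` (data.frame).
#' @export
connectivity_matrix <- function(cohort, subsets,
                                network_type = c("contemporaneous", "directed"),
                                mode = c("partial", "zero_order"),
                                engine = c("cpp", "r")) {
  network_type <- match.arg(network_type)
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  ids <- participant_ids(cohort)
  m <- length(subsets)
  values <- matrix(NA_real_, length(ids), m,
                   dimnames = list(ids, subset_labels(subsets)))
  fails <- list()

  type_code <- if (network_type == "directed") 0L
               else if (mode == "partial") 1L else 2L

  for (p in seq_along(ids)) {
    panel <- cohort$panels[[p]]
    if (engine == "cpp") {
      lp <- lagged_pair(panel)
      sub_idx <- vapply(subsets, function(s) match(s$items, panel$item_names),
                        integer(length(subsets[[1]]$items)))
      res <- batch_fit_cpp(lp$X, lp$Y, sub_idx, type_code, FALSE)
      values[p, ] <- res$connectivity
      bad <- which(res$fail != 0)
      for (s in bad) {
        fails[[length(fails) + 1]] <- data.frame(
          participant = ids[p], subset = subset_labels(subsets[s]),
          reason = c("insufficient data", "singular fit")[res$fail[s]],
          stringsAsFactors = FALSE)
      }
    } else {
      for (s in seq_len(m)) {
        val <- tryCatch({
          fit <- fit_var(panel, subsets[[s]])
          if (network_type == "directed") fit$directed$connectivity
          else contemporaneous_from_residuals(fit, mode)$connectivity
        }, error = function(e) {
          fails[[length(fails) + 1]] <<- data.frame(
            participant = ids[p], subset = subset_labels(subsets[s]),
            reason = conditionMessage(e), stringsAsFactors = FALSE)
          NA_real_
        })
        values[p, s] <- val
      }
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(participant = character(0), subset = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(list(values = values, subsets = subsets,
                 network_type = network_type, mode = mode,
                 failures = failures),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d participants x %d subsets (%s), %d failed fits\n",
              nrow(x$values), ncol(x$values), x$network_type,
              nrow(x$failures)))
  invisible(x)
}

#' Per-participant average connectivity
#'
#' Arithmetic mean of each participant's connectivity over all subsets with a
#' successful fit — the "per-person average connectivity" individual-difference
#' score.
#'
#' @param result A [connectivity_matrix()] result.
#' @return Named numeric vector.
#' @export
per_participant_mean <- function(result) {
  stopifnot(inherits(result, "connectivity_matrix"))
  all_missing <- rowSums(!is.na(result$values)) == 0
  if (any(all_missing)) {
    stop("participant(s) with no successful fit: ",
         paste(rownames(result$values)[all_missing], collapse = ", "),
         call. = FALSE)
  }
  rowMeans(result$values, na.rm = TRUE)
}

# joint |z| >= outlier_sd removal on two aligned vectors; z on this sample
remove_joint_outliers <- function(x, y, outlier_sd = 3) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  zx <- if (sd(x) > 0) abs(x - mean(x)) / sd(x) else rep(0, length(x))
  zy <- if (sd(y) > 0) abs(y - mean(y)) / sd(y) else rep(0, length(y))
  ok <- zx < outlier_sd & zy < outlier_sd
  list(x = x[ok], y = y[ok], n_used = sum(ok))
}

pearson_with_p <- function(x, y) {
  r <- cor(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Per-subset associations between connectivity and an outcome
#'
#' For every subset: joint removal of participants at least `outlier_sd`
#' standard deviations from the mean on that subset's connectivity or on the
#' outcome (z-scores computed on that analysis's own sample), then the
#' Pearson correlation with a two-sided p-value from the t reference
#' distribution on `n_used - 2` degrees of freedom. No multiple-testing
#' correction, matching how distributions of subnetwork correlations are
#' summarized (median r, IQR, proportion of p < 0.05).
#'
#' @param result A [connectivity_matrix()] result.
#' @param outcome Named numeric vector aligned to participants.
#' @param outlier_sd Outlier threshold in SD units (default 3).
#' @return Object of class `subset_association`: `per_subset` data.frame
#'   (subset, n_negative, r, p, n_used, note) and `summary` list
#'   (median_r, iqr_r, prop_p_below_05, n_subsets_used).
#' @export
subset_outcome_associations <- function(result, outcome, outlier_sd = 3) {
  stopifnot(inherits(result, "connectivity_matrix"))
  ids <- rownames(result$values)
  if (!is.null(names(outcome))) outcome <- outcome[ids]
  if (sum(!is.na(outcome)) < 4) stop("need >= 4 participants with outcome",
                                     call. = FALSE)
  m <- ncol(result$values)
  r <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  note <- rep(NA_character_, m)
  for (s in seq_len(m)) {
    cl <- remove_joint_outliers(result$values[, s], outcome, outlier_sd)
    n_used[s] <- cl$n_used
    if (cl$n_used < 4) { note[s] <- "too few participants"; next }
    if (sd(cl$x) == 0 || sd(cl$y) == 0) { note[s] <- "zero variance"; next }
    pr <- pearson_with_p(cl$x, cl$y)
    r[s] <- pr$r; p[s] <- pr$p
  }
  used <- !is.na(r)
  per_subset <- data.frame(
    subset = colnames(result$values),
    n_negative = vapply(result$subsets, `[[`, integer(1), "n_negative"),
    r = r, p = p, n_used = n_used, note = note,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(per_subset = per_subset,
         summary = list(
           median_r = median(r[used]),
           iqr_r = unname(quantile(r[used], c(0.25, 0.75))),
           prop_p_below_05 = mean(p[used] < 0.05),
           n_subsets_used = sum(used))),
    class = "subset_association"
  )
}

#' @export
print.subset_association <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<subset_association> %d subsets: median r = %.3f (IQR %.3f, %.3f), %.2f%% of p < 0.05\n",
              s$n_subsets_used, s$median_r, s$iqr_r[1], s$iqr_r[2],
              100 * s$prop_p_below_05))
  invisible(x)
}
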