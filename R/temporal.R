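# Weekly contemporaneous connectivity and the lagged (before/after)
# connectivity-depression models.

panel_week_index <- function(panel) {
  per_day <- max(1L, round(24 / panel$hours_between))
  slot <- seq_len(nrow(panel$values)) - 1
  (slot %/% per_day) %/% 7 + 1
}

#' Weekly contemporaneous connectivity
#'
#' For every participant and subset, residuals from the full-series VAR fit
#' are partitioned by study week (week w = days 7(w-1)..7w-1 of the grid); a
#' contemporaneous network is computed from each week's residual rows
#' (weeks with fewer than k + 2 complete rows are missing for that subset),
#' and weekly connectivity is averaged across subsets with a value.
#' Re-using full-series residuals, rather than refitting a k-predictor VAR on
#' ~14 rows, is what keeps weekly estimates defined at all.
#'
#' @param cohort A prepared [ema_cohort].
#' @param subsets List of [node_subset].
#' @param mode Contemporaneous edge mode.
#' @return Object of class `weekly_connectivity`: `values` (participants x
#'   weeks matrix, `NA` where no subset produced a value) and `n_subsets`
#'   (same shape, contributing subset counts).
#' @export
weekly_connectivity <- function(cohort, subsets,
                                mode = c("partial", "zero_order")) {
  mode <- match.arg(mode)
  ids <- participant_ids(cohort)
  n_weeks <- max(vapply(cohort$panels, function(p)
    max(panel_week_index(p)), numeric(1)))
  values <- matrix(NA_real_, length(ids), n_weeks,
                   dimnames = list(ids, paste0("week", seq_len(n_weeks))))
  n_sub <- matrix(0L, length(ids), n_weeks, dimnames = dimnames(values))

  for (p in seq_along(ids)) {
    panel <- cohort$panels[[p]]
    # residual row r belongs to the week of its outcome slot r (0-based)
    week_of_row <- panel_week_index(panel)[-1]
    acc <- matrix(0, 1, n_weeks)
    cnt <- integer(n_weeks)
    for (s in subsets) {
      k <- length(s$items)
      resid <- tryCatch(fit_var(panel, s)$residuals, error = function(e) NULL)
      if (is.null(resid)) next
      for (w in seq_len(n_weeks)) {
        rows <- week_of_row == w & complete.cases(resid)
        if (sum(rows) < k + 2) next
        edges <- tryCatch(
          partial_cor_matrix(cov(resid[rows, , drop = FALSE]), mode = mode),
          error = function(e) NULL)
        if (is.null(edges)) next
        acc[w] <- acc[w] + sum(edges[upper.tri(edges)])
        cnt[w] <- cnt[w] + 1L
      }
    }
    has <- cnt > 0
    values[p, has] <- acc[has] / cnt[has]
    n_sub[p, ] <- cnt
  }
  structure(list(values = values, n_subsets = n_sub),
            class = "weekly_connectivity")
}

#' @export
print.weekly_connectivity <- function(x, ...) {
  cat(sprintf("<weekly_connectivity> %d participants x %d weeks (%.1f%% cells observed)\n",
              nrow(x$values), ncol(x$values), 100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Lagged weekly connectivity-depression model
#'
#' Tests whether weekly connectivity precedes (`direction = "before"`: pairs
#' connectivity in week w with depression in week w + 1) or follows
#' (`"after"`: depression in week w - 1, baseline counting as week 0) weekly
#' depression. Connectivity and depression are z-scored over the pooled
#' usable observations; the model is an OLS regression of depression on the
#' person-mean-centered connectivity with per-person intercepts (fixed
#' effects).
#'
#' @param weekly A [weekly_connectivity()] result.
#' @param depression Named list of [depression_series].
#' @param direction `"before"` or `"after"`.
#' @param min_pairs_per_participant Minimum usable week pairs to keep a
#'   participant (default 2).
#' @param min_participants Minimum participants after filtering (default 10).
#' @return Object of class `lagged_model`: `direction`, `beta`, `se`, `t`,
#'   `p`, `n_observations`, `n_participants`.
#' @export
lagged_model <- function(weekly, depression, direction = c("before", "after"),
                         min_pairs_per_participant = 2, min_participants = 10) {
  direction <- match.arg(direction)
  stopifnot(inherits(weekly, "weekly_connectivity"))
  ids <- rownames(weekly$values)
  W <- ncol(weekly$values)

  rows <- list()
  for (id in ids) {
    d <- depression[[id]]
    if (is.null(d)) next
    for (w in seq_len(W)) {
      conn <- weekly$values[id, w]
      target_week <- if (direction == "before") w + 1 else w - 1
      if (target_week < 0 || target_week > 8) next
      dep <- d$scores[target_week + 1]
      if (is.na(conn) || is.na(dep)) next
      rows[[length(rows) + 1]] <- data.frame(pid = id, conn = conn, dep = dep,
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no usable (participant, week) pairs", call. = FALSE)
  df <- do.call(rbind, rows)
  tab <- table(df$pid)
  keep <- names(tab)[tab >= min_pairs_per_participant]
  df <- df[df$pid %in% keep, , drop = FALSE]
  if (length(keep) < min_participants) {
    stop("fewer than ", min_participants, " participants with >= ",
         min_pairs_per_participant, " usable week pairs", call. = FALSE)
  }
  if (sd(df$conn) == 0 || sd(df$dep) == 0) {
    stop("degenerate predictor or outcome variance", call. = FALSE)
  }
  df$conn <- (df$conn - mean(df$conn)) / sd(df$conn)
  df$dep <- (df$dep - mean(df$dep)) / sd(df$dep)
  pm <- tapply(df$conn, df$pid, mean)
  df$conn_c <- df$conn - pm[df$pid]
  if (sd(df$conn_c) == 0) stop("degenerate predictor variance", call. = FALSE)

  fit <- lm(dep ~ conn_c + factor(pid), data = df)
  sm <- summary(fit)$coefficients["conn_c", ]
  structure(
    list(direction = direction, beta = unname(sm[1]), se = unname(sm[2]),
         t = unname(sm[3]), p = unname(sm[4]), n_observations = nrow(df),
         n_participants = length(keep)),
    class = "lagged_model"
  )
}

#' @export
print.lagged_model <- function(x, ...) {
  cat(sprintf("<lagged_model> connectivity (%s): beta = %.3f (SE %.3f), t = %.2f, p = %.3g (n = %d obs, %d participants)\n",
              x$direction, x$beta, x$se, x$t, x$p, x$n_observations,
              x$n_participants))
  invisible(x)
}
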