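# Inclusion rules and per-item series preparation.

#' Apply participant-inclusion rules
#'
#' A participant is included when (a) the fraction of scheduled assessments
#' with at least one answered item is at least `min_completion` and (b) at
#' least `min_weekly` of the up-to-9 depression administrations (baseline +
#' 8 weekly) are present. Filtering is idempotent.
#'
#' @param cohort An [ema_cohort].
#' @param min_completion Minimum completion fraction (default 0.75).
#' @param min_weekly Minimum number of depression scores (default 7). Ignored
#'   (treated as satisfied) when the cohort has no depression series.
#' @return List with `cohort` (filtered) and `report` (data.frame with one
#'   row per input participant: completion, n_weekly_scores, included,
#'   exclusion_reason).
#' @export
apply_inclusion <- function(cohort, min_completion = 0.75, min_weekly = 7) {
  stopifnot(inherits(cohort, "ema_cohort"), length(cohort$panels) >= 1)
  ids <- participant_ids(cohort)
  completion <- vapply(cohort$panels, function(p) {
    mean(rowSums(!is.na(p$values)) > 0)
  }, numeric(1))
  has_dep <- !is.null(cohort$depression)
  n_weekly <- vapply(ids, function(id) {
    if (!has_dep || is.null(cohort$depression[[id]])) return(NA_integer_)
    sum(!is.na(cohort$depression[[id]]$scores))
  }, integer(1))

  ok_completion <- completion >= min_completion
  ok_weekly <- if (has_dep) !is.na(n_weekly) & n_weekly >= min_weekly
               else rep(TRUE, length(ids))
  included <- ok_completion & ok_weekly
  reason <- rep(NA_character_, length(ids))
  reason[!ok_completion] <- "completion"
  reason[ok_completion & !ok_weekly] <- "weekly"

  report <- data.frame(
    participant = ids,
    completion = completion,
    n_weekly_scores = n_weekly,
    included = included,
    exclusion_reason = reason,
    stringsAsFactors = FALSE, row.names = NULL
  )
  keep <- ids[included]
  if (length(keep) == 0) {
    filtered <- structure(list(panels = list(), depression = if (has_dep)
      list() else NULL, design_label = cohort$design_label),
      class = "ema_cohort")
  } else {
    filtered <- ema_cohort(cohort$panels[keep],
                           depression = if (has_dep)
                             cohort$depression[keep] else NULL,
                           design_label = cohort$design_label)
  }
  list(cohort = filtered, report = report)
}

#' Prepare a panel's item series for network estimation
#'
#' Optionally removes a per-item ordinary linear time trend (fit on observed
#' points only) and/or z-scores each item within the participant. Missing
#' cells stay missing; the missingness pattern is never altered. Output of
#' either transform is marked `continuous` since values leave the original
#' response scale.
#'
#' @param panel An [ema_panel].
#' @param detrend Remove a linear trend per item? Default `FALSE`.
#' @param standardize Z-score each item (mean 0, SD 1 over observed points)?
#'   Default `TRUE`.
#' @return A transformed [ema_panel].
#' @export
prepare_series <- function(panel, detrend = FALSE, standardize = TRUE) {
  stopifnot(inherits(panel, "ema_panel"))
  v <- panel$values
  t_idx <- seq_len(nrow(v)) - 1
  for (j in seq_len(ncol(v))) {
    obs <- !is.na(v[, j])
    if (detrend) {
      if (sum(obs) < 3) {
        stop("item '", panel$item_names[j],
             "' has < 3 observed points; cannot detrend", call. = FALSE)
      }
      fit <- lm(v[obs, j] ~ t_idx[obs])
      v[obs, j] <- stats::residuals(fit) + mean(v[obs, j])
    }
    if (standardize) {
      s <- sd(v[obs, j])
      if (!is.finite(s) || s == 0) {
        stop("item '", panel$item_names[j],
             "' has zero variance; cannot standardize", call. = FALSE)
      }
      v[obs, j] <- (v[obs, j] - mean(v[obs, j])) / s
    }
  }
  scale <- if (detrend || standardize) "continuous" else panel$scale
  ema_panel(panel$participant_id, v, panel$item_valence, scale = scale,
            hours_between = panel$hours_between)
}

#' Prepare every panel in a cohort
#'
#' @param cohort An [ema_cohort].
#' @inheritParams prepare_series
#' @return The cohort with transformed panels.
#' @export
prepare_cohort <- function(cohort, detrend = FALSE, standardize = TRUE) {
  cohort$panels <- lapply(cohort$panels, prepare_series, detrend = detrend,
                          standardize = standardize)
  cohort
}
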