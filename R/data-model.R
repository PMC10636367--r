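#' @useDynLib emanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats .lm.fit coef complete.cases cor cor.test cov lm median pt
#'   quantile rnorm runif sd var setNames
#' @importFrom utils combn read.csv
NULL

SCALE_BOUNDS <- list(
  likert     = c(-3, 3),
  vas        = c(0, 100),
  continuous = c(-Inf, Inf)
)

#' EMA panel: one participant's item-by-assessment matrix
#'
#' An `ema_panel` holds one participant's ratings on an equidistant assessment
#' grid. Missed assessments are kept as rows of `NA`, never deleted, so that
#' slot `t - 1` is always the previous nominal assessment (e.g. 12 hours
#' earlier) and lag-1 regressions never silently degrade to longer lags.
#'
#' @param participant_id Participant identifier (coerced to character).
#' @param values Numeric matrix, assessments (rows, slot 0..T-1) by items
#'   (columns). Column names are the item labels. `NA` marks missing cells.
#' @param item_valence Named character vector mapping every item to
#'   `"negative"` or `"positive"`.
#' @param scale Response scale: `"likert"` (-3..+3), `"vas"` (0..100) or
#'   `"continuous"` (unbounded, e.g. after standardization).
#' @param hours_between Nominal spacing of the assessment grid in hours.
#'
#' @return An object of class `ema_panel`.
#' @export
ema_panel <- function(participant_id, values, item_valence,
                      scale = c("likert", "vas", "continuous"),
                      hours_between = 12) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  items <- colnames(values)
  if (is.null(items) || anyDuplicated(items) > 0) {
    stop("`values` must have unique column names (item labels)", call. = FALSE)
  }
  if (!all(items %in% names(item_valence))) {
    miss <- setdiff(items, names(item_valence))
    stop("valence undefined for item(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  item_valence <- item_valence[items]
  if (!all(item_valence %in% c("negative", "positive"))) {
    stop("item_valence entries must be 'negative' or 'positive'", call. = FALSE)
  }
  b <- SCALE_BOUNDS[[scale]]
  obs <- values[!is.na(values)]
  if (length(obs) && (min(obs) < b[1] || max(obs) > b[2])) {
    stop(sprintf("observed value outside %s bounds [%g, %g]", scale, b[1], b[2]),
         call. = FALSE)
  }
  stopifnot(is.numeric(hours_between), hours_between > 0)
  structure(
    list(
      participant_id = as.character(participant_id),
      item_names     = items,
      item_valence   = item_valence,
      values         = values,
      scale          = scale,
      hours_between  = hours_between
    ),
    class = "ema_panel"
  )
}

#' @export
print.ema_panel <- function(x, ...) {
  cat(sprintf(
    "<ema_panel> participant %s: %d assessments x %d items (%s, %g h grid), %.1f%% observed\n",
    x$participant_id, nrow(x$values), ncol(x$values), x$scale,
    x$hours_between, 100 * mean(!is.na(x$values))
  ))
  invisible(x)
}

n_assessments <- function(panel) nrow(panel$values)

#' Weekly depression sum-score series
#'
#' Up to nine administrations of a 0-60 depression sum score (CES-D style):
#' index 0 is the baseline (intake) score, indices 1..8 the weekly follow-ups.
#' Missing weeks are `NA`.
#'
#' @param participant_id Participant identifier.
#' @param scores Numeric vector of length <= 9; entry 1 is baseline (week 0).
#'   Padded with `NA` to length 9.
#' @return An object of class `depression_series`.
#' @export
depression_series <- function(participant_id, scores) {
  if (length(scores) > 9) {
    stop("at most 9 depression scores (baseline + 8 weeks)", call. = FALSE)
  }
  scores <- as.numeric(scores)
  ok <- scores[!is.na(scores)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 60)) {
    stop("depression scores must lie in [0, 60]", call. = FALSE)
  }
  scores <- c(scores, rep(NA_real_, 9 - length(scores)))
  structure(
    list(participant_id = as.character(participant_id), scores = scores),
    class = "depression_series"
  )
}

#' @export
print.depression_series <- function(x, ...) {
  cat(sprintf("<depression_series> participant %s: %d/9 scores\n",
              x$participant_id, sum(!is.na(x$scores))))
  invisible(x)
}

#' Cohort: panels plus depression series
#'
#' @param panels Named list of [ema_panel] objects (names = participant ids).
#' @param depression Named list of [depression_series], or `NULL` when weekly
#'   depression was not collected (e.g. proxy-outcome designs).
#' @param design_label Free-text tag describing the sampling design.
#' @return An object of class `ema_cohort`.
#' @export
ema_cohort <- function(panels, depression = NULL, design_label = "") {
  stopifnot(is.list(panels), length(panels) >= 1)
  ids <- vapply(panels, function(p) p$participant_id, character(1))
  names(panels) <- ids
  if (!is.null(depression)) {
    names(depression) <- vapply(depression, function(d) d$participant_id,
                                character(1))
  }
  structure(
    list(panels = panels, depression = depression,
         design_label = design_label),
    class = "ema_cohort"
  )
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat(sprintf("<ema_cohort> %d participants%s%s\n", length(x$panels),
              if (is.null(x$depression)) ", no depression series" else "",
              if (nzchar(x$design_label)) paste0(" [", x$design_label, "]") else ""))
  invisible(x)
}

participant_ids <- function(cohort) names(cohort$panels)

#' Read a long-format EMA table
#'
#' Reads a comma-separated table with columns `participant`,
#' `assessment_index`, `item`, `value` and assembles one [ema_panel] per
#' participant on a complete equidistant grid spanning that participant's
#' min..max assessment index. Cells absent from the file become `NA`.
#'
#' @param path Path to a CSV file (header row required).
#' @param scale Response scale the values must respect.
#' @param valence_map Named character vector item -> `"negative"`/`"positive"`.
#'   Rows with items not in the map are a hard error.
#' @param hours_between Nominal grid spacing in hours.
#' @return An [ema_cohort] with panels only (no depression series).
#' @export
read_ema_table <- function(path, scale = c("likert", "vas", "continuous"),
                           valence_map, hours_between = 12) {
  scale <- match.arg(scale)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "assessment_index", "item", "value")
  if (!all(need %in% names(df))) {
    stop("EMA table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$participant <- as.character(df$participant)
  df$item <- as.character(df$item)
  df <- df[!is.na(df$value), , drop = FALSE]

  unknown <- setdiff(unique(df$item), names(valence_map))
  if (length(unknown)) {
    stop("unknown item label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  b <- SCALE_BOUNDS[[scale]]
  bad <- which(df$value < b[1] | df$value > b[2])
  if (length(bad)) {
    stop(sprintf("value %g outside %s bounds at row %d", df$value[bad[1]],
                 scale, bad[1]), call. = FALSE)
  }
  key <- paste(df$participant, df$assessment_index, df$item, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop("duplicate (participant, assessment_index, item) at row ",
         which(duplicated(key))[1], call. = FALSE)
  }

  items <- names(valence_map)
  panels <- lapply(split(df, df$participant), function(d) {
    grid <- seq(min(d$assessment_index), max(d$assessment_index))
    m <- matrix(NA_real_, length(grid), length(items),
                dimnames = list(NULL, items))
    m[cbind(match(d$assessment_index, grid), match(d$item, items))] <- d$value
    ema_panel(d$participant[1], m, valence_map, scale = scale,
              hours_between = hours_between)
  })
  ema_cohort(panels, depression = NULL)
}

#' Read a weekly depression sum-score table
#'
#' Expects columns `participant`, `week` (0 = baseline, 1..8 = weekly) and
#' `score` (integer 0-60). Missing weeks stay `NA` in the assembled series.
#'
#' @param path Path to a CSV file.
#' @return Named list of [depression_series].
#' @export
read_depression_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "week", "score")
  if (!all(need %in% names(df))) {
    stop("depression table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$week < 0 | df$week > 8)) {
    stop("week outside 0..8", call. = FALSE)
  }
  if (any(!is.na(df$score) & (df$score < 0 | df$score > 60))) {
    stop("depression score outside [0, 60]", call. = FALSE)
  }
  out <- lapply(split(df, as.character(df$participant)), function(d) {
    s <- rep(NA_real_, 9)
    s[d$week + 1] <- d$score
    depression_series(d$participant[1], s)
  })
  out[order(names(out))]
}

#' Write a pipeline result as keyed structured text (JSON)
#'
#' Serializes any pipeline result losslessly (full double precision) so that
#' a read-back reproduces every numeric value to at least 12 significant
#' digits. Matrices are stored as nested arrays; S3 classes are recorded in a
#' `.class` field.
#'
#' @param path Output file path.
#' @param payload Any result object from this package (or a plain list).
#' @export
write_results <- function(path, payload) {
  enc <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) {
      out <- lapply(x, enc)
      cls <- setdiff(class(x), "list")
      if (length(cls)) out[[".class"]] <- cls[1]
      return(out)
    }
    x
  }
  body <- enc(payload)
  if (is.null(body) || (is.list(body) && length(body) == 0)) {
    body <- structure(list(), names = character(0))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                              na = "null", dataframe = "columns"), con)
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path File written by [write_results()].
#' @return Parsed list; matrices come back as numeric matrices.
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
}
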