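# Exemplar (cross-participant mean) networks, case-dropping bootstrap
# stability (CS coefficients) and cross-sample edge correlations.

type_code_of <- function(network_type, mode) {
  if (network_type == "directed") 0L else if (mode == "partial") 1L else 2L
}

# per-participant vectorized edges for one subset; NULL when the fit fails
panel_edge_vector <- function(panel, subset, network_type, mode = "partial") {
  lp <- lagged_pair(panel)
  idx <- matrix(match(subset$items, panel$item_names), ncol = 1)
  res <- batch_fit_cpp(lp$X, lp$Y, idx, type_code_of(network_type, mode), TRUE)
  if (res$fail[1] != 0) return(NULL)
  drop(res$edges)
}

edge_matrix_from_vector <- function(v, k, items, network_type) {
  if (network_type == "directed") {
    matrix(v, k, k, dimnames = list(items, items))
  } else {
    M <- matrix(0, k, k, dimnames = list(items, items))
    M[upper.tri(M)] <- v
    M + t(M)
  }
}

#' Exemplar network: entrywise mean edges across participants
#'
#' Averages each edge of the chosen subnetwork across all participants with a
#' successful fit, producing the cohort-level exemplar network used for
#' stability and cross-sample comparisons.
#'
#' @param cohort A prepared [ema_cohort].
#' @param subset A [node_subset].
#' @param network_type `"contemporaneous"` (default) or `"directed"`.
#' @param mode Contemporaneous edge mode.
#' @return k x k mean edge matrix with attributes `n_participants` (number of
#'   successful fits) and `network_type`.
#' @export
exemplar_network <- function(cohort, subset,
                             network_type = c("contemporaneous", "directed"),
                             mode = c("partial", "zero_order")) {
  network_type <- match.arg(network_type)
  mode <- match.arg(mode)
  vecs <- lapply(cohort$panels, panel_edge_vector, subset = subset,
                 network_type = network_type, mode = mode)
  vecs <- vecs[!vapply(vecs, is.null, logical(1))]
  if (length(vecs) == 0) stop("no successful fits for exemplar network",
                              call. = FALSE)
  mean_vec <- colMeans(do.call(rbind, vecs))
  k <- length(subset$items)
  M <- edge_matrix_from_vector(mean_vec, k, subset$items, network_type)
  attr(M, "n_participants") <- length(vecs)
  attr(M, "network_type") <- network_type
  M
}

#' Case-dropping bootstrap correlation stability
#'
#' For each drop fraction `f` in `drop_grid`, `B` bootstrap replicates each
#' remove a uniformly random fraction `f` of the chosen unit — whole
#' participants, or assessment slots within every participant — re-estimate
#' the exemplar network, and correlate its vectorized non-redundant edges
#' with the full-data exemplar. The CS coefficient is the largest fraction
#' whose 5th-percentile correlation is still at least `cs_threshold` (the
#' conventional "95% of replicates correlate >= 0.7" rule); 0 when none.
#' Replicates whose data cannot be fit are discarded and counted; a fraction
#' with more than 50% discarded replicates is flagged unreliable and cannot
#' carry the CS.
#'
#' @param cohort A prepared [ema_cohort].
#' @param subset A [node_subset].
#' @param network_type `"contemporaneous"` or `"directed"`.
#' @param drop_unit `"participants"` (default) or `"assessments"`.
#' @param drop_grid Ordered drop fractions (default 0.05..0.75 by 0.05; 0 is
#'   allowed for testing and yields correlation 1).
#' @param B Bootstrap replicates per fraction (default 500).
#' @param cs_threshold Correlation threshold (default 0.7).
#' @param seed Integer seed; results are bit-reproducible.
#' @param mode Contemporaneous edge mode.
#' @return Object of class `stability_result`: `table` data.frame
#'   (drop_fraction, q05, n_used, n_discarded, unreliable), `cs`,
#'   `cs_threshold`, `B`, `drop_unit`, `network_type`.
#' @export
correlation_stability <- function(cohort, subset,
                                  network_type = c("contemporaneous", "directed"),
                                  drop_unit = c("participants", "assessments"),
                                  drop_grid = seq(0.05, 0.75, by = 0.05),
                                  B = 500, cs_threshold = 0.7, seed = 1,
                                  mode = c("partial", "zero_order")) {
  network_type <- match.arg(network_type)
  drop_unit <- match.arg(drop_unit)
  mode <- match.arg(mode)
  panels <- cohort$panels
  n <- length(panels)

  # per-participant full-data edge vectors; participant dropping reuses them
  full_vecs <- lapply(panels, panel_edge_vector, subset = subset,
                      network_type = network_type, mode = mode)
  ok <- !vapply(full_vecs, is.null, logical(1))
  if (!any(ok)) stop("no successful full-data exemplar fit", call. = FALSE)
  vec_mat <- do.call(rbind, full_vecs[ok])
  full <- colMeans(vec_mat)
  if (sd(full) == 0) stop("full-data exemplar has zero edge variance",
                          call. = FALSE)

  q05 <- rep(NA_real_, length(drop_grid))
  n_disc <- integer(length(drop_grid))

  with_seed(seed, {
    for (g in seq_along(drop_grid)) {
      f <- drop_grid[g]
      cors <- rep(NA_real_, B)
      for (b in seq_len(B)) {
        if (drop_unit == "participants") {
          n_ok <- nrow(vec_mat)
          keep <- sample.int(n_ok, n_ok - round(f * n_ok))
          if (length(keep) < 1) next
          rep_vec <- colMeans(vec_mat[keep, , drop = FALSE])
        } else {
          vecs <- vector("list", n)
          for (p in seq_len(n)) {
            panel <- panels[[p]]
            T <- nrow(panel$values)
            drop_rows <- sample.int(T, round(f * T))
            if (length(drop_rows)) {
              panel$values[drop_rows, ] <- NA_real_
            }
            vecs[[p]] <- panel_edge_vector(panel, subset, network_type, mode)
          }
          vecs <- vecs[!vapply(vecs, is.null, logical(1))]
          if (length(vecs) == 0) next
          rep_vec <- colMeans(do.call(rbind, vecs))
        }
        if (sd(rep_vec) == 0) next
        cors[b] <- cor(rep_vec, full)
      }
      done <- !is.na(cors)
      n_disc[g] <- sum(!done)
      if (any(done)) q05[g] <- quantile(cors[done], 0.05, names = FALSE)
    }
  })

  unreliable <- n_disc > B / 2
  eligible <- !unreliable & !is.na(q05) & q05 >= cs_threshold
  cs <- if (any(eligible)) max(drop_grid[eligible]) else 0
  structure(
    list(table = data.frame(drop_fraction = drop_grid, q05 = q05,
                            n_used = B - n_disc, n_discarded = n_disc,
                            unreliable = unreliable, row.names = NULL),
         cs = cs, cs_threshold = cs_threshold, B = B, drop_unit = drop_unit,
         network_type = network_type),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %s network, dropping %s: CS(%.1f) = %.2f (B = %d)\n",
              x$network_type, x$drop_unit, x$cs_threshold, x$cs, x$B))
  invisible(x)
}

#' Correlation of edge strengths between two exemplar networks
#'
#' Pearson correlation of the vectorized edges of two networks estimated on
#' the same subset and of the same type: all k^2 entries for directed
#' networks, the unique off-diagonal entries for contemporaneous ones.
#'
#' @param netA,netB k x k edge matrices (e.g. from [exemplar_network()]).
#' @param network_type `"contemporaneous"` or `"directed"`.
#' @return Pearson r.
#' @export
cross_sample_edge_correlation <- function(netA, netB,
                                          network_type = c("contemporaneous",
                                                           "directed")) {
  network_type <- match.arg(network_type)
  a <- vectorize_edges(as.matrix(netA), network_type)
  b <- vectorize_edges(as.matrix(netB), network_type)
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) stop("zero edge variance", call. = FALSE)
  cor(a, b)
}
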