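# Per-participant lag-1 VAR estimation and the two derived networks.
#
# The directed network's k^2 edges are the unpenalized OLS lag-1 regression
# coefficients (diagonal = autoregression/inertia). The contemporaneous
# network is built from the residuals of those k regressions, by default as
# partial correlations (off-diagonal of the scaled negative inverse residual
# covariance), with a zero-order Pearson mode also exposed. Connectivity is
# the signed sum of edges: all k^2 entries for directed networks, the
# k(k-1)/2 unique off-diagonal entries for contemporaneous ones.

#' Define a node subset
#'
#' @param items Ordered unique item labels (2 <= k).
#' @param item_valence Optional named valence vector used to count negative
#'   items in the subset.
#' @return Object of class `node_subset` with fields `items`, `n_negative`.
#' @export
node_subset <- function(items, item_valence = NULL) {
  stopifnot(length(items) >= 2, anyDuplicated(items) == 0)
  n_neg <- if (is.null(item_valence)) NA_integer_ else
    sum(item_valence[items] == "negative")
  structure(list(items = as.character(items), n_negative = n_neg),
            class = "node_subset")
}

#' @export
print.node_subset <- function(x, ...) {
  cat("<node_subset> {", paste(x$items, collapse = ", "), "}\n")
  invisible(x)
}

# lagged design pieces for a panel: Y = values rows 2..T, X = rows 1..T-1
lagged_pair <- function(panel) {
  v <- panel$values
  T <- nrow(v)
  list(Y = v[2:T, , drop = FALSE], X = v[1:(T - 1), , drop = FALSE])
}

#' Fit the lag-1 VAR for a node subset
#'
#' One OLS regression per item in the subset: the item at slot `t` on all k
#' subset items at slot `t - 1` plus an intercept. Only consecutive grid
#' slots form a lag pair; if slot `t - 1` is missing the observation at `t`
#' contributes no row (12-h lags never degrade to 24-h lags). Rows are
#' dropped listwise per equation: a row is used when the outcome and all k
#' lagged predictors are observed. No penalization or thresholding.
#'
#' @param panel A prepared [ema_panel].
#' @param subset A [node_subset] whose items all appear in the panel.
#' @return List of class `var_fit` with `directed` (a `directed_network`:
#'   `edges` k x k matrix, row i = equation for item i, column j = lagged
#'   predictor j; `intercepts`; `n_lag_pairs_used`; `connectivity`) and
#'   `residuals` (a (T-1) x k matrix, `NA` on rows an equation did not use,
#'   used downstream for contemporaneous networks).
#' @export
fit_var <- function(panel, subset) {
  stopifnot(inherits(panel, "ema_panel"), inherits(subset, "node_subset"))
  missing_items <- setdiff(subset$items, panel$item_names)
  if (length(missing_items)) {
    stop("subset item(s) not in panel: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  k <- length(subset$items)
  lp <- lagged_pair(panel)
  X <- lp$X[, subset$items, drop = FALSE]
  Y <- lp$Y[, subset$items, drop = FALSE]
  pred_ok <- rowSums(is.na(X)) == 0

  edges <- matrix(NA_real_, k, k, dimnames = list(subset$items, subset$items))
  intercepts <- numeric(k)
  resid <- matrix(NA_real_, nrow(Y), k, dimnames = list(NULL, subset$items))
  n_used <- integer(k)

  for (i in seq_len(k)) {
    rows <- pred_ok & !is.na(Y[, i])
    n_used[i] <- sum(rows)
    if (n_used[i] < k + 2) {
      stop(sprintf("insufficient data: %d complete lagged pairs for item '%s' (need >= %d)",
                   n_used[i], subset$items[i], k + 2), call. = FALSE)
    }
    D <- cbind(1, X[rows, , drop = FALSE])
    fit <- .lm.fit(D, Y[rows, i])
    if (fit$rank < ncol(D)) {
      stop("perfectly collinear lagged predictors in subset {",
           paste(subset$items, collapse = ", "), "}", call. = FALSE)
    }
    cf <- fit$coefficients
    intercepts[i] <- cf[1]
    edges[i, ] <- cf[-1]
    resid[rows, i] <- fit$residuals
  }

  directed <- structure(
    list(edges = edges, intercepts = setNames(intercepts, subset$items),
         n_lag_pairs_used = n_used, connectivity = sum(edges)),
    class = "directed_network"
  )
  structure(list(directed = directed, residuals = resid, subset = subset),
            class = "var_fit")
}

#' Contemporaneous network from VAR residuals
#'
#' Aligns the k residual series on their common row set and computes either
#' partial correlations (default; `edges[i, j] = -P[i, j] /
#' sqrt(P[i, i] * P[j, j])` with `P` the inverse residual covariance) or
#' zero-order Pearson correlations. Diagonal forced to 0.
#'
#' @param fit A `var_fit` from [fit_var()], or a bare residual matrix.
#' @param mode `"partial"` (default) or `"zero_order"`.
#' @return A `contemporaneous_network`: symmetric `edges` matrix with zero
#'   diagonal, `n_rows_used`, `mode`, and `connectivity` (signed sum of the
#'   unique off-diagonal edges).
#' @export
contemporaneous_from_residuals <- function(fit, mode = c("partial", "zero_order")) {
  mode <- match.arg(mode)
  resid <- if (inherits(fit, "var_fit")) fit$residuals else as.matrix(fit)
  k <- ncol(resid)
  common <- complete.cases(resid)
  n <- sum(common)
  if (n < k + 2) {
    stop(sprintf("only %d common residual rows (need >= %d)", n, k + 2),
         call. = FALSE)
  }
  R <- resid[common, , drop = FALSE]
  edges <- partial_cor_matrix(cov(R), mode = mode)
  dimnames(edges) <- dimnames(resid)[c(2, 2)]
  structure(
    list(edges = edges, n_rows_used = n, mode = mode,
         connectivity = sum(edges[upper.tri(edges)])),
    class = "contemporaneous_network"
  )
}

# shared kernel: covariance -> partial (or zero-order) correlation matrix
partial_cor_matrix <- function(S, mode = "partial") {
  k <- ncol(S)
  if (mode == "zero_order") {
    d <- sqrt(diag(S))
    edges <- S / tcrossprod(d)
  } else {
    P <- tryCatch(solve(S), error = function(e)
      stop("singular residual covariance", call. = FALSE))
    d <- sqrt(diag(P))
    edges <- -P / tcrossprod(d)
  }
  diag(edges) <- 0
  (edges + t(edges)) / 2
}

#' Signed-sum connectivity of a network
#'
#' Directed networks: the sum of all k^2 signed edges, autoregressive
#' diagonal included. Contemporaneous networks: the sum of the k(k-1)/2
#' unique signed off-diagonal edges.
#'
#' @param network A `directed_network` or `contemporaneous_network`.
#' @return A single number.
#' @export
connectivity <- function(network) UseMethod("connectivity")

#' @export
connectivity.directed_network <- function(network) {
  if (any(!is.finite(network$edges))) stop("non-finite edge", call. = FALSE)
  sum(network$edges)
}

#' @export
connectivity.contemporaneous_network <- function(network) {
  if (any(!is.finite(network$edges))) stop("non-finite edge", call. = FALSE)
  sum(network$edges[upper.tri(network$edges)])
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, connectivity = %.4f\n",
              ncol(x$edges), x$connectivity))
  invisible(x)
}

#' @export
print.contemporaneous_network <- function(x, ...) {
  cat(sprintf("<contemporaneous_network> %d nodes (%s), connectivity = %.4f\n",
              ncol(x$edges), x$mode, x$connectivity))
  invisible(x)
}

# vectorize edges the way stability/cross-sample correlations need them:
# all k^2 entries (column-major) for directed, unique off-diagonal for
# contemporaneous
vectorize_edges <- function(edges, network_type) {
  if (network_type == "directed") as.vector(edges)
  else edges[upper.tri(edges)]
}
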