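# Synthetic cohorts with stationary per-person VAR(1) emotion dynamics, a
# between-person connectivity gradient, and weekly depression scores coupled
# to negative affect. All randomness is seeded and restores the caller's RNG.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

# lag matrix at gradient value gamma: diagonal kept, off-diagonal scaled
lag_matrix <- function(spec, gamma) {
  A <- spec$A0 * gamma
  diag(A) <- diag(spec$A0)
  A
}

# innovation covariance at gamma: precision K = I - gamma * W, so the
# innovation partial correlations are exactly gamma * W (off-diagonal)
innovation_cov <- function(spec, gamma) {
  K <- diag(spec$n_items) - gamma * spec$W
  S <- solve(K)
  d <- 1 / sqrt(diag(S))
  S <- S * tcrossprod(d)           # unit innovation variances
  (S + t(S)) / 2
}

#' Build a generative VAR(1) specification for synthetic EMA cohorts
#'
#' Constructs population parameters for a stationary lag-1 vector
#' autoregression over affect items: a template lag matrix `A0` with positive
#' autoregression on the diagonal, and an innovation partial-correlation
#' template `W`. Off-diagonal structure follows item valence: negative items
#' couple positively with each other and with depression-relevant dynamics,
#' positive items couple positively with each other, and cross-valence
#' couplings are negative and a quarter as strong. A connectivity multiplier
#' `gamma` in `[0, gamma_max]` scales both off-diagonal lag coefficients and
#' innovation partial correlations, so directed and contemporaneous
#' connectivity track the same between-person gradient. `gamma_max` is the
#' largest multiplier (capped at 2) for which the process stays comfortably
#' stationary (spectral radius of the lag matrix <= 0.95) and the innovation
#' precision stays positive definite (minimum eigenvalue >= 0.05).
#'
#' @param n_items Number of EMA items (>= 1).
#' @param base_coupling Magnitude scale of the off-diagonal lag couplings and
#'   of the innovation partial-correlation couplings. 0 gives a diagonal
#'   (decoupled) process. Only the product with `gamma` matters up to the
#'   stationarity cap, which is where `gamma_max` is placed.
#' @param seed Integer seed for the random template draw.
#' @param n_negative Number of negative-valence items (first `n_negative`
#'   items). Default mirrors a 9-negative / 7-positive pool scaled to
#'   `n_items`.
#' @param design List with `assessments_per_day`, `n_days`, `hours_between`.
#'   Default: 2/day for 56 days, 12 h apart (112 assessments).
#' @param scale Output scale: `"likert"` (round + clip to -3..3), `"vas"`
#'   (affine map of -3..3 onto 0..100, clipped) or `"continuous"` (raw).
#' @param missing_rate Probability that a whole assessment (row) is missing
#'   completely at random.
#' @param depression_link List with `a` (offset), `b` (slope on the weekly
#'   mean of negative items) and `noise_sd`; weekly score
#'   `D_w = round(clip(a + b * mean_neg_w + noise, 0, 60))`.
#' @return An object of class `generative_spec`.
#' @export
make_spec <- function(n_items = 16, base_coupling = 0.125, seed = 1,
                      n_negative = max(1L, round(n_items * 9 / 16)),
                      design = list(assessments_per_day = 2, n_days = 56,
                                    hours_between = 12),
                      scale = c("likert", "vas", "continuous"),
                      missing_rate = 0.1,
                      depression_link = list(a = 0, b = 25, noise_sd = 1)) {
  scale <- match.arg(scale)
  stopifnot(n_items >= 1, base_coupling >= 0,
            n_negative >= 0, n_negative <= n_items,
            missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    valence <- c(rep("negative", n_negative),
                 rep("positive", n_items - n_negative))
    item_names <- paste0(ifelse(valence == "negative", "neg", "pos"),
                         seq_len(n_items))
    # cross-valence couplings are negative and a quarter of the within-valence
    # strength: real exemplar networks show strong positive within-valence
    # partials and much weaker negative cross-valence ones, and heavy
    # cancellation would otherwise null the signed subset sums
    same <- outer(valence, valence, "==")
    sign_str <- ifelse(same, 1, -0.25)

    A0 <- matrix(0, n_items, n_items)
    if (n_items > 1) {
      mag <- matrix(runif(n_items^2, 0.5, 1), n_items)
      # lag couplings at 0.6x the innovation couplings: both channels then
      # reach their stationarity caps at a similar gamma
      A0 <- 0.6 * base_coupling * mag * sign_str
    }
    diag(A0) <- runif(n_items, 0.25, 0.35)

    W <- matrix(0, n_items, n_items)
    if (n_items > 1) {
      magw <- matrix(runif(n_items^2, 0.5, 1), n_items)
      W <- base_coupling * magw * sign_str
      W <- (W + t(W)) / 2
    }
    diag(W) <- 0
  })

  spec <- structure(
    list(n_items = n_items, item_names = item_names, item_valence =
           setNames(valence, item_names), A0 = A0, W = W,
         intercepts = rep(0, n_items), gamma_range = c(0, NA_real_),
         depression_link = depression_link, missing_rate = missing_rate,
         scale = scale, design = design, base_coupling = base_coupling,
         seed = seed),
    class = "generative_spec"
  )

  ok <- function(g) {
    spectral_radius(lag_matrix(spec, g)) <= 0.95 &&
      min(eigen(diag(n_items) - g * W, only.values = TRUE,
                symmetric = TRUE)$values) >= 0.05
  }
  if (!ok(0)) stop("no gamma > 0 satisfies stationarity", call. = FALSE)
  lo <- 0; hi <- 2
  if (ok(hi)) {
    gmax <- hi
  } else {
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (ok(mid)) lo <- mid else hi <- mid
    }
    gmax <- lo
  }
  if (gmax <= 0) stop("no gamma > 0 satisfies stationarity", call. = FALSE)
  spec$gamma_range <- c(0, gmax)
  spec
}

#' @export
print.generative_spec <- function(x, ...) {
  cat(sprintf(
    "<generative_spec> %d items (%d negative), gamma in [0, %.3f], %s scale, %d x %d/day design\n",
    x$n_items, sum(x$item_valence == "negative"), x$gamma_range[2], x$scale,
    x$design$n_days, x$design$assessments_per_day))
  invisible(x)
}

# simulate the latent continuous trajectory (post burn-in), T x n_items
simulate_latent <- function(spec, gamma, T, burn_in = 200) {
  A <- lag_matrix(spec, gamma)
  S <- innovation_cov(spec, gamma)
  L <- t(chol(S))
  n <- spec$n_items
  total <- burn_in + T
  eps <- L %*% matrix(rnorm(n * total), n, total)
  x <- matrix(0, total, n)
  prev <- rep(0, n)
  cvec <- spec$intercepts
  for (t in seq_len(total)) {
    prev <- cvec + drop(A %*% prev) + eps[, t]
    x[t, ] <- prev
  }
  if (any(!is.finite(x))) stop("non-finite draw in simulation", call. = FALSE)
  x[(burn_in + 1):total, , drop = FALSE]
}

discretize <- function(x, scale) {
  if (scale == "continuous") return(x)
  if (scale == "likert") {
    x <- sign(x) * floor(abs(x) + 0.5)  # round half away from zero
    x[x > 3] <- 3; x[x < -3] <- -3
  } else {
    x <- (x + 3) / 6 * 100
    x[x > 100] <- 100; x[x < 0] <- 0
  }
  x
}

#' Simulate one participant's EMA panel
#'
#' Draws `x_t = c + A(gamma) x_{t-1} + eps_t`, `eps_t ~ N(0, S(gamma))`,
#' discards a burn-in of 200 steps, maps values onto the declared scale, and
#' deletes whole assessments completely at random at the spec's missing rate.
#'
#' @param spec A [make_spec()] object.
#' @param gamma Connectivity multiplier within `spec$gamma_range`.
#' @param T Number of assessments to keep (>= 2).
#' @param seed Integer seed.
#' @return An [ema_panel].
#' @export
simulate_participant <- function(spec, gamma, T = NULL, seed = 1) {
  if (is.null(T)) T <- spec$design$assessments_per_day * spec$design$n_days
  stopifnot(T >= 2)
  if (gamma < spec$gamma_range[1] || gamma > spec$gamma_range[2]) {
    stop(sprintf("gamma = %g outside gamma_range [%g, %g]", gamma,
                 spec$gamma_range[1], spec$gamma_range[2]), call. = FALSE)
  }
  with_seed(seed, {
    x <- discretize(simulate_latent(spec, gamma, T), spec$scale)
    if (spec$missing_rate > 0) {
      drop_row <- runif(T) < spec$missing_rate
      x[drop_row, ] <- NA_real_
    }
  })
  colnames(x) <- spec$item_names
  ema_panel(paste0("sim", seed), x, spec$item_valence, scale = spec$scale,
            hours_between = spec$design$hours_between)
}

#' Simulate a full cohort with ground truth
#'
#' Draws one connectivity multiplier `gamma_i ~ Uniform(gamma_range)` per
#' participant, simulates each EMA panel under the spec's design, and
#' generates depression sum scores: the baseline from the mean negative
#' affect of one extra pre-study week, weekly scores from the mean negative
#' affect of each study week. Depression uses the complete (pre-missingness)
#' trajectories: missing a prompt does not change how a week felt.
#'
#' @param spec A [make_spec()] object.
#' @param n_participants Cohort size (>= 1).
#' @param seed Integer seed; per-participant streams are derived from it.
#' @return A list of class `simulated_cohort` with elements `cohort`
#'   ([ema_cohort]), `true_gamma` (named numeric) and `true_networks` (per
#'   participant: lag matrix `A` and innovation partial-correlation matrix).
#' @export
simulate_cohort <- function(spec, n_participants, seed = 1) {
  stopifnot(n_participants >= 1)
  d <- spec$design
  per_week <- d$assessments_per_day * 7
  T <- d$assessments_per_day * d$n_days
  n_weeks <- d$n_days %/% 7
  if (per_week < 2) stop("design implies < 2 assessments per week", call. = FALSE)

  link <- spec$depression_link
  neg <- which(spec$item_valence == "negative")
  panels <- vector("list", n_participants)
  depression <- vector("list", n_participants)
  true_networks <- vector("list", n_participants)

  gamma <- with_seed(seed, runif(n_participants, spec$gamma_range[1],
                                 spec$gamma_range[2]))
  for (i in seq_len(n_participants)) {
    id <- sprintf("p%03d", i)
    sub_seed <- (seed * 1009L + i) %% 2147483647L
    with_seed(sub_seed, {
      lat <- simulate_latent(spec, gamma[i], T + per_week)
      x <- discretize(lat, spec$scale)
      base_week <- x[seq_len(per_week), , drop = FALSE]
      study <- x[(per_week + 1):(per_week + T), , drop = FALSE]
      weekly_neg <- vapply(seq_len(n_weeks), function(w) {
        rows <- ((w - 1) * per_week + 1):(w * per_week)
        mean(study[rows, neg, drop = FALSE])
      }, numeric(1))
      raw <- link$a + link$b * c(mean(base_week[, neg, drop = FALSE]),
                                 weekly_neg) +
        link$noise_sd * rnorm(n_weeks + 1)
      scores <- round(pmin(60, pmax(0, raw)))
      obs <- study
      if (spec$missing_rate > 0) {
        obs[runif(T) < spec$missing_rate, ] <- NA_real_
      }
    })
    colnames(obs) <- spec$item_names
    panels[[i]] <- ema_panel(id, obs, spec$item_valence, scale = spec$scale,
                             hours_between = d$hours_between)
    depression[[i]] <- depression_series(id, c(scores,
                                               rep(NA_real_, 8 - n_weeks)))
    pc <- gamma[i] * spec$W
    diag(pc) <- 0
    true_networks[[i]] <- list(A = lag_matrix(spec, gamma[i]),
                               partial_cor = pc)
  }
  ids <- vapply(panels, function(p) p$participant_id, character(1))
  names(true_networks) <- ids
  structure(
    list(cohort = ema_cohort(panels, depression,
                             design_label = sprintf("synthetic %d/day x %d d",
                                                    d$assessments_per_day,
                                                    d$n_days)),
         true_gamma = setNames(gamma, ids),
         true_networks = true_networks,
         spec = spec),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d participants, gamma in [%.3f, %.3f]\n",
              length(x$true_gamma), min(x$true_gamma), max(x$true_gamma)))
  invisible(x)
}
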