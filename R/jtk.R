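#' Exact null distribution of the Jonckheere-Terpstra statistic
#'
#' Under exchangeability the JT statistic for ordered groups of sizes
#' n_1, ..., n_k decomposes into a sum of independent Mann-Whitney counts
#' U(N_{i-1}, n_i) (merging group i into the pooled preceding groups), so its
#' exact null probability mass is the convolution of the corresponding
#' Mann-Whitney count distributions. The statistic is reported on the
#' concordant-minus-discordant scale S = 2T - M where T is the concordance
#' count and M = sum_{i<j} n_i n_j the number of between-group pairs, so S
#' ranges over -M, -M+2, ..., M and S/M is Kendall's tau-a restricted to
#' between-group pairs.
#'
#' For total n above `exact_limit` a normal approximation with continuity
#' correction is used (classical JT moments).
#'
#' @param group_sizes integer vector of group sizes in reference order.
#' @param exact_limit largest total n for which the exact convolution is
#'   computed, default 50.
#' @return An object of class `jtk_null`: for the exact case, `t_support`
#'   (0..M), `prob`, `stat` (S = 2T - M) and `M`; for the approximate case,
#'   `M`, `mean_t`, `sd_t` and `method = "normal"`.
#' @export
jtk_null <- function(group_sizes, exact_limit = 50) {
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) < 2) abort_located("need >= 2 groups")
  if (any(group_sizes < 1)) abort_located("empty group in group_sizes")
  n_tot <- sum(group_sizes)
  M <- sum(utils::combn(length(group_sizes), 2, function(ix)
    group_sizes[ix[1]] * group_sizes[ix[2]]))
  if (n_tot > exact_limit) {
    var_t <- (n_tot^2 * (2 * n_tot + 3) -
                sum(group_sizes^2 * (2 * group_sizes + 3))) / 72
    return(structure(list(group_sizes = group_sizes, M = M, method = "normal",
                          mean_t = M / 2, sd_t = sqrt(var_t)),
                     class = "jtk_null"))
  }
  # convolution of Mann-Whitney count pmfs via base R's exact dwilcox
  prob <- 1
  n_prev <- group_sizes[1]
  for (k in seq_along(group_sizes)[-1]) {
    nk <- group_sizes[k]
    comp <- stats::dwilcox(0:(n_prev * nk), m = n_prev, n = nk)
    prob <- if (identical(prob, 1)) comp else
      as.vector(stats::convolve(prob, rev(comp), type = "open"))
    n_prev <- n_prev + nk
  }
  prob <- pmax(prob, 0)
  prob <- prob / sum(prob)
  structure(list(group_sizes = group_sizes, M = M, method = "exact",
                 t_support = 0:M, stat = 2 * (0:M) - M, prob = prob),
            class = "jtk_null")
}

#' @export
print.jtk_null <- function(x, ...) {
  cat("JT null, groups (", paste(x$group_sizes, collapse = ", "), "), M =",
      x$M, ", method:", x$method, "\n")
  invisible(x)
}

# Two-sided p-value for an observed S (= concordant - discordant) under a null
jtk_null_p <- function(null, s_obs) {
  if (null$method == "exact")
    return(min(1, sum(null$prob[abs(null$stat) >= abs(s_obs) - 1e-9])))
  t_obs <- (s_obs + null$M) / 2
  z <- (abs(t_obs - null$mean_t) - 0.5) / null$sd_t
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

# Precompute reference-ordering structures shared by all features measured on
# the same time grid: one entry per distinct two-sided alternative (lags whose
# reference orderings are identical or exact reversals are one alternative).
jtk_prepare <- function(time_h, period_h = 24, lag_step_h = NULL,
                        exact_limit = 50) {
  t_fold <- time_h %% period_h
  ut <- sort(unique(round(t_fold, 9)))
  if (length(ut) < 2) abort_located("JTK needs >= 2 distinct time points")
  if (is.null(lag_step_h)) {
    lags <- ut
  } else {
    lags <- seq(0, period_h - 1e-9, by = lag_step_h)
  }
  w <- 2 * pi / period_h
  alts <- list()
  keys <- character()
  lag_of_key <- list()
  for (lag in lags) {
    ref <- round(cos(w * (t_fold - lag)), 9)
    lev <- sort(unique(ref))
    if (length(lev) < 2) next        # reference constant at this lag
    grp <- match(ref, lev)            # 1 = lowest reference value
    key_f <- paste(grp, collapse = ",")
    key_r <- paste(length(lev) + 1 - grp, collapse = ",")
    key <- min(key_f, key_r)
    pos <- match(key, keys)
    if (is.na(pos)) {
      keys <- c(keys, key)
      groups <- split(seq_along(ref), grp)
      alts[[length(alts) + 1]] <- list(
        groups = groups,
        sizes = lengths(groups),
        lag = lag, reversed_lag = (lag + period_h / 2) %% period_h)
      lag_of_key[[length(lag_of_key) + 1]] <- lag
    }
  }
  if (length(alts) == 0)
    abort_located("no usable lag: reference waveform constant on this time grid")
  # null depends only on the multiset of group sizes; cache by signature
  null_cache <- new.env(parent = emptyenv())
  for (i in seq_along(alts)) {
    sig <- paste(alts[[i]]$sizes, collapse = "_")
    if (is.null(null_cache[[sig]]))
      null_cache[[sig]] <- jtk_null(alts[[i]]$sizes, exact_limit = exact_limit)
    alts[[i]]$null <- null_cache[[sig]]
  }
  list(time_h = t_fold, period_h = period_h, alternatives = alts,
       n_alternatives = length(alts), w = w)
}

# Concordant-minus-discordant count of y against one ordered grouping
jtk_score_alt <- function(groups, y) {
  k <- length(groups)
  s <- 0
  for (g in 1:(k - 1)) {
    yg <- y[groups[[g]]]
    for (h in (g + 1):k) {
      s <- s + sum(sign(rep(y[groups[[h]]], each = length(yg)) - yg))
    }
  }
  s
}

jtk_score <- function(prep, y) {
  n_alt <- prep$n_alternatives
  p_each <- numeric(n_alt)
  s_each <- numeric(n_alt)
  for (i in seq_len(n_alt)) {
    alt <- prep$alternatives[[i]]
    s <- jtk_score_alt(alt$groups, y)
    s_each[i] <- s
    p_each[i] <- jtk_null_p(alt$null, s)
  }
  best <- which.min(p_each)
  alt <- prep$alternatives[[best]]
  s <- s_each[best]
  # concordance with the reference peaks at the lag; anti-concordance means
  # the half-period shifted lag of the same two-sided alternative
  best_lag <- if (s >= 0) alt$lag else alt$reversed_lag
  p <- min(1, p_each[best] * n_alt)
  ref <- cos(prep$w * (prep$time_h - best_lag))
  a <- tryCatch(unname(stats::coef(stats::lm(y ~ ref))[2]), error = function(e) 0)
  if (!is.finite(a)) a <- 0
  list(p_value = p, p_min_raw = p_each[best], best_lag_h = best_lag,
       kendall_tau = s / alt$null$M, amplitude_estimate = max(a, 0),
       n_alternatives = n_alt)
}

#' JTK_CYCLE rank-based rhythmicity test
#'
#' Scores the concordance of a series against phase-shifted cosine reference
#' waveforms of fixed period via the Jonckheere-Terpstra statistic. For each
#' lag on the grid (one lag per sampling interval by default), observations
#' are grouped by the distinct values of the reference cosine and ordered by
#' increasing reference value; ties in `y` contribute zero concordance
#' (tau-a convention, conservative under the tie-free exact null). The
#' reported p-value is the minimum exact two-sided tail over lags, Bonferroni
#' multiplied by the number of distinct two-sided alternatives (lags whose
#' orderings are reversals of each other count once), capped at 1.
#'
#' @param time_h sampling times (hours).
#' @param y response values.
#' @param period_h fixed test period, default 24.
#' @param lag_step_h lag-grid step; default uses the distinct sampling times.
#' @param exact_limit largest n for the exact null (see [jtk_null()]).
#' @return list with `p_value` (Bonferroni over alternatives), `p_min_raw`,
#'   `best_lag_h` (phase of the best reference), `kendall_tau`,
#'   `amplitude_estimate` (least-squares cosine amplitude at the best lag,
#'   clamped at 0) and `n_alternatives`.
#' @export
jtk_test <- function(time_h, y, period_h = 24, lag_step_h = NULL,
                     exact_limit = 50) {
  ok <- is.finite(time_h) & is.finite(y)
  prep <- jtk_prepare(time_h[ok], period_h = period_h,
                      lag_step_h = lag_step_h, exact_limit = exact_limit)
  jtk_score(prep, y[ok])
}
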