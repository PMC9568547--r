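# Shared fixtures and independent oracles, built in code at test time.

# small synthetic study used by most module tests (fast but realistic)
small_config <- function(seed = 42, ...) {
  synth_config(n_taxa = 40, seed = seed, ...)
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(small_config())
    cache
  }
})

toy_count_table <- function() {
  m <- matrix(c(10L, 30L, 5L,
                20L, 20L, 10L,
                100L, 0L, 50L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("taxA", "taxB", "SPIKE_1")))
  count_table(m, spike_ids = "SPIKE_1")
}

# all permutations of a vector (for brute-force nulls, n <= 7)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# brute-force JT statistic distribution by enumerating all orderings
jt_enum_stats <- function(group_sizes) {
  n <- sum(group_sizes)
  groups <- split(seq_len(n), rep(seq_along(group_sizes), group_sizes))
  vapply(all_perms(seq_len(n)), function(y)
    rhythmbiome:::jtk_score_alt(groups, y), numeric(1))
}

# independent cosinor oracle: profile the phase on a fine grid with
# golden-section refinement; amplitude/mesor from the normal equations at
# each candidate phase, written out long-hand (no lm)
cosinor_grid_oracle <- function(time_h, y, period_h = 24) {
  rss_at <- function(phi) {
    x <- cos(2 * pi * (time_h - phi) / period_h)
    n <- length(y)
    sxx <- sum(x^2) - sum(x)^2 / n
    sxy <- sum(x * y) - sum(x) * sum(y) / n
    A <- sxy / sxx
    m <- mean(y) - A * mean(x)
    sum((y - m - A * x)^2)
  }
  grid <- seq(0, period_h, length.out = 4801)
  r <- vapply(grid, rss_at, numeric(1))
  phi0 <- grid[which.min(r)]
  opt <- stats::optimize(rss_at, c(phi0 - 0.01, phi0 + 0.01), tol = 1e-12)
  phi <- opt$minimum %% period_h
  x <- cos(2 * pi * (time_h - phi) / period_h)
  A <- (sum(x * y) - sum(x) * sum(y) / length(y)) /
    (sum(x^2) - sum(x)^2 / length(y))
  if (A < 0) { A <- -A; phi <- (phi + period_h / 2) %% period_h }
  list(mesor = mean(y) - A * mean(cos(2 * pi * (time_h - phi) / period_h)),
       amplitude = A, phase_h = phi)
}

# classical rank-difference Spearman formula (tie-free vectors only)
spearman_formula_oracle <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  rho <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
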