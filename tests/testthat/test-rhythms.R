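test_that("cosinor recovers a noise-free wave to machine precision", {
  t <- seq(0, 21, by = 3)
  y <- 5 + 2 * cos(2 * pi * (t - 6) / 24)
  f <- fit_cosinor(t, y)
  expect_equal(f$mesor, 5, tolerance = 1e-10)
  expect_equal(f$amplitude, 2, tolerance = 1e-10)
  expect_equal(f$phase_h, 6, tolerance = 1e-10)
  expect_lt(f$p_value, 1e-10)
  expect_equal(predict(f, 6), 7, tolerance = 1e-9)
})

test_that("cosinor handles degenerate inputs by convention", {
  t <- seq(0, 21, by = 3)
  f <- fit_cosinor(t, rep(3, 8))
  expect_equal(f$amplitude, 0)
  expect_equal(f$p_value, 1)
  expect_error(fit_cosinor(c(1, 2, 3), c(1, 2, 3)), ">= 4 observations")
  expect_error(fit_cosinor(c(1, 1, 2, 2), 1:4), "distinct time")
})

test_that("cosinor equals an independent grid-search oracle on noisy data", {
  set.seed(81)
  for (i in 1:5) {
    t <- rep(seq(1, 22, by = 3), each = 3)
    y <- 2 + 1.5 * cos(2 * pi * (t - runif(1, 0, 24)) / 24) + rnorm(length(t), sd = 0.4)
    f <- fit_cosinor(t, y)
    o <- cosinor_grid_oracle(t, y)
    expect_equal(f$mesor, o$mesor, tolerance = 1e-6)
    expect_equal(f$amplitude, o$amplitude, tolerance = 1e-6)
    expect_equal(f$phase_h, o$phase_h, tolerance = 1e-5)
  }
})

test_that("harmonic regression nests the cosinor and captures 12-h waves", {
  t <- rep(seq(1, 22, by = 3), each = 2)
  # pure 12-h wave: no 24-h component
  y12 <- 1 + 0.8 * cos(4 * pi * (t - 3) / 24)
  h <- fit_harmonic(t, y12)
  expect_lt(h$amplitude_a, 1e-8)
  expect_equal(h$amplitude_b, 0.8, tolerance = 1e-8)
  expect_equal(h$phase_b_h, 3, tolerance = 1e-8)
  # pure 24-h wave: reduces to the cosinor parameters
  y24 <- 1 + 0.8 * cos(2 * pi * (t - 9) / 24)
  h2 <- fit_harmonic(t, y24)
  c2 <- fit_cosinor(t, y24)
  expect_equal(h2$amplitude_a, c2$amplitude, tolerance = 1e-8)
  expect_equal(h2$phase_a_h, c2$phase_h, tolerance = 1e-8)
  expect_lt(h2$amplitude_b, 1e-8)
  # noisy mixture still matches the 24-h oracle closely on the 24-h term
  set.seed(4)
  ym <- 1 + 1.2 * cos(2 * pi * (t - 5) / 24) + 0.5 * cos(4 * pi * (t - 2) / 24) +
    rnorm(length(t), sd = 0.1)
  hm <- fit_harmonic(t, ym)
  expect_equal(hm$amplitude_a, 1.2, tolerance = 0.1)
  expect_equal(hm$phase_a_h, 5, tolerance = 0.5)
})

test_that("JT exact null matches brute-force enumeration (n <= 7)", {
  designs <- list(c(1, 1), c(2, 2), c(2, 3), c(1, 2, 3), c(2, 2, 3),
                  c(3, 4), c(1, 1, 1, 2, 2))
  for (gs in designs) {
    null <- jtk_null(gs)
    expect_equal(sum(null$prob), 1, tolerance = 1e-12)
    s <- jt_enum_stats(gs)
    emp <- vapply(null$stat, function(v) mean(s == v), numeric(1))
    expect_lt(max(abs(cumsum(emp) - cumsum(null$prob))), 1e-12)
  }
  # two singleton groups: statistic is +-1 with probability 1/2
  n11 <- jtk_null(c(1, 1))
  expect_equal(n11$stat[n11$prob > 0], c(-1, 1))
  expect_equal(n11$prob[n11$prob > 0], c(0.5, 0.5))
  expect_error(jtk_null(c(0, 2)), "empty group")
})

test_that("jtk_test finds the phase of a clean cosine and caps p at ties", {
  t <- rep(seq(1, 22, by = 3), each = 3)
  y <- 3 + cos(2 * pi * (t - 7) / 24)
  j <- jtk_test(t, y)
  expect_equal(j$best_lag_h, 7)
  expect_equal(j$kendall_tau, 1)
  expect_equal(j$amplitude_estimate, 1, tolerance = 1e-8)
  # reported p = minimal attainable exact tail x alternative count
  expect_equal(j$p_value, j$p_min_raw * j$n_alternatives)
  # all-tied series
  j0 <- jtk_test(t, rep(1, length(t)))
  expect_equal(j0$p_value, 1)
  expect_equal(j0$kendall_tau, 0)
})

test_that("jtk_test p matches permutation enumeration at n = 6", {
  t6 <- c(0, 4, 8, 12, 16, 20)
  set.seed(12)
  y <- rnorm(6)
  prep <- rhythmbiome:::jtk_prepare(t6)
  perms <- all_perms(y)
  p_enum <- vapply(prep$alternatives, function(alt) {
    s_obs <- rhythmbiome:::jtk_score_alt(alt$groups, y)
    s_all <- vapply(perms, function(yy)
      rhythmbiome:::jtk_score_alt(alt$groups, yy), numeric(1))
    mean(abs(s_all) >= abs(s_obs))
  }, numeric(1))
  expected <- min(1, min(p_enum) * prep$n_alternatives)
  j <- jtk_test(t6, y)
  expect_equal(j$p_value, expected, tolerance = 1e-12)
})

test_that("jtk_test is invariant under strictly monotone transforms", {
  set.seed(3)
  t <- rep(seq(1, 22, by = 3), each = 3)
  y <- 2 + cos(2 * pi * (t - 10) / 24) + rnorm(length(t), sd = 0.5)
  j1 <- jtk_test(t, y)
  j2 <- jtk_test(t, exp(2 * y))
  expect_equal(j1$p_value, j2$p_value)
  expect_equal(j1$kendall_tau, j2$kendall_tau)
  expect_equal(j1$best_lag_h, j2$best_lag_h)
})

test_that("normal-approximation tail is close to the exact tail", {
  gs <- rep(6, 8)  # 48 observations, 8 groups
  ex <- jtk_null(gs, exact_limit = 50)
  ap <- jtk_null(gs, exact_limit = 10)
  expect_equal(ap$method, "normal")
  for (s in c(200, 300, 400)) {
    expect_equal(rhythmbiome:::jtk_null_p(ap, s),
                 rhythmbiome:::jtk_null_p(ex, s), tolerance = 0.01)
  }
})

test_that("rhythm_calls recovers the generator truth and labels correctly", {
  d <- small_dataset()
  rel <- relative_abundance(d$counts)
  calls <- rhythm_calls(rel, d$meta, "control")
  truth <- d$truth$taxa
  # every truly rhythmic taxon is detected at this amplitude/noise ratio
  sens <- mean(calls$is_rhythmic[match(
    truth$taxon[truth$rhythmic_control], calls$taxon)])
  expect_gte(sens, 0.9)
  # boundary: alpha = 1 flags everything
  calls_all <- rhythm_calls(rel, d$meta, "control", alpha = 1)
  expect_true(all(calls_all$is_rhythmic))
  # single-taxon table: Bonferroni with m = 1 leaves p unchanged
  one <- rhythm_calls(rel[, 1, drop = FALSE], d$meta, "control")
  expect_equal(one$jtk_adj_p, one$jtk_p)
  expect_error(rhythm_calls(rel, d$meta, "no_such_group"), "not present")
})

test_that("peak-phase matrix is peak-normalized and phase-ordered", {
  d <- small_dataset()
  rel <- relative_abundance(d$counts)
  calls <- rhythm_calls(rel, d$meta, "control")
  ppm <- peak_phase_matrix(rel, d$meta, calls)
  expect_equal(unname(apply(ppm$matrix, 1, max)), rep(1, nrow(ppm$matrix)))
  phases <- calls$phase_h[match(rownames(ppm$matrix), calls$taxon)]
  expect_true(!is.unsorted(phases))
  # the ridge of per-row peaks moves monotonically for rhythmic taxa
  rhythmic <- rownames(ppm$matrix) %in% calls$taxon[calls$is_rhythmic]
  tp <- as.numeric(sub("^t", "", colnames(ppm$matrix)))
  peak_t <- tp[apply(ppm$matrix[rhythmic, ], 1, which.max)]
  ph <- phases[rhythmic]
  circ_err <- pmin(abs(peak_t - ph), 24 - abs(peak_t - ph))
  expect_lt(mean(circ_err), 3)  # within one sampling interval on average
})
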