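#' Fixed-period cosinor regression
#'
#' Fits y = mesor + amplitude * cos(2*pi*(t - phase)/period) by least squares
#' through the linearization y = m + a*cos(wt) + b*sin(wt), w = 2*pi/period.
#' The amplitude is sqrt(a^2 + b^2) >= 0 and the peak phase is
#' (period/2*pi) * atan2(b, a) folded into [0, period). The p-value is the
#' F-test of the two rhythm coefficients against the intercept-only model.
#' Repeated measures are pooled: subjects at the same time point are treated
#' as independent replicates.
#'
#' @param time_h sampling times in hours.
#' @param y response values (same length).
#' @param period_h fixed period, default 24.
#' @return An object of class `cosinor_fit`: list with `mesor`, `amplitude`,
#'   `phase_h` (peak time in \[0, period)), `period_h`, `p_value`,
#'   `r_squared`, `n_obs`, and the linear coefficients `a`, `b`.
#' @export
fit_cosinor <- function(time_h, y, period_h = 24) {
  ok <- is.finite(time_h) & is.finite(y)
  time_h <- time_h[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4) abort_located("cosinor needs >= 4 observations")
  if (length(unique(round(time_h, 9))) < 3)
    abort_located("cosinor needs >= 3 distinct time points")
  w <- 2 * pi / period_h
  cw <- cos(w * time_h); sw <- sin(w * time_h)
  if (stats::sd(y) == 0) {
    return(structure(list(mesor = y[1], amplitude = 0, phase_h = 0,
                          period_h = period_h, p_value = 1, r_squared = 0,
                          n_obs = n, a = 0, b = 0), class = "cosinor_fit"))
  }
  fit <- stats::lm(y ~ cw + sw)
  null <- stats::lm(y ~ 1)
  a <- unname(stats::coef(fit)["cw"])
  b <- unname(stats::coef(fit)["sw"])
  amp <- sqrt(a^2 + b^2)
  phase <- (atan2(b, a) * period_h / (2 * pi)) %% period_h
  an <- stats::anova(null, fit)
  p <- an[["Pr(>F)"]][2]
  if (is.na(p)) p <- 1  # perfect fit or degenerate residuals
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(mesor = unname(stats::coef(fit)[1]), amplitude = amp,
                 phase_h = phase, period_h = period_h, p_value = p,
                 r_squared = 1 - rss / tss, n_obs = n, a = a, b = b),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("cosinor (period %g h): mesor %.4g, amplitude %.4g, peak %.2f h, p = %.3g\n",
              x$period_h, x$mesor, x$amplitude, x$phase_h, x$p_value))
  invisible(x)
}

#' Predict from a cosinor fit
#' @param object a `cosinor_fit`.
#' @param time_h times (hours) at which to evaluate the fitted curve.
#' @param ... unused.
#' @export
predict.cosinor_fit <- function(object, time_h, ...) {
  object$mesor + object$amplitude *
    cos(2 * pi * (time_h - object$phase_h) / object$period_h)
}

#' Two-component harmonic regression
#'
#' Adds a 12-h (second harmonic) cosine term to the 24-h cosinor:
#' y = baseline + A*cos(2*pi*(t - phiA)/24) + B*cos(4*pi*(t - phiB)/24).
#' Fit by least squares on the sine/cosine linearization of both harmonics;
#' the p-value is the F-test of all four rhythm coefficients. When the
#' second-harmonic amplitude is zero the fit reduces to [fit_cosinor()].
#'
#' @param time_h sampling times (hours).
#' @param y response values.
#' @param period_h fundamental period, default 24.
#' @return list with `baseline`, `amplitude_a`, `phase_a_h` (24-h component),
#'   `amplitude_b`, `phase_b_h` (12-h component), `p_value`, `n_obs`.
#' @export
fit_harmonic <- function(time_h, y, period_h = 24) {
  ok <- is.finite(time_h) & is.finite(y)
  time_h <- time_h[ok]; y <- y[ok]
  n <- length(y)
  if (n < 6) abort_located("harmonic regression needs >= 6 observations")
  if (length(unique(round(time_h, 9))) < 5)
    abort_located("harmonic regression needs >= 5 distinct time points")
  w <- 2 * pi / period_h
  c1 <- cos(w * time_h); s1 <- sin(w * time_h)
  c2 <- cos(2 * w * time_h); s2 <- sin(2 * w * time_h)
  if (stats::sd(y) == 0) {
    return(list(baseline = y[1], amplitude_a = 0, phase_a_h = 0,
                amplitude_b = 0, phase_b_h = 0, p_value = 1, n_obs = n))
  }
  fit <- stats::lm(y ~ c1 + s1 + c2 + s2)
  null <- stats::lm(y ~ 1)
  co <- stats::coef(fit)
  a1 <- unname(co["c1"]); b1 <- unname(co["s1"])
  a2 <- unname(co["c2"]); b2 <- unname(co["s2"])
  an <- stats::anova(null, fit)
  p <- an[["Pr(>F)"]][2]
  if (is.na(p)) p <- 1
  list(baseline = unname(co[1]),
       amplitude_a = sqrt(a1^2 + b1^2),
       phase_a_h = (atan2(b1, a1) * period_h / (2 * pi)) %% period_h,
       amplitude_b = sqrt(a2^2 + b2^2),
       phase_b_h = (atan2(b2, a2) * period_h / (4 * pi)) %% (period_h / 2),
       p_value = p, n_obs = n)
}
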