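# Drug-release kinetics: cumulative-release construction with
# aliquot-replacement correction, normalization to the 24 h maximum, the
# ultra-fast (Tao-Lu) saturating release model, and burst release rates.

#' Aliquot-sampled release measurement series
#'
#' At each sampling time an aliquot is withdrawn from the release chamber
#' and replaced with fresh buffer, so later measured concentrations
#' understate the cumulative release; defaults are a 14 mL chamber with
#' 1 mL aliquots.
#'
#' @param t sampling times (min), strictly increasing, > 0.
#' @param C_sample measured concentration in each extracted aliquot (mg/mL).
#' @param V_reservoir chamber volume (mL), default 14.
#' @param V_aliquot extracted/replaced volume (mL), default 1;
#'   `0 <= V_aliquot <= V_reservoir`.
#' @return object of class `release_series`.
#' @export
release_series <- function(t, C_sample, V_reservoir = 14, V_aliquot = 1) {
  if (!is.numeric(t) || !is.numeric(C_sample) ||
      length(t) != length(C_sample) || length(t) < 1L ||
      anyNA(t) || anyNA(C_sample)) {
    abort("`t` and `C_sample` must be numeric vectors of equal length",
          "mnswell_validation_error")
  }
  if (any(t <= 0)) {
    abort("sampling times must be > 0", "mnswell_validation_error")
  }
  check_strictly_increasing(t, "t")
  check_scalar_pos(V_reservoir, "V_reservoir")
  check_scalar_nonneg(V_aliquot, "V_aliquot")
  if (V_aliquot > V_reservoir) {
    abort("V_aliquot must not exceed V_reservoir", "mnswell_validation_error")
  }
  structure(list(t = as.numeric(t), C_sample = as.numeric(C_sample),
                 V_reservoir = V_reservoir, V_aliquot = V_aliquot),
            class = "release_series")
}

#' Aliquot-replacement correction of cumulative concentrations
#'
#' Standard dissolution-testing correction for sampling with replacement:
#' C_cum(t_i) = C_sample(t_i) + (V_aliquot / V_reservoir) *
#' sum_{j < i} C_sample(t_j). Reduces to the raw series when no volume is
#' replaced, and is non-decreasing whenever the raw concentrations are
#' nonnegative and non-decreasing.
#'
#' @param series a [release_series()].
#' @return numeric vector of corrected cumulative concentrations (mg/mL).
#' @export
cumulative_correct <- function(series) {
  if (!inherits(series, "release_series")) {
    abort("`series` must be a release_series", "mnswell_validation_error")
  }
  C <- series$C_sample
  if (any(C < 0)) {
    abort("concentrations must be nonnegative", "mnswell_validation_error")
  }
  frac <- series$V_aliquot / series$V_reservoir
  prior <- c(0, cumsum(C)[-length(C)])
  C + frac * prior
}

#' Cumulative release percentage
#'
#' C%(t_i) = C_cum(t_i) / C_max * 100 with C_max the total (corrected)
#' drug concentration at 24 h, so the final point reads 100%.
#'
#' @param C_cum corrected cumulative concentrations (mg/mL).
#' @param C_max normalizing concentration (mg/mL), > 0; by convention the
#'   corrected cumulative value at the final 24 h sample.
#' @return percent series.
#' @export
cumulative_percent <- function(C_cum, C_max) {
  check_scalar_pos(C_max, "C_max")
  if (!is.numeric(C_cum) || anyNA(C_cum)) {
    abort("`C_cum` must be numeric", "mnswell_validation_error")
  }
  C_cum / C_max * 100
}

#' Fit the ultra-fast (saturating) release model
#'
#' The ultra-fast release law y = k t / (1 + a t), with y the fraction of
#' the 24 h release, linearizes as 1/y = (1/k)(1/t) + a/k. The fit is
#' ordinary least squares of 1/y on 1/t: k = 1/slope, a = intercept * k,
#' and r^2 is the squared Pearson correlation in the linearized
#' coordinates. The fitted plateau is k/a.
#'
#' @param t sampling times (min), > 0.
#' @param frac fractional release Q_t / Q_24h, in (0, 1].
#' @return object of class `release_params`: `k` (1/min), `a` (1/min),
#'   `r2`, `plateau` (= k/a), `slope`, `intercept`, `n_used`.
#' @export
taolu_fit <- function(t, frac) {
  if (!is.numeric(t) || !is.numeric(frac) || length(t) != length(frac)) {
    abort("`t` and `frac` must be numeric vectors of equal length",
          "mnswell_validation_error")
  }
  keep <- is.finite(t) & is.finite(frac) & t > 0 & frac > 0
  t <- t[keep]; frac <- frac[keep]
  if (length(t) < 3L) {
    abort("ultra-fast release fit needs >= 3 usable points",
          "mnswell_insufficient_data_error")
  }
  x <- 1 / t
  y <- 1 / frac
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- fit$coefficients[[1]]
  slope <- fit$coefficients[[2]]
  if (!is.finite(slope) || slope <= 0) {
    abort("degenerate release fit: nonpositive slope (data inconsistent with the model)",
          "mnswell_degenerate_fit_error")
  }
  k <- 1 / slope
  a <- intercept * k
  if (!is.finite(a) || a <= 0) {
    abort("degenerate release fit: nonpositive empirical parameter a",
          "mnswell_degenerate_fit_error")
  }
  r2 <- stats::cor(x, y)^2
  structure(list(k = k, a = a, r2 = r2, plateau = k / a,
                 slope = slope, intercept = intercept, n_used = length(t)),
            class = "release_params")
}

#' @export
print.release_params <- function(x, ...) {
  cat(sprintf("<release_params> k = %.4g /min, a = %.4g /min, plateau = %.3f, r2 = %.4f (n = %d)\n",
              x$k, x$a, x$plateau, x$r2, x$n_used))
  invisible(x)
}

#' Forward ultra-fast release curve
#'
#' @param params a [release_params()] fit (or any list with `k`, `a`).
#' @param t times (min, >= 0), vectorized.
#' @return fractional release; 0 at t = 0, approaching k/a.
#' @export
taolu_predict <- function(params, t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    abort("`t` must be nonnegative", "mnswell_validation_error")
  }
  k <- params$k; a <- params$a
  check_scalar_pos(k, "k")
  check_scalar_pos(a, "a")
  k * t / (1 + a * t)
}

#' Nonlinear least-squares fit of the ultra-fast release model
#'
#' Unlinearized cross-check for [taolu_fit()] — the reciprocal
#' linearization amplifies noise at small fractions, so the two fits are
#' compared, not conflated.
#'
#' @param t times (min).
#' @param frac fractional release.
#' @param start optional starting list (`k`, `a`); defaults to the
#'   linearized estimates.
#' @return object of class `release_params`.
#' @export
taolu_fit_nls <- function(t, frac, start = NULL) {
  keep <- is.finite(t) & is.finite(frac) & t > 0 & frac > 0
  t <- t[keep]; frac <- frac[keep]
  if (length(t) < 3L) {
    abort("ultra-fast release fit needs >= 3 usable points",
          "mnswell_insufficient_data_error")
  }
  if (is.null(start)) {
    lin <- taolu_fit(t, frac)
    start <- list(k = lin$k, a = lin$a)
  }
  fit <- stats::nls(frac ~ k * t / (1 + a * t), start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1,
                                                 minFactor = 1e-10))
  co <- stats::coef(fit)
  k <- unname(co["k"]); a <- unname(co["a"])
  structure(list(k = k, a = a,
                 r2 = stats::cor(frac, stats::predict(fit))^2,
                 plateau = k / a, slope = 1 / k, intercept = a / k,
                 n_used = length(t)),
            class = "release_params")
}

#' Early-window release rate
#'
#' Least-squares slope of the cumulative percentage against time over
#' `[0, window_end]` — the burst-release rate in %/min (e.g. the slope up
#' to 120 min).
#'
#' @param C_percent cumulative release percentages.
#' @param t times (min), same length.
#' @param window_end end of the window (min), default 120.
#' @return slope (%/min).
#' @export
release_rate <- function(C_percent, t, window_end = 120) {
  if (!is.numeric(C_percent) || !is.numeric(t) ||
      length(C_percent) != length(t)) {
    abort("`C_percent` and `t` must be numeric vectors of equal length",
          "mnswell_validation_error")
  }
  keep <- is.finite(t) & is.finite(C_percent) & t >= 0 & t <= window_end
  t <- t[keep]; Cp <- C_percent[keep]
  if (length(t) < 2L || length(unique(t)) < 2L) {
    abort("release rate needs >= 2 distinct points within the window",
          "mnswell_insufficient_data_error")
  }
  fit <- stats::lm.fit(cbind(1, t), Cp)
  fit$coefficients[[2]]
}

#' Read a release series from CSV
#'
#' Expects header `t_min,C_sample_mg_per_mL`; chamber and aliquot volumes
#' are supplied as sidecar scalars.
#'
#' @param path file path.
#' @param V_reservoir chamber volume (mL).
#' @param V_aliquot aliquot volume (mL).
#' @return a [release_series()].
#' @export
read_release_csv <- function(path, V_reservoir = 14, V_aliquot = 1) {
  d <- utils::read.csv(path)
  if (!all(c("t_min", "C_sample_mg_per_mL") %in% names(d))) {
    abort(sprintf("%s: expected columns t_min,C_sample_mg_per_mL", path),
          "mnswell_parse_error")
  }
  release_series(d$t_min, d$C_sample_mg_per_mL,
                 V_reservoir = V_reservoir, V_aliquot = V_aliquot)
}
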