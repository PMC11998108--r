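# Gravimetric swelling analysis: swelling-percentage series,
# pseudo-second-order kinetic fitting (linearized and nonlinear), and gel
# characterization (equilibrium water content, gel fraction, porosity).

#' Timestamped array-mass series
#'
#' @param t sampling times (min), strictly increasing, nonnegative.
#' @param m measured wet masses (mg), positive.
#' @param m0 initial dry (xerogel-state) mass (mg), positive.
#' @return object of class `mass_series`.
#' @export
mass_series <- function(t, m, m0) {
  if (!is.numeric(t) || !is.numeric(m) || length(t) != length(m) ||
      length(t) < 1L || anyNA(t) || anyNA(m)) {
    abort("`t` and `m` must be numeric vectors of equal length",
          "mnswell_validation_error")
  }
  if (any(t < 0)) abort("times must be nonnegative", "mnswell_validation_error")
  check_strictly_increasing(t, "t")
  if (any(m <= 0)) abort("masses must be positive", "mnswell_validation_error")
  check_scalar_pos(m0, "m0")
  structure(list(t = as.numeric(t), m = as.numeric(m), m0 = m0),
            class = "mass_series")
}

#' Swelling percentage from a mass series
#'
#' S(t) = (m_t - m_0) / m_0 * 100, the mass gained by fluid uptake relative
#' to the dry state. Negative values (mass below the dry mass, typically an
#' evaporation or handling artifact) are rejected.
#'
#' @param series a [mass_series()].
#' @return data.frame with columns `t` (min) and `S` (percent).
#' @export
swelling_percent_series <- function(series) {
  if (!inherits(series, "mass_series")) {
    abort("`series` must be a mass_series", "mnswell_validation_error")
  }
  S <- (series$m - series$m0) / series$m0 * 100
  if (any(S < 0)) {
    abort("negative swelling percentage: mass below initial dry mass",
          "mnswell_validation_error")
  }
  data.frame(t = series$t, S = S)
}

#' Fit pseudo-second-order swelling kinetics
#'
#' The pseudo-second-order model dS/dt = k_s (S_inf - S)^2 has closed form
#' S(t) = k_s S_inf^2 t / (1 + k_s S_inf t) and linearizes as
#' t/S = 1/(k_s S_inf^2) + t / S_inf. The fit is ordinary least squares of
#' t/S on t (the conventional plot): S_inf = 1/slope,
#' k_s = slope^2 / intercept, and r^2 is the squared Pearson correlation of
#' (t, t/S). Points with t = 0 or S <= 0 are dropped before linearization
#' (t/S is undefined there); a message notes how many were dropped.
#'
#' With S in percent, k_s carries units 1/(percent * min); see
#' [ks_percent_to_fraction()] for the mg/mg convention.
#'
#' @param t times (min).
#' @param S swelling percentages.
#' @return object of class `pso_params`: `S_inf`, `k_s`, `r2`, `slope`,
#'   `intercept`, `n_used`.
#' @export
pso_fit <- function(t, S) {
  if (!is.numeric(t) || !is.numeric(S) || length(t) != length(S)) {
    abort("`t` and `S` must be numeric vectors of equal length",
          "mnswell_validation_error")
  }
  keep <- is.finite(t) & is.finite(S) & t > 0 & S > 0
  if (sum(!keep) > 0) {
    message(sprintf("pso_fit: dropped %d point(s) with t <= 0 or S <= 0",
                    sum(!keep)))
  }
  t <- t[keep]; S <- S[keep]
  if (length(t) < 3L) {
    abort("pseudo-second-order fit needs >= 3 usable points",
          "mnswell_insufficient_data_error")
  }
  y <- t / S
  fit <- stats::lm.fit(cbind(1, t), y)
  intercept <- fit$coefficients[[1]]
  slope <- fit$coefficients[[2]]
  if (!is.finite(slope) || !is.finite(intercept) || slope <= 0 ||
      intercept <= 0) {
    abort("degenerate pseudo-second-order fit: nonpositive slope or intercept (data inconsistent with the model)",
          "mnswell_degenerate_fit_error")
  }
  S_inf <- 1 / slope
  k_s <- slope^2 / intercept
  r2 <- stats::cor(t, y)^2
  structure(list(S_inf = S_inf, k_s = k_s, r2 = r2,
                 slope = slope, intercept = intercept, n_used = length(t)),
            class = "pso_params")
}

#' @export
print.pso_params <- function(x, ...) {
  cat(sprintf("<pso_params> S_inf = %.4g %%, k_s = %.4g /(%%*min), r2 = %.4f (n = %d)\n",
              x$S_inf, x$k_s, x$r2, x$n_used))
  invisible(x)
}

#' Forward pseudo-second-order swelling curve
#'
#' @param params a [pso_params()] fit (or any list with `S_inf`, `k_s`).
#' @param t times (min, >= 0), vectorized.
#' @return swelling percentages; 0 at t = 0, approaching `S_inf`.
#' @export
pso_predict <- function(params, t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    abort("`t` must be nonnegative", "mnswell_validation_error")
  }
  S_inf <- params$S_inf; k_s <- params$k_s
  check_scalar_pos(S_inf, "S_inf")
  check_scalar_pos(k_s, "k_s")
  k_s * S_inf^2 * t / (1 + k_s * S_inf * t)
}

#' Nonlinear least-squares pseudo-second-order fit
#'
#' Unconstrained Gauss-Newton fit of the forward model to (t, S). This is
#' the cross-check for the conventional linearized fit: identical on
#' noise-free data, and more robust under multiplicative noise (the
#' linearization weights early points heavily). Reported alongside, never
#' silently substituted.
#'
#' @param t times (min).
#' @param S swelling percentages.
#' @param start optional list with starting `S_inf`, `k_s`; defaults to the
#'   linearized estimates.
#' @return object of class `pso_params` (with `r2` the squared correlation
#'   of observed and fitted S).
#' @export
pso_fit_nls <- function(t, S, start = NULL) {
  keep <- is.finite(t) & is.finite(S) & t > 0 & S > 0
  t <- t[keep]; S <- S[keep]
  if (length(t) < 3L) {
    abort("pseudo-second-order fit needs >= 3 usable points",
          "mnswell_insufficient_data_error")
  }
  if (is.null(start)) {
    lin <- suppressMessages(pso_fit(t, S))
    start <- list(S_inf = lin$S_inf, k_s = lin$k_s)
  }
  fit <- stats::nls(S ~ k_s * S_inf^2 * t / (1 + k_s * S_inf * t),
                    start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1,
                                                 minFactor = 1e-10))
  co <- stats::coef(fit)
  pred <- stats::predict(fit)
  structure(list(S_inf = unname(co["S_inf"]), k_s = unname(co["k_s"]),
                 r2 = stats::cor(S, pred)^2,
                 slope = 1 / unname(co["S_inf"]),
                 intercept = 1 / (unname(co["k_s"]) * unname(co["S_inf"])^2),
                 n_used = length(t)),
            class = "pso_params")
}

#' Gel mass record for equilibrium characterization
#'
#' @param m0 initial array mass (mg).
#' @param m_inf mass at equilibrium swelling (mg); if omitted, derive it
#'   from a fitted plateau with [m_inf_from_fit()].
#' @param m_x xerogel (re-dried) mass (mg).
#' @param m_EtOH ethanol-treated array mass (mg).
#' @param V_T total hydrogel volume (cm^3).
#' @param rho_EtOH ethanol density (g/cm^3), default 0.789.
#' @return object of class `gel_masses`; unused fields may be NA.
#' @export
gel_masses <- function(m0, m_inf = NA_real_, m_x = NA_real_,
                       m_EtOH = NA_real_, V_T = NA_real_, rho_EtOH = 0.789) {
  check_scalar_pos(m0, "m0")
  for (nm in c("m_inf", "m_x", "m_EtOH", "V_T")) {
    v <- get(nm)
    if (!is.na(v)) check_scalar_pos(v, nm)
  }
  check_scalar_pos(rho_EtOH, "rho_EtOH")
  structure(list(m0 = m0, m_inf = m_inf, m_x = m_x, m_EtOH = m_EtOH,
                 V_T = V_T, rho_EtOH = rho_EtOH),
            class = "gel_masses")
}

#' Equilibrium mass from a fitted swelling plateau
#'
#' The mass at equilibrium swelling is rarely observed directly; it is
#' derived from the fitted plateau as m_inf = m0 * (1 + S_inf / 100).
#'
#' @param m0 initial mass (mg).
#' @param params a [pso_params()] fit.
#' @return equilibrium mass (mg).
#' @export
m_inf_from_fit <- function(m0, params) {
  check_scalar_pos(m0, "m0")
  m0 * (1 + params$S_inf / 100)
}

#' Equilibrium water content
#'
#' EWC(%) = (m_inf - m_x) / m_x * 100: water mass held at equilibrium
#' relative to the xerogel mass.
#'
#' @param masses a [gel_masses()] with `m_inf` and `m_x` set.
#' @return percent.
#' @export
ewc <- function(masses) {
  if (is.na(masses$m_x) || masses$m_x <= 0) {
    abort("EWC needs xerogel mass m_x > 0", "mnswell_validation_error")
  }
  if (is.na(masses$m_inf)) {
    abort("EWC needs equilibrium mass m_inf", "mnswell_validation_error")
  }
  (masses$m_inf - masses$m_x) / masses$m_x * 100
}

#' Gel fraction
#'
#' GF(%) = m_x / m0 * 100: the crosslinked (insoluble) mass fraction
#' surviving a swell/re-dry cycle.
#'
#' @param masses a [gel_masses()] with `m_x` set.
#' @return percent.
#' @export
gel_fraction <- function(masses) {
  if (is.na(masses$m_x)) {
    abort("gel fraction needs xerogel mass m_x", "mnswell_validation_error")
  }
  masses$m_x / masses$m0 * 100
}

#' Solvent-displacement porosity
#'
#' phi = (m_EtOH - m0) / (V_T * rho_EtOH): pore volume fraction inferred
#' from the mass of ethanol taken up into the pore space. Values outside
#' [0, 1] indicate measurement inconsistency and trigger a warning.
#'
#' @param masses a [gel_masses()] with `m_EtOH` and `V_T` set; masses in g
#'   and volume in cm^3 (or any consistent unit pair with `rho_EtOH`).
#' @return pore volume fraction.
#' @export
porosity <- function(masses) {
  if (is.na(masses$V_T) || masses$V_T <= 0) {
    abort("porosity needs total gel volume V_T > 0", "mnswell_validation_error")
  }
  if (is.na(masses$m_EtOH)) {
    abort("porosity needs ethanol-treated mass m_EtOH",
          "mnswell_validation_error")
  }
  phi <- (masses$m_EtOH - masses$m0) / (masses$V_T * masses$rho_EtOH)
  if (phi < 0 || phi > 1) {
    warning(sprintf("porosity %.3f outside [0, 1]: check masses/volume", phi))
  }
  phi
}

#' Read a swelling mass series from CSV
#'
#' Expects header `t_min,mass_mg`; `m0` is supplied separately (sidecar
#' scalar).
#'
#' @param path file path.
#' @param m0 initial dry mass (mg).
#' @return a [mass_series()].
#' @export
read_swelling_csv <- function(path, m0) {
  d <- utils::read.csv(path)
  if (!all(c("t_min", "mass_mg") %in% names(d))) {
    abort(sprintf("%s: expected columns t_min,mass_mg", path),
          "mnswell_parse_error")
  }
  mass_series(d$t_min, d$mass_mg, m0 = m0)
}
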