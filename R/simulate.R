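# Seeded synthetic-data generators emulating each measurement process:
# gravimetric swelling curves, aliquot-sampled release series,
# two-compartment absorption time courses, and jittered needle profiles.
# Every generator records its truth and seed in the emitted object so
# recovery tests never re-enter parameters by hand. Noise is multiplicative
# Gaussian (a measurement coefficient of variation); seeds are mandatory.

#' Default sampling grids mirroring the laboratory protocols
#'
#' Swelling masses every 10 min to 180 min; release aliquots every 10 min
#' to 60 min, then 120, 240, 480 and 1440 min.
#'
#' @name sim_grids
#' @export
default_swelling_times <- function() seq(10, 180, by = 10)

#' @rdname sim_grids
#' @export
default_release_times <- function() c(seq(10, 60, by = 10), 120, 240, 480, 1440)

sim_truth <- function(x, truth, seed, noise_cv) {
  attr(x, "truth") <- truth
  attr(x, "seed") <- seed
  attr(x, "noise_cv") <- noise_cv
  x
}

check_sim_args <- function(seed, noise_cv) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed)) {
    abort("a single integer `seed` is required (no default)",
          "mnswell_validation_error")
  }
  check_scalar_nonneg(noise_cv, "noise_cv")
}

#' Simulate a gravimetric swelling mass series
#'
#' Masses follow m(t_i) = m0 * (1 + S(t_i)/100) * (1 + e_i) with S the
#' pseudo-second-order forward curve and e_i ~ Normal(0, noise_cv).
#'
#' @param S_inf true equilibrium swelling (percent).
#' @param k_s true rate constant (1/(percent * min)).
#' @param m0 initial dry mass (mg).
#' @param t sampling times (min), strictly increasing; default every 10 min
#'   to 180 min.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed (required).
#' @return a [mass_series()] carrying `truth`, `seed` and `noise_cv`
#'   attributes.
#' @export
gen_swelling_series <- function(S_inf, k_s, m0,
                                t = default_swelling_times(),
                                noise_cv = 0, seed) {
  check_sim_args(seed, noise_cv)
  check_scalar_pos(S_inf, "S_inf")
  check_scalar_pos(k_s, "k_s")
  check_scalar_pos(m0, "m0")
  check_strictly_increasing(t, "t")
  set.seed(as.integer(seed))
  S <- pso_predict(list(S_inf = S_inf, k_s = k_s), t)
  m <- m0 * (1 + S / 100) * (1 + stats::rnorm(length(t), 0, noise_cv))
  m <- pmax(m, m0 * 1e-6)
  sim_truth(mass_series(t, m, m0 = m0),
            list(S_inf = S_inf, k_s = k_s, m0 = m0), seed, noise_cv)
}

#' Simulate an aliquot-sampled release series
#'
#' Builds the true cumulative concentration curve from the ultra-fast
#' release model, inverts the aliquot-replacement correction to obtain the
#' per-sample concentrations an analyst would actually measure (so
#' [cumulative_correct()] applied to the noise-free output recovers the
#' true curve exactly), then applies multiplicative noise to the samples.
#'
#' @param k true release rate constant (1/min).
#' @param a true empirical parameter (1/min).
#' @param C_max total drug concentration scale at 24 h (mg/mL).
#' @param t sampling times (min); default the laboratory grid.
#' @param V_reservoir,V_aliquot chamber and aliquot volumes (mL).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed (required).
#' @return a [release_series()] carrying `truth`, `seed` and `noise_cv`
#'   attributes.
#' @export
gen_release_series <- function(k, a, C_max = 1,
                               t = default_release_times(),
                               V_reservoir = 14, V_aliquot = 1,
                               noise_cv = 0, seed) {
  check_sim_args(seed, noise_cv)
  check_scalar_pos(k, "k")
  check_scalar_pos(a, "a")
  check_scalar_pos(C_max, "C_max")
  if (any(t <= 0)) abort("times must be > 0", "mnswell_validation_error")
  check_strictly_increasing(t, "t")
  set.seed(as.integer(seed))
  C_cum <- taolu_predict(list(k = k, a = a), t) * C_max
  # invert the aliquot correction: samples whose corrected cumulative
  # series equals the true curve
  frac <- V_aliquot / V_reservoir
  C_sample <- numeric(length(t))
  run <- 0
  for (i in seq_along(t)) {
    C_sample[i] <- C_cum[i] - frac * run
    run <- run + C_sample[i]
  }
  C_sample <- pmax(C_sample * (1 + stats::rnorm(length(t), 0, noise_cv)), 0)
  sim_truth(release_series(t, C_sample, V_reservoir = V_reservoir,
                           V_aliquot = V_aliquot),
            list(k = k, a = a, C_max = C_max), seed, noise_cv)
}

#' Simulate a two-compartment absorption time course
#'
#' Ct(t) = (C0/2) * (1 - exp(-2 A P t / V)) with multiplicative noise,
#' truncated into [0, C0/2) so the permeability inversion stays defined.
#'
#' @param P true permeability (cm/s).
#' @param C0 initial bulk concentration (mg/mL).
#' @param A permeation area (cm^2).
#' @param V solution volume (mL = cm^3).
#' @param t sampling times (s), > 0.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed (required).
#' @return data.frame with columns `t` (s) and `Ct` (mg/mL), carrying
#'   `truth`, `seed` and `noise_cv` attributes.
#' @export
gen_absorption_course <- function(P, C0, A, V,
                                  t = seq(3600, 86400, by = 3600),
                                  noise_cv = 0, seed) {
  check_sim_args(seed, noise_cv)
  check_scalar_pos(P, "P")
  check_scalar_pos(C0, "C0")
  check_scalar_pos(A, "A")
  check_scalar_pos(V, "V")
  if (any(t <= 0)) abort("times must be > 0", "mnswell_validation_error")
  check_strictly_increasing(t, "t")
  set.seed(as.integer(seed))
  Ct <- (C0 / 2) * (1 - exp(-2 * A * P * t / V))
  Ct <- Ct * (1 + stats::rnorm(length(t), 0, noise_cv))
  Ct <- pmin(pmax(Ct, 0), (C0 / 2) * (1 - 1e-12))
  sim_truth(data.frame(t = t, Ct = Ct),
            list(P = P, C0 = C0, A = A, V = V), seed, noise_cv)
}

#' Simulate a measured needle profile with radius jitter
#'
#' Samples a parametric shape and adds seeded Gaussian jitter (standard
#' deviation `jitter_um`) to the radii, clipped at zero — emulating the
#' digitization of microscope images into coordinates.
#'
#' @param params a [shape_params()].
#' @param jitter_um radius jitter standard deviation (um, >= 0).
#' @param n_samples profile sample count.
#' @param seed RNG seed (required).
#' @return a [radial_profile()] carrying `truth`, `seed` and `noise_cv`
#'   attributes.
#' @export
gen_profile <- function(params, jitter_um = 0, n_samples = 2001, seed) {
  check_sim_args(seed, jitter_um)
  prof <- shape_profile(params, n_samples)
  set.seed(as.integer(seed))
  r <- pmax(prof$r + stats::rnorm(length(prof$r), 0, jitter_um), 0)
  sim_truth(radial_profile(prof$x, r,
                           label = paste0(params$family, " (jittered)")),
            params, seed, jitter_um)
}
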