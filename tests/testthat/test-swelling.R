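test_that("swelling percentage is mass gain relative to the dry mass", {
  s <- mass_series(t = c(10, 20, 180), m = c(300, 400, 456), m0 = 100)
  out <- swelling_percent_series(s)
  expect_equal(out$S, c(200, 300, 356))
  # worked cells: (m0 100, m 456) -> 356 %; (m0 200, m 774) -> 287 %
  expect_equal(swelling_percent_series(
    mass_series(10, 774, m0 = 200))$S, 287)
  # m = m0 -> 0 %
  expect_equal(swelling_percent_series(mass_series(10, 200, m0 = 200))$S, 0)
  # negative swelling (evaporation artifact) is rejected
  expect_error(swelling_percent_series(mass_series(10, 150, m0 = 200)),
               class = "mnswell_validation_error")
  expect_error(mass_series(c(10, 10), c(1, 2), m0 = 1),
               class = "mnswell_validation_error")
})

test_that("pseudo-second-order fit recovers noise-free parameters exactly", {
  t <- seq(10, 180, by = 10)
  truth <- list(S_inf = 500, k_s = 2e-4)
  S <- pso_predict(truth, t)
  fit <- pso_fit(t, S)
  expect_equal(fit$S_inf, 500, tolerance = 1e-6)
  expect_equal(fit$k_s, 2e-4, tolerance = 1e-6)
  # t/S is exactly linear in t on model data
  expect_equal(fit$r2, 1.0, tolerance = 1e-10)

  # independent oracle: unconstrained nonlinear least squares on the same
  # points, started from the generating truth
  nls_fit <- stats::nls(S ~ k_s * S_inf^2 * t / (1 + k_s * S_inf * t),
                        data = data.frame(t = t, S = S),
                        start = list(S_inf = 450, k_s = 3e-4),
                        control = stats::nls.control(scaleOffset = 1,
                                                     tol = 1e-11))
  co <- stats::coef(nls_fit)
  expect_equal(fit$S_inf, unname(co["S_inf"]), tolerance = 1e-6)
  expect_equal(fit$k_s, unname(co["k_s"]), tolerance = 1e-6)
  # and the package's own nonlinear route agrees too
  nl <- pso_fit_nls(t, S)
  expect_equal(nl$S_inf, 500, tolerance = 1e-6)
  expect_equal(nl$k_s, 2e-4, tolerance = 1e-6)
})

test_that("pso_fit round-trips across the physical parameter range", {
  t <- seq(10, 180, by = 10)
  for (S_inf in c(50, 200, 714, 2000)) {
    for (k_s in c(1e-6, 1e-5, 5.35e-5, 1e-3, 1e-2)) {
      S <- pso_predict(list(S_inf = S_inf, k_s = k_s), t)
      fit <- pso_fit(t, S)
      expect_lt(rel_err(fit$S_inf, S_inf), 1e-6)
      expect_lt(rel_err(fit$k_s, k_s), 1e-6)
    }
  }
})

test_that("degenerate and underdetermined swelling data raise typed errors", {
  t <- seq(10, 60, 10)
  # constant series: the line passes through the origin, intercept 0
  expect_error(pso_fit(t, rep(400, 6)),
               class = "mnswell_degenerate_fit_error")
  # decreasing series gives a negative slope
  expect_error(pso_fit(c(10, 20, 30, 40), c(10, 200, 400, 4000) * 100),
               class = "mnswell_degenerate_fit_error")
  # fewer than 3 usable points (t = 0 and S = 0 are dropped with a message)
  expect_message(
    expect_error(pso_fit(c(0, 10, 20), c(0, 100, 150)),
                 class = "mnswell_insufficient_data_error"),
    "dropped")
})

test_that("pso_predict has the model's fixed points and asymptote", {
  p <- list(S_inf = 714, k_s = 5.35e-5)
  expect_equal(pso_predict(p, 0), 0)
  # half-saturation at t = 1/(k_s * S_inf)
  expect_equal(pso_predict(p, 1 / (p$k_s * p$S_inf)), p$S_inf / 2)
  expect_equal(pso_predict(p, 1e9), p$S_inf, tolerance = 1e-3)
  expect_true(all(diff(pso_predict(p, seq(0, 300, 5))) > 0))
  expect_error(pso_predict(p, -1), class = "mnswell_validation_error")
})

test_that("gel characterization formulas reproduce the worked cells", {
  # EWC: (m_inf 683, m_x 100) -> 583 %
  expect_equal(ewc(gel_masses(m0 = 100, m_inf = 683, m_x = 100)), 583)
  expect_equal(ewc(gel_masses(m0 = 100, m_inf = 200, m_x = 100)), 100)
  expect_equal(ewc(gel_masses(m0 = 100, m_inf = 100, m_x = 100)), 0)
  # GF: (m0 100, m_x 97) -> 97 %
  expect_equal(gel_fraction(gel_masses(m0 = 100, m_x = 97)), 97)
  expect_equal(gel_fraction(gel_masses(m0 = 100, m_x = 50)), 50)
  # porosity: ethanol uptake 0.11835 g into 1 cm^3 -> 0.15
  expect_equal(porosity(gel_masses(m0 = 1, m_EtOH = 1.11835, V_T = 1)), 0.15)
  expect_equal(porosity(gel_masses(m0 = 1, m_EtOH = 1, V_T = 1)), 0)
  # full pore volume: uptake mass equals V_T * rho exactly
  expect_equal(porosity(gel_masses(m0 = 1, m_EtOH = 2, V_T = 2,
                                   rho_EtOH = 0.5)), 1)
  expect_warning(porosity(gel_masses(m0 = 1, m_EtOH = 2, V_T = 1)),
                 "outside")
  expect_error(ewc(gel_masses(m0 = 100, m_inf = 683)),
               class = "mnswell_validation_error")
})

test_that("fitted plateau links mass and swelling consistently", {
  # m_inf = m0 (1 + S_inf/100) makes EWC computable from a fit alone,
  # and the two EWC routes agree when the measured plateau matches the fit
  t <- seq(10, 180, 10)
  S <- pso_predict(list(S_inf = 583, k_s = 1e-4), t)
  fit <- pso_fit(t, S)
  m0 <- 100
  m_inf <- m_inf_from_fit(m0, fit)
  expect_equal(m_inf, 683, tolerance = 1e-6)
  expect_equal(ewc(gel_masses(m0 = m0, m_inf = m_inf, m_x = m0)),
               fit$S_inf, tolerance = 1e-6)
})

test_that("rate-constant unit conversion is the fixed factor 100", {
  expect_equal(ks_percent_to_fraction(5.35e-5), 5.35e-3)
  expect_equal(ks_fraction_to_percent(ks_percent_to_fraction(9.41e-5)),
               9.41e-5)
})

test_that("swelling CSV reader enforces its dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t_min = c(10, 20), mass_mg = c(300, 350)),
                   f, row.names = FALSE)
  s <- read_swelling_csv(f, m0 = 100)
  expect_s3_class(s, "mass_series")
  expect_equal(s$m, c(300, 350))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = 1, mass = 2), bad, row.names = FALSE)
  expect_error(read_swelling_csv(bad, m0 = 100),
               class = "mnswell_parse_error")
})
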