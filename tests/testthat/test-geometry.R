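test_that("shape profiles match their defining geometry", {
  # cone: linear taper, r(0) = 0, r(h) = base_radius
  cone <- shape_profile(shape_params("conical", height = 900,
                                     base_radius = 150), n_samples = 901)
  expect_equal(cone$r[1], 0)
  expect_equal(cone$r[length(cone$r)], 150)
  expect_equal(cone$r, 150 * cone$x / 900, tolerance = 1e-12)

  # candlelit: maximal radius is the head radius, attained at the head center
  cand <- shape_profile(shape_params("candlelit", height = 900,
                                     head_radius = 177, head_center = 250,
                                     shaft_radius = 100))
  expect_equal(max(cand$r), 177)
  expect_equal(cand$x[which.max(cand$r)], 250)
  # shaft region is cylindrical down to the base
  expect_true(all(cand$r[cand$x > 400] == 100))

  # funnel: non-decreasing radius, reaches the base radius
  fun <- shape_profile(shape_params("funnel", base_radius = 150))
  expect_true(all(diff(fun$r) >= 0))
  expect_equal(fun$r[length(fun$r)], 150)

  # validation errors
  expect_error(shape_params("conical", height = -1),
               class = "mnswell_validation_error")
  expect_error(shape_params("candlelit", head_center = 1000),
               class = "mnswell_validation_error")
  expect_error(shape_params("candlelit", head_radius = 50,
                            shaft_radius = 100),
               class = "mnswell_validation_error")
  expect_error(radial_profile(c(1, 2), c(1, 1)),
               class = "mnswell_validation_error")
  expect_error(radial_profile(c(0, 2, 1), c(1, 1, 1)),
               class = "mnswell_validation_error")
})

test_that("revolve_volume matches closed forms and is exactly additive", {
  # cone pi R^2 h / 3; the sampled profile is exactly linear so the
  # segmentwise quadratic integration is exact
  expect_equal(revolve_volume(cone_profile(150, 900)),
               pi * 150^2 * 900 / 3, tolerance = 1e-12)
  expect_equal(revolve_volume(cylinder_profile(100, 500)),
               pi * 100^2 * 500, tolerance = 1e-12)
  expect_equal(revolve_volume(hemisphere_profile(200, 1001)),
               2 * pi * 200^3 / 3, tolerance = 0.005)

  # additivity over split intervals to 1e-9 relative
  hemi <- hemisphere_profile(200, 501)
  for (split in c(37.3, 100, 161.8)) {
    expect_equal(revolve_volume(hemi, 0, split) +
                   revolve_volume(hemi, split, 200),
                 revolve_volume(hemi, 0, 200), tolerance = 1e-9)
  }

  expect_error(revolve_volume(hemi, -1, 100), class = "mnswell_range_error")
  expect_error(revolve_volume(hemi, 100, 300), class = "mnswell_range_error")
  expect_error(revolve_volume(hemi, 100, 100), class = "mnswell_range_error")
})

test_that("apply_swell rescales height and base diameter affinely", {
  cone <- cone_profile(150, 900)
  inc <- swell_increment(delta_height = 150, delta_base_diameter = 75)
  sw <- apply_swell(cone, inc)
  expect_equal(max(sw$x), 1050)
  expect_equal(sw$r[length(sw$r)], 150 * (300 + 75) / 300)

  # identity increment leaves the profile unchanged
  id <- apply_swell(cone, swell_increment(0, 0))
  expect_equal(id$x, cone$x)
  expect_equal(id$r, cone$r)

  # volume is monotone under nonnegative increments
  expect_gte(revolve_volume(sw), revolve_volume(cone))

  # zero base radius cannot absorb a diameter increment
  spike <- radial_profile(c(0, 450, 900), c(0, 100, 0))
  expect_error(apply_swell(spike, inc), class = "mnswell_validation_error")
})

test_that("band_volume_fraction covers the degenerate and uniform cases", {
  cyl <- cylinder_profile(100, 500)
  # band spanning the whole inserted needle, fully inserted -> 1
  expect_equal(band_volume_fraction(cyl, depth_band(0, 500, 0)), 1.0)
  # deepest half of a uniform cylinder -> 0.5
  expect_equal(band_volume_fraction(cyl, depth_band(250, 500, 0)), 0.5)
  # band entirely beyond the inserted length -> 0, not an error
  expect_equal(band_volume_fraction(cyl, depth_band(600, 700, 0)), 0)
  # uninserted offset shifts depths: with 100 um offset the needle spans
  # depths [-100, 400]; band [300, 400] is the deepest 100 um
  expect_equal(band_volume_fraction(cyl, depth_band(300, 400, 100)), 0.2)
  expect_error(depth_band(500, 400), class = "mnswell_validation_error")
})

test_that("band fractions are additive and tile to one", {
  cand <- shape_profile(default_shapes()$candlelit)
  edges <- seq(0, 900, by = 150)
  fracs <- vapply(seq_len(length(edges) - 1), function(i) {
    band_volume_fraction(cand, depth_band(edges[i], edges[i + 1], 0))
  }, numeric(1))
  expect_equal(sum(fracs), 1.0, tolerance = 1e-9)
  # pairwise merge equals sum of parts
  expect_equal(band_volume_fraction(cand, depth_band(150, 450, 0)),
               fracs[2] + fracs[3], tolerance = 1e-9)
})

test_that("swollen candlelit outranks conical and funnel in the SCS band", {
  shapes <- default_shapes()
  inc <- swell_increment()
  swollen <- lapply(shapes, function(s) apply_swell(shape_profile(s), inc))
  pre <- lapply(shapes, shape_profile)

  # default band: ordering candlelit > conical > funnel after swelling
  band <- depth_band()
  post <- vapply(swollen, band_volume_fraction, numeric(1), band = band)
  expect_gt(post[["candlelit"]], post[["conical"]])
  expect_gt(post[["conical"]], post[["funnel"]])

  # the candlelit head's in-band absolute volume never decreases under
  # swelling, for any band midpoint in the plausible SCS range
  for (mid in seq(400, 600, by = 25)) {
    b <- depth_band(mid - 50, mid + 50)
    h_pre <- max(pre$candlelit$x)
    h_post <- max(swollen$candlelit$x)
    v_pre <- band_volume_fraction(pre$candlelit, b) *
      revolve_volume(pre$candlelit)
    v_post <- band_volume_fraction(swollen$candlelit, b) *
      revolve_volume(swollen$candlelit)
    expect_gte(v_post, v_pre)
    expect_gt(h_post, h_pre)
  }
})

test_that("percent_volume_change is plain relative change in percent", {
  expect_equal(percent_volume_change(1, 1), 0)
  expect_equal(percent_volume_change(2, 3), 50)
  expect_equal(percent_volume_change(1, 11.94), 1094)
  expect_error(percent_volume_change(0, 1), class = "mnswell_validation_error")
})

test_that("profile CSV round trip preserves samples", {
  p <- shape_profile(default_shapes()$conical, n_samples = 41)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  q <- read_profile_csv(f)
  expect_equal(q$x, p$x)
  expect_equal(q$r, p$r)
  # wrong header is a parse error
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1:3, b = 1:3), bad, row.names = FALSE)
  expect_error(read_profile_csv(bad), class = "mnswell_parse_error")
})
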