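# shared helpers: relative error and analytic reference profiles

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# hemisphere of radius R sampled on n points (flat face at x = R)
hemisphere_profile <- function(R = 200, n = 1001) {
  x <- seq(0, R, length.out = n)
  radial_profile(x, sqrt(pmax(R^2 - x^2, 0)), label = "hemisphere")
}

cylinder_profile <- function(r = 100, h = 500, n = 1001) {
  radial_profile(seq(0, h, length.out = n), rep(r, n), label = "cylinder")
}

cone_profile <- function(R = 150, h = 900, n = 1001) {
  x <- seq(0, h, length.out = n)
  radial_profile(x, R * x / h, label = "cone")
}
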