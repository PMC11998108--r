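# Microneedle geometry: sampled radius-vs-depth profiles, solid-of-revolution
# volumes, the affine swelling transform, and volume-fraction scoring against
# a suprachoroidal depth band.

#' Sampled radial profile of a microneedle
#'
#' A microneedle is modelled as a solid of revolution about its axis: a
#' function r = f(x) giving the local radius at axial distance x from the
#' tip. Profiles come either from the parametric shape families
#' ([shape_profile()]) or from digitized microscope images (axial position /
#' radius pairs read from CSV).
#'
#' @param x strictly increasing axial positions from the tip (um); `x[1]`
#'   must be 0.
#' @param r local radii (um), same length as `x`, all nonnegative.
#' @param label free-text identifier.
#' @return object of class `radial_profile`.
#' @export
radial_profile <- function(x, r, label = "") {
  if (!is.numeric(x) || !is.numeric(r) || length(x) != length(r) ||
      length(x) < 2L || anyNA(x) || anyNA(r)) {
    abort("`x` and `r` must be numeric vectors of equal length >= 2",
          "mnswell_validation_error")
  }
  if (x[1] != 0) {
    abort("profile must start at the tip: x[1] == 0",
          "mnswell_validation_error")
  }
  check_strictly_increasing(x, "x")
  if (any(r < 0)) {
    abort("all radii must be nonnegative", "mnswell_validation_error")
  }
  structure(list(x = as.numeric(x), r = as.numeric(r),
                 label = as.character(label)[1]),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %s: %d samples, height %.1f um, max radius %.1f um\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$x), max(x$x), max(x$r)))
  invisible(x)
}

profile_height <- function(profile) max(profile$x)

#' Parametric microneedle shape families
#'
#' Three design families are supported. `conical`: linear taper from a point
#' tip to `base_radius`. `funnel`: quadratic (convex) flare from a small
#' `tip_radius` to `base_radius`, concentrating volume at the base.
#' `candlelit`: a sharp conical tip joined tangentially to a circular-arc
#' bulbous head of maximal radius `head_radius` centered at `head_center`,
#' descending to a cylindrical shaft of `shaft_radius` that runs to the
#' base — the design that concentrates swellable volume at the target
#' tissue depth.
#'
#' @param family one of `"candlelit"`, `"conical"`, `"funnel"`.
#' @param height needle height (um).
#' @param base_radius radius at the base (um; conical/funnel).
#' @param head_radius maximal head radius (um; candlelit).
#' @param head_center axial position of the head apex from the tip (um;
#'   candlelit). Must exceed `head_radius` so the tip cone can meet the head
#'   tangentially.
#' @param shaft_radius shaft radius (um; candlelit).
#' @param tip_radius radius at the tip (um; funnel).
#' @return object of class `shape_params`.
#' @export
shape_params <- function(family = c("candlelit", "conical", "funnel"),
                         height = 900,
                         base_radius = 150,
                         head_radius = 177,
                         head_center = 250,
                         shaft_radius = 100,
                         tip_radius = 20) {
  family <- match.arg(family)
  check_scalar_pos(height, "height")
  if (family == "conical") {
    check_scalar_pos(base_radius, "base_radius")
  } else if (family == "funnel") {
    check_scalar_pos(base_radius, "base_radius")
    check_scalar_pos(tip_radius, "tip_radius")
    if (tip_radius >= base_radius) {
      abort("funnel requires tip_radius < base_radius",
            "mnswell_validation_error")
    }
  } else {
    check_scalar_pos(head_radius, "head_radius")
    check_scalar_pos(head_center, "head_center")
    check_scalar_pos(shaft_radius, "shaft_radius")
    if (head_center >= height) {
      abort("candlelit requires 0 < head_center < height",
            "mnswell_validation_error")
    }
    if (head_radius < shaft_radius) {
      abort("candlelit requires head_radius >= shaft_radius",
            "mnswell_validation_error")
    }
    if (head_radius >= head_center) {
      abort("candlelit requires head_radius < head_center (tangent tip cone)",
            "mnswell_validation_error")
    }
    if (head_center + sqrt(head_radius^2 - shaft_radius^2) >= height) {
      abort("candlelit head does not fit below the base",
            "mnswell_validation_error")
    }
  }
  structure(list(family = family, height = height, base_radius = base_radius,
                 head_radius = head_radius, head_center = head_center,
                 shaft_radius = shaft_radius, tip_radius = tip_radius),
            class = "shape_params")
}

# analytic radius function of a shape family, vectorized over x
shape_radius <- function(params, x) {
  h <- params$height
  switch(params$family,
    conical = params$base_radius * x / h,
    funnel = params$tip_radius +
      (params$base_radius - params$tip_radius) * (x / h)^2,
    candlelit = {
      R <- params$head_radius
      c0 <- params$head_center
      s <- params$shaft_radius
      x_tan <- (c0^2 - R^2) / c0           # tangent point of tip cone on head
      slope <- R / sqrt(c0^2 - R^2)
      x_end <- c0 + sqrt(R^2 - s^2)        # head arc meets shaft radius
      r <- numeric(length(x))
      tip <- x <= x_tan
      arc <- x > x_tan & x <= x_end
      r[tip] <- slope * x[tip]
      r[arc] <- sqrt(pmax(R^2 - (x[arc] - c0)^2, 0))
      r[x > x_end] <- s
      r
    }
  )
}

candlelit_breakpoints <- function(params) {
  R <- params$head_radius
  c0 <- params$head_center
  c((c0^2 - R^2) / c0, c0, c0 + sqrt(R^2 - params$shaft_radius^2))
}

#' Sample a parametric shape into a radial profile
#'
#' Samples the analytic radius function on `n_samples` uniformly spaced
#' points over `[0, height]`; for the candlelit family the exact
#' breakpoints (tangent point, head apex, arc/shaft junction) are added so
#' the sampled profile attains the true maximal radius.
#'
#' @param params a [shape_params()] object.
#' @param n_samples number of uniform samples (>= 2).
#' @return a [radial_profile()].
#' @export
shape_profile <- function(params, n_samples = 2001) {
  if (!inherits(params, "shape_params")) {
    abort("`params` must be a shape_params object", "mnswell_validation_error")
  }
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2) {
    abort("`n_samples` must be >= 2", "mnswell_validation_error")
  }
  x <- seq(0, params$height, length.out = as.integer(n_samples))
  if (params$family == "candlelit") {
    x <- sort(unique(c(x, candlelit_breakpoints(params))))
  }
  radial_profile(x, shape_radius(params, x), label = params$family)
}

#' Solid-of-revolution volume of a profile segment
#'
#' Computes pi * integral of f(x)^2 over `[x_lo, x_hi]` with f the
#' piecewise-linear interpolant of the sampled radii. On each knot segment
#' the integrand is an exact quadratic, so the integral is evaluated in
#' closed form (h/3 * (r0^2 + r0*r1 + r1^2) per segment); the quadrature is
#' therefore exactly additive over subintervals, and its only error is the
#' piecewise-linear approximation of the underlying radius curve, which
#' vanishes as O(h^2) in the profile sampling step.
#'
#' @param profile a [radial_profile()].
#' @param x_lo,x_hi integration bounds (um), `0 <= x_lo < x_hi <= height`.
#' @return volume in um^3.
#' @export
revolve_volume <- function(profile, x_lo = 0, x_hi = profile_height(profile)) {
  if (!inherits(profile, "radial_profile")) {
    abort("`profile` must be a radial_profile", "mnswell_validation_error")
  }
  h <- profile_height(profile)
  if (!is.finite(x_lo) || !is.finite(x_hi) || x_lo < 0 || x_hi > h ||
      x_lo >= x_hi) {
    abort("integration interval must satisfy 0 <= x_lo < x_hi <= height",
          "mnswell_range_error")
  }
  inner <- profile$x[profile$x > x_lo & profile$x < x_hi]
  grid <- c(x_lo, inner, x_hi)
  r <- stats::approx(profile$x, profile$r, xout = grid)$y
  dx <- diff(grid)
  r0 <- r[-length(r)]
  r1 <- r[-1]
  pi * sum(dx * (r0^2 + r0 * r1 + r1^2) / 3)
}

#' Swelling increment of a needle
#'
#' Literature-reported hydrogel microneedle swelling is summarized as an
#' increase in height and in base diameter; defaults are the ~150 um height
#' and ~75 um base-diameter gains used for the theoretical volume model.
#'
#' @param delta_height height increase (um, >= 0).
#' @param delta_base_diameter base diameter increase (um, >= 0).
#' @export
swell_increment <- function(delta_height = 150, delta_base_diameter = 75) {
  check_scalar_nonneg(delta_height, "delta_height")
  check_scalar_nonneg(delta_base_diameter, "delta_base_diameter")
  structure(list(delta_height = delta_height,
                 delta_base_diameter = delta_base_diameter),
            class = "swell_increment")
}

#' Apply an affine swelling transform to a profile
#'
#' Axial coordinates are scaled by `(height + delta_height) / height` and
#' radii by `(d + delta_base_diameter) / d`, with `d` the base diameter
#' (twice the radius at the base) — an affine model of isotropic-per-axis
#' hydrogel expansion anchored at the measured height and base gains.
#'
#' @param profile a [radial_profile()].
#' @param inc a [swell_increment()].
#' @return the swollen [radial_profile()].
#' @export
apply_swell <- function(profile, inc = swell_increment()) {
  if (!inherits(profile, "radial_profile") ||
      !inherits(inc, "swell_increment")) {
    abort("need a radial_profile and a swell_increment",
          "mnswell_validation_error")
  }
  h <- profile_height(profile)
  base_d <- 2 * profile$r[length(profile$r)]
  if (base_d <= 0 && inc$delta_base_diameter > 0) {
    abort("cannot scale radii: base radius is 0", "mnswell_validation_error")
  }
  ax <- (h + inc$delta_height) / h
  rad <- if (base_d > 0) (base_d + inc$delta_base_diameter) / base_d else 1
  out <- radial_profile(profile$x * ax, profile$r * rad,
                        label = paste0(profile$label, " (swollen)"))
  # the needle was inserted before it swelled: remember the height at
  # insertion time so depth scoring can keep the tip at its seated depth
  attr(out, "insertion_height") <- attr(profile, "insertion_height") %||% h
  out
}

#' Scleral/suprachoroidal depth band
#'
#' Depth is measured from the tissue surface (depth 0) downward; the needle
#' is inserted tip-first, so the tip lies deepest and an axial point x (from
#' the tip) sits at depth `(height - uninserted_offset) - x`. The default
#' band is +/- 50 um around the ~500 um suprachoroidal depth at the limbus,
#' and the default 100 um offset reflects the portion of a candlelit needle
#' that remains above the surface after application.
#'
#' @param top_depth shallow edge of the band (um below surface).
#' @param bottom_depth deep edge of the band (um below surface).
#' @param uninserted_offset needle length above the surface (um, >= 0).
#' @export
depth_band <- function(top_depth = 450, bottom_depth = 550,
                       uninserted_offset = 100) {
  check_scalar_nonneg(top_depth, "top_depth")
  check_scalar_pos(bottom_depth, "bottom_depth")
  check_scalar_nonneg(uninserted_offset, "uninserted_offset")
  if (top_depth >= bottom_depth) {
    abort("need 0 <= top_depth < bottom_depth", "mnswell_validation_error")
  }
  structure(list(top_depth = top_depth, bottom_depth = bottom_depth,
                 uninserted_offset = uninserted_offset),
            class = "depth_band")
}

#' Fraction of needle volume lying inside a depth band
#'
#' The score behind the shape comparison: the volume of the needle segment
#' whose tissue depth falls in `[top_depth, bottom_depth]`, divided by the
#' full needle volume. A larger in-band fraction means more swellable
#' polymer sits at the depth where the suprachoroidal space opens.
#'
#' Depth anchoring: an axial point x (measured from the tip) lies at depth
#' `(insertion_height - uninserted_offset) - x`, where `insertion_height`
#' is the needle height at insertion time. For a profile straight from
#' [shape_profile()] or an image this is its own height; for a profile
#' transformed by [apply_swell()] the pre-swell height is carried along, so
#' the tip stays seated at its insertion depth and the swollen needle
#' extends toward (and above) the tissue surface rather than advancing
#' deeper — in-situ swelling cannot drive the tip further through the
#' sclera.
#'
#' @param profile a [radial_profile()].
#' @param band a [depth_band()].
#' @param insertion_height optional explicit needle height at insertion
#'   time (um); defaults to the profile's recorded value, else its height.
#' @return fraction in `[0, 1]`; 0 when the band misses the inserted length.
#' @export
band_volume_fraction <- function(profile, band = depth_band(),
                                 insertion_height = NULL) {
  if (!inherits(profile, "radial_profile") || !inherits(band, "depth_band")) {
    abort("need a radial_profile and a depth_band", "mnswell_validation_error")
  }
  h <- profile_height(profile)
  h_ins <- insertion_height %||% attr(profile, "insertion_height") %||% h
  inserted <- h_ins - band$uninserted_offset
  if (inserted <= 0) return(0)
  # axial interval whose depth lies in [top, bottom], clipped to the needle
  x_lo <- max(inserted - band$bottom_depth, 0)
  x_hi <- min(inserted - band$top_depth, h)
  if (x_hi <= x_lo) return(0)
  revolve_volume(profile, x_lo, x_hi) / revolve_volume(profile)
}

#' Percent volume change between two volumes
#'
#' @param v0 reference volume (> 0).
#' @param vt volume at the later time point.
#' @return `(vt - v0) / v0 * 100`.
#' @export
percent_volume_change <- function(v0, vt) {
  check_scalar_pos(v0, "v0")
  if (!is.numeric(vt) || anyNA(vt)) {
    abort("`vt` must be numeric", "mnswell_validation_error")
  }
  (vt - v0) / v0 * 100
}

#' Pinned default shape set for the three design families
#'
#' The candlelit head radius (177 um) comes from the fabricated head
#' diameter of 354 um; all needles are 900 um high.
#'
#' @return named list of [shape_params()] for candlelit, conical and funnel.
#' @export
default_shapes <- function() {
  list(
    candlelit = shape_params("candlelit", height = 900, head_radius = 177,
                             head_center = 250, shaft_radius = 100),
    conical = shape_params("conical", height = 900, base_radius = 150),
    funnel = shape_params("funnel", height = 900, base_radius = 150,
                          tip_radius = 20)
  )
}

#' Read / write a radial profile as CSV
#'
#' Plain comma-separated files with header `x_um,r_um`, one row per sample.
#'
#' @param path file path.
#' @param label profile label (read only).
#' @return a [radial_profile()] (read) or the path, invisibly (write).
#' @export
read_profile_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("x_um", "r_um") %in% names(d))) {
    abort(sprintf("%s: expected columns x_um,r_um", path),
          "mnswell_parse_error")
  }
  radial_profile(d$x_um, d$r_um, label = label)
}

#' @rdname read_profile_csv
#' @param profile a [radial_profile()] to write.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(x_um = profile$x, r_um = profile$r),
                   path, row.names = FALSE)
  invisible(path)
}
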