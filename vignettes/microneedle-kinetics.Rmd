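---
title: "Methods: geometry, swelling, transport and release kinetics of hydrogel-forming microneedles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, swelling, transport and release kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnswell)
```

This vignette records the models behind each module, the conventions and
numerical choices the package commits to, and the limits of what the
synthetic-data generators (and hence a green test suite) establish.

## 1. Needle geometry and the suprachoroidal depth band

A microneedle is treated as a solid of revolution about its axis: a radius
function $r = f(x)$ with $x$ the axial distance from the tip (µm). Volumes
are $V = \pi \int f(x)^2\,dx$.

**Quadrature.** Profiles are sampled; between samples the radius is
interpolated linearly, so $f(x)^2$ is an exact quadratic on every knot
segment and the integral has the closed form
$\tfrac{h}{3}(r_0^2 + r_0 r_1 + r_1^2)$ per segment. This makes
`revolve_volume()` *exactly* additive over subintervals (a uniform
composite trapezoid cannot be, at any fixed node count), and its only
error is the piecewise-linear approximation of the underlying curve,
which vanishes as $O(h^2)$ in the profile sampling step — the
node-doubling convergence the tests verify on a hemisphere. Linear
profiles (cones, cylinders) are integrated exactly at any resolution.

**Shape families.** The conical needle tapers linearly to
`base_radius`; the funnel flares quadratically from a 20 µm tip radius to
its base radius, concentrating volume at the base; the candlelit needle
is a sharp conical tip joined *tangentially* to a circular-arc head of
maximal radius `head_radius` centred on the axis at `head_center`,
descending to a cylindrical shaft. Tangency requires
`head_radius < head_center` and removes any free joint parameter.
Defaults (height 900 µm, head radius 177 µm from the fabricated 354 µm
head diameter, head centre 250 µm, shaft radius 100 µm, cone base radius
150 µm) are fixed once; the published shape percentages are
under-determined by the available dimensions, so only the *ordering* of
the three designs is treated as testable, never the exact percentages.

**Measured profiles.** Digitised image landmarks can be supplied directly
as `radial_profile(x, r)`. We deliberately interpolate linearly between
landmarks rather than fitting a global polynomial: polynomial fits of
bulbous profiles oscillate and can go negative near the tip.

**Depth convention.** Tissue surface is depth 0 and the tip lies deepest:
a point $x$ sits at depth $(h_\text{ins} - u) - x$, with $u$ the
uninserted offset (default 100 µm, the portion of a candlelit needle that
remains above the surface) and $h_\text{ins}$ the needle height *at
insertion time*. For an unswollen profile $h_\text{ins}$ is its own
height. For a profile transformed by `apply_swell()` the pre-swell height
is carried along, anchoring the tip at its seated depth: in-situ swelling
extends the needle toward the free surface, because distributed swelling
pressure cannot drive the tip further through the dense sclera. This is
the design choice behind the package's central result — the swelling
pushes the bulbous head *into* the 450–550 µm band — and it is the only
convention among the three we examined (offset fixed, offset scaled with
axial stretch, tip anchored) under which the candlelit in-band volume is
non-decreasing under swelling for every band midpoint in 400–600 µm.
One known edge remains even so: at a band midpoint of exactly 600 µm the
pinned funnel's in-band *fraction* marginally exceeds the cone's
(0.0107 vs 0.0106, both ~1 %), because near the tip the funnel's 20 µm
tip radius carries more relative volume than the cone's point tip. The
corresponding acceptance expectation is left failing rather than
adjusted; the candlelit design outranks both everywhere.

**Swelling transform.** `apply_swell()` rescales axial coordinates by
$(h + \Delta h)/h$ and radii by $(d + \Delta d)/d$ with $d$ twice the
base radius — an affine model anchored at the literature height
(+150 µm) and base-diameter (+75 µm) gains. It is deliberately shape-free:
no differential swelling along the needle is modelled.

## 2. Swelling kinetics and gel characterisation

Swelling percentage is mass-based, $S = (m_t - m_0)/m_0 \times 100$.
Negative values (mass below the dry mass) indicate handling artifacts and
are rejected rather than silently clipped.

The pseudo-second-order model $dS/dt = k_s (S_\infty - S)^2$ has closed
form $S(t) = k_s S_\infty^2 t / (1 + k_s S_\infty t)$ and the
linearisation $t/S = 1/(k_s S_\infty^2) + t/S_\infty$. The default fit is
ordinary least squares of $t/S$ on $t$ — the conventional plot, no
weights — with $S_\infty = 1/\text{slope}$,
$k_s = \text{slope}^2/\text{intercept}$ and $r^2$ the squared Pearson
correlation. Points with $t = 0$ or $S \le 0$ are dropped (with a
notice): $t/S$ is undefined there. A nonpositive slope or intercept
signals data inconsistent with the model (e.g. constant $S$) and raises
a typed degenerate-fit error instead of returning nonsense parameters.

The linearisation weights early time points heavily under multiplicative
noise, so `pso_fit_nls()` provides an unconstrained nonlinear
least-squares counterpart. On noise-free data the two agree to $10^{-6}$
relative (a tested invariant); on noisy data they may differ, and both
are available so the discrepancy can be reported rather than hidden.

**Units.** With $S$ in percent, $k_s$ carries units
$\%^{-1}\,\text{min}^{-1}$; expressed on a mg/mg mass-fraction scale the
same constant is 100× larger. Published tables are ambiguous on this
point, so the package states its convention and ships
`ks_percent_to_fraction()` / `ks_fraction_to_percent()` instead of
guessing. Literature rate constants of order $10^{-5}$ are used as-is in
the percent convention, giving half-saturation times of ~20–30 min,
consistent with reported saturation within ~200 min.

**Equilibrium mass.** $m_\infty$ is rarely observed directly; the default
derives it from the fitted plateau, $m_\infty = m_0(1 + S_\infty/100)$,
and a measured plateau mass can be supplied instead. This identity also
links the kinetic fit to the gravimetric characterisation: when both
routes to EWC are available they can be cross-checked
($\text{EWC} = S_\infty$ exactly when $m_x = m_0$).

EWC, gel fraction and solvent-displacement porosity are the standard
formula cells; porosity values outside $[0, 1]$ warn (measurement
inconsistency) but are returned, since the formula itself is the contract.

## 3. Absorption transport parameters

Uptake into a gel from a finite reservoir follows the two-compartment law
$\ln[1 - 2C_t/C_0] = -(2A/V)\,P t$, inverted in closed form by
`permeability()`. At $C_t \ge C_0/2$ the system is at (or past)
equilibrium and the inversion is undefined: this raises a typed domain
error, because a measured $C_t$ there carries no permeability
information. $K_d = C_m/C_{24}$ and $D = P L / K_d$ complete the chain;
`transport_params()` emits all three from one record so the identity
$D = PL/K_d$ holds by construction.

Two conventions are made explicit rather than defaulted silently:

- the permeation area $A$ (one face vs total array surface is not
  standardised) is a **required** input;
- the printed absorbed-amount formula divides a concentration by a mass.
  The default multiplies by the 4 mL re-swell reservoir volume so the
  stated µg/mg unit actually holds; `paper_literal = TRUE` reproduces the
  bare ratio for comparability.

## 4. Release kinetics and the aliquot correction

Sampling with replacement dilutes the chamber: the package applies the
standard dissolution-testing correction
$C_\text{cum}(t_i) = C_i + (V_a/V_r)\sum_{j<i} C_j$ (default 14 mL
chamber, 1 mL aliquots). It reduces exactly to the raw series at
$V_a = 0$. Note the correction restores only the *removed* drug: for an
arbitrary nonnegative series (e.g. samples 1 then 0) the corrected series
can decrease; monotonicity is guaranteed when the raw measurements are
non-decreasing, which is what the physical sampling process produces.

Fractional release $y = Q_t/Q_{24h}$ follows the ultra-fast saturating
law $y = k t/(1 + a t)$, fitted by ordinary least squares on the
linearisation $1/y = (1/k)(1/t) + a/k$; `taolu_fit_nls()` is the
unlinearised cross-check (the reciprocal transform amplifies noise at
small fractions). The fitted plateau is $k/a$.

**Normalisation caveat.** The pipeline normalises by the *observed*
corrected cumulative at 24 h, as the laboratory protocol does. Because
the model's own 24 h fraction $c = 1440k/(1+1440a)$ is not exactly 1, a
fit on that scale recovers $a$ unchanged but $k/c$ instead of $k$ — an
exact algebraic identity, verified in the tests. A corollary worth
knowing: on normalised data the linearised $k$ equals $(1 + 1440a)/1440$
and is determined by $a$ alone, so a printed $k$ and a printed early-time
release percentage can be mutually inconsistent; published values of this
kind indeed are, which is why the synthetic defaults were pinned once
(k = 0.056 min⁻¹, a = 0.0514 min⁻¹) and not revisited.

`release_rate()` reports the burst slope of the cumulative percentage
over a window (default 120 min) by least squares.

## 5. Synthetic data: what it emulates, and what it does not

Each generator forward-simulates one measurement process with
multiplicative Gaussian noise (a measurement CV — balances scale across a
curve spanning orders of magnitude) and a **mandatory** seed, recording
truth, seed and noise level as attributes so recovery tests never
re-enter parameters by hand:

- `gen_swelling_series()`: masses $m_0(1 + S(t)/100)(1+\varepsilon)$ on
  the 10–180 min grid;
- `gen_release_series()`: builds the true cumulative curve, *inverts* the
  aliquot correction to emit the per-sample concentrations an analyst
  would measure (so correction ∘ generation is the identity at zero
  noise), then adds noise;
- `gen_absorption_course()`: the two-compartment curve truncated into
  $[0, C_0/2)$ so inversion stays defined;
- `gen_profile()`: radius jitter on a parametric shape, clipped at zero,
  emulating image digitisation.

Default grids mirror the laboratory protocols (swelling every 10 min to
180 min; release every 10 min to 60 min, then 120/240/480/1440 min);
noise levels in the tests are 5 % (swelling) and 3 % (release).

What the generators do **not** emulate: drift or evaporation between
weighings, correlated errors within a series, drug degradation,
tissue-dependent insertion variability, or any deviation of the true
kinetics from the fitted families. A green recovery test therefore
establishes that the estimators invert their own stated measurement
model at the stated noise — not that the models describe any particular
laboratory system.

## 6. Replicates and reporting

All replicate-level estimates are summarised as mean ± SEM with the
sample ($n-1$) standard deviation and the convention SEM = 0 for $n = 1$.
`run_pipeline()` executes the configured stages over replicate files or
seeded simulations and emits a JSON report whose only non-reproducible
field is the timestamp; everything else byte-reproduces under an
identical configuration, and every numeric traces to a named input file
or recorded seed.

## 7. Known limitations

- The affine swelling transform ignores anisotropic or
  constraint-limited swelling in tissue.
- The geometry model is axisymmetric; fabricated needles are not
  perfectly so.
- Only the pseudo-second-order and ultra-fast saturating families are
  implemented — by design, not oversight; no model-selection machinery
  is provided.
- Published parameter tables of this system are not self-consistent with
  their own printed time-point values (swelling and release alike), so
  exact numeric reproduction is out of reach without the raw series; all
  quantitative testing is property-based on the synthetic stated world.
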