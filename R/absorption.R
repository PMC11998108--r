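# Drug-absorption quantification: absorbed amount per unit array mass and
# the two-compartment mass-transport parameters (permeability, partition
# coefficient, diffusion coefficient).

#' Absorbed drug amount per unit array mass
#'
#' The drug released into the re-swell reservoir is quantified by HPLC as a
#' concentration; the loading per milligram of array is
#' `C * V_res * 1000 / Mx` (ug drug per mg array). Protocols often print
#' the formula as a bare concentration-over-mass ratio `C / Mx`, which is
#' dimensionally a per-volume quantity; `literal = TRUE` reproduces that
#' printed form, the default multiplies by the reservoir volume so the
#' stated ug/mg unit actually holds.
#'
#' @param C_measured measured reservoir concentration (mg/mL).
#' @param V_res re-swell reservoir volume (mL), default 4.
#' @param Mx array mass (mg).
#' @param literal if TRUE return the bare ratio `C_measured / Mx`.
#' @return absorbed amount (ug drug per mg array).
#' @export
absorbed_amount <- function(C_measured, V_res = 4, Mx, literal = FALSE) {
  check_scalar_pos(Mx, "Mx")
  check_scalar_nonneg(C_measured, "C_measured")
  if (literal) return(C_measured / Mx)
  check_scalar_pos(V_res, "V_res")
  C_measured * V_res * 1000 / Mx
}

#' Absorption measurement record
#'
#' Bundles the scalar measurements of one absorption experiment: a gel
#' array immersed in a finite drug reservoir, with uptake following the
#' two-compartment equilibrium law (at equilibrium the absorbed
#' concentration approaches half the initial bulk concentration for equal
#' effective volumes, hence the bound `Ct < C0/2`).
#'
#' @param C0 initial bulk drug concentration (mg/mL).
#' @param Ct drug concentration absorbed into the array at time `t` (mg/mL).
#' @param C24 concentration remaining in the reservoir at 24 h (mg/mL).
#' @param Cm absorbed concentration in the array (mg/mL).
#' @param V drug solution volume (mL).
#' @param A permeation area (cm^2) — the external array surface; no default,
#'   it must be supplied or computed from geometry.
#' @param L array thickness after 24 h (cm).
#' @param t exposure time (s), default 24 h.
#' @param Mx array mass (mg).
#' @param V_res re-swell reservoir volume (mL).
#' @return object of class `absorption_record`.
#' @export
absorption_record <- function(C0, Ct, C24 = NA_real_, Cm = NA_real_,
                              V, A, L = NA_real_, t = 86400,
                              Mx = NA_real_, V_res = 4) {
  check_scalar_pos(C0, "C0")
  check_scalar_nonneg(Ct, "Ct")
  check_scalar_pos(V, "V")
  check_scalar_pos(A, "A")
  check_scalar_pos(t, "t")
  if (Ct >= C0 / 2) {
    abort("Ct must be below C0/2 (two-compartment equilibrium bound)",
          "mnswell_validation_error")
  }
  structure(list(C0 = C0, Ct = Ct, C24 = C24, Cm = Cm, V = V, A = A,
                 L = L, t = t, Mx = Mx, V_res = V_res),
            class = "absorption_record")
}

#' Permeability coefficient from two-compartment uptake
#'
#' Inverts ln(1 - 2 Ct / C0) = -(2 A / V) * P * t:
#' P = -(V / (2 A t)) * ln(1 - 2 Ct / C0). `Ct >= C0/2` means equilibrium
#' was reached (or a measurement error) and the logarithm is undefined; a
#' domain error is raised.
#'
#' @param rec an [absorption_record()], or NULL when the scalar arguments
#'   are given directly.
#' @param Ct,C0,A,V,t scalar overrides (used when `rec` is NULL).
#' @return permeability P (cm/s).
#' @export
permeability <- function(rec = NULL, Ct = rec$Ct, C0 = rec$C0,
                         A = rec$A, V = rec$V, t = rec$t) {
  check_scalar_pos(C0, "C0")
  check_scalar_nonneg(Ct, "Ct")
  check_scalar_pos(A, "A")
  check_scalar_pos(V, "V")
  check_scalar_pos(t, "t")
  if (Ct >= C0 / 2) {
    abort("Ct >= C0/2: two-compartment equilibrium reached, permeability undefined",
          "mnswell_domain_error")
  }
  -(V / (2 * A * t)) * log(1 - 2 * Ct / C0)
}

#' Solute partition coefficient
#'
#' K_d = C_m / C_24: drug concentration inside the gel over the
#' concentration remaining in the reservoir at equilibrium.
#'
#' @param Cm absorbed concentration in the array (mg/mL).
#' @param C24 reservoir concentration at 24 h (mg/mL), > 0.
#' @return dimensionless partition coefficient.
#' @export
partition_coefficient <- function(Cm, C24) {
  check_scalar_nonneg(Cm, "Cm")
  check_scalar_pos(C24, "C24")
  Cm / C24
}

#' Diffusion coefficient from permeability, thickness and partition
#'
#' D = P * L / K_d.
#'
#' @param P permeability (cm/s).
#' @param L array thickness (cm), > 0.
#' @param Kd partition coefficient, > 0.
#' @return diffusion coefficient (cm^2/s).
#' @export
diffusion_coefficient <- function(P, L, Kd) {
  check_scalar_nonneg(P, "P")
  check_scalar_pos(L, "L")
  check_scalar_pos(Kd, "Kd")
  P * L / Kd
}

#' Full transport-parameter bundle from an absorption record
#'
#' Computes P, K_d and D from one record; the identity D = P L / K_d holds
#' by construction.
#'
#' @param rec an [absorption_record()] with `C24`, `Cm` and `L` set.
#' @return object of class `transport_params`: `P` (cm/s), `Kd`, `D`
#'   (cm^2/s).
#' @export
transport_params <- function(rec) {
  if (!inherits(rec, "absorption_record")) {
    abort("`rec` must be an absorption_record", "mnswell_validation_error")
  }
  if (is.na(rec$Cm) || is.na(rec$C24) || is.na(rec$L)) {
    abort("transport_params needs Cm, C24 and L", "mnswell_validation_error")
  }
  P <- permeability(rec)
  Kd <- partition_coefficient(rec$Cm, rec$C24)
  D <- diffusion_coefficient(P, rec$L, Kd)
  structure(list(P = P, Kd = Kd, D = D, L = rec$L),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("<transport_params> P = %.3g cm/s, Kd = %.3g, D = %.3g cm^2/s\n",
              x$P, x$Kd, x$D))
  invisible(x)
}
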