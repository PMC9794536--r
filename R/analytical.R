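#' Equivalent contact radius of two spheres
#'
#' Harmonic combination `R = (1/R_cell + 1/R_tip)^-1` of the cell and
#' indenter tip radii; `R_tip = Inf` recovers the flat-punch limit
#' `R = R_cell`.
#'
#' @param R_cell_um Cell radius, µm (`> 0`).
#' @param R_tip_um Indenter tip radius, µm (`> 0`, may be `Inf`).
#' @return Equivalent radius, µm.
#' @examples
#' equivalent_radius(8, 2.5) # 40/21
#' @export
equivalent_radius <- function(R_cell_um, R_tip_um) {
  if (any(R_cell_um <= 0) || any(R_tip_um <= 0)) {
    abort("Radii must be positive.", class = "cytomech_domain_error")
  }
  1 / (1 / R_cell_um + 1 / R_tip_um)
}

hertz_prefactor <- function(E_MPa, nu, R_eq_um,
                            denominator = c("one_minus_nu_sq", "one_minus_nu")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "one_minus_nu_sq") 1 - nu^2 else 1 - nu
  4 * E_MPa * sqrt(R_eq_um) / (3 * den)
}

#' Hertz spherical-indentation force
#'
#' Elastic contact of a rigid sphere on a deformable sphere:
#' `F = 4 E R^(1/2) delta^(3/2) / (3 (1 - nu^2))`, with `R` the
#' equivalent radius of [equivalent_radius()]. Output in µN
#' (1 MPa·µm² = 1 µN).
#'
#' The `(1 - nu^2)` denominator is the classical Hertz form; the related
#' relaxation expression of [hertz_sls_force()] carries `(1 - nu)`
#' instead, and both are kept as conventionally printed in the AFM
#' indentation literature — `denominator` switches either function to the
#' other convention when a consistent pair is wanted.
#'
#' @param delta_um Indentation depth(s), µm, `>= 0`; vectorised.
#' @param E_MPa Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @param R_eq_um Equivalent radius, µm.
#' @param denominator `"one_minus_nu_sq"` (default here) or
#'   `"one_minus_nu"`.
#' @return Force(s), µN.
#' @examples
#' hertz_force(1.5, E_MPa = 1.28e-3, nu = 0.37, R_eq_um = equivalent_radius(8, 2.5))
#' @export
hertz_force <- function(delta_um, E_MPa, nu, R_eq_um,
                        denominator = c("one_minus_nu_sq", "one_minus_nu")) {
  if (any(delta_um < 0)) {
    abort("`delta_um` must be non-negative.", class = "cytomech_domain_error")
  }
  check_elastic(E_MPa, nu)
  hertz_prefactor(E_MPa, nu, R_eq_um, match.arg(denominator)) * delta_um^1.5
}

#' Hertz-SLS stress-relaxation force
#'
#' Force under a step indentation `delta` held constant, for a
#' standard-linear-solid material:
#' `F(t) = (4 E_R R^(1/2) delta^(3/2)) / (3 (1 - nu)) *
#'   (1 + ((tau_sigma - tau_epsilon)/tau_epsilon) exp(-t/tau_epsilon))`.
#' Relaxes monotonically from `F(0) = F_inf * tau_sigma/tau_epsilon` to
#' `F_inf`.
#'
#' @inheritParams hertz_force
#' @param t_s Time(s) since the step, s, `>= 0`; vectorised (recycled
#'   against `delta_um`).
#' @param E_R_MPa,tau_sigma_s,tau_epsilon_s SLS parameters (see
#'   [sls_derive()]).
#' @param denominator `"one_minus_nu"` (default here, as conventional for
#'   this relaxation form) or `"one_minus_nu_sq"`.
#' @return Force(s), µN.
#' @export
hertz_sls_force <- function(delta_um, t_s, E_R_MPa, tau_sigma_s, tau_epsilon_s,
                            nu, R_eq_um,
                            denominator = c("one_minus_nu", "one_minus_nu_sq")) {
  if (any(delta_um < 0) || any(t_s < 0)) {
    abort("`delta_um` and `t_s` must be non-negative.", class = "cytomech_domain_error")
  }
  pref <- hertz_prefactor(1, nu, R_eq_um, match.arg(denominator))
  pref * delta_um^1.5 * relaxation_modulus(t_s, E_R_MPa, tau_sigma_s, tau_epsilon_s)
}

#' Half-space elastic aspiration length
#'
#' Elastic limit of the half-space micropipette model:
#' `L_p = R_p * phi * dP / (pi * E)`, with punch coefficient
#' `phi ~ 2.1`. Assumes an incompressible half space and infinitesimal
#' strain; see the vignette for the applicability caveats.
#'
#' @param R_p_um Pipette radius, µm.
#' @param dP_MPa Applied suction magnitude, MPa; vectorised.
#' @param E_MPa Young's modulus, MPa (`> 0`).
#' @param phi Punch coefficient (default 2.1).
#' @return Aspirated projection length(s), µm.
#' @examples
#' aspiration_elastic(4, 1e-4, 4.5e-4)
#' @export
aspiration_elastic <- function(R_p_um, dP_MPa, E_MPa, phi = 2.1) {
  if (any(E_MPa <= 0) || any(R_p_um <= 0) || any(phi <= 0)) {
    abort("`E_MPa`, `R_p_um` and `phi` must be positive.", class = "cytomech_domain_error")
  }
  R_p_um * phi * dP_MPa / (pi * E_MPa)
}

#' Half-space aspiration creep (Maxwell SLS form)
#'
#' Creep of the aspirated projection length under a constant pressure
#' step:
#' `L_p(t) = R_p (phi dP / (pi E1)) (1 - (E2/(E1+E2)) exp(-t/tau))`,
#' rising monotonically from `R_p phi dP / (pi (E1+E2))` at `t = 0` to
#' the elastic asymptote `R_p phi dP / (pi E1)`.
#'
#' @inheritParams aspiration_elastic
#' @param t_s Time(s) since the pressure step, s, `>= 0`; vectorised.
#' @param E1_MPa,E2_MPa Spring constants of the Maxwell SLS
#'   representation, MPa (`E1 > 0`, `E2 >= 0`).
#' @param tau_s Characteristic creep time, s (`> 0`).
#' @return Projection length(s), µm.
#' @export
sato_creep <- function(t_s, R_p_um, dP_MPa, E1_MPa, E2_MPa, tau_s, phi = 2.1) {
  if (any(t_s < 0)) {
    abort("`t_s` must be non-negative.", class = "cytomech_domain_error")
  }
  if (any(E1_MPa <= 0) || any(E2_MPa < 0) || any(tau_s <= 0)) {
    abort("Require E1 > 0, E2 >= 0, tau > 0.", class = "cytomech_domain_error")
  }
  R_p_um * phi * dP_MPa / (pi * E1_MPa) *
    (1 - E2_MPa / (E1_MPa + E2_MPa) * exp(-t_s / tau_s))
}
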