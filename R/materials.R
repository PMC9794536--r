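#' Convert linear-elastic parameters to compressible Neo-Hookean parameters
#'
#' Uses the compressible Neo-Hookean convention `C10 = mu/2`, `D1 = 2/K`
#' with shear modulus `mu = E / (2(1 + nu))` and bulk modulus
#' `K = E / (3(1 - 2 nu))`, so that
#' `C10 = E / (4(1 + nu))` and `D1 = 6(1 - 2 nu) / E`.
#' An incompressible material (`nu = 0.5`) is encoded as `D1 = 0`.
#'
#' @param E_MPa Young's modulus in MPa; vectorised.
#' @param nu Poisson's ratio, in `(-1, 0.5]`; vectorised.
#' @return A tibble with columns `C10_MPa`, `D1_perMPa` and a logical
#'   `incompressible` flag (`TRUE` where `nu == 0.5`).
#' @examples
#' elastic_to_neohookean(1.28e-2, 0.3) # cell membrane
#' @export
elastic_to_neohookean <- function(E_MPa, nu) {
  check_elastic(E_MPa, nu, allow_incompressible = TRUE)
  tibble(
    C10_MPa = E_MPa / (4 * (1 + nu)),
    D1_perMPa = 6 * (1 - 2 * nu) / E_MPa,
    incompressible = nu == 0.5
  )
}

#' Convert Neo-Hookean parameters back to linear-elastic parameters
#'
#' Exact inverse of [elastic_to_neohookean()]. `D1 = 0` maps to
#' `nu = 0.5` exactly (incompressible), with `E = 6 C10`.
#'
#' @param C10_MPa Shear-like Neo-Hookean coefficient in MPa; vectorised.
#' @param D1_perMPa Compressibility coefficient in 1/MPa (`>= 0`); vectorised.
#' @return A tibble with columns `E_MPa` and `nu`.
#' @export
neohookean_to_elastic <- function(C10_MPa, D1_perMPa) {
  if (any(!is.finite(C10_MPa) | C10_MPa <= 0)) {
    abort("`C10_MPa` must be positive and finite.", class = "cytomech_invalid_parameter")
  }
  if (any(!is.finite(D1_perMPa) | D1_perMPa < 0)) {
    abort("`D1_perMPa` must be non-negative and finite.", class = "cytomech_invalid_parameter")
  }
  # mu = 2 C10, K = 2 / D1; nu = (3K - 2mu) / (2(3K + mu))
  x <- C10_MPa * D1_perMPa # = 3(1 - 2 nu) / (2 (1 + nu))
  nu <- (3 - 2 * x) / (2 * x + 6)
  tibble(E_MPa = 4 * C10_MPa * (1 + nu), nu = nu)
}

#' Derived standard-linear-solid moduli
#'
#' From the relaxed modulus `E_R` (the lone spring `k1`) and the two
#' relaxation times, computes the instantaneous modulus
#' `E0 = E_R (1 + (tau_sigma - tau_epsilon)/tau_epsilon) = E_R tau_sigma/tau_epsilon`,
#' the long-term modulus `E_inf`, the Maxwell-arm spring
#' `k2 = E_R (tau_sigma/tau_epsilon - 1)` and its dashpot
#' `eta = k2 tau_epsilon` (MPa·s).
#'
#' Two conventions for `E_inf` are offered. The default, `"as_printed"`,
#' is `E_inf = E_R (1 + nu)`, the indentation-literature form this package
#' follows; `"shear_consistent"` returns `E_inf = E_R` (the spring that
#' remains after the Maxwell arm relaxes). The `(1 + nu)` factor mixes
#' Poisson's ratio into a time-domain modulus and is kept verbatim for
#' comparability; see the package vignette.
#'
#' @param E_R_MPa Relaxed modulus in MPa (`> 0`).
#' @param tau_sigma_s Relaxation time under constant load, s.
#' @param tau_epsilon_s Relaxation time under constant deformation, s;
#'   requires `tau_sigma_s >= tau_epsilon_s > 0`.
#' @param nu Poisson's ratio (enters `E_inf` only, in the default convention).
#' @param einf_convention `"as_printed"` (default) or `"shear_consistent"`.
#' @return One-row tibble: `E0_MPa`, `Einf_MPa`, `k2_MPa`, `eta_MPa_s`.
#' @examples
#' sls_derive(4.5e-4, 19.7, 9.5, nu = 0.37)
#' @export
sls_derive <- function(E_R_MPa, tau_sigma_s, tau_epsilon_s, nu,
                       einf_convention = c("as_printed", "shear_consistent")) {
  einf_convention <- match.arg(einf_convention)
  check_sls(E_R_MPa, tau_sigma_s, tau_epsilon_s)
  k2 <- E_R_MPa * (tau_sigma_s / tau_epsilon_s - 1)
  tibble(
    E0_MPa = E_R_MPa * tau_sigma_s / tau_epsilon_s,
    Einf_MPa = if (einf_convention == "as_printed") E_R_MPa * (1 + nu) else E_R_MPa,
    k2_MPa = k2,
    eta_MPa_s = k2 * tau_epsilon_s
  )
}

#' Standard-linear-solid relaxation modulus
#'
#' `E(t) = E_R (1 + ((tau_sigma - tau_epsilon)/tau_epsilon) exp(-t/tau_epsilon))`.
#' Decays monotonically from `E0 = E_R tau_sigma/tau_epsilon` at `t = 0`
#' to `E_R` as `t -> Inf`.
#'
#' @param t_s Time(s) in seconds, `>= 0`; vectorised.
#' @inheritParams sls_derive
#' @return Numeric vector of moduli, MPa.
#' @export
relaxation_modulus <- function(t_s, E_R_MPa, tau_sigma_s, tau_epsilon_s) {
  check_sls(E_R_MPa, tau_sigma_s, tau_epsilon_s)
  if (any(t_s < 0)) {
    abort("`t_s` must be non-negative.", class = "cytomech_domain_error")
  }
  E_R_MPa * (1 + (tau_sigma_s - tau_epsilon_s) / tau_epsilon_s * exp(-t_s / tau_epsilon_s))
}

#' Ratio of two elastic moduli
#'
#' The stiffness ratio `Q = E1 / E2` used to generate stiffer/softer cell
#' variants; for the bundled cell types 1 and 2 the cytoplasm ratio is
#' 1.28e-3 / 1.00e-4 = 12.8 (printed as 12.78 from unrounded inputs).
#'
#' @param E1_MPa,E2_MPa Young's moduli in MPa; `E2_MPa` must be nonzero.
#' @return The dimensionless ratio.
#' @export
q_ratio <- function(E1_MPa, E2_MPa) {
  if (any(E2_MPa == 0)) {
    abort("`E2_MPa` must be nonzero.", class = "cytomech_domain_error")
  }
  E1_MPa / E2_MPa
}

subcomponent_roles <- c("cytoplasm", "microtubule", "microfilament", "membrane", "nucleus")

#' Assemble a cell material set
#'
#' Builds a validated `cell_materials` tibble: one row per subcomponent
#' role (cytoplasm, microtubule, microfilament, membrane, nucleus) with
#' elastic parameters, Neo-Hookean parameters re-derived from them, and
#' (for the cytoplasm) the SLS triplet.
#'
#' @param df A data frame with columns `role`, `E_MPa`, `nu` and optionally
#'   `E_R_MPa`, `tau_sigma_s`, `tau_epsilon_s` (NA where absent).
#' @param label Free-text label carried in the `label` attribute.
#' @return A `cell_materials` tibble with columns `role`, `E_MPa`, `nu`,
#'   `C10_MPa`, `D1_perMPa`, `E_R_MPa`, `tau_sigma_s`, `tau_epsilon_s`.
#' @export
cell_materials <- function(df, label = "custom") {
  df <- as_tibble(df)
  missing_roles <- setdiff(subcomponent_roles, df$role)
  if (length(missing_roles) > 0) {
    abort(paste0("Missing subcomponent role(s): ", paste(missing_roles, collapse = ", ")),
      class = "cytomech_config_error"
    )
  }
  unknown <- setdiff(df$role, subcomponent_roles)
  if (length(unknown) > 0) {
    abort(paste0("Unknown subcomponent role(s): ", paste(unknown, collapse = ", ")),
      class = "cytomech_config_error"
    )
  }
  for (col in c("E_R_MPa", "tau_sigma_s", "tau_epsilon_s")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  nh <- elastic_to_neohookean(df$E_MPa, df$nu)
  out <- df |>
    mutate(C10_MPa = nh$C10_MPa, D1_perMPa = nh$D1_perMPa) |>
    select(all_of(c(
      "role", "E_MPa", "nu", "C10_MPa", "D1_perMPa",
      "E_R_MPa", "tau_sigma_s", "tau_epsilon_s"
    ))) |>
    arrange(match(.data$role, subcomponent_roles))
  attr(out, "label") <- label
  class(out) <- c("cell_materials", class(out))
  out
}

#' Reference material sets for cell types 1 and 2
#'
#' The two bundled chondrocyte-like parameter sets. Cell type 2 has a
#' cytoplasm one order of magnitude softer (ratio 12.8) and proportionally
#' softer subcomponents. Only the cytoplasm carries a viscoelastic (SLS)
#' description; the cytoskeletal fibres, membrane and nucleus are elastic.
#' Neo-Hookean columns are derived from `(E, nu)` by
#' [elastic_to_neohookean()].
#'
#' @return A `cell_materials` tibble (see [cell_materials()]).
#' @examples
#' cell_type_1()
#' @export
cell_type_1 <- function() {
  cell_materials(
    tibble(
      role = subcomponent_roles,
      E_MPa = c(1.28e-3, 1.53e4, 3.32e4, 1.28e-2, 5.11e-3),
      nu = c(0.37, 0.38, 0.38, 0.30, 0.37),
      E_R_MPa = c(4.50e-4, NA, NA, NA, NA),
      tau_sigma_s = c(19.7, NA, NA, NA, NA),
      tau_epsilon_s = c(9.5, NA, NA, NA, NA)
    ),
    label = "cell type 1"
  )
}

#' @rdname cell_type_1
#' @export
cell_type_2 <- function() {
  cell_materials(
    tibble(
      role = subcomponent_roles,
      E_MPa = c(1.00e-4, 1.20e3, 2.60e3, 1.00e-3, 4.00e-4),
      nu = c(0.37, 0.38, 0.38, 0.30, 0.37),
      E_R_MPa = c(4.50e-4, NA, NA, NA, NA),
      tau_sigma_s = c(19.7, NA, NA, NA, NA),
      tau_epsilon_s = c(9.5, NA, NA, NA, NA)
    ),
    label = "cell type 2"
  )
}

#' Scale a material set by a stiffness ratio Q
#'
#' Multiplies (`mode = "stiffer"`) or divides (`mode = "softer"`) the
#' Young's modulus of every subcomponent not listed in `fix` by `Q`, and
#' re-derives the Neo-Hookean parameters from the scaled moduli. Fixing the
#' cytoplasm while scaling everything else isolates the cytoskeletal (plus
#' membrane/nucleus) contribution to the whole-cell response; scaling with
#' `Q = 12.8` maps the cell-type-2 cytoskeleton onto cell type 1's.
#'
#' @param materials A `cell_materials` tibble.
#' @param Q Positive scaling ratio (the bundled cell types give 12.8;
#'   the conventionally quoted value is 12.78).
#' @param mode `"stiffer"` (multiply) or `"softer"` (divide).
#' @param fix Character vector of roles left untouched (default
#'   `"cytoplasm"`).
#' @return A new `cell_materials` tibble, label suffixed with the scaling.
#' @examples
#' scale_materials(cell_type_1(), Q = 12.78, mode = "stiffer")
#' @export
scale_materials <- function(materials, Q, mode = c("stiffer", "softer"),
                            fix = "cytoplasm") {
  mode <- match.arg(mode)
  stopifnot(inherits(materials, "cell_materials"))
  if (!is.numeric(Q) || length(Q) != 1 || Q <= 0) {
    abort("`Q` must be a single positive number.", class = "cytomech_config_error")
  }
  unknown <- setdiff(fix, subcomponent_roles)
  if (length(unknown) > 0) {
    abort(paste0("Unknown role(s) in `fix`: ", paste(unknown, collapse = ", ")),
      class = "cytomech_config_error"
    )
  }
  fac <- if (mode == "stiffer") Q else 1 / Q
  df <- as_tibble(materials) |>
    mutate(E_MPa = ifelse(.data$role %in% fix, .data$E_MPa, .data$E_MPa * fac))
  cell_materials(df,
    label = sprintf(
      "%s %s Q=%g (fixed: %s)", attr(materials, "label"),
      if (mode == "stiffer") "x" else "/", Q, paste(fix, collapse = ",")
    )
  )
}

#' @export
print.cell_materials <- function(x, ...) {
  cat("<cell_materials> ", attr(x, "label"), "\n", sep = "")
  NextMethod()
}

# -- validation helpers --------------------------------------------------

check_elastic <- function(E_MPa, nu, allow_incompressible = FALSE) {
  nu_hi <- if (allow_incompressible) 0.5 else 0.5 - .Machine$double.eps
  bad <- !is.finite(E_MPa) | E_MPa <= 0 | !is.finite(nu) | nu <= -1 |
    (if (allow_incompressible) nu > 0.5 else nu >= 0.5)
  if (any(bad)) {
    abort("Elastic parameters require E > 0 and -1 < nu <= 0.5 (nu = 0.5 only where incompressibility is representable).",
      class = "cytomech_invalid_parameter"
    )
  }
  invisible(TRUE)
}

check_sls <- function(E_R_MPa, tau_sigma_s, tau_epsilon_s) {
  bad <- !is.finite(E_R_MPa) | E_R_MPa <= 0 |
    !is.finite(tau_sigma_s) | !is.finite(tau_epsilon_s) |
    tau_epsilon_s <= 0 | tau_sigma_s < tau_epsilon_s
  if (any(bad)) {
    abort("SLS parameters require E_R > 0 and tau_sigma >= tau_epsilon > 0.",
      class = "cytomech_invalid_parameter"
    )
  }
  invisible(TRUE)
}
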