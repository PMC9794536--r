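#' Cell model: continuum (CM) or continuum-tensegrity (CTM)
#'
#' Bundles materials, gross geometry and (for the CTM) the prestressed
#' tensegrity cytoskeleton. The CM responds through the analytical
#' continuum models alone; the CTM adds the cytoskeletal structural
#' response in parallel (force-additive at matched displacement).
#'
#' @param variant `"CM"` or `"CTM"`.
#' @param materials A `cell_materials` tibble (default [cell_type_1()]).
#' @param geometry A `cell_geometry` row (default [cell_geometry()]).
#' @param cytoskeleton A prestressed `tensegrity`; if `NULL` and
#'   `variant = "CTM"`, one is built from the geometry's radius and the
#'   microtubule/microfilament moduli of `materials`, in `orientation`,
#'   and prestressed at `cable_prestrain`.
#' @param orientation Passed to [build_tensegrity()] when the
#'   cytoskeleton is auto-built.
#' @param cable_prestrain Passed to [apply_prestress()] likewise.
#' @param coupling Only `"parallel"` is implemented.
#' @return A `cell_model` object.
#' @examples
#' cm <- cell_model("CM")
#' ctm <- cell_model("CTM")
#' @export
cell_model <- function(variant = c("CM", "CTM"),
                       materials = cell_type_1(),
                       geometry = cell_geometry(),
                       cytoskeleton = NULL,
                       orientation = "config1",
                       cable_prestrain = 0.01,
                       coupling = "parallel") {
  variant <- match.arg(variant)
  coupling <- match.arg(coupling, "parallel")
  stopifnot(inherits(materials, "cell_materials"))
  if (variant == "CTM" && is.null(cytoskeleton)) {
    mt <- materials$E_MPa[materials$role == "microtubule"]
    mf <- materials$E_MPa[materials$role == "microfilament"]
    cytoskeleton <- build_tensegrity(
      R_cell_um = geometry$R_cell_um, orientation = orientation,
      E_strut_MPa = mt, E_cable_MPa = mf
    )
    cytoskeleton <- apply_prestress(cytoskeleton, cable_prestrain = cable_prestrain)
  }
  if (variant == "CTM" && is.null(cytoskeleton)) {
    abort("A CTM requires a cytoskeleton.", class = "cytomech_config_error")
  }
  structure(
    list(
      variant = variant, materials = materials, geometry = geometry,
      cytoskeleton = cytoskeleton, coupling = coupling
    ),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> %s | %s | R_cell = %g um%s\n",
    x$variant, attr(x$materials, "label"), x$geometry$R_cell_um,
    if (!is.null(x$cytoskeleton)) {
      paste0(" | cytoskeleton ", attr(x$cytoskeleton, "orientation"))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' AFM indent-and-hold loading protocol
#'
#' Constant-velocity approach to a target depth followed by a hold at
#' fixed depth (stress relaxation). Defaults mirror common
#' chondrocyte-AFM practice: 9.5 µm/s approach, 1.5 µm depth, 60 s hold.
#'
#' @param speed_um_s Approach velocity, µm/s.
#' @param depth_um Target indentation depth, µm.
#' @param hold_s Hold duration, s.
#' @param R_tip_um Indenter tip radius, µm (default 2.5).
#' @param dt_s Output sampling interval during the hold, s.
#' @param n_ramp Output samples across the loading ramp.
#' @return A `loading_protocol` list with `kind = "afm"`.
#' @export
afm_protocol <- function(speed_um_s = 9.5, depth_um = 1.5, hold_s = 60,
                         R_tip_um = 2.5, dt_s = 0.1, n_ramp = 50) {
  stopifnot(speed_um_s > 0, depth_um > 0, hold_s >= 0, dt_s > 0, R_tip_um > 0)
  structure(
    list(
      kind = "afm", speed_um_s = speed_um_s, depth_um = depth_um,
      hold_s = hold_s, R_tip_um = R_tip_um, dt_s = dt_s, n_ramp = n_ramp
    ),
    class = "loading_protocol"
  )
}

#' MPA step-and-creep loading protocol
#'
#' Pressure ramped linearly over `ramp_s` (1 s default) then held
#' constant while the aspirated length creeps, for `hold_s`.
#'
#' @param dP_MPa Suction magnitude, MPa (default 1e-4 MPa = 100 Pa).
#' @param ramp_s Pressure ramp duration, s; `0` gives an ideal step.
#' @param hold_s Creep duration after the ramp, s.
#' @param ratio Cell-to-pipette diameter ratio `D_c/D_p` (equals the
#'   radius ratio); sets `R_p = R_cell / ratio`.
#' @param dt_s Output sampling interval, s.
#' @return A `loading_protocol` list with `kind = "mpa"`.
#' @export
mpa_protocol <- function(dP_MPa = 1e-4, ramp_s = 1, hold_s = 60,
                         ratio = 2, dt_s = 0.1) {
  stopifnot(dP_MPa > 0, ramp_s >= 0, hold_s > 0, ratio > 1, dt_s > 0)
  structure(
    list(
      kind = "mpa", dP_MPa = dP_MPa, ramp_s = ramp_s, hold_s = hold_s,
      ratio = ratio, dt_s = dt_s
    ),
    class = "loading_protocol"
  )
}

# hereditary (convolution) force for a ramp-and-hold indentation of an
# SLS half-space: F(t) = pref * int_0^t E(t-s) d[delta(s)^(3/2)]
hereditary_afm_force <- function(t, speed, depth, E_R, tau_sigma, tau_epsilon,
                                 nu, R_eq, denominator = "one_minus_nu",
                                 quad_step = NULL) {
  t_ramp <- depth / speed
  pref <- hertz_prefactor(1, nu, R_eq, denominator)
  h <- quad_step %||% (t_ramp / 400)
  edges <- seq(0, t_ramp, by = h)
  if (tail(edges, 1) < t_ramp) edges <- c(edges, t_ramp)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  dg <- diff((speed * edges)^1.5)
  vapply(t, function(tt) {
    if (tt <= 0) {
      return(0)
    }
    if (tt >= t_ramp) {
      sum(relaxation_modulus(tt - mids, E_R, tau_sigma, tau_epsilon) * dg) * pref
    } else {
      e2 <- edges[edges < tt]
      e2 <- c(e2, tt)
      m2 <- (head(e2, -1) + tail(e2, -1)) / 2
      dg2 <- diff((speed * e2)^1.5)
      sum(relaxation_modulus(tt - m2, E_R, tau_sigma, tau_epsilon) * dg2) * pref
    }
  }, numeric(1))
}

#' Simulate an AFM indent-and-hold experiment
#'
#' Quasi-static force response of the cell to a constant-velocity ramp to
#' `depth_um` followed by a hold. The continuum (cytoplasm) contribution
#' is the hereditary integral
#' `F(t) = (4 sqrt(R) / (3(1 - nu))) * int_0^t E(t - s) d[delta(s)^(3/2)]`
#' with the SLS relaxation modulus of [relaxation_modulus()]; for an
#' ideal step it reduces to [hertz_sls_force()], and at these loading
#' rates (ramp time well below `tau_epsilon`) its hold phase tracks the
#' step solution closely. For a CTM, the cytoskeletal reaction from
#' [indentation_sweep()] at the instantaneous depth is added in parallel
#' (the cytoskeleton is elastic, so its term is constant during the
#' hold).
#'
#' @param model A `cell_model`.
#' @param protocol An [afm_protocol()].
#' @param denominator Denominator convention of the continuum prefactor
#'   (see [hertz_force()]).
#' @param sweep_steps Depth samples for the CTM cytoskeleton sweep.
#' @return A `cyto_curve` tibble: `t_s`, `delta_um`, `F_nN`.
#' @export
simulate_afm <- function(model, protocol = afm_protocol(),
                         denominator = "one_minus_nu", sweep_steps = 50) {
  stopifnot(inherits(model, "cell_model"), protocol$kind == "afm")
  cy <- model$materials[model$materials$role == "cytoplasm", ]
  if (!is.finite(cy$E_R_MPa)) {
    abort("Cytoplasm must carry SLS parameters for an AFM simulation.",
      class = "cytomech_config_error"
    )
  }
  R_eq <- equivalent_radius(model$geometry$R_cell_um, protocol$R_tip_um)
  t_ramp <- protocol$depth_um / protocol$speed_um_s
  t <- unique(sort(c(
    seq(0, t_ramp, length.out = protocol$n_ramp + 1),
    seq(t_ramp, t_ramp + protocol$hold_s, by = protocol$dt_s),
    t_ramp + protocol$hold_s
  )))
  delta <- pmin(protocol$speed_um_s * t, protocol$depth_um)
  quad <- t_ramp / max(400, 4 * ceiling(t_ramp / protocol$dt_s))
  F_uN <- hereditary_afm_force(
    t, protocol$speed_um_s, protocol$depth_um,
    cy$E_R_MPa, cy$tau_sigma_s, cy$tau_epsilon_s, cy$nu, R_eq,
    denominator = denominator, quad_step = quad
  )
  meta <- list(
    kind = "afm", model = model$variant,
    materials = attr(model$materials, "label"),
    R_tip_um = protocol$R_tip_um, speed_um_s = protocol$speed_um_s,
    depth_um = protocol$depth_um, hold_s = protocol$hold_s,
    denominator = denominator, coupling = NULL
  )
  if (model$variant == "CTM") {
    sweep <- indentation_sweep(model$cytoskeleton, protocol$depth_um,
      n_steps = sweep_steps
    )
    F_csk_uN <- approx(sweep$delta_um, sweep$force_nN / 1e3, xout = delta)$y
    F_uN <- F_uN + F_csk_uN
    meta$coupling <- model$coupling
    meta$orientation <- attr(model$cytoskeleton, "orientation")
    meta$cable_prestrain <- attr(model$cytoskeleton, "cable_prestrain")
  }
  new_curve(tibble(t_s = t, delta_um = delta, F_nN = F_uN * 1e3), meta)
}

#' Simulate a micropipette step-and-creep experiment
#'
#' Aspirated projection length under a pressure ramp (default 1 s) and
#' hold. The continuum response is the half-space creep solution
#' propagated through the ramp by Boltzmann superposition (evaluated in
#' closed form); `ramp_s = 0` reproduces [sato_creep()] exactly. The SLS
#' cytoplasm maps onto the Maxwell-form creep springs as `E1 = E_R`,
#' `E2 = k2` and `tau = tau_sigma` by default (overridable via `E1_MPa`,
#' `E2_MPa`, `tau_s`).
#'
#' For a CTM, the cytoskeleton is loaded through [aspiration_load()] and
#' [solve_static()]; its secant axial stiffness at the aspirated pole is
#' combined with the continuum secant stiffness as parallel compliances,
#' which always reduces the aspirated length. If no node falls inside the
#' pipette the cytoskeletal term is zero (with a warning) and the CTM
#' coincides with the CM.
#'
#' @param model A `cell_model`.
#' @param protocol An [mpa_protocol()].
#' @param phi Punch coefficient (default 2.1).
#' @param E1_MPa,E2_MPa,tau_s Optional overrides of the SLS-to-creep
#'   parameter mapping.
#' @return A `cyto_curve` tibble: `t_s`, `dP_MPa`, `Lp_um`; metadata
#'   records `ratio`, mapping and (for CTM) the cytoskeletal stiffness.
#' @export
simulate_mpa <- function(model, protocol = mpa_protocol(), phi = 2.1,
                         E1_MPa = NULL, E2_MPa = NULL, tau_s = NULL) {
  stopifnot(inherits(model, "cell_model"), protocol$kind == "mpa")
  R_cell <- model$geometry$R_cell_um
  R_p <- R_cell / protocol$ratio
  if (R_p >= R_cell) {
    abort("Pipette radius must be below the cell radius.", class = "cytomech_config_error")
  }
  cy <- model$materials[model$materials$role == "cytoplasm", ]
  if (is.null(E1_MPa)) {
    if (!is.finite(cy$E_R_MPa)) {
      abort("Cytoplasm must carry SLS parameters (or pass E1/E2/tau).",
        class = "cytomech_config_error"
      )
    }
    drv <- sls_derive(cy$E_R_MPa, cy$tau_sigma_s, cy$tau_epsilon_s, cy$nu)
    E1_MPa <- cy$E_R_MPa
    E2_MPa <- drv$k2_MPa
    tau_s <- cy$tau_sigma_s
  }
  t <- unique(sort(c(
    seq(0, protocol$ramp_s + protocol$hold_s, by = protocol$dt_s),
    protocol$ramp_s, protocol$ramp_s + protocol$hold_s
  )))
  Lp <- ramped_creep(
    t, protocol$ramp_s, R_p, protocol$dP_MPa,
    E1_MPa, E2_MPa, tau_s, phi
  )
  dP_t <- protocol$dP_MPa * if (protocol$ramp_s > 0) pmin(t / protocol$ramp_s, 1) else rep(1, length(t))
  meta <- list(
    kind = "mpa", model = model$variant,
    materials = attr(model$materials, "label"),
    ratio = protocol$ratio, R_p_um = R_p, dP_MPa = protocol$dP_MPa,
    phi = phi, E1_MPa = E1_MPa, E2_MPa = E2_MPa, tau_s = tau_s,
    sls_mapping = "E1=E_R, E2=k2, tau=tau_sigma",
    halfspace_assumptions = "incompressible, infinitesimal-strain"
  )
  if (model$variant == "CTM") {
    k_cs <- cytoskeleton_aspiration_stiffness(
      model$cytoskeleton, R_p, protocol$dP_MPa
    )
    F_tot <- protocol$dP_MPa * pi * R_p^2
    # parallel compliances at matched load: 1/L = 1/L_cm + k_cs/F
    pos <- Lp > 0
    Lp[pos] <- Lp[pos] / (1 + k_cs * Lp[pos] / F_tot)
    meta$coupling <- model$coupling
    meta$orientation <- attr(model$cytoskeleton, "orientation")
    meta$k_cytoskeleton_uN_per_um <- k_cs
  }
  new_curve(tibble(t_s = t, dP_MPa = dP_t, Lp_um = Lp), meta)
}

# closed-form Boltzmann superposition of the half-space creep response
# over a linear pressure ramp of duration t_r
ramped_creep <- function(t, t_r, R_p, dP, E1, E2, tau, phi) {
  C <- R_p * phi * dP / (pi * E1)
  r <- E2 / (E1 + E2)
  if (t_r <= 0) {
    return(sato_creep(t, R_p, dP, E1, E2, tau, phi))
  }
  out <- numeric(length(t))
  early <- t <= t_r
  out[early] <- C / t_r * (t[early] - r * tau * (1 - exp(-t[early] / tau)))
  late <- !early
  out[late] <- C * (1 - r * exp(-t[late] / tau) * tau / t_r * (exp(t_r / tau) - 1))
  out
}

# secant axial stiffness (uN/um) of the aspirated pole nodes
cytoskeleton_aspiration_stiffness <- function(csk, R_p_um, dP_MPa,
                                              settings = solver_settings()) {
  bc <- aspiration_load(csk, R_p_um, dP_MPa)
  if (attr(bc, "n_inside") == 0) {
    return(0)
  }
  sol <- solve_static(csk, bc, settings)
  loaded <- bc$loads$node
  w <- mean(sol$nodes$uz_um[match(loaded, sol$nodes$node)])
  if (w <= 0) {
    return(0)
  }
  attr(bc, "total_load_uN") / w
}

#' Aspiration response across pipette-size ratios
#'
#' Runs [simulate_mpa()] for each cell-to-pipette diameter ratio and
#' stacks the curves, with the aspirated length also normalised by the
#' pipette radius or by the cell radius (the latter eases comparison when
#' pipette size varies). For the pure half-space CM, `Lp/R_p` at fixed
#' pressure is identical across ratios (the model has no size effect);
#' cytoskeletal size effects make the CTM deviate.
#'
#' @param model A `cell_model`.
#' @param ratios Diameter ratios `D_c/D_p` (default 1.5, 2, 3, 4, 5.5).
#' @param protocol A template [mpa_protocol()]; its `ratio` field is
#'   replaced per run.
#' @param normalize `"Rp"` or `"Rcell"`: which radius scales the
#'   `Lp_norm` column.
#' @param quiet Suppress empty-load warnings for ratios whose pipette
#'   captures no cytoskeletal node (default `TRUE`).
#' @return A tibble: `ratio`, `t_s`, `dP_MPa`, `Lp_um`, `Lp_norm`.
#' @export
sweep_ratios <- function(model, ratios = c(1.5, 2, 3, 4, 5.5),
                         protocol = mpa_protocol(),
                         normalize = c("Rp", "Rcell"), quiet = TRUE) {
  normalize <- match.arg(normalize)
  stopifnot(all(ratios > 1))
  R_cell <- model$geometry$R_cell_um
  purrr::map(ratios, function(rat) {
    p <- protocol
    p$ratio <- rat
    run <- function() simulate_mpa(model, p)
    cv <- if (quiet) {
      withCallingHandlers(run(), cytomech_empty_load = function(w) {
        invokeRestart("muffleWarning")
      })
    } else {
      run()
    }
    scale <- if (normalize == "Rp") R_cell / rat else R_cell
    mutate(as_tibble(cv), ratio = rat, Lp_norm = .data$Lp_um / scale, .before = 1)
  }) |> list_rbind()
}
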