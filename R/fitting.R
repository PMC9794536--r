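#' Generate a synthetic experiment curve
#'
#' Seeded fixture generator for the inverse problems: evaluates one of
#' the closed-form models on a regular grid and applies multiplicative
#' Gaussian noise `signal * (1 + N(0, sd))`. Deterministic given `seed`;
#' `noise_sd = 0` returns the closed form exactly.
#'
#' @param model_kind `"hertz"` (loading F-delta), `"hertz_sls"`
#'   (relaxation F-t at fixed depth) or `"sato"` (creep Lp-t).
#' @param params Named list of model parameters:
#'   * hertz: `E_MPa`, `nu`, `R_eq_um`;
#'   * hertz_sls: `E_R_MPa`, `tau_sigma_s`, `tau_epsilon_s`, `nu`,
#'     `R_eq_um`, `delta_um`;
#'   * sato: `E1_MPa`, `E2_MPa`, `tau_s`, `R_p_um`, `dP_MPa`, and
#'     optionally `phi` (default 2.1).
#' @param protocol Named list: `n` (samples, default 600) and `depth_um`
#'   (hertz, default 1.5) or `hold_s` (the time models, default 60).
#' @param noise_sd Relative noise standard deviation (default 0).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A `cyto_curve` tibble with the model's natural columns and
#'   metadata recording the generator, parameters, noise and seed.
#' @examples
#' generate_synthetic_curve(
#'   "sato",
#'   list(E1_MPa = 4.5e-4, E2_MPa = 4.8e-4, tau_s = 10, R_p_um = 4, dP_MPa = 1e-4),
#'   noise_sd = 0.05, seed = 1
#' )
#' @export
generate_synthetic_curve <- function(model_kind = c("hertz", "hertz_sls", "sato"),
                                     params, protocol = list(),
                                     noise_sd = 0, seed = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed)) {
    abort("A `seed` is required when `noise_sd > 0`.", class = "cytomech_config_error")
  }
  n <- protocol$n %||% 600
  df <- switch(model_kind,
    hertz = {
      depth <- protocol$depth_um %||% 1.5
      delta <- seq(0, depth, length.out = n)
      tibble(delta_um = delta, F_nN = 1e3 * hertz_force(
        delta, params$E_MPa, params$nu, params$R_eq_um
      ))
    },
    hertz_sls = {
      hold <- protocol$hold_s %||% 60
      t <- seq(0, hold, length.out = n)
      tibble(t_s = t, F_nN = 1e3 * hertz_sls_force(
        params$delta_um, t, params$E_R_MPa, params$tau_sigma_s,
        params$tau_epsilon_s, params$nu, params$R_eq_um
      ))
    },
    sato = {
      hold <- protocol$hold_s %||% 60
      t <- seq(0, hold, length.out = n)
      tibble(t_s = t, Lp_um = sato_creep(
        t, params$R_p_um, params$dP_MPa, params$E1_MPa, params$E2_MPa,
        params$tau_s, params$phi %||% 2.1
      ))
    }
  )
  signal <- names(df)[2]
  if (noise_sd > 0) {
    eps <- withr::with_seed(seed, rnorm(nrow(df), 0, noise_sd))
    df[[signal]] <- df[[signal]] * (1 + eps)
  }
  new_curve(df, meta = c(
    list(kind = "synthetic", generator = model_kind),
    params,
    list(noise_sd = noise_sd, seed = seed)
  ))
}

new_fit <- function(model_kind, parameters, curve, fitted, converged,
                    extra = list()) {
  obs <- curve[[setdiff(names(curve), c("t_s", "delta_um", "dP_MPa"))[1]]]
  resid <- obs - fitted
  structure(
    c(
      list(
        model_kind = model_kind, parameters = parameters,
        data = curve, fitted = fitted,
        residual_norm = sqrt(sum(resid^2)), n_points = length(obs),
        converged = converged,
        noise_sd = curve_meta(curve)$noise_sd, seed = curve_meta(curve)$seed
      ),
      extra
    ),
    class = "cyto_fit"
  )
}

#' @export
print.cyto_fit <- function(x, ...) {
  cat(sprintf(
    "<cyto_fit> %s | n = %d | converged: %s | residual norm %.4g\n",
    x$model_kind, x$n_points, x$converged, x$residual_norm
  ))
  print(x$parameters)
  invisible(x)
}

#' Fit the Hertz loading model to a force-indentation curve
#'
#' With Poisson's ratio and the equivalent radius fixed, the Hertz force
#' is linear in the Young's modulus, so the least-squares estimate is
#' closed-form: `E = sum(g F) / sum(g^2)` with
#' `g = pref(nu, R) * delta^(3/2)`.
#'
#' @param curve A `cyto_curve`/data frame with columns `delta_um`
#'   (non-decreasing) and `F_nN`.
#' @param nu Fixed Poisson's ratio.
#' @param R_eq_um Fixed equivalent radius, µm.
#' @param denominator Prefactor convention (see [hertz_force()]).
#' @return A `cyto_fit` with parameter `E_MPa`.
#' @export
fit_hertz <- function(curve, nu, R_eq_um, denominator = "one_minus_nu_sq") {
  check_curve_columns(curve, c("delta_um", "F_nN"))
  if (is.unsorted(curve$delta_um)) {
    abort("`delta_um` must be non-decreasing for a loading curve.",
      class = "cytomech_input_error"
    )
  }
  g <- hertz_prefactor(1, nu, R_eq_um, denominator) * curve$delta_um^1.5
  F_uN <- curve$F_nN / 1e3
  E_hat <- sum(g * F_uN) / sum(g^2)
  dof <- max(1, length(g) - 1)
  sigma2 <- sum((F_uN - E_hat * g)^2) / dof
  se <- sqrt(sigma2 / sum(g^2))
  params <- tibble(
    term = "E_MPa", estimate = E_hat, std_error = se, unit = "MPa"
  )
  new_fit("hertz", params, as_curve_input(curve), 1e3 * E_hat * g, TRUE)
}

#' Fit the SLS relaxation model to a hold-phase force record
#'
#' Nonlinear least squares of
#' `F(t) = pref(nu, R) E_R delta^(3/2) (1 + (dtau/tau_eps) exp(-t/tau_eps))`
#' in the parameterisation `(E_R, tau_eps, dtau >= 0)` with
#' `tau_sigma = tau_eps + dtau`, which enforces
#' `tau_sigma >= tau_epsilon` by construction. Starting values come from
#' the curve's asymptotes (tail level gives `E_R`, initial/final force
#' ratio gives `tau_sigma/tau_epsilon`, log-linear decay gives
#' `tau_eps`), refined by a 5-point multi-start around them. The derived
#' instantaneous and long-term moduli of [sls_derive()] are reported
#' alongside.
#'
#' A hold shorter than about one `tau_epsilon` triggers a wide-uncertainty
#' warning (the decay is barely observed), not a failure. An essentially
#' constant force is recovered as the degenerate single spring
#' (`tau_sigma = tau_epsilon`).
#'
#' @param curve Curve with columns `t_s`, `F_nN` (hold phase, fixed
#'   depth).
#' @param nu Fixed Poisson's ratio.
#' @param R_eq_um Fixed equivalent radius, µm.
#' @param delta_um Fixed indentation depth, µm.
#' @param denominator Prefactor convention (default `"one_minus_nu"`).
#' @param bootstrap If `TRUE`, adds case-resampling bootstrap standard
#'   errors (`n_boot` seeded resamples) to the Jacobian-based ones.
#' @param n_boot,boot_seed Bootstrap resample count and seed.
#' @return A `cyto_fit` with parameters `E_R_MPa`, `tau_sigma_s`,
#'   `tau_epsilon_s` and derived `E0_MPa`, `Einf_MPa`.
#' @export
fit_sls_relaxation <- function(curve, nu, R_eq_um, delta_um,
                               denominator = "one_minus_nu",
                               bootstrap = FALSE, n_boot = 200, boot_seed = 1) {
  check_curve_columns(curve, c("t_s", "F_nN"))
  t <- curve$t_s
  F_uN <- curve$F_nN / 1e3
  pref <- hertz_prefactor(1, nu, R_eq_um, denominator) * delta_um^1.5
  # asymptote-based initial values
  F_inf0 <- mean(tail(F_uN, max(3, round(length(F_uN) / 10))))
  F_00 <- mean(head(F_uN, max(3, round(length(F_uN) / 50))))
  ER0 <- F_inf0 / pref
  ratio0 <- max(F_00 / F_inf0, 1)
  if (ratio0 - 1 < 1e-6) {
    ER_hat <- mean(F_uN) / pref
    tau_fixed <- max(diff(range(t)), 1)
    params <- sls_param_table(ER_hat, tau_fixed, tau_fixed, NA, NA, NA, nu)
    return(new_fit(
      "hertz_sls", params, as_curve_input(curve),
      rep(1e3 * ER_hat * pref, length(t)), TRUE,
      extra = list(degenerate = TRUE)
    ))
  }
  dec <- F_uN - F_inf0
  pos <- dec > 0.05 * (F_00 - F_inf0) & t > 0
  taueps0 <- if (sum(pos) >= 3) {
    -1 / coef(lm(log(dec[pos]) ~ t[pos]))[[2]]
  } else {
    diff(range(t)) / 5
  }
  taueps0 <- min(max(taueps0, 1e-3), 10 * diff(range(t)))
  dtau0 <- (ratio0 - 1) * taueps0
  model_fun <- function(ER, taueps, dtau, tt) {
    pref * ER * (1 + dtau / taueps * exp(-tt / taueps))
  }
  starts <- list(
    c(ER0, taueps0, dtau0),
    c(ER0, taueps0 * 0.3, dtau0 * 0.3),
    c(ER0, taueps0 * 3, dtau0 * 3),
    c(ER0, taueps0 * 0.3, dtau0 * 3),
    c(ER0, taueps0 * 3, dtau0 * 0.3)
  )
  best <- multi_start_nls(
    F_uN ~ model_fun(ER, taueps, dtau, t),
    data = list(F_uN = F_uN, t = t),
    starts = lapply(starts, function(s) list(ER = s[1], taueps = s[2], dtau = s[3])),
    lower = c(ER = 1e-12, taueps = 1e-6, dtau = 0)
  )
  est <- coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(vc), 0))
  tau_eps <- est[["taueps"]]
  tau_sig <- tau_eps + est[["dtau"]]
  # var(tau_sigma) = var(taueps) + var(dtau) + 2 cov
  se_tausig <- if (all(is.finite(vc))) {
    sqrt(max(vc["taueps", "taueps"] + vc["dtau", "dtau"] + 2 * vc["taueps", "dtau"], 0))
  } else {
    NA_real_
  }
  if (diff(range(t)) < tau_eps) {
    warn("Hold duration is shorter than the fitted tau_epsilon; estimates are weakly constrained.",
      class = "cytomech_wide_uncertainty"
    )
  }
  params <- sls_param_table(
    est[["ER"]], tau_sig, tau_eps,
    se[["ER"]], se_tausig, se[["taueps"]], nu
  )
  fitted <- 1e3 * model_fun(est[["ER"]], tau_eps, est[["dtau"]], t)
  fit <- new_fit("hertz_sls", params, as_curve_input(curve), fitted,
    best$converged,
    extra = list(degenerate = FALSE)
  )
  if (bootstrap) {
    fit$parameters <- add_bootstrap_se(
      fit$parameters, curve, n_boot, boot_seed,
      function(cv) fit_sls_relaxation(cv, nu, R_eq_um, delta_um, denominator)
    )
  }
  fit
}

sls_param_table <- function(ER, tau_sig, tau_eps, se_ER, se_ts, se_te, nu) {
  drv <- sls_derive(ER, tau_sig, tau_eps, nu)
  tibble(
    term = c("E_R_MPa", "tau_sigma_s", "tau_epsilon_s", "E0_MPa", "Einf_MPa"),
    estimate = c(ER, tau_sig, tau_eps, drv$E0_MPa, drv$Einf_MPa),
    std_error = c(se_ER, se_ts, se_te, NA, NA),
    unit = c("MPa", "s", "s", "MPa", "MPa")
  )
}

#' Fit the half-space creep model to an aspiration record
#'
#' Nonlinear least squares of
#' `L_p(t) = a (1 - r exp(-t/tau))` with `a = R_p phi dP / (pi E1)` and
#' `r = E2/(E1+E2)`, initialised from the asymptotes (`a` from the tail,
#' `a (1 - r)` from the first samples, `tau` from the log-linear decay)
#' with a 5-point multi-start, then mapped back to the spring constants
#' `E1 = R_p phi dP / (pi a)` and `E2 = E1 r / (1 - r)`. A flat record is
#' recovered as the elastic limit `E2 = 0`.
#'
#' @param curve Curve with columns `t_s`, `Lp_um` (all positive), at
#'   constant pressure.
#' @param R_p_um,dP_MPa Fixed pipette radius (µm) and pressure step
#'   (MPa).
#' @param phi Fixed punch coefficient (default 2.1).
#' @inheritParams fit_sls_relaxation
#' @return A `cyto_fit` with parameters `E1_MPa`, `E2_MPa`, `tau_s`.
#' @export
fit_sato_creep <- function(curve, R_p_um, dP_MPa, phi = 2.1,
                           bootstrap = FALSE, n_boot = 200, boot_seed = 1) {
  check_curve_columns(curve, c("t_s", "Lp_um"))
  if (any(curve$Lp_um <= 0)) {
    abort("Aspiration lengths must be positive.", class = "cytomech_input_error")
  }
  t <- curve$t_s
  L <- curve$Lp_um
  amp <- R_p_um * phi * dP_MPa / pi
  a0 <- mean(tail(L, max(3, round(length(L) / 10))))
  L0 <- mean(head(L, max(3, round(length(L) / 50))))
  r0 <- min(max(1 - L0 / a0, 1e-8), 0.99)
  if (r0 < 1e-6) {
    E1 <- amp / mean(L)
    params <- tibble(
      term = c("E1_MPa", "E2_MPa", "tau_s"),
      estimate = c(E1, 0, NA),
      std_error = c(NA, NA, NA),
      unit = c("MPa", "MPa", "s")
    )
    return(new_fit("sato", params, as_curve_input(curve),
      rep(mean(L), length(t)), TRUE,
      extra = list(degenerate = TRUE)
    ))
  }
  ris <- a0 - L
  pos <- ris > 0.05 * (a0 - L0) & t > 0
  tau0 <- if (sum(pos) >= 3) {
    -1 / coef(lm(log(ris[pos]) ~ t[pos]))[[2]]
  } else {
    diff(range(t)) / 5
  }
  tau0 <- min(max(tau0, 1e-3), 10 * diff(range(t)))
  model_fun <- function(a, r, tau, tt) a * (1 - r * exp(-tt / tau))
  starts <- list(
    c(a0, r0, tau0),
    c(a0, r0, tau0 * 0.3), c(a0, r0, tau0 * 3),
    c(a0, min(r0 * 2, 0.99), tau0), c(a0, r0 * 0.5, tau0)
  )
  best <- multi_start_nls(
    L ~ model_fun(a, r, tau, t),
    data = list(L = L, t = t),
    starts = lapply(starts, function(s) list(a = s[1], r = s[2], tau = s[3])),
    lower = c(a = 1e-12, r = 0, tau = 1e-6),
    upper = c(a = Inf, r = 1 - 1e-9, tau = Inf)
  )
  est <- coef(best$fit)
  a <- est[["a"]]
  r <- est[["r"]]
  tau <- est[["tau"]]
  E1 <- amp / a
  E2 <- E1 * r / (1 - r)
  # delta-method standard errors through (E1, E2) = f(a, r)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) matrix(NA, 3, 3))
  se <- rep(NA_real_, 3)
  if (all(is.finite(vc))) {
    J <- rbind(
      c(-amp / a^2, 0, 0),
      c(-amp * r / (a^2 * (1 - r)), amp / (a * (1 - r)^2), 0),
      c(0, 0, 1)
    )
    se <- sqrt(pmax(diag(J %*% vc %*% t(J)), 0))
  }
  params <- tibble(
    term = c("E1_MPa", "E2_MPa", "tau_s"),
    estimate = c(E1, E2, tau),
    std_error = se,
    unit = c("MPa", "MPa", "s")
  )
  fit <- new_fit(
    "sato", params, as_curve_input(curve),
    model_fun(a, r, tau, t), best$converged
  )
  if (bootstrap) {
    fit$parameters <- add_bootstrap_se(
      fit$parameters, curve, n_boot, boot_seed,
      function(cv) fit_sato_creep(cv, R_p_um, dP_MPa, phi)
    )
  }
  fit
}

# run nlsLM from several starts, keep the lowest-deviance converged fit
multi_start_nls <- function(formula, data, starts, lower, upper = NULL) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula,
        data = data, start = s,
        lower = lower, upper = upper %||% rep(Inf, length(lower)),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    dev <- sum(stats::residuals(fit)^2)
    if (is.null(best) || dev < best$dev) {
      best <- list(fit = fit, dev = dev, converged = fit$convInfo$isConv %||% TRUE)
    }
  }
  if (is.null(best)) {
    abort("All nonlinear least-squares starts failed.", class = "cytomech_fit_error")
  }
  best
}

add_bootstrap_se <- function(parameters, curve, n_boot, seed, refit) {
  curve <- as_curve_input(curve)
  ests <- withr::with_seed(seed, {
    replicate(n_boot, {
      idx <- sort(sample.int(nrow(curve), replace = TRUE))
      cv <- new_curve(curve[idx, ], curve_meta(curve))
      out <- tryCatch(refit(cv)$parameters$estimate, error = function(e) NULL)
      if (is.null(out)) rep(NA_real_, nrow(parameters)) else out[seq_len(nrow(parameters))]
    })
  })
  parameters$boot_se <- apply(matrix(ests, nrow = nrow(parameters)), 1, sd, na.rm = TRUE)
  parameters
}

as_curve_input <- function(curve) {
  if (inherits(curve, "cyto_curve")) curve else new_curve(curve)
}
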