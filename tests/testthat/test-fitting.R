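sls_params <- function() {
  list(
    E_R_MPa = SLS_CYTO$E_R, tau_sigma_s = SLS_CYTO$tau_sigma,
    tau_epsilon_s = SLS_CYTO$tau_epsilon, nu = SLS_CYTO$nu,
    R_eq_um = R_EQ, delta_um = 1.5
  )
}
sato_params <- function() {
  list(E1_MPa = 4.5e-4, E2_MPa = 4.8e-4, tau_s = 10, R_p_um = 4, dP_MPa = 1e-4)
}
fit_est <- function(fit) setNames(tidy(fit)$estimate, tidy(fit)$term)

test_that("the synthetic generator is exact, seeded and calibrated", {
  clean <- generate_synthetic_curve("hertz_sls", sls_params())
  expect_equal(
    clean$F_nN,
    1e3 * hertz_sls_force(
      1.5, clean$t_s, SLS_CYTO$E_R, SLS_CYTO$tau_sigma,
      SLS_CYTO$tau_epsilon, SLS_CYTO$nu, R_EQ
    )
  )
  a <- generate_synthetic_curve("hertz_sls", sls_params(), noise_sd = 0.05, seed = 7)
  b <- generate_synthetic_curve("hertz_sls", sls_params(), noise_sd = 0.05, seed = 7)
  expect_identical(a$F_nN, b$F_nN)
  d <- generate_synthetic_curve("hertz_sls", sls_params(), noise_sd = 0.05, seed = 8)
  expect_false(identical(a$F_nN, d$F_nN))
  # empirical relative sd of the residuals sits near the requested level
  rel <- a$F_nN / clean$F_nN - 1
  expect_gt(sd(rel), 0.04)
  expect_lt(sd(rel), 0.06)
  expect_error(
    generate_synthetic_curve("hertz_sls", sls_params(), noise_sd = 0.05),
    class = "cytomech_config_error"
  )
})

test_that("noise-free closed-loop fits recover the generating parameters", {
  # Hertz
  ch <- generate_synthetic_curve(
    "hertz", list(E_MPa = 1.28e-3, nu = 0.37, R_eq_um = R_EQ)
  )
  fh <- fit_hertz(ch, 0.37, R_EQ)
  expect_lt(abs(fit_est(fh)[["E_MPa"]] / 1.28e-3 - 1), 1e-6)
  # SLS relaxation
  cs <- generate_synthetic_curve("hertz_sls", sls_params())
  fs <- fit_sls_relaxation(cs, 0.37, R_EQ, 1.5)
  es <- fit_est(fs)
  expect_lt(max_rel_err(
    es[c("E_R_MPa", "tau_sigma_s", "tau_epsilon_s")],
    c(4.5e-4, 19.7, 9.5)
  ), 1e-3)
  # derived moduli are reported alongside
  expect_lt(abs(es[["E0_MPa"]] / (4.5e-4 * 19.7 / 9.5) - 1), 1e-3)
  expect_lt(abs(es[["Einf_MPa"]] / (4.5e-4 * 1.37) - 1), 1e-3)
  # creep
  cc <- generate_synthetic_curve("sato", sato_params())
  fc <- fit_sato_creep(cc, 4, 1e-4)
  expect_lt(max_rel_err(fit_est(fc), c(4.5e-4, 4.8e-4, 10)), 1e-3)
})

test_that("closed-loop identity holds across random admissible parameters", {
  set.seed(99)
  for (k in 1:25) {
    # relaxation
    te <- runif(1, 3, 12)
    ts <- te * runif(1, 1.3, 3)
    ER <- 10^runif(1, -4, -3)
    p <- list(
      E_R_MPa = ER, tau_sigma_s = ts, tau_epsilon_s = te,
      nu = 0.37, R_eq_um = R_EQ, delta_um = 1.5
    )
    f <- fit_sls_relaxation(
      generate_synthetic_curve("hertz_sls", p), 0.37, R_EQ, 1.5
    )
    expect_lt(max_rel_err(
      fit_est(f)[c("E_R_MPa", "tau_sigma_s", "tau_epsilon_s")], c(ER, ts, te)
    ), 1e-4)
    # creep
    E1 <- 10^runif(1, -4, -3)
    E2 <- 10^runif(1, -4, -3)
    tau <- runif(1, 3, 12)
    ps <- list(E1_MPa = E1, E2_MPa = E2, tau_s = tau, R_p_um = 4, dP_MPa = 1e-4)
    fcl <- fit_sato_creep(generate_synthetic_curve("sato", ps), 4, 1e-4)
    expect_lt(max_rel_err(fit_est(fcl), c(E1, E2, tau)), 1e-4)
  }
})

test_that("fits at 5% noise stay within their recovery tolerances", {
  cs <- generate_synthetic_curve("hertz_sls", sls_params(), noise_sd = 0.05, seed = 1)
  es <- fit_est(fit_sls_relaxation(cs, 0.37, R_EQ, 1.5))
  expect_lt(max_rel_err(
    es[c("E_R_MPa", "tau_sigma_s", "tau_epsilon_s")], c(4.5e-4, 19.7, 9.5)
  ), 0.10)
  cc <- generate_synthetic_curve("sato", sato_params(), noise_sd = 0.05, seed = 1)
  ec <- fit_est(fit_sato_creep(cc, 4, 1e-4))
  expect_lt(abs(ec[["E1_MPa"]] / 4.5e-4 - 1), 0.05)
  expect_lt(abs(ec[["E2_MPa"]] / 4.8e-4 - 1), 0.15)
  expect_lt(abs(ec[["tau_s"]] / 10 - 1), 0.15)
  ch <- generate_synthetic_curve(
    "hertz", list(E_MPa = 1.28e-3, nu = 0.37, R_eq_um = R_EQ),
    noise_sd = 0.05, seed = 1
  )
  expect_lt(abs(fit_est(fit_hertz(ch, 0.37, R_EQ))[["E_MPa"]] / 1.28e-3 - 1), 0.03)
})

test_that("estimator error shrinks when the sample size doubles", {
  err_for_n <- function(n) {
    median(vapply(1:50, function(s) {
      cv <- generate_synthetic_curve("hertz_sls", sls_params(),
        protocol = list(n = n), noise_sd = 0.05, seed = s
      )
      es <- fit_est(fit_sls_relaxation(cv, 0.37, R_EQ, 1.5))
      max_rel_err(
        es[c("E_R_MPa", "tau_sigma_s", "tau_epsilon_s")], c(4.5e-4, 19.7, 9.5)
      )
    }, numeric(1)))
  }
  expect_lt(err_for_n(600), err_for_n(300))
})

test_that("fits are invariant to a consistent time-unit rescaling", {
  cc <- generate_synthetic_curve("sato", sato_params(), noise_sd = 0.02, seed = 3)
  f_s <- fit_est(fit_sato_creep(cc, 4, 1e-4))
  cc_min <- cc
  cc_min$t_s <- cc$t_s / 60 # express time in minutes
  f_min <- fit_est(fit_sato_creep(cc_min, 4, 1e-4))
  expect_equal(f_min[["E1_MPa"]], f_s[["E1_MPa"]], tolerance = 1e-6)
  expect_equal(f_min[["E2_MPa"]], f_s[["E2_MPa"]], tolerance = 1e-6)
  expect_equal(60 * f_min[["tau_s"]], f_s[["tau_s"]], tolerance = 1e-6)
})

test_that("fit linearity, input validation and degenerate limits behave", {
  ch <- generate_synthetic_curve(
    "hertz", list(E_MPa = 1.28e-3, nu = 0.37, R_eq_um = R_EQ)
  )
  doubled <- ch
  doubled$F_nN <- 2 * ch$F_nN
  expect_equal(
    fit_est(fit_hertz(doubled, 0.37, R_EQ))[["E_MPa"]],
    2 * fit_est(fit_hertz(ch, 0.37, R_EQ))[["E_MPa"]],
    tolerance = 1e-12
  )
  shuffled <- ch[sample.int(nrow(ch)), ]
  expect_error(fit_hertz(shuffled, 0.37, R_EQ), class = "cytomech_input_error")
  # constant force -> degenerate single spring
  flat <- tibble::tibble(t_s = seq(0, 60, length.out = 200), F_nN = 5)
  fd <- fit_est(fit_sls_relaxation(flat, 0.37, R_EQ, 1.5))
  expect_equal(fd[["tau_sigma_s"]], fd[["tau_epsilon_s"]])
  pref <- 1e3 * 4 * sqrt(R_EQ) * 1.5^1.5 / (3 * (1 - 0.37))
  expect_equal(fd[["E_R_MPa"]], 5 / pref, tolerance = 1e-9)
  # flat creep record -> elastic limit E2 = 0
  flatL <- tibble::tibble(t_s = seq(0, 60, length.out = 200), Lp_um = 0.59)
  fe <- fit_est(fit_sato_creep(flatL, 4, 1e-4))
  expect_equal(fe[["E2_MPa"]], 0)
  expect_equal(fe[["E1_MPa"]], 4 * 2.1 * 1e-4 / (pi * 0.59), tolerance = 1e-9)
  neg <- tibble::tibble(t_s = 0:5, Lp_um = c(0.1, 0.2, -0.1, 0.3, 0.4, 0.5))
  expect_error(fit_sato_creep(neg, 4, 1e-4), class = "cytomech_input_error")
})

test_that("tidy, glance and bootstrap surfaces are coherent", {
  cc <- generate_synthetic_curve("sato", sato_params(), noise_sd = 0.05, seed = 2)
  fit <- fit_sato_creep(cc, 4, 1e-4, bootstrap = TRUE, n_boot = 30, boot_seed = 5)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "unit", "boot_se") %in% names(td)))
  expect_true(all(td$boot_se[1:2] > 0))
  # jackknife-style sanity: bootstrap and Jacobian SEs agree in order of magnitude
  expect_lt(abs(log10(td$boot_se[1] / td$std_error[1])), 1)
  gl <- glance(fit)
  expect_equal(gl$n_points, nrow(cc))
  expect_true(gl$converged)
})
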