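test_that("AFM hold phase converges to the step-relaxation solution", {
  cm <- cell_model("CM")
  cv <- simulate_afm(cm)
  t_ramp <- 1.5 / 9.5
  hold <- cv$t_s >= t_ramp + 1 # give the ramp transient one second
  step_F <- 1e3 * hertz_sls_force(
    1.5, cv$t_s[hold] - t_ramp, SLS_CYTO$E_R, SLS_CYTO$tau_sigma,
    SLS_CYTO$tau_epsilon, SLS_CYTO$nu, R_EQ
  )
  expect_lt(max(abs(cv$F_nN[hold] / step_F - 1)), 0.01)
  # at a much faster ramp the whole hold curve collapses onto the step form
  fast <- simulate_afm(cm, afm_protocol(speed_um_s = 1000, depth_um = 1.5, hold_s = 60))
  tr2 <- 1.5 / 1000
  h2 <- fast$t_s >= tr2
  stepF2 <- 1e3 * hertz_sls_force(
    1.5, fast$t_s[h2] - tr2, SLS_CYTO$E_R, SLS_CYTO$tau_sigma,
    SLS_CYTO$tau_epsilon, SLS_CYTO$nu, R_EQ
  )
  expect_lt(max(abs(fast$F_nN[h2] / stepF2 - 1)), 1e-4)
})

test_that("an elastic cytoplasm reproduces the Hertz loading curve sample by sample", {
  mats <- cell_type_1()
  mats$tau_sigma_s[mats$role == "cytoplasm"] <- mats$tau_epsilon_s[mats$role == "cytoplasm"]
  cm <- cell_model("CM", materials = cell_materials(tibble::as_tibble(mats), "elastic"))
  cv <- simulate_afm(cm)
  loading <- cv$t_s <= 1.5 / 9.5
  expected <- 1e3 * hertz_force(cv$delta_um[loading], SLS_CYTO$E_R, SLS_CYTO$nu, R_EQ,
    denominator = "one_minus_nu"
  )
  expect_equal(cv$F_nN[loading], expected, tolerance = 1e-12)
})

test_that("halving the sampling interval leaves reported forces unchanged to 0.1%", {
  cm <- cell_model("CM")
  c1 <- simulate_afm(cm, afm_protocol(dt_s = 0.2, hold_s = 20))
  c2 <- simulate_afm(cm, afm_protocol(dt_s = 0.1, hold_s = 20))
  m <- merge(as.data.frame(c1), as.data.frame(c2), by = "t_s")
  m <- m[m$t_s > 0, ]
  expect_gt(nrow(m), 50)
  expect_lt(max(abs(m$F_nN.x / m$F_nN.y - 1)), 0.001)
})

test_that("the tensegrity cytoskeleton always stiffens the AFM response", {
  cm <- cell_model("CM")
  ctm <- cell_model("CTM")
  p <- afm_protocol(hold_s = 10)
  c_cm <- simulate_afm(cm, p)
  c_ctm <- simulate_afm(ctm, p)
  expect_equal(c_cm$t_s, c_ctm$t_s)
  expect_true(all(c_ctm$F_nN >= c_cm$F_nN - 1e-9))
  expect_gt(max(c_ctm$F_nN - c_cm$F_nN), 0)
  # CM output is independent of any cytoskeleton carried along
  cm2 <- cell_model("CM", cytoskeleton = prestressed_graph())
  expect_equal(simulate_afm(cm2, p)$F_nN, c_cm$F_nN)
})

test_that("Q-scaling the cytoskeleton shifts the AFM force in the expected directions", {
  p <- afm_protocol(hold_s = 1)
  base <- simulate_afm(cell_model("CTM"), p)
  soft <- simulate_afm(
    cell_model("CTM", materials = scale_materials(cell_type_1(), 12.78, "softer")), p
  )
  stiff <- simulate_afm(
    cell_model("CTM", materials = scale_materials(cell_type_1(), 12.78, "stiffer")), p
  )
  cm <- simulate_afm(cell_model("CM"), p)
  Fb <- max(base$F_nN)
  expect_lt(max(soft$F_nN), Fb)
  expect_gt(max(stiff$F_nN), Fb)
  # the cytoskeletal contribution is homogeneous of degree one in the
  # fibre moduli under displacement control: scaling by Q multiplies it
  # by Q exactly (the full-FE saturation asymmetry is outside this
  # reduced model; see the vignette)
  csk_base <- max(base$F_nN) - max(cm$F_nN)
  csk_soft <- max(soft$F_nN) - max(cm$F_nN)
  csk_stiff <- max(stiff$F_nN) - max(cm$F_nN)
  expect_equal(csk_soft, csk_base / 12.78, tolerance = 1e-6)
  expect_equal(csk_stiff, csk_base * 12.78, tolerance = 1e-6)
})

test_that("MPA ramp superposition has the exact step limit and ramp-free asymptote", {
  cm <- cell_model("CM")
  step <- simulate_mpa(cm, mpa_protocol(ramp_s = 0, hold_s = 60))
  drv <- sls_derive(SLS_CYTO$E_R, SLS_CYTO$tau_sigma, SLS_CYTO$tau_epsilon, SLS_CYTO$nu)
  exact <- sato_creep(step$t_s, 4, 1e-4, SLS_CYTO$E_R, drv$k2_MPa, SLS_CYTO$tau_sigma)
  expect_equal(step$Lp_um, exact, tolerance = 1e-15)
  # the creep asymptote does not depend on the ramp duration
  long1 <- simulate_mpa(cm, mpa_protocol(ramp_s = 1, hold_s = 400))
  long2 <- simulate_mpa(cm, mpa_protocol(ramp_s = 4, hold_s = 400))
  expect_equal(tail(long1$Lp_um, 1), tail(long2$Lp_um, 1), tolerance = 1e-6)
  expect_lt(abs(tail(long1$Lp_um, 1) / aspiration_elastic(4, 1e-4, SLS_CYTO$E_R) - 1), 1e-3)
})

test_that("the cytoskeleton reduces aspiration length, more so for wider pipettes", {
  p2 <- mpa_protocol(ratio = 2, hold_s = 30)
  cm <- cell_model("CM")
  cm_curve <- simulate_mpa(cm, p2)
  ctm <- cell_model("CTM")
  ctm_curve <- simulate_mpa(ctm, p2)
  expect_true(all(ctm_curve$Lp_um <= cm_curve$Lp_um + 1e-12))
  gap2 <- tail(cm_curve$Lp_um, 1) - tail(ctm_curve$Lp_um, 1)
  expect_gt(gap2, 0)
  # at ratio 3 the pipette no longer reaches any receptor node: gap vanishes
  p3 <- mpa_protocol(ratio = 3, hold_s = 30)
  cm3 <- simulate_mpa(cm, p3)
  ctm3 <- suppressWarnings(simulate_mpa(ctm, p3))
  gap3 <- tail(cm3$Lp_um, 1) - tail(ctm3$Lp_um, 1)
  expect_lt(gap3, gap2)
  expect_equal(ctm3$Lp_um, cm3$Lp_um)
})

test_that("the two cytoskeleton orientations give different aspiration curves", {
  p <- mpa_protocol(ratio = 2, hold_s = 20)
  c1 <- simulate_mpa(cell_model("CTM", orientation = "config1"), p)
  c2 <- simulate_mpa(cell_model("CTM", orientation = "config2"), p)
  expect_false(isTRUE(all.equal(tail(c1$Lp_um, 1), tail(c2$Lp_um, 1))))
})

test_that("ratio sweep normalisation exposes the cytoskeletal size effect", {
  ratios <- c(1.5, 2, 3, 4, 5.5)
  cm <- cell_model("CM")
  sw <- sweep_ratios(cm, ratios, mpa_protocol(hold_s = 10), normalize = "Rp")
  expect_equal(sort(unique(sw$ratio)), ratios)
  # pipette radii follow R_cell / ratio
  Rp <- vapply(
    ratios,
    function(r) {
      rows <- sw$ratio == r & sw$Lp_um > 0
      (sw$Lp_um[rows] / sw$Lp_norm[rows])[1]
    },
    numeric(1)
  )
  expect_equal(Rp, 8 / ratios, tolerance = 1e-9)
  # half-space CM: Lp/Rp at the final time identical across ratios
  final_cm <- tapply(sw$Lp_norm, sw$ratio, function(x) tail(x, 1))
  expect_lt(diff(range(final_cm)) / mean(final_cm), 1e-12)
  # CTM: the normalised response varies with the ratio
  swt <- sweep_ratios(cell_model("CTM"), ratios, mpa_protocol(hold_s = 10))
  final_ctm <- tapply(swt$Lp_norm, swt$ratio, function(x) tail(x, 1))
  expect_gt(diff(range(final_ctm)) / mean(final_ctm), 0.01)
})
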