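test_that("force-density self-stress matches an independent null-space oracle", {
  g <- build_tensegrity(8)
  s <- find_selfstress(g)
  expect_equal(attr(s, "null_dim"), 1)
  # normalised pattern: cables +1, struts -3/2
  expect_equal(unname(s$force_density[s$kind == "cable"]), rep(1, 24), tolerance = 1e-9)
  expect_equal(unname(s$force_density[s$kind == "strut"]), rep(-1.5, 6), tolerance = 1e-9)
  # member-force ratio sqrt(6)
  ratio <- abs(mean(s$member_force[s$kind == "strut"])) /
    abs(mean(s$member_force[s$kind == "cable"]))
  expect_equal(ratio, sqrt(6), tolerance = 1e-9)
  # independent oracle: pracma null space of the same equilibrium matrix
  skip_if_not_installed("pracma")
  A <- cytomech:::equilibrium_matrix(g)
  Np <- pracma::nullspace(A)
  expect_equal(ncol(Np), 1)
  q_oracle <- Np[, 1] / mean(Np[g$members$kind == "cable", 1])
  expect_equal(unname(s$force_density), unname(q_oracle), tolerance = 1e-8)
})

test_that("self-stress is invariant under rigid rotation and absent for corrupted graphs", {
  g <- build_tensegrity(8, rotation_deg = 53.1, rotation_axis = "x")
  s <- find_selfstress(g)
  expect_equal(unname(s$force_density[s$kind == "strut"]), rep(-1.5, 6), tolerance = 1e-9)
  bad <- build_tensegrity(8)
  bad$members <- bad$members[-which(bad$members$kind == "cable")[1], ]
  expect_error(find_selfstress(bad), class = "cytomech_no_selfstress")
})

test_that("prestressing by rest-length adjustment is self-equilibrated and linear", {
  g <- build_tensegrity(8)
  g0 <- apply_prestress(g, cable_prestrain = 0)
  expect_equal(g0$members$rest_length_um, g$members$length_um, tolerance = 1e-15)
  gp <- prestressed_graph()
  sol <- solve_static(gp)
  expect_true(sol$converged)
  expect_lt(max(abs(sol$u)), 1e-8)
  # cable force = prestrain * EA; strut/cable force ratio sqrt(6)
  Fc <- sol$members$force_uN[sol$members$kind == "cable"]
  Fs <- sol$members$force_uN[sol$members$kind == "strut"]
  expect_equal(unname(Fc), rep(0.01 * 3.32e4 * 1.8e-5, 24), tolerance = 1e-9)
  expect_equal(abs(mean(Fs)) / mean(Fc), sqrt(6), tolerance = 1e-9)
  # doubling the prestrain doubles every member force
  g2 <- prestressed_graph(prestrain = 0.02)
  sol2 <- solve_static(g2)
  expect_equal(sol2$members$force_uN, 2 * sol$members$force_uN, tolerance = 1e-9)
  # buckling floor warning is opt-in
  expect_warning(
    apply_prestress(g, cable_prestrain = 0.01, strut_force_floor_uN = 1e-6),
    class = "cytomech_buckling_warning"
  )
})

test_that("tangent stiffness is the Hessian of the strain energy", {
  gp <- prestressed_graph()
  set.seed(11)
  for (trial in 1:3) {
    u0 <- rnorm(36, 0, 2e-3)
    K <- tangent_stiffness(gp, u0)
    expect_equal(K, t(K), tolerance = 1e-12)
    h <- 1e-6
    Kfd <- matrix(0, 36, 36)
    for (k in 1:36) {
      e <- numeric(36)
      e[k] <- h
      Kfd[, k] <- (cytomech:::internal_forces(gp, u0 + e) -
        cytomech:::internal_forces(gp, u0 - e)) / (2 * h)
    }
    expect_lt(max(abs(K - Kfd)) / max(abs(K)), 1e-6)
    # and the residual is the gradient of the energy
    gfd <- vapply(1:36, function(k) {
      e <- numeric(36)
      e[k] <- h
      (cytomech:::strain_energy(gp, u0 + e) -
        cytomech:::strain_energy(gp, u0 - e)) / (2 * h)
    }, numeric(1))
    gr <- cytomech:::internal_forces(gp, u0)
    expect_lt(max(abs(gr - gfd)) / max(abs(gr)), 1e-6)
  }
})

test_that("static solves satisfy global equilibrium and symmetry", {
  gp <- prestressed_graph()
  # opposite axial point loads on the two poles
  poles <- order(gp$nodes$z_um)
  bottom2 <- poles[1:2]
  top2 <- rev(poles)[1:2]
  bc <- boundary_conditions(
    fixed = tidyr::expand_grid(node = bottom2, axis = 1:3),
    loads = tibble::tibble(node = top2, axis = 3L, value_uN = -2e-3)
  )
  sol <- solve_static(gp, bc)
  expect_true(sol$converged)
  expect_true(all(sol$members$force_uN[sol$members$kind == "cable"] >= 0))
  gl <- glance(sol)
  expect_lt(gl$force_balance_uN, 1e-8)
  # mirror symmetry of the load case: the two loaded nodes move identically in z
  uz <- sol$nodes$uz_um[match(top2, sol$nodes$node)]
  expect_equal(uz[1], uz[2], tolerance = 1e-9)
  # a mechanism without prestress or regularization is rejected
  g0 <- apply_prestress(build_tensegrity(8), cable_prestrain = 0)
  expect_error(
    solve_static(g0, bc, solver_settings(regularization = 0, n_increments = 1)),
    class = "cytomech_singular_system"
  )
})

test_that("reaction to a small prescribed displacement matches the assembled tangent", {
  gp <- prestressed_graph()
  K <- tangent_stiffness(gp)
  bc_sup <- fix_bottom_nodes(gp)
  node <- which.max(gp$nodes$z_um)
  delta <- 1e-6
  bc <- boundary_conditions(
    fixed = bc_sup$fixed,
    prescribed = tibble::tibble(node = node, axis = 3L, value_um = -delta)
  )
  sol <- solve_static(gp, bc, solver_settings(n_increments = 1))
  R <- sol$reactions$R_uN[sol$reactions$node == node & sol$reactions$axis == 3L]
  # oracle: static condensation of the analytic tangent at the prestressed state
  pdofs <- c(cytomech:::dof_index(bc$fixed$node, bc$fixed$axis), cytomech:::dof_index(node, 3L))
  free <- setdiff(1:36, pdofs)
  d_full <- numeric(36)
  d_full[cytomech:::dof_index(node, 3L)] <- -delta
  uf <- solve(K[free, free], -K[free, pdofs] %*% d_full[pdofs])
  u_full <- d_full
  u_full[free] <- uf
  R_oracle <- (K %*% u_full)[cytomech:::dof_index(node, 3L)]
  expect_equal(R, as.numeric(R_oracle), tolerance = 1e-4)
})

test_that("indentation response starts at zero, refines consistently and is initially linear", {
  gp <- prestressed_graph()
  cv <- indentation_sweep(gp, 1.5, n_steps = 25)
  expect_equal(cv$force_nN[1], 0)
  expect_true(all(diff(cv$force_nN) > -1e-9))
  cv2 <- indentation_sweep(gp, 1.5, n_steps = 50)
  m <- merge(as.data.frame(cv), as.data.frame(cv2), by = "delta_um")
  expect_gt(nrow(m), 10)
  expect_lt(
    max(abs(m$force_nN.x - m$force_nN.y) / pmax(abs(m$force_nN.y), 1e-6)), 0.001
  )
  # small-displacement linearity
  small <- indentation_sweep(gp, 0.01, n_steps = 10)
  r2 <- summary(lm(force_nN ~ delta_um, as.data.frame(small)))$r.squared
  expect_gt(r2, 0.9999)
})

test_that("indentation force-displacement is invariant under rigid z-rotation", {
  gp <- prestressed_graph()
  gr <- apply_prestress(
    build_tensegrity(8, rotation_deg = 30, rotation_axis = "z"),
    cable_prestrain = 0.01
  )
  c1 <- indentation_sweep(gp, 0.8, n_steps = 10)
  c2 <- indentation_sweep(gr, 0.8, n_steps = 10)
  expect_equal(c2$force_nN, c1$force_nN, tolerance = 1e-8)
})

test_that("aspiration loading conserves the total suction force", {
  gp <- prestressed_graph()
  bc <- aspiration_load(gp, 4, 1e-4)
  expect_equal(sum(bc$loads$value_uN), 1e-4 * pi * 16)
  expect_equal(attr(bc, "n_inside"), 2)
  bc0 <- aspiration_load(gp, 4, 0)
  expect_equal(sum(bc0$loads$value_uN), 0)
  expect_warning(aspiration_load(gp, 2.5, 1e-4), class = "cytomech_empty_load")
  expect_error(aspiration_load(gp, 9, 1e-4), class = "cytomech_config_error")
})

test_that("the two cytoskeleton dispositions respond differently to the same pipette", {
  w <- vapply(c("config1", "config2"), function(or) {
    g <- prestressed_graph(orientation = or)
    bc <- aspiration_load(g, 4, 1e-4)
    sol <- solve_static(g, bc)
    expect_true(sol$converged)
    mean(sol$nodes$uz_um[match(bc$loads$node, sol$nodes$node)])
  }, numeric(1))
  expect_gt(abs(w["config1"] - w["config2"]), 1e-4)
})
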