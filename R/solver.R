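# Geometrically nonlinear statics of the prestressed tensegrity graph.
# State variable is the 36-vector of nodal displacements from the built
# geometry; members are large-displacement bars with engineering strain on
# the rest length, cables bilinear (zero force and stiffness when slack).

dof_index <- function(node, axis) 3L * (node - 1L) + axis

node_positions <- function(g, u = NULL) {
  P <- as.matrix(g$nodes[, c("x_um", "y_um", "z_um")])
  if (!is.null(u)) P <- P + matrix(u, ncol = 3, byrow = TRUE)
  P
}

# Half-width (in strain) of the C1 quadratic transition regularising the
# tension-only cable law around zero strain. The taut branch (strain >= es)
# is exactly linear, so prestress self-equilibrium is untouched; nearly
# slack cables carry at most EA*es/4 (~1e-7 uN) of residual tension, which
# keeps the Newton iteration smooth across slackening events.
.cable_es <- 1e-6

# cable axial force and stiffness under the regularised bilinear law
cable_force <- function(e, EA, es = .cable_es) {
  ifelse(e <= -es, 0,
    ifelse(e >= es, EA * e, EA * (e + es)^2 / (4 * es))
  )
}

cable_stiffness <- function(e, EA, es = .cable_es) {
  ifelse(e <= -es, 0,
    ifelse(e >= es, EA, EA * (e + es) / (2 * es))
  )
}

cable_energy_density <- function(e, EA, es = .cable_es) {
  # integral of cable_force in e (per unit EA*L0), offset-free at e <= -es
  ifelse(e <= -es, 0,
    ifelse(e >= es, e^2 / 2 + es^2 / 6, (e + es)^3 / (12 * es))
  ) * EA
}

# per-member geometry and axial force at displacement u
member_state <- function(g, u = NULL) {
  P <- node_positions(g, u)
  m <- g$members
  dvec <- P[m$j, , drop = FALSE] - P[m$i, , drop = FALSE]
  L <- sqrt(rowSums(dvec^2))
  EA <- m$E_MPa * m$area_um2
  e <- (L - m$rest_length_um) / m$rest_length_um
  cab <- m$kind == "cable"
  N <- EA * e
  N[cab] <- cable_force(e[cab], EA[cab])
  k_ax <- EA
  k_ax[cab] <- cable_stiffness(e[cab], EA[cab])
  slack <- cab & e < .cable_es
  list(dvec = dvec, L = L, EA = EA, e = e, N = N, k_ax = k_ax, slack = slack)
}

# total strain energy (uN*um); fully slack cables store none
strain_energy <- function(g, u = NULL) {
  st <- member_state(g, u)
  m <- g$members
  cab <- m$kind == "cable"
  dens <- st$EA * st$e^2 / 2
  dens[cab] <- cable_energy_density(st$e[cab], st$EA[cab])
  sum(dens * m$rest_length_um)
}

# gradient of strain energy wrt nodal positions (internal force vector, uN)
internal_forces <- function(g, u = NULL) {
  st <- member_state(g, u)
  m <- g$members
  grad <- numeric(3L * nrow(g$nodes))
  coef <- st$N / st$L
  for (k in seq_len(nrow(m))) {
    f <- coef[k] * st$dvec[k, ] # force on node j along i->j is -N*n; on i is +N*n
    ii <- dof_index(m$i[k], 1:3)
    jj <- dof_index(m$j[k], 1:3)
    grad[ii] <- grad[ii] - f
    grad[jj] <- grad[jj] + f
  }
  grad
}

#' Tangent stiffness of a tensegrity graph
#'
#' Assembles the consistent tangent (material + geometric) stiffness of
#' the graph at nodal displacement `u` from the built geometry. Each
#' member contributes `(k n n' + (N/L)(I - n n'))` in its local frame,
#' where `k` is its axial stiffness over the rest length: `EA/L0` for
#' struts and taut cables, zero for fully slack cables, with a narrow C1
#' quadratic transition (half-width 1e-6 strain) between the two cable
#' branches that keeps the Newton iteration smooth across slackening.
#' The matrix is the Hessian of the total strain energy.
#'
#' @param g A `tensegrity` object (see [build_tensegrity()]).
#' @param u Optional displacement vector, length `3 * n_nodes` (µm),
#'   ordered `(x1, y1, z1, x2, ...)`. Default: built geometry.
#' @return A dense symmetric matrix, µN/µm.
#' @export
tangent_stiffness <- function(g, u = NULL) {
  st <- member_state(g, u)
  m <- g$members
  ndof <- 3L * nrow(g$nodes)
  K <- matrix(0, ndof, ndof)
  I3 <- diag(3)
  for (k in seq_len(nrow(m))) {
    if (st$k_ax[k] == 0 && st$N[k] == 0) next
    n <- st$dvec[k, ] / st$L[k]
    nn <- tcrossprod(n)
    Km <- (st$k_ax[k] / m$rest_length_um[k]) * nn + (st$N[k] / st$L[k]) * (I3 - nn)
    ii <- dof_index(m$i[k], 1:3)
    jj <- dof_index(m$j[k], 1:3)
    K[ii, ii] <- K[ii, ii] + Km
    K[jj, jj] <- K[jj, jj] + Km
    K[ii, jj] <- K[ii, jj] - Km
    K[jj, ii] <- K[jj, ii] - Km
  }
  K
}

#' Self-stress state by the force-density method
#'
#' Finds the member force-density pattern in equilibrium with zero
#' external load: the null space of the nodal equilibrium matrix
#' (3 n_nodes x n_members), computed by singular value decomposition. For
#' the 6-strut/24-cable graph the null space is one-dimensional; the
#' basis vector is normalised so every cable carries force density +1,
#' which puts every strut at -3/2, and member forces
#' (density x length) at ratio `|F_strut| / |F_cable| = sqrt(6)`.
#'
#' @param g A `tensegrity` object.
#' @param tol Relative singular-value cutoff for the null space.
#' @return A `selfstress` tibble: `member`, `kind`, `force_density`
#'   (signed, cables +), `member_force` (density x built length; unit
#'   amplitude — physical scaling happens in [apply_prestress()]).
#' @export
find_selfstress <- function(g, tol = 1e-9) {
  viol <- validate_topology(g)
  if (nrow(viol) > 0) {
    abort("Graph fails topology validation; see validate_topology().",
      class = "cytomech_no_selfstress"
    )
  }
  A <- equilibrium_matrix(g)
  sv <- svd(A)
  null_dim <- sum(sv$d < tol * max(sv$d))
  if (null_dim < 1) {
    abort("Equilibrium matrix has no null space: no self-stress state exists.",
      class = "cytomech_no_selfstress"
    )
  }
  q <- sv$v[, ncol(sv$v)]
  cables <- g$members$kind == "cable"
  q <- q / mean(q[cables])
  out <- tibble(
    member = g$members$member,
    kind = g$members$kind,
    force_density = q,
    member_force = q * member_lengths(g$nodes, g$members)
  )
  attr(out, "null_dim") <- null_dim
  class(out) <- c("selfstress", class(out))
  out
}

# columns = members; 3 rows per node: sum_m q_m (x_i - x_j) = 0
equilibrium_matrix <- function(g) {
  P <- node_positions(g)
  m <- g$members
  A <- matrix(0, 3L * nrow(g$nodes), nrow(m))
  for (k in seq_len(nrow(m))) {
    d <- P[m$i[k], ] - P[m$j[k], ]
    A[dof_index(m$i[k], 1:3), k] <- d
    A[dof_index(m$j[k], 1:3), k] <- -d
  }
  A
}

#' Prestress a tensegrity graph
#'
#' Sets member rest lengths so that the built geometry carries the
#' self-stress state scaled to a chosen cable prestrain: each cable then
#' carries force `prestrain * E A`, each strut the matching compressive
#' force, and a no-load solve leaves the geometry unchanged. Rest lengths
#' follow from `N = EA (L - L0)/L0`, i.e. `L0 = L / (1 + N/(EA))`.
#'
#' Tensegrities are mechanisms without prestress, so some positive
#' prestrain is required before [solve_static()] can resist load without
#' regularization; 0.01 is the package default. If `strut_force_floor_uN`
#' is supplied, a warning is raised when any strut's compression exceeds
#' it in magnitude (e.g. an Euler-type buckling estimate — buckling itself
#' is not modelled, matching the truss idealisation of cytoskeletal
#' fibres).
#'
#' @param g A `tensegrity` object.
#' @param selfstress Optional `selfstress` state (default
#'   `find_selfstress(g)`).
#' @param cable_prestrain Non-negative cable prestrain (default 0.01).
#' @param strut_force_floor_uN Optional compressive-force magnitude above
#'   which a buckling warning is emitted.
#' @return The graph with updated `rest_length_um` and a
#'   `cable_prestrain` attribute.
#' @export
apply_prestress <- function(g, selfstress = find_selfstress(g),
                            cable_prestrain = 0.01,
                            strut_force_floor_uN = NULL) {
  stopifnot(cable_prestrain >= 0)
  m <- g$members
  L <- member_lengths(g$nodes, m)
  cables <- m$kind == "cable"
  # amplitude giving each cable strain = cable_prestrain
  EA_cable <- (m$E_MPa * m$area_um2)[which(cables)[1]]
  L_cable <- L[which(cables)[1]]
  s <- cable_prestrain * EA_cable / L_cable
  N <- s * selfstress$force_density * L
  if (!is.null(strut_force_floor_uN) &&
    any(-N[!cables] > strut_force_floor_uN)) {
    warn(
      sprintf(
        "Strut compression (max %.3g uN) exceeds the supplied force floor (%.3g uN); buckling is not modelled.",
        max(-N[!cables]), strut_force_floor_uN
      ),
      class = "cytomech_buckling_warning"
    )
  }
  EA <- m$E_MPa * m$area_um2
  g$members$rest_length_um <- L / (1 + N / EA)
  g$members$length_um <- L
  attr(g, "cable_prestrain") <- cable_prestrain
  g
}

#' Boundary conditions for the tensegrity solver
#'
#' Collects per-axis supports, prescribed displacements and point loads.
#' A degree of freedom may carry a load or a prescribed displacement, not
#' both. Axes are `1, 2, 3` for x, y, z.
#'
#' @param fixed Tibble/data frame with columns `node`, `axis`: fully
#'   locked DOFs (prescribed displacement zero).
#' @param prescribed Tibble with columns `node`, `axis`, `value_um`:
#'   displacement-driven DOFs.
#' @param loads Tibble with columns `node`, `axis`, `value_uN`:
#'   force-driven DOFs.
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(fixed = NULL, prescribed = NULL, loads = NULL) {
  fixed <- if (is.null(fixed)) tibble(node = integer(), axis = integer()) else as_tibble(fixed)
  prescribed <- if (is.null(prescribed)) {
    tibble(node = integer(), axis = integer(), value_um = numeric())
  } else {
    as_tibble(prescribed)
  }
  loads <- if (is.null(loads)) {
    tibble(node = integer(), axis = integer(), value_uN = numeric())
  } else {
    as_tibble(loads)
  }
  disp_keys <- c(
    paste(fixed$node, fixed$axis),
    paste(prescribed$node, prescribed$axis)
  )
  if (anyDuplicated(disp_keys)) {
    abort("A DOF appears more than once among fixed/prescribed entries.",
      class = "cytomech_config_error"
    )
  }
  clash <- intersect(disp_keys, paste(loads$node, loads$axis))
  if (length(clash) > 0) {
    abort("A DOF cannot be both load-driven and displacement-driven.",
      class = "cytomech_config_error"
    )
  }
  structure(list(fixed = fixed, prescribed = prescribed, loads = loads),
    class = "boundary_conditions"
  )
}

#' Fully fix the lowest nodes of a graph
#'
#' Support helper mimicking focal adhesion sites: the `n` nodes with the
#' lowest z coordinate are locked in all three translations.
#'
#' @param g A `tensegrity` object.
#' @param n Number of nodes to fix (default 4).
#' @return A `boundary_conditions` object.
#' @export
fix_bottom_nodes <- function(g, n = 4) {
  ord <- order(g$nodes$z_um)[seq_len(n)]
  boundary_conditions(fixed = tidyr::expand_grid(node = ord, axis = 1:3))
}

#' Solver settings
#'
#' @param n_increments Load/displacement increments (default 50).
#' @param newton_tol Residual norm tolerance, µN (default 1e-10).
#' @param max_newton_iter Newton iterations per increment (default 50).
#' @param regularization Diagonal stiffness floor (µN/µm) added to the
#'   tangent so fully slack configurations stay solvable; it does not
#'   alter the converged equilibrium (default 1e-10).
#' @param cable_model Only `"slack_bilinear"` is implemented: cables carry
#'   linear tension, zero force and stiffness in compression.
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(n_increments = 50, newton_tol = 1e-10,
                            max_newton_iter = 50, regularization = 1e-10,
                            cable_model = "slack_bilinear") {
  stopifnot(newton_tol > 0, n_increments >= 1)
  cable_model <- match.arg(cable_model, "slack_bilinear")
  structure(
    list(
      n_increments = n_increments, newton_tol = newton_tol,
      max_newton_iter = max_newton_iter, regularization = regularization,
      cable_model = cable_model
    ),
    class = "solver_settings"
  )
}

#' Static equilibrium of a tensegrity under loads and displacements
#'
#' Incremental Newton solver for the geometrically nonlinear, tension-only
#' cable truss. Loads and prescribed displacements are ramped over
#' `settings$n_increments` increments; within each, full Newton iterations
#' with the consistent tangent and a halving line search drive the free
#' residual below `settings$newton_tol`.
#'
#' @param g A (normally prestressed) `tensegrity` object.
#' @param bc A `boundary_conditions` object.
#' @param settings A `solver_settings` object.
#' @param u0 Optional initial displacement guess (length 36), for
#'   continuation across solves.
#' @return A `tenseg_solution`: list with `nodes` (deformed positions and
#'   displacements), `members` (with `force_uN`; cables clipped at zero),
#'   `reactions` (tibble `node`, `axis`, `R_uN` at constrained DOFs),
#'   `converged`, `iterations`, `residual_norm`.
#' @export
solve_static <- function(g, bc = boundary_conditions(),
                         settings = solver_settings(), u0 = NULL) {
  stopifnot(inherits(g, "tensegrity"), inherits(bc, "boundary_conditions"))
  ndof <- 3L * nrow(g$nodes)
  pd <- c(
    dof_index(bc$fixed$node, bc$fixed$axis),
    dof_index(bc$prescribed$node, bc$prescribed$axis)
  )
  pd_val <- c(rep(0, nrow(bc$fixed)), bc$prescribed$value_um)
  free <- setdiff(seq_len(ndof), pd)
  f_full <- numeric(ndof)
  f_full[dof_index(bc$loads$node, bc$loads$axis)] <- bc$loads$value_uN
  if (length(free) == ndof && attr(g, "cable_prestrain") == 0 &&
    settings$regularization <= 0) {
    abort("Unsupported, unprestressed graph with zero regularization is a mechanism.",
      class = "cytomech_singular_system"
    )
  }
  u <- if (is.null(u0)) numeric(ndof) else u0
  total_iter <- 0L
  converged <- TRUE
  res_norm <- NA_real_
  for (inc in seq_len(settings$n_increments)) {
    a <- inc / settings$n_increments
    u[pd] <- a * pd_val
    f <- a * f_full
    r <- internal_forces(g, u) - f
    res_norm <- sqrt(sum(r[free]^2))
    it <- 0L
    while (res_norm > settings$newton_tol && it < settings$max_newton_iter) {
      K <- tangent_stiffness(g, u)
      if (settings$regularization > 0) {
        diag(K) <- diag(K) + settings$regularization
      }
      du <- tryCatch(
        solve(K[free, free, drop = FALSE], -r[free]),
        error = function(e) {
          abort("Singular tangent stiffness: mechanism motion without prestress/regularization.",
            class = "cytomech_singular_system", parent = e
          )
        }
      )
      step <- 1
      repeat {
        u_try <- u
        u_try[free] <- u[free] + step * du
        r_try <- internal_forces(g, u_try) - f
        new_norm <- sqrt(sum(r_try[free]^2))
        if (new_norm < res_norm || step < 1 / 128 || new_norm <= settings$newton_tol) break
        step <- step / 2
      }
      u <- u_try
      r <- r_try
      res_norm <- new_norm
      it <- it + 1L
    }
    total_iter <- total_iter + it
    if (res_norm > settings$newton_tol) {
      converged <- FALSE
      break
    }
  }
  st <- member_state(g, u)
  P <- node_positions(g, u)
  grad <- internal_forces(g, u)
  R <- grad - f_full
  reactions <- tibble(
    node = c(bc$fixed$node, bc$prescribed$node),
    axis = c(bc$fixed$axis, bc$prescribed$axis),
    R_uN = R[pd]
  )
  structure(
    list(
      nodes = tibble(
        node = g$nodes$node,
        x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
        ux_um = u[dof_index(g$nodes$node, 1)],
        uy_um = u[dof_index(g$nodes$node, 2)],
        uz_um = u[dof_index(g$nodes$node, 3)]
      ),
      members = mutate(g$members, force_uN = st$N, length_um = st$L),
      reactions = reactions,
      applied_loads = bc$loads,
      u = u,
      converged = converged,
      iterations = total_iter,
      residual_norm = res_norm
    ),
    class = "tenseg_solution"
  )
}

#' @export
print.tenseg_solution <- function(x, ...) {
  cat(sprintf(
    "<tenseg_solution> converged: %s | iterations: %d | residual %.3e uN\n",
    x$converged, x$iterations, x$residual_norm
  ))
  invisible(x)
}

#' Indentation force-displacement sweep
#'
#' Quasi-static indentation of the prestressed cytoskeleton: the nodes
#' whose built height exceeds the descending contact plane are displaced
#' down onto it (axial DOF prescribed; lateral DOFs free), the bottom
#' support of `bc_base` holds the cell, and the reaction transmitted to
#' the indenter is recorded at each depth. Solutions continue from the
#' previous depth, so the whole sweep is a single equilibrium path.
#'
#' @param g A prestressed `tensegrity` object.
#' @param delta_max_um Maximum indentation depth, µm.
#' @param n_steps Number of depths sampled (default 50).
#' @param bc_base Support boundary conditions (default
#'   [fix_bottom_nodes()] with 4 nodes).
#' @param settings Solver settings; each depth step is solved in a single
#'   increment continuing from the previous one.
#' @return A `cyto_curve` tibble: `delta_um`, `force_nN` (indenter
#'   reaction, nN), with solver metadata attributes.
#' @export
indentation_sweep <- function(g, delta_max_um, n_steps = 50,
                              bc_base = fix_bottom_nodes(g),
                              settings = solver_settings()) {
  stopifnot(delta_max_um > 0)
  z0 <- g$nodes$z_um
  z_top <- max(z0)
  deltas <- seq(0, delta_max_um, length.out = n_steps + 1)
  u <- NULL
  force <- numeric(length(deltas))
  conv <- logical(length(deltas))
  step_settings <- modifyList(settings, list(n_increments = 1))
  class(step_settings) <- class(settings)
  for (k in seq_along(deltas)) {
    d <- deltas[k]
    contact <- which(z0 > z_top - d + 1e-12)
    if (d == 0 || length(contact) == 0) {
      force[k] <- 0
      conv[k] <- TRUE
      next
    }
    presc <- tibble(
      node = contact, axis = 3L,
      value_um = (z_top - d) - z0[contact]
    )
    bc <- boundary_conditions(
      fixed = bc_base$fixed,
      prescribed = presc, loads = bc_base$loads
    )
    sol <- solve_static(g, bc, step_settings, u0 = u)
    u <- sol$u
    idx <- sol$reactions$node %in% contact & sol$reactions$axis == 3L
    force[k] <- -sum(sol$reactions$R_uN[idx])
    conv[k] <- sol$converged
    if (!sol$converged) {
      warn(sprintf("Indentation sweep stopped at delta = %.4g um (solver not converged); curve truncated.", d))
      force <- force[seq_len(k)]
      deltas <- deltas[seq_len(k)]
      conv <- conv[seq_len(k)]
      break
    }
  }
  new_curve(
    tibble(delta_um = deltas, force_nN = force * 1e3),
    meta = list(
      kind = "tensegrity_indentation",
      orientation = attr(g, "orientation"),
      cable_prestrain = attr(g, "cable_prestrain"),
      converged = all(conv)
    )
  )
}

#' Aspiration loading of the cytoskeleton
#'
#' Builds the boundary conditions of a micropipette pull: nodes on the
#' aspirated (top) side lying within the pipette radius share the total
#' suction force `dP * pi * R_p^2` equally as axial point loads; the
#' support of `bc_base` (bottom nodes, opposite pole) is retained.
#'
#' @param g A `tensegrity` object.
#' @param R_p_um Pipette radius, µm (must be below the cell radius).
#' @param dP_MPa Pressure step magnitude, MPa.
#' @param bc_base Support boundary conditions (default
#'   [fix_bottom_nodes()]).
#' @return A `boundary_conditions` object; attribute `n_inside` records
#'   how many nodes are loaded. Zero nodes inside the pipette raises an
#'   empty-load warning.
#' @export
aspiration_load <- function(g, R_p_um, dP_MPa, bc_base = fix_bottom_nodes(g)) {
  R_cell <- attr(g, "R_cell_um")
  if (R_p_um <= 0 || R_p_um >= R_cell) {
    abort("`R_p_um` must lie in (0, R_cell).", class = "cytomech_config_error")
  }
  radial <- sqrt(g$nodes$x_um^2 + g$nodes$y_um^2)
  inside <- which(radial < R_p_um & g$nodes$z_um > 0)
  total <- dP_MPa * pi * R_p_um^2
  if (length(inside) == 0) {
    warn("No tensegrity nodes inside the pipette radius; aspiration load is empty.",
      class = "cytomech_empty_load"
    )
    loads <- NULL
  } else {
    loads <- tibble(node = inside, axis = 3L, value_uN = total / length(inside))
  }
  bc <- boundary_conditions(fixed = bc_base$fixed, loads = loads)
  attr(bc, "n_inside") <- length(inside)
  attr(bc, "total_load_uN") <- if (length(inside)) total else 0
  bc
}
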