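#' Cell geometry descriptor
#'
#' Records the gross geometry of an adherent rounded cell: radius, adherent
#' height, substrate contact radius, nucleus ellipsoid semi-axes and
#' membrane thickness. Defaults describe a 16 µm diameter cell adhering at
#' ~14 µm height with an 8 x 5 µm (major x minor axis) nucleus and a 6 nm
#' membrane.
#'
#' @param R_cell_um Cell radius, µm.
#' @param height_um Adherent cell height, µm, in `(0, 2 R_cell]`.
#' @param contact_radius_um Substrate contact radius, µm; default computed
#'   from the spherical cap via [spherical_cap_contact()].
#' @param nucleus_semiaxes_um Length-3 vector `(a, a, c)` of nucleus
#'   semi-axes, µm.
#' @param membrane_thickness_um Membrane thickness, µm (6 nm default).
#' @return A one-row `cell_geometry` tibble.
#' @export
cell_geometry <- function(R_cell_um = 8, height_um = 14,
                          contact_radius_um = spherical_cap_contact(R_cell_um, height_um),
                          nucleus_semiaxes_um = c(4, 4, 2.5),
                          membrane_thickness_um = 6e-3) {
  stopifnot(R_cell_um > 0, length(nucleus_semiaxes_um) == 3)
  if (height_um <= 0 || height_um > 2 * R_cell_um) {
    abort("`height_um` must lie in (0, 2*R_cell_um].", class = "cytomech_domain_error")
  }
  if (contact_radius_um >= R_cell_um) {
    abort("`contact_radius_um` must be smaller than `R_cell_um`.",
      class = "cytomech_domain_error"
    )
  }
  out <- tibble(
    R_cell_um = R_cell_um, height_um = height_um,
    contact_radius_um = contact_radius_um,
    nucleus_a_um = nucleus_semiaxes_um[1], nucleus_c_um = nucleus_semiaxes_um[3],
    membrane_thickness_um = membrane_thickness_um
  )
  class(out) <- c("cell_geometry", class(out))
  out
}

#' Contact radius of a truncated sphere
#'
#' A sphere of radius `R` resting on a plane with apex height `h` above it
#' (so `R < h <= 2R`) meets the plane in a circle of radius
#' `sqrt(R^2 - (h - R)^2)`. For an 8 µm cell at 14 µm height this gives
#' `sqrt(28) ~ 5.29` µm, close to the ~6 µm conventionally assumed for
#' adherent chondrocytes.
#'
#' @param R_cell_um Sphere radius, µm.
#' @param height_um Truncated height, µm, in `(0, 2 R_cell]`
#'   (`height = R` is the hemisphere, `height = 2R` the full sphere
#'   touching at a point).
#' @return Contact radius, µm.
#' @export
spherical_cap_contact <- function(R_cell_um, height_um) {
  if (any(height_um <= 0 | height_um > 2 * R_cell_um)) {
    abort("`height_um` must lie in (0, 2*R_cell_um].",
      class = "cytomech_domain_error"
    )
  }
  sqrt(R_cell_um^2 - (height_um - R_cell_um)^2)
}

#' Build the 6-strut / 24-cable tensegrity cytoskeleton
#'
#' Constructs the classic expanded-octahedron (Jessen icosahedron)
#' tensegrity inscribed in a sphere of radius `R_cell_um`: the 12 nodes are
#' the cyclic permutations of `(0, ±1, ±2)` scaled by `u = R/sqrt(5)`, the
#' 6 struts (microtubules, compression) join the node pairs differing only
#' in the sign of their `±2` coordinate (length `4u`), and the 24 cables
#' (actin microfilaments, tension) are the edges of length `sqrt(6) u`.
#' Each node joins exactly one strut and four cables; the cable/strut
#' length ratio is `sqrt(6)/4`.
#'
#' `orientation = "config1"` places one strut pair along the loading (z)
#' axis with its nodes nearest the poles; `"config2"` is the same
#' structure rotated 45 degrees about the horizontal (y) axis, presenting
#' a different face — and a different set of receptor nodes — to the
#' indenter or pipette. (A rotation about the loading axis itself would
#' leave every axisymmetric loading problem unchanged, so the two
#' dispositions must differ by a rotation with a horizontal component.)
#' Arbitrary orientations can be explored through `rotation_deg` and
#' `rotation_axis`, overriding `orientation`.
#'
#' @param R_cell_um Circumscribing sphere radius, µm.
#' @param orientation `"config1"` or `"config2"`.
#' @param rotation_deg Optional rotation angle in degrees about
#'   `rotation_axis` (overrides `orientation`).
#' @param rotation_axis `"x"`, `"y"` or `"z"`; used with `rotation_deg`.
#' @param area_strut_um2 Strut cross-section, µm² (default 190 nm² = 1.9e-4).
#' @param area_cable_um2 Cable cross-section, µm² (default 18 nm² = 1.8e-5).
#' @param E_strut_MPa,E_cable_MPa Young's moduli of strut and cable
#'   material; defaults are the microtubule and microfilament moduli of
#'   [cell_type_1()].
#' @return A `tensegrity` object: list with `nodes` (tibble: `node`, `x_um`,
#'   `y_um`, `z_um`) and `members` (tibble: `member`, `i`, `j`, `kind`,
#'   `area_um2`, `E_MPa`, `length_um`, `rest_length_um`), plus metadata
#'   attributes. Rest lengths equal built lengths until
#'   [apply_prestress()] is used.
#' @examples
#' g <- build_tensegrity(8)
#' validate_topology(g)
#' @export
build_tensegrity <- function(R_cell_um = 8,
                             orientation = c("config1", "config2"),
                             rotation_deg = NULL, rotation_axis = "y",
                             area_strut_um2 = 1.9e-4, area_cable_um2 = 1.8e-5,
                             E_strut_MPa = 1.53e4, E_cable_MPa = 3.32e4) {
  orientation <- match.arg(orientation)
  stopifnot(R_cell_um > 0)
  u <- R_cell_um / sqrt(5)
  base <- rbind(
    c(0, 1, 2), c(0, 1, -2), c(0, -1, 2), c(0, -1, -2),
    c(2, 0, 1), c(-2, 0, 1), c(2, 0, -1), c(-2, 0, -1),
    c(1, 2, 0), c(1, -2, 0), c(-1, 2, 0), c(-1, -2, 0)
  )
  xyz <- base * u
  ang <- if (!is.null(rotation_deg)) {
    rotation_deg * pi / 180
  } else if (orientation == "config2") pi / 4 else 0
  if (ang != 0) {
    axis <- if (!is.null(rotation_deg)) match.arg(rotation_axis, c("x", "y", "z")) else "y"
    c_ <- cos(ang)
    s_ <- sin(ang)
    rot <- switch(axis,
      x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
      y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
      z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
    )
    xyz <- xyz %*% t(rot)
  }
  nodes <- tibble(
    node = seq_len(12),
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3]
  )
  # struts: pairs differing only in the sign of the "2" coordinate
  struts <- cbind(
    i = c(1L, 3L, 5L, 7L, 9L, 11L),
    j = c(2L, 4L, 6L, 8L, 10L, 12L)
  )
  # cables: edges at squared distance 6 u^2 in the unscaled lattice
  d2 <- as.matrix(stats::dist(base))^2
  idx <- which(upper.tri(d2) & abs(d2 - 6) < 1e-9, arr.ind = TRUE)
  cables <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  members <- tibble(
    i = c(struts[, "i"], cables[, "i"]),
    j = c(struts[, "j"], cables[, "j"]),
    kind = rep(c("strut", "cable"), c(nrow(struts), nrow(cables))),
    area_um2 = rep(c(area_strut_um2, area_cable_um2), c(nrow(struts), nrow(cables))),
    E_MPa = rep(c(E_strut_MPa, E_cable_MPa), c(nrow(struts), nrow(cables)))
  ) |>
    mutate(member = row_number(), .before = 1)
  members$length_um <- member_lengths(nodes, members)
  members$rest_length_um <- members$length_um
  structure(
    list(nodes = nodes, members = members),
    class = "tensegrity",
    R_cell_um = R_cell_um,
    orientation = if (!is.null(rotation_deg)) sprintf("rotated_%gdeg", rotation_deg) else orientation,
    cable_prestrain = 0
  )
}

member_lengths <- function(nodes, members) {
  P <- as.matrix(nodes[, c("x_um", "y_um", "z_um")])
  sqrt(rowSums((P[members$i, , drop = FALSE] - P[members$j, , drop = FALSE])^2))
}

#' Validate tensegrity topology
#'
#' Checks the structural facts that define the 6-strut/24-cable
#' cytoskeleton graph: exactly 12 nodes, 6 struts and 24 cables; every node
#' incident to exactly 1 strut and 4 cables; all strut lengths equal and
#' all cable lengths equal (relative spread below `tol`).
#'
#' @param g A `tensegrity` object.
#' @param tol Relative length-uniformity tolerance (default 1e-9).
#' @return A tibble of violations (columns `check`, `detail`); zero rows
#'   means the graph is valid.
#' @export
validate_topology <- function(g, tol = 1e-9) {
  stopifnot(inherits(g, "tensegrity"))
  v <- list()
  note <- function(check, detail) tibble(check = check, detail = detail)
  if (nrow(g$nodes) != 12) v <- c(v, list(note("node_count", sprintf("%d nodes, expected 12", nrow(g$nodes)))))
  n_strut <- sum(g$members$kind == "strut")
  n_cable <- sum(g$members$kind == "cable")
  if (n_strut != 6) v <- c(v, list(note("strut_count", sprintf("%d struts, expected 6", n_strut))))
  if (n_cable != 24) v <- c(v, list(note("cable_count", sprintf("%d cables, expected 24", n_cable))))
  inc <- function(kind) {
    m <- g$members[g$members$kind == kind, ]
    tabulate(c(m$i, m$j), nbins = nrow(g$nodes))
  }
  deg_s <- inc("strut")
  deg_c <- inc("cable")
  bad <- which(deg_s != 1 | deg_c != 4)
  for (k in bad) {
    v <- c(v, list(note(
      "node_degree",
      sprintf("node %d touches %d strut(s) and %d cable(s), expected 1 and 4", k, deg_s[k], deg_c[k])
    )))
  }
  L <- member_lengths(g$nodes, g$members)
  for (kind in c("strut", "cable")) {
    Lk <- L[g$members$kind == kind]
    if (length(Lk) > 1 && diff(range(Lk)) > tol * mean(Lk)) {
      v <- c(v, list(note(
        "length_uniformity",
        sprintf("%s lengths spread %.3e relative", kind, diff(range(Lk)) / mean(Lk))
      )))
    }
  }
  if (length(v) == 0) {
    tibble(check = character(), detail = character())
  } else {
    bind_rows(v)
  }
}

#' @export
print.tensegrity <- function(x, ...) {
  cat(sprintf(
    "<tensegrity> %d nodes, %d struts, %d cables | R = %g um | %s | cable prestrain %g\n",
    nrow(x$nodes), sum(x$members$kind == "strut"), sum(x$members$kind == "cable"),
    attr(x, "R_cell_um"), attr(x, "orientation"), attr(x, "cable_prestrain")
  ))
  invisible(x)
}

#' Export a tensegrity graph
#'
#' Writers for tool-agnostic inspection: Wavefront OBJ (nodes as vertices,
#' members as line elements), legacy-VTK polydata, and a plain TSV edge
#' list (`node_i`, `node_j`, `kind`, `length_um`).
#'
#' @param g A `tensegrity` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tensegrity_obj <- function(g, path) {
  lines <- c(
    "# cytomech tensegrity export",
    sprintf("v %.9g %.9g %.9g", g$nodes$x_um, g$nodes$y_um, g$nodes$z_um),
    sprintf("l %d %d", g$members$i, g$members$j)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tensegrity_obj
#' @export
write_tensegrity_vtk <- function(g, path) {
  n <- nrow(g$nodes)
  m <- nrow(g$members)
  lines <- c(
    "# vtk DataFile Version 3.0",
    "cytomech tensegrity", "ASCII", "DATASET POLYDATA",
    sprintf("POINTS %d double", n),
    sprintf("%.9g %.9g %.9g", g$nodes$x_um, g$nodes$y_um, g$nodes$z_um),
    sprintf("LINES %d %d", m, 3 * m),
    sprintf("2 %d %d", g$members$i - 1L, g$members$j - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tensegrity_obj
#' @export
write_tensegrity_edges <- function(g, path) {
  df <- tibble(
    node_i = g$members$i, node_j = g$members$j,
    kind = g$members$kind,
    length_um = member_lengths(g$nodes, g$members)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
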