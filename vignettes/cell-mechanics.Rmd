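---
title: "Reduced-order continuum and continuum-tensegrity models of single-cell mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order continuum and continuum-tensegrity models of single-cell mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomech)
```

## The problem

Two experiments dominate single-cell micromechanics. In **AFM indentation**
a cantilever with a spherical tip presses into the top of an adherent cell
at constant velocity, holds at a target depth, and records force versus
depth and time; the hold phase shows stress relaxation. In **micropipette
aspiration (MPA)** a glass pipette applies a negative pressure to the cell
surface and the aspirated projection length $L_p$ creeps toward an
asymptote. Both probe the same viscoelastic machinery — cytoplasm,
cytoskeleton, membrane, nucleus — from opposite sides (compression vs
tension), and both are routinely interpreted through closed-form
half-space models whose assumptions real cells violate.

`cytomech` implements the reduced-order counterpart of a
continuum-tensegrity description of a chondrocyte-like cell: the
homogeneous continuum model (CM) responds through analytical contact and
aspiration mechanics with a standard-linear-solid (SLS) cytoplasm, and
the combined continuum-tensegrity model (CTM) adds a prestressed
6-strut/24-cable cytoskeletal structure whose reaction is coupled in
parallel. The aim is not to reproduce full finite-element force curves —
that requires a volumetric mesh, contact and tie constraints far outside
a desk-scale package — but to expose, test and invert every analytical
ingredient those simulations are compared against, and to reproduce the
structural facts and directional conclusions of the combined model.

## Unit system

Lengths are in µm, moduli and pressures in MPa, times in s, forces in µN
(1 MPa·µm² = 1 µN). Column names carry units (`E_MPa`, `delta_um`,
`Lp_um`); curve objects report force in nN (1 µN = 1000 nN), which is the
natural scale of cell experiments. The CLI accepts pressures with `Pa`,
`kPa` or `MPa` suffixes.

## Materials

Each of the five subcomponents carries a linear-elastic pair $(E, \nu)$,
a compressible Neo-Hookean pair derived from it as

$$C_{10} = \frac{E}{4(1+\nu)} = \frac{\mu}{2}, \qquad
  D_1 = \frac{6(1-2\nu)}{E} = \frac{2}{K},$$

and, for the cytoplasm only, the SLS triplet $(E_R, \tau_\sigma,
\tau_\varepsilon)$: the lone spring $k_1 = E_R$, the relaxation times
under constant load and constant deformation, with
$\tau_\sigma \ge \tau_\varepsilon$ guaranteeing a non-negative Maxwell
spring $k_2 = E_R(\tau_\sigma/\tau_\varepsilon - 1)$ and dashpot
$\eta = k_2 \tau_\varepsilon$. The relaxation modulus is

$$E(t) = E_R\left(1 + \frac{\tau_\sigma - \tau_\varepsilon}
  {\tau_\varepsilon}e^{-t/\tau_\varepsilon}\right),$$

decaying from $E_0 = E_R \tau_\sigma/\tau_\varepsilon$ to $E_R$. Two
bundled sets, `cell_type_1()` and `cell_type_2()`, differ by a cytoplasm
stiffness ratio $Q = E_{el,1}/E_{el,2} = 12.8$ (conventionally quoted as
12.78 from unrounded inputs); `scale_materials()` multiplies or divides
every non-fixed subcomponent modulus by $Q$ and re-derives the
Neo-Hookean pairs, generating the stiffer/softer variants used to probe
the cytoskeleton's role.

```{r}
cell_type_1()
sls_derive(4.5e-4, 19.7, 9.5, nu = 0.37)
```

Two conventions are preserved exactly as they circulate in the
indentation literature, each behind an explicit option rather than a
silent correction:

* the Hertz loading force carries $1-\nu^2$ in its denominator while the
  SLS relaxation force carries $1-\nu$; `hertz_force()` and
  `hertz_sls_force()` default to their respective printed forms and
  accept a `denominator` argument to force either;
* the long-term modulus reported from relaxation fits is
  $E_\infty = E_R(1+\nu)$, which mixes Poisson's ratio into a
  time-domain modulus (an indentation-geometry convention);
  `sls_derive(einf_convention = "shear_consistent")` returns the plain
  $E_R$ instead.

Tabulated comparisons use 1% relative tolerance throughout because the
reference tables print three significant figures.

## The tensegrity cytoskeleton

The cytoskeleton is the classic expanded-octahedron (Jessen icosahedron)
tensegrity: 12 nodes at the cyclic permutations of $(0, \pm 1, \pm 2)$
scaled by $u = R/\sqrt{5}$, so all nodes lie on the cell sphere; 6 struts
(microtubules, cross-section 190 nm²) of length $4u$ joining the pairs
that differ only in the sign of their $\pm 2$ coordinate; 24 cables
(actin microfilaments, 18 nm²) of length $\sqrt{6}\,u$. Every node joins
exactly one strut and four cables and the cable/strut length ratio is
$\sqrt{6}/4$. `validate_topology()` checks all of this and reports
violations as data.

Form finding uses the force-density method: the one-dimensional null
space of the nodal equilibrium matrix, normalised to cable force density
$+1$, puts every strut at $-3/2$ and the member-force magnitude ratio at
$\sqrt{6}$. `apply_prestress()` converts a chosen cable prestrain into
rest lengths ($L_0 = L/(1 + N/EA)$) so the built geometry is exactly
self-equilibrated. Tensegrities are mechanisms without prestress, so a
positive prestrain is mandatory; no experimental value is available for
the absolute cytoskeletal prestress, and the package default of 0.01
cable strain is a round, small-strain choice reported in every output
and exposed as an argument. Euler buckling of struts is not modelled
(the members are straight truss elements); an optional force floor
triggers a warning instead, off by default because the idealised
pinned-strut buckling load of an isolated nanometre-scale filament is
far below any useful prestress while filaments in cells are laterally
reinforced.

### Orientations

`orientation = "config1"` puts one strut pair along the loading axis with
its nodes nearest the poles. For the second disposition, note that any
rotation *about the loading axis itself* maps the whole boundary-value
problem (axial loads assigned by radial distance from the axis,
lowest-node supports) onto its rotated image, so the response would be
exactly identical — a useful invariance, which the test suite asserts,
but not a second configuration in any physical sense. `"config2"` is
therefore a 45° rotation about a *horizontal* axis: it presents a
different face to the pipette or indenter, changes how many receptor
nodes fall inside the pipette mouth, and produces genuinely different
aspirated-pole displacements. Arbitrary axis/angle combinations are
available through `rotation_deg`/`rotation_axis`.

## The nonlinear solver

`solve_static()` is an incremental Newton solver on the 36 nodal degrees
of freedom. Members are large-displacement bars with engineering strain
on the rest length; the consistent tangent adds the material term
$k\,\mathbf{n}\mathbf{n}^\top$ and the geometric (prestress) term
$(N/L)(\mathbf{I}-\mathbf{n}\mathbf{n}^\top)$. Cables are tension-only:
zero force and stiffness in compression, linear in tension. Numerical
choices:

* the bilinear cable law is regularised by a C1 quadratic transition of
  half-width $10^{-6}$ strain around zero; the taut branch is exactly
  linear (so prestress equilibrium is exact) and a nearly slack cable
  carries at most $EA \cdot 10^{-6}/4 \approx 10^{-7}$ µN of residual
  tension. Without this, full Newton steps chatter between slack/taut
  active sets at coarse load increments;
* 50 increments by default, Newton tolerance $10^{-10}$ µN on the free
  residual norm, a halving line search on residual growth, and an
  optional diagonal stiffness floor ($10^{-10}$ µN/µm) for fully slack
  configurations;
* supports mimic focal adhesions: the four lowest nodes are fully fixed
  by default (`fix_bottom_nodes()`), exposed as an argument;
* ties in "lowest node" selection are broken by node index, which is
  deterministic for the bundled orientations.

`indentation_sweep()` prescribes the axial coordinate of every node
above the descending contact plane (lateral components left free) and
records the indenter reaction; each depth continues from the previous
equilibrium, so the sweep is one quasi-static path. With the bundled
geometry only the two apex nodes are ever engaged at chondrocyte-scale
depths (the next node layer sits $R/\sqrt{5} \approx 3.6$ µm lower).
`aspiration_load()` distributes the total suction force
$\Delta P \cdot \pi R_p^2$ equally over the nodes inside the pipette
radius on the aspirated side; conservation of that total is exact by
construction. A pipette that captures no node raises an empty-load
warning and contributes no cytoskeletal stiffness.

## Analytical experiment models

Loading: Hertz contact of a rigid sphere (tip radius $R_{tip}$) on the
cell sphere through the equivalent radius
$R = (1/R_{cell} + 1/R_{tip})^{-1}$,
$F = \tfrac{4 E \sqrt{R}}{3(1-\nu^2)}\,\delta^{3/2}$. Relaxation: the
SLS step response
$F(t) = \tfrac{4 E_R \sqrt{R}\,\delta^{3/2}}{3(1-\nu)}
 \left(1 + \tfrac{\tau_\sigma-\tau_\varepsilon}{\tau_\varepsilon}
 e^{-t/\tau_\varepsilon}\right)$. Aspiration: the half-space creep form

$$L_p(t) = R_p \frac{\phi \Delta P}{\pi E_1}
  \left(1 - \frac{E_2}{E_1 + E_2} e^{-t/\tau}\right),$$

with punch coefficient $\phi \approx 2.1$ (a free parameter here; its
weak dependence on the pipette wall is not modelled), rising from
$R_p \phi \Delta P / \pi(E_1+E_2)$ to the elastic limit
$R_p \phi \Delta P / \pi E_1$. These half-space forms assume an
incompressible medium and infinitesimal strain; real cells are
compressible ($\nu \approx 0.35$–$0.4$) and aspirated strains are large,
which is precisely why the full simulations exist. The package flags the
assumption in output metadata and makes no fabricated compressibility
correction.

## Virtual experiments

`simulate_afm()` evolves the ramp-and-hold protocol (defaults: 9.5 µm/s
to 1.5 µm, 60 s hold, 2.5 µm tip) quasi-statically. The continuum force
is the hereditary (convolution) integral

$$F(t) = \frac{4\sqrt{R}}{3(1-\nu)}
  \int_0^t E(t-s)\, \mathrm d\!\left[\delta^{3/2}(s)\right],$$

evaluated by midpoint quadrature over the ramp (step tied to the
sampling interval, at least 400 cells); it reduces exactly to the Hertz
curve for an elastic material and converges to the step-relaxation
solution as the ramp quickens — at 9.5 µm/s the ramp lasts 0.16 s
against $\tau_\varepsilon = 9.5$ s and the hold phase tracks the step
form well within 1%. The explicit-dynamics transient of the reference
simulations (inertia, contact waves) is deliberately replaced by this
quasi-static evolution, consistent with the low loading rates and with
the quasi-static analytical references themselves.

`simulate_mpa()` propagates the creep solution through the 1 s pressure
ramp by Boltzmann superposition, in closed form; `ramp_s = 0` recovers
the pure step exactly, and the creep asymptote is ramp-independent. How
the cytoplasm SLS triplet maps onto the creep form's $(E_1, E_2, \tau)$
is not fixed by the source material; the package default is the
documented choice $E_1 = E_R$, $E_2 = k_2$, $\tau = \tau_\sigma$, and all
three are overridable arguments.

**Coupling.** The CTM adds the cytoskeletal response in parallel — i.e.
force-additive at matched displacement for AFM, and compliance-combined
at matched load for MPA, where the cytoskeletal term is the secant axial
stiffness of the aspirated pole nodes (a documented heuristic standing
in for the volumetric tie constraints of the full model). Parallel
coupling is the only reduced-order scheme that preserves both
components' individual calibrations; it is declared in the metadata of
every CTM output. Membrane and nucleus enter only through the Q-scaling
material sweeps — their continuum role cannot be reproduced without the
full mesh.

Two directional consequences follow and are asserted as inequalities in
the tests: the CTM is never softer than the CM in indentation, and never
aspirates further in MPA; the cytoskeletal reduction of $L_p$ grows as
$D_c/D_p$ decreases (a wider pipette engages receptor nodes; at
$D_c/D_p = 3$ the bundled geometry has none inside the mouth and the CTM
coincides with the CM).

**A provable limitation.** Under displacement control the cytoskeletal
reaction is positively homogeneous of degree one in the fibre moduli:
scaling every member stiffness by $Q$ leaves the equilibrium path
unchanged and scales all forces by exactly $Q$. The full-model
observation that *softening* the subcomponents changes the response
relatively more than *stiffening* them — a saturation effect of the
series compliance between cytoskeleton and continuum — therefore cannot
arise in this reduced class. The tests assert the directions and the
exact Q-homogeneity instead.

## Synthetic curves and inverse fitting

`generate_synthetic_curve()` evaluates one of the three closed forms on
a regular grid (600 points by default over a 60 s hold or 1.5 µm ramp)
and applies multiplicative Gaussian noise $x(1 + \mathcal N(0, sd))$,
deterministic given a seed. It emulates the sampling density and noise
floor of a clean single-cell record; it does **not** emulate drift,
contact-point mis-identification, adhesion tails, instrument filtering
or cell-to-cell variability, so passing recovery tests demonstrate
identifiability of the models under their own assumptions, not
robustness to real-world artefacts.

The fitters hold the geometry fixed and estimate only material
parameters:

* `fit_hertz()` — $E$ is linear in the model, closed-form least squares;
* `fit_sls_relaxation()` — nonlinear least squares in
  $(E_R, \tau_\varepsilon, \Delta\tau \ge 0)$ with
  $\tau_\sigma = \tau_\varepsilon + \Delta\tau$, which enforces
  $\tau_\sigma \ge \tau_\varepsilon$ by construction;
* `fit_sato_creep()` — nonlinear least squares in the amplitude/ratio
  form $a(1 - r e^{-t/\tau})$, mapped back to $(E_1, E_2)$.

Both nonlinear fits start from asymptote-derived values (tail level,
initial/final ratio, log-linear decay rate) refined by a deterministic
5-point multi-start (time constants scaled by 0.3/3), Levenberg-
Marquardt with a relative tolerance of $10^{-12}$, and report
Jacobian-based standard errors with an optional seeded 200-resample
bootstrap. Degenerate records are recognised rather than failed: a
constant force returns the single-spring limit
$\tau_\sigma = \tau_\varepsilon$, a flat creep record returns $E_2 = 0$.
A hold shorter than the fitted $\tau_\varepsilon$ triggers a
wide-uncertainty warning. Fits are invariant to consistent time-unit
rescaling, and closed-loop recovery (fit applied to its own noise-free
forward model) is exact to well below 0.1% across the admissible
parameter range.

```{r}
R_eq <- equivalent_radius(8, 2.5)
curve <- generate_synthetic_curve(
  "hertz_sls",
  list(
    E_R_MPa = 4.5e-4, tau_sigma_s = 19.7, tau_epsilon_s = 9.5,
    nu = 0.37, R_eq_um = R_eq, delta_um = 1.5
  ),
  noise_sd = 0.05, seed = 1
)
tidy(fit_sls_relaxation(curve, nu = 0.37, R_eq_um = R_eq, delta_um = 1.5))
```

## Problem sizes and verification scope

The structural model has 12 nodes / 30 members / 36 degrees of freedom,
solved densely; a 50-step indentation sweep completes in about a second.
Verification couples every component to an independent oracle: pairwise
distance enumeration for the graph, a second null-space implementation
for the self-stress, finite differences of the strain energy for the
residual and tangent, frozen 50-digit evaluations for the closed forms,
increment/step refinement for the path quantities, and seeded
50-replicate Monte-Carlo recovery (600 samples, 5% noise) for the
fitters. Acceptance-level quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* No volumetric continuum: membrane and nucleus have no independent
  mechanical channel; bottom-substrate effects and pipette fillet
  geometry are absent.
* Parallel coupling is a stand-in for tie constraints; it bounds the CTM
  on the stiff side and cannot show coupling-induced saturation (see
  above).
* Struts do not buckle; cables have no viscosity (the source model
  assigns viscoelasticity to the cytoplasm only).
* The half-space aspiration forms inherit their incompressibility and
  small-strain assumptions; the package reports them as metadata rather
  than correcting for them.
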