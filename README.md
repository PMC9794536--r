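# cytomech

Reduced-order continuum and continuum-tensegrity models of single-cell
mechanics, for the two workhorse experiments of cell biomechanics:

* **AFM indentation** — a spherical cantilever tip pressed into an
  adherent cell at constant velocity, then held (stress relaxation);
* **Micropipette aspiration (MPA)** — negative pressure at the cell
  surface, recording the creeping projection length inside the pipette.

The package is aimed at cell-mechanics researchers who interpret such
experiments on chondrocyte-like (or tumour-derived) cells and want the
analytical models, the cytoskeletal structural model and the inverse
fitting machinery in one tested, scriptable place.

## What it computes

**Analytical mechanics.** Hertz loading of a rigid sphere on the cell,
with equivalent radius `R = (1/R_cell + 1/R_tip)^-1`:

    F = 4 E √R δ^(3/2) / (3(1 − ν²))

standard-linear-solid (SLS) stress relaxation under a held indentation:

    F(t) = 4 E_R √R δ^(3/2) / (3(1 − ν)) · (1 + ((τσ − τε)/τε) e^(−t/τε))

and half-space aspiration creep with punch coefficient φ ≈ 2.1:

    L_p(t) = R_p (φΔP / (π E₁)) (1 − (E₂/(E₁+E₂)) e^(−t/τ))

**Materials.** Per-subcomponent parameter sets (cytoplasm, microtubules,
microfilaments, membrane, nucleus) with exact conversions between
linear-elastic and compressible Neo-Hookean descriptions
(`C10 = E/4(1+ν)`, `D1 = 6(1−2ν)/E`), SLS algebra
(`E₀ = E_R τσ/τε`, `k₂`, `η`), and Q-ratio scaling that generates
stiffer/softer cell variants while holding chosen subcomponents fixed.

**Cytoskeleton.** The classic 6-strut/24-cable expanded-octahedron
tensegrity (12 nodes on the cell sphere; cable/strut length ratio
`√6/4`), form-found by the force-density method (struts at density −3/2
when cables are +1, member-force ratio `√6`), prestressed through rest
lengths, and solved by an incremental Newton method with tension-only
cables — driving virtual indentation sweeps and aspiration loadings.

**Virtual experiments and inversion.** Quasi-static indent-and-hold
(hereditary-integral continuum force + cytoskeletal reaction in
parallel) and step-and-creep (ramp handled by Boltzmann superposition in
closed form), plus seeded synthetic-curve generation and
Levenberg-Marquardt inverse fits recovering `E`, `(E_R, τσ, τε)` or
`(E₁, E₂, τ)` from force/creep records.

## Worked example

```r
library(cytomech)

# membrane elastic parameters -> Neo-Hookean
elastic_to_neohookean(1.28e-2, 0.3)
#> # A tibble: 1 × 3
#>    C10_MPa D1_perMPa incompressible
#>      <dbl>     <dbl> <lgl>
#> 1 0.002462     187.5 FALSE

# Hertz force at 1.5 um depth, 2.5 um tip on an 8 um cell (in nN)
R_eq <- equivalent_radius(8, 2.5)
1e3 * hertz_force(1.5, E_MPa = 1.28e-3, nu = 0.37, R_eq_um = R_eq)
#> [1] 5.013544

# the force-density self-stress of the cytoskeleton
g <- apply_prestress(build_tensegrity(8))
dplyr::count(find_selfstress(g), kind, density = round(force_density, 6))
#> # A tibble: 2 × 3
#>   kind  density     n
#> 1 cable     1      24
#> 2 strut    -1.5     6

# a full virtual AFM experiment on the continuum-tensegrity model
afm <- simulate_afm(cell_model("CTM"))
afm
#> <cyto_curve> kind=afm | model=CTM | materials=cell type 1 | R_tip_um=2.5 | ...
#> # A tibble: 651 × 3
#>        t_s delta_um  F_nN
#> 1 0            0     0
#> 2 0.003158     0.03 14.12
#> 3 0.006316     0.06 28.22
#> # ...
autoplot(afm)

# recover SLS parameters from a noisy synthetic relaxation record
curve <- generate_synthetic_curve(
  "hertz_sls",
  list(E_R_MPa = 4.5e-4, tau_sigma_s = 19.7, tau_epsilon_s = 9.5,
       nu = 0.37, R_eq_um = R_eq, delta_um = 1.5),
  noise_sd = 0.05, seed = 1
)
fit <- fit_sls_relaxation(curve, nu = 0.37, R_eq_um = R_eq, delta_um = 1.5)
tidy(fit)
#> # A tibble: 5 × 4
#>   term            estimate    std_error unit
#> 1 E_R_MPa        0.0004498  0.000001730 MPa
#> 2 tau_sigma_s   19.75       0.3955      s
#> 3 tau_epsilon_s  9.451      0.1962      s
#> 4 E0_MPa         0.0009400 NA           MPa
#> 5 Einf_MPa       0.0006162 NA           MPa
```

The fitted `E_R = 4.498e-4` MPa, `τσ = 19.75` s, `τε = 9.45` s recover
the generating values (4.5e-4, 19.7, 9.5) to well under 1% despite 5%
multiplicative noise; `E0` and `Einf` are the derived instantaneous and
long-term moduli. `autoplot()` works on curves and fits; `tidy()` /
`glance()` on fits and solver solutions.

A thin command-line wrapper ships in `inst/scripts/cytomech`, e.g.

```sh
Rscript inst/scripts/cytomech material convert --set inst/extdata/celltype1.yaml
Rscript inst/scripts/cytomech simulate afm --model ctm --out afm.tsv
Rscript inst/scripts/cytomech fit creep --in lp.tsv --Rp 4 --dP 100Pa
```

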