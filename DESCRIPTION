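Package: cytomech
Title: Reduced-Order Continuum-Tensegrity Models of Single-Cell Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and reduced-order structural models for single-cell
    micromechanics experiments on chondrocyte-like cells. Implements Hertz
    spherical-indentation loading and standard-linear-solid stress relaxation
    for AFM, the half-space elastic and creep models for micropipette
    aspiration, conversions among linear-elastic, Neo-Hookean and
    standard-linear-solid material descriptions of cell subcomponents, a
    geometrically nonlinear solver for the classic 6-strut/24-cable
    tensegrity cytoskeleton with tension-only cables and prestress, virtual
    indent-and-hold and step-and-creep experiment drivers combining continuum
    and cytoskeletal responses, and seeded inverse fitting of viscoelastic
    parameters from force and creep curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
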