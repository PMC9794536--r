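# Shared fixtures: tabulated subcomponent parameters (3 s.f., as printed
# in the reference material tables) and a memoised prestressed graph.

R_EQ <- cytomech::equivalent_radius(8, 2.5) # 40/21 um

# printed (E, nu, C10, D1) per subcomponent for the two cell types
printed_materials <- function() {
  tibble::tribble(
    ~set, ~role, ~E_MPa, ~nu, ~C10_MPa, ~D1_perMPa,
    "ct1", "cytoplasm", 1.28e-3, 0.37, 2.33e-4, 1.22e+3,
    "ct1", "microtubule", 1.53e+4, 0.38, 2.78e+3, 9.39e-5,
    "ct1", "microfilament", 3.32e+4, 0.38, 6.02e+3, 4.33e-5,
    "ct1", "membrane", 1.28e-2, 0.30, 2.46e-3, 1.88e+2,
    "ct1", "nucleus", 5.11e-3, 0.37, 9.33e-4, 3.05e+2,
    "ct2", "cytoplasm", 1.00e-4, 0.37, 1.83e-5, 1.56e+4,
    "ct2", "microtubule", 1.20e+3, 0.38, 2.17e+2, 1.20e-3,
    "ct2", "microfilament", 2.60e+3, 0.38, 4.71e+2, 5.54e-4,
    "ct2", "membrane", 1.00e-3, 0.30, 1.92e-4, 2.40e+3,
    "ct2", "nucleus", 4.00e-4, 0.37, 7.30e-5, 3.90e+3
  )
}

# cytoplasm SLS triplet shared by both cell types
SLS_CYTO <- list(E_R = 4.50e-4, tau_sigma = 19.7, tau_epsilon = 9.5, nu = 0.37)

prestressed_graph <- local({
  cache <- new.env()
  function(orientation = "config1", prestrain = 0.01) {
    key <- paste(orientation, prestrain)
    if (is.null(cache[[key]])) {
      g <- cytomech::build_tensegrity(8, orientation = orientation)
      cache[[key]] <- cytomech::apply_prestress(g, cable_prestrain = prestrain)
    }
    cache[[key]]
  }
})

max_rel_err <- function(est, truth) max(abs(est / truth - 1))
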