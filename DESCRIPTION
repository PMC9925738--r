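Package: dc4
Title: Density-Corrected DFT Composite Energies with a Charge-Dependent
    Dispersion Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for density-corrected density-functional theory (DC-DFT)
    workflows built around the HF-DFT composite ansatz: a density functional
    evaluated non-self-consistently on Hartree-Fock orbitals plus a charge-
    and coordination-dependent ("D4"-type) dispersion correction with
    Becke-Johnson damping. Provides an engine contract with a deterministic
    analytic toy engine and a cached-energy store, the dispersion model
    (electronegativity-equilibration charges, coordination numbers,
    Casimir-Polder C6 coefficients), density-sensitivity diagnostics with
    density-sensitive/insensitive classification, dispersion-parameter
    fitting restricted to density-insensitive training reactions, many-body
    expansion of cluster interaction energies, and benchmark metrics
    (per-dataset MAE, pooled water metric, WTMAD-2).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
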