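#' Density-corrected composite energy of a molecule
#'
#' One engine call for the base energy (the functional evaluated on the
#' density requested by `spec`, e.g. the Hartree-Fock density for HF-DFT)
#' plus the dispersion correction: `E_total = E_base + E_disp`.
#'
#' @param mol a `dc4_molecule`.
#' @param engine an engine (see [evaluate_energy()]).
#' @param spec a [method_spec()].
#' @param params [d4_params()]; all-zero scalings give `E_total = E_base`.
#' @param tables [d4_reference_tables()].
#' @param include_atm include the three-body dispersion term.
#' @return A `dc4_energy_record` with Hartree fields `E_base`, `E_disp`,
#'   `E_total` and the full engine result.
#' @export
composite_energy <- function(mol, engine, spec, params = d4_params(),
                             tables = d4_reference_tables(),
                             include_atm = FALSE) {
  res <- evaluate_energy(engine, mol, spec)
  if (!isTRUE(res$converged)) {
    abort(sprintf("engine did not converge for molecule '%s'", mol$label))
  }
  disp <- dispersion_energy(mol, params, tables, include_atm = include_atm)
  structure(
    list(label = mol$label, E_base = res$total_energy,
         E_disp = disp$total_energy,
         E_total = res$total_energy + disp$total_energy,
         spec = spec, params = params, engine_result = res),
    class = "dc4_energy_record"
  )
}

#' @export
print.dc4_energy_record <- function(x, ...) {
  cat(sprintf(
    "<energy '%s': total %.10f Eh = base %.10f + dispersion %.10f>\n",
    x$label, x$E_total, x$E_base, x$E_disp))
  invisible(x)
}

#' Reaction energy from an energy lookup
#'
#' `sum_i nu_i E_i` converted to kcal/mol. With products carrying positive
#' coefficients, a bound complex's interaction energy comes out negative.
#'
#' @param rxn a [reaction()].
#' @param energy_lookup named list/vector mapping species labels to Hartree
#'   energies or to `dc4_energy_record` objects.
#' @return Reaction energy, kcal/mol.
#' @export
reaction_energy <- function(rxn, energy_lookup) {
  e <- vapply(rxn$species, function(lab) {
    rec <- energy_lookup[[lab]]
    if (is.null(rec)) abort(sprintf("no energy for species '%s'", lab))
    if (inherits(rec, "dc4_energy_record")) rec$E_total else as.numeric(rec)
  }, 0)
  hartree_to_kcal(sum(rxn$coefficients * e))
}

#' Density sensitivity of a reaction
#'
#' The magnitude of the reaction-energy change when the functional is
#' evaluated on two different proxy densities — here the Hartree-Fock
#' density versus an LDA-quality density (the `"lda-proxy"` method):
#' `S = |dE_functional[n_HF] - dE_functional[n_proxy]|` in kcal/mol. Large
#' sensitivity flags a density-driven error. The proxy functional identifier
#' is pluggable.
#'
#' @param rxn a [reaction()].
#' @param molecules named list of `dc4_molecule` resolving the species.
#' @param engine an engine.
#' @param functional base functional identifier.
#' @param basis basis identifier.
#' @param proxy_functional identifier of the proxy-density method.
#' @param cutoff DS/DI cutoff in kcal/mol (default 2).
#' @param spin_threshold relative `<S^2>` deviation flagging contamination.
#' @return A `dc4_sensitivity_record`: `tag`, `s_tilde` (kcal/mol),
#'   `classification` (`"DS"`/`"DI"`), `cutoff_used`, `spin_contaminated`.
#' @export
density_sensitivity <- function(rxn, molecules, engine,
                                functional = "r2scan", basis = "def2-QZVP",
                                proxy_functional = "lda-proxy",
                                cutoff = 2.0, spin_threshold = 0.1) {
  spec_hf <- method_spec("HF", functional = functional, basis = basis)
  spec_proxy <- method_spec("SC", functional = proxy_functional, basis = basis)
  res_hf <- lapply(rxn$species, function(lab) {
    evaluate_energy(engine, molecules[[lab]], spec_hf)
  })
  res_proxy <- lapply(rxn$species, function(lab) {
    evaluate_energy(engine, molecules[[lab]], spec_proxy)
  })
  bad <- !vapply(c(res_hf, res_proxy), function(r) isTRUE(r$converged), TRUE)
  if (any(bad)) abort(sprintf("engine failure within reaction '%s'", rxn$tag))
  de_hf <- sum(rxn$coefficients * vapply(res_hf, `[[`, 0, "total_energy"))
  de_proxy <- sum(rxn$coefficients * vapply(res_proxy, `[[`, 0, "total_energy"))
  s_tilde <- hartree_to_kcal(abs(de_hf - de_proxy))
  mults <- vapply(rxn$species, function(lab) molecules[[lab]]$multiplicity, 1L)
  spin <- spin_screen(res_hf, multiplicities = mults,
                      threshold = spin_threshold)
  sensitivity_record(rxn$tag, s_tilde, cutoff = cutoff,
                     spin_contaminated = spin)
}

sensitivity_record <- function(tag, s_tilde, cutoff = 2.0,
                               spin_contaminated = FALSE) {
  stopifnot(s_tilde >= 0)
  structure(
    list(tag = tag, s_tilde = s_tilde,
         classification = classify_sensitivity(s_tilde, cutoff),
         cutoff_used = cutoff, spin_contaminated = spin_contaminated),
    class = "dc4_sensitivity_record"
  )
}

#' Classify a density sensitivity as DS or DI
#'
#' A reaction is density-sensitive (DS) when its sensitivity reaches the
#' cutoff, density-insensitive (DI) otherwise. The boundary value itself is
#' classified DS — the conservative convention for training-set exclusion.
#'
#' @param s_tilde sensitivity, kcal/mol, `>= 0`.
#' @param cutoff cutoff, kcal/mol (default 2, the standard choice).
#' @return `"DS"` or `"DI"`.
#' @export
classify_sensitivity <- function(s_tilde, cutoff = 2.0) {
  stopifnot(all(s_tilde >= 0), cutoff >= 0)
  ifelse(s_tilde >= cutoff, "DS", "DI")
}

#' Spin-contamination screen over a reaction's engine results
#'
#' Flags the reaction when any open-shell species' `<S^2>` deviates from the
#' exact `S(S+1)` by more than `threshold` (relative). Closed-shell species
#' (no spin expectation) never flag.
#'
#' @param results list of `dc4_engine_result`.
#' @param multiplicities integer multiplicities matching `results`.
#' @param threshold relative deviation tolerance (default 0.1); at 0, any
#'   nonzero deviation flags.
#' @return Logical scalar.
#' @export
spin_screen <- function(results, multiplicities, threshold = 0.1) {
  stopifnot(length(results) == length(multiplicities))
  flags <- mapply(function(res, mult) {
    s2 <- res$spin_expectation
    if (is.null(s2) || is.na(s2) || mult == 1L) return(FALSE)
    s <- (mult - 1) / 2
    exact <- s * (s + 1)
    abs(s2 - exact) > threshold * exact
  }, results, multiplicities)
  any(flags)
}

#' Density sensitivities for every reaction of a set
#'
#' @param rset a `dc4_reaction_set`.
#' @param engine an engine.
#' @param ... passed to [density_sensitivity()].
#' @return A tibble with one row per reaction: `tag`, `s_tilde`,
#'   `classification`, `cutoff_used`, `spin_contaminated`.
#' @export
sensitivity_table <- function(rset, engine, ...) {
  recs <- lapply(rset$reactions, function(r) {
    density_sensitivity(r, rset$molecules, engine, ...)
  })
  purrr::map_dfr(recs, function(s) {
    tibble::tibble(tag = s$tag, s_tilde = s$s_tilde,
                   classification = s$classification,
                   cutoff_used = s$cutoff_used,
                   spin_contaminated = s$spin_contaminated)
  })
}

#' Composite reaction energies for a whole set
#'
#' Evaluates each distinct species once (memoized by label) and assembles
#' per-reaction energies.
#'
#' @param rset a `dc4_reaction_set`.
#' @param engine an engine.
#' @param spec a [method_spec()].
#' @param params [d4_params()].
#' @param tables [d4_reference_tables()].
#' @param include_atm include the three-body dispersion term.
#' @return A tibble: `tag`, `dataset`, `computed`, `reference`, `error`
#'   (all kcal/mol).
#' @export
reaction_energies <- function(rset, engine, spec, params = d4_params(),
                              tables = d4_reference_tables(),
                              include_atm = FALSE) {
  lookup <- lapply(rset$molecules, function(m) {
    composite_energy(m, engine, spec, params, tables, include_atm = include_atm)
  })
  purrr::map_dfr(rset$reactions, function(r) {
    de <- reaction_energy(r, lookup)
    tibble::tibble(tag = r$tag, dataset = r$dataset, computed = de,
                   reference = r$reference_energy,
                   error = de - r$reference_energy)
  })
}
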