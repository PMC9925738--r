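#' Specify an electronic-structure method
#'
#' The single currency through which all energies are requested.
#' `density_source` says whose orbitals/density the functional is evaluated
#' on: `"SC"` for the functional's own self-consistent density, `"HF"` for a
#' non-self-consistent evaluation on converged Hartree-Fock orbitals (one HF
#' SCF, one functional evaluation, no post-HF orbital relaxation).
#'
#' @param density_source `"SC"` or `"HF"`.
#' @param functional functional identifier, e.g. `"r2scan"`, `"scan"`, or the
#'   `"lda-proxy"` used by density-sensitivity evaluation.
#' @param basis basis-set identifier.
#' @param grid_level small integer quadrature-grid level.
#' @return An object of class `dc4_method_spec`.
#' @export
method_spec <- function(density_source = c("HF", "SC"), functional = "r2scan",
                        basis = "def2-QZVP", grid_level = 5L) {
  density_source <- match.arg(density_source)
  if (!nzchar(functional)) abort("functional identifier must be non-empty")
  structure(
    list(density_source = density_source, functional = functional,
         basis = basis, grid_level = as.integer(grid_level)),
    class = "dc4_method_spec"
  )
}

#' @export
print.dc4_method_spec <- function(x, ...) {
  cat(sprintf("<method: %s density / %s / %s / grid %d>\n",
              x$density_source, x$functional, x$basis, x$grid_level))
  invisible(x)
}

engine_result <- function(total_energy, spin_expectation = NA_real_,
                          converged = TRUE, metadata = list()) {
  if (converged && !is.finite(total_energy)) abort("non-finite energy")
  structure(
    list(total_energy = total_energy, spin_expectation = spin_expectation,
         converged = converged, metadata = metadata),
    class = "dc4_engine_result"
  )
}

#' @export
print.dc4_engine_result <- function(x, ...) {
  cat(sprintf("<engine result: E = %.10f Eh, converged = %s>\n",
              x$total_energy, x$converged))
  invisible(x)
}

#' Evaluate an electronic-structure energy
#'
#' The engine contract: every implementation (toy engine, cached store, or an
#' adapter to a real quantum-chemistry backend) answers the same call. Results
#' are deterministic for fixed inputs and backend version. A non-converged
#' result is returned explicitly, never silently consumed: downstream code
#' must check `converged`.
#'
#' @param engine an engine object (e.g. [toy_engine()], [cached_engine()]).
#' @param mol a `dc4_molecule`.
#' @param spec a [method_spec()].
#' @return A `dc4_engine_result` with `total_energy` in Hartree.
#' @export
evaluate_energy <- function(engine, mol, spec) {
  UseMethod("evaluate_energy")
}

#' @export
evaluate_energy.default <- function(engine, mol, spec) {
  abort("not a dc4 engine object")
}

# ---- toy engine --------------------------------------------------------

#' Parameters of the analytic toy engine
#'
#' The toy engine's closed-form energy is a sum of tabulated atomic energies
#' plus Morse-type pair interactions, with an optional per-molecule
#' density-error knob delta. It exists to make every downstream module
#' testable against hand-computable values; the numbers are of physically
#' plausible magnitude (hydrogen-bond-depth pair wells) but model no real
#' system.
#'
#' Density handling: for a molecule with knob `delta` (Hartree), evaluating
#' with `density_source = "SC"` adds `delta`; with `density_source = "HF"`
#' adds `hf_fraction * delta` (HF densities carry only a small residual of
#' the density-driven error); with `functional = "lda-proxy"` adds `-delta`,
#' so the density sensitivity of a reaction is an analytically known linear
#' function of its species' deltas.
#'
#' @param atomic_energies named Hartree energies per element.
#' @param well_depth named per-element Morse well-depth factors (Hartree);
#'   pair depth is the geometric mean.
#' @param well_radius named per-element radii (Angstrom); pair equilibrium
#'   distance is the sum.
#' @param morse_width inverse-width `a` of the Morse well (1/Angstrom).
#' @param delta named per-molecule-label density-error knob (Hartree).
#' @param hf_fraction residual fraction of delta carried by the HF density.
#' @param spin_contamination named per-label `<S^2>` overrides.
#' @return A list of class `dc4_toy_params`.
#' @export
toy_params <- function(atomic_energies = c(H = -0.5, C = -37.8, N = -54.4, O = -75.0),
                       well_depth = c(H = 0.02, C = 0.04, N = 0.045, O = 0.05),
                       well_radius = c(H = 0.35, C = 0.75, N = 0.70, O = 0.65),
                       morse_width = 1.8,
                       delta = c(),
                       hf_fraction = 0.1,
                       spin_contamination = c()) {
  structure(
    list(atomic_energies = atomic_energies, well_depth = well_depth,
         well_radius = well_radius, morse_width = morse_width,
         delta = delta, hf_fraction = hf_fraction,
         spin_contamination = spin_contamination),
    class = "dc4_toy_params"
  )
}

#' Deterministic analytic toy engine
#'
#' @param params a [toy_params()] object.
#' @return An engine usable with [evaluate_energy()].
#' @export
toy_engine <- function(params = toy_params()) {
  stopifnot(inherits(params, "dc4_toy_params"))
  structure(list(params = params), class = c("dc4_toy_engine", "dc4_engine"))
}

#' Closed-form toy energy
#'
#' Exposed separately from the engine object so tests can hand-evaluate it.
#'
#' @param mol a `dc4_molecule`.
#' @param spec a [method_spec()].
#' @param params a [toy_params()] object.
#' @return A `dc4_engine_result`.
#' @export
toy_evaluate <- function(mol, spec, params = toy_params()) {
  miss <- setdiff(unique(mol$elements), names(params$atomic_energies))
  if (length(miss) > 0) {
    abort(paste0("toy engine lacks parameters for element(s): ",
                 paste(miss, collapse = ", ")))
  }
  e <- sum(params$atomic_energies[mol$elements])
  n <- n_atoms(mol)
  if (n > 1) {
    d <- unname(params$well_depth[mol$elements])
    re <- unname(params$well_radius[mol$elements])
    a <- params$morse_width
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- sqrt(sum((mol$coordinates[i, ] - mol$coordinates[j, ])^2))
        dij <- sqrt(d[i] * d[j])
        reij <- re[i] + re[j]
        e <- e + dij * ((1 - exp(-a * (r - reij)))^2 - 1)
      }
    }
  }
  delta <- unname(params$delta[mol$label])
  if (is.null(delta) || is.na(delta)) delta <- 0
  kappa <- if (identical(spec$functional, "lda-proxy")) {
    -1
  } else if (spec$density_source == "HF") {
    params$hf_fraction
  } else {
    1
  }
  s2 <- unname(params$spin_contamination[mol$label])
  if (is.null(s2) || is.na(s2)) {
    s <- (mol$multiplicity - 1) / 2
    s2 <- if (mol$multiplicity == 1L) NA_real_ else s * (s + 1)
  }
  engine_result(e + kappa * delta, spin_expectation = s2,
                metadata = list(backend = "toy", functional = spec$functional,
                                density_source = spec$density_source))
}

#' @export
evaluate_energy.dc4_toy_engine <- function(engine, mol, spec) {
  toy_evaluate(mol, spec, engine$params)
}

# ---- cached-energy store ----------------------------------------------

#' Canonical cache key for an energy evaluation
#'
#' Hash of the element list, coordinates rounded to 1e-6 Angstrom, charge,
#' multiplicity and the method fields. Jitter below the rounding level maps
#' to the same key; any chemically meaningful change produces a new one.
#'
#' @param mol a `dc4_molecule`.
#' @param spec a [method_spec()].
#' @return A character key.
#' @export
energy_cache_key <- function(mol, spec) {
  payload <- paste(
    paste(mol$elements, collapse = ","),
    paste(sprintf("%.6f", round(mol$coordinates, 6)), collapse = ","),
    mol$charge, mol$multiplicity,
    spec$density_source, spec$functional, spec$basis, spec$grid_level,
    sep = "|"
  )
  rlang::hash(payload)
}

#' Create an in-memory energy store
#'
#' @param records optional tibble/data frame with columns `key`,
#'   `energy_hartree`, `spin_expectation` (as written by [write_energy_store()]).
#' @return An environment-backed store.
#' @export
energy_store <- function(records = NULL) {
  env <- new.env(parent = emptyenv())
  if (!is.null(records)) {
    for (i in seq_len(nrow(records))) {
      assign(records$key[i],
             list(energy = records$energy_hartree[i],
                  spin = records$spin_expectation[i]),
             envir = env)
    }
  }
  structure(list(env = env), class = "dc4_energy_store")
}

#' Insert an energy into a store
#' @param store a [energy_store()].
#' @param mol,spec the evaluation identity.
#' @param energy Hartree energy to store.
#' @param spin_expectation optional `<S^2>`.
#' @return The store, invisibly.
#' @export
store_energy <- function(store, mol, spec, energy, spin_expectation = NA_real_) {
  assign(energy_cache_key(mol, spec),
         list(energy = energy, spin = spin_expectation), envir = store$env)
  invisible(store)
}

#' Read/write a cache store as JSON lines
#'
#' One JSON object per line with fields `key`, `energy_hartree`,
#' `spin_expectation`; Hartree values survive the round trip bit-identically
#' (17 significant digits).
#'
#' @param store a `dc4_energy_store`.
#' @param path file path.
#' @return `write_energy_store()` the path invisibly; `read_energy_store()`
#'   a store.
#' @export
write_energy_store <- function(store, path) {
  keys <- ls(store$env)
  lines <- vapply(keys, function(k) {
    rec <- get(k, envir = store$env)
    jsonlite::toJSON(
      list(key = k, energy_hartree = rec$energy, spin_expectation = rec$spin),
      auto_unbox = TRUE, digits = I(17), na = "null"
    )
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_energy_store
#' @export
read_energy_store <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  energy_store(tibble::tibble(
    key = vapply(recs, `[[`, "", "key"),
    energy_hartree = vapply(recs, `[[`, 0, "energy_hartree"),
    spin_expectation = vapply(recs, function(r) {
      r$spin_expectation %||% NA_real_
    }, 0)
  ))
}

#' Cached-energy engine
#'
#' Serves energies from a store by canonical key. A miss raises an explicit
#' error carrying the key, unless a fallback engine is configured, in which
#' case the fallback result is computed and inserted.
#'
#' @param store a [energy_store()].
#' @param fallback optional engine for cache misses.
#' @return An engine usable with [evaluate_energy()].
#' @export
cached_engine <- function(store, fallback = NULL) {
  structure(list(store = store, fallback = fallback),
            class = c("dc4_cached_engine", "dc4_engine"))
}

#' @export
evaluate_energy.dc4_cached_engine <- function(engine, mol, spec) {
  key <- energy_cache_key(mol, spec)
  if (exists(key, envir = engine$store$env, inherits = FALSE)) {
    rec <- get(key, envir = engine$store$env)
    return(engine_result(rec$energy, spin_expectation = rec$spin,
                         metadata = list(backend = "cache", key = key)))
  }
  if (is.null(engine$fallback)) {
    abort(sprintf("cache miss for molecule '%s' (key %s) and no fallback engine",
                  mol$label, key))
  }
  res <- evaluate_energy(engine$fallback, mol, spec)
  store_energy(engine$store, mol, spec, res$total_energy, res$spin_expectation)
  res
}
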