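#' Settings for the synthetic reaction-set generator
#'
#' The generator emulates the structure of a dispersion-correction training
#' problem: association reactions (water dimers and mixed closed-shell
#' diatomic pairs) whose reference energies are the toy-engine base energy
#' plus an exact dispersion tail computed with known parameters, so that
#' fitting can recover those parameters. A controllable fraction of
#' reactions carries a density-error knob on the complex, making them
#' density-sensitive with an analytically known sensitivity and giving the
#' HF-density model a systematic residual bias — the mechanism that
#' separates principled (DI-only) from naive (all-reaction) fitting.
#'
#' @param true_params [d4_params()] used to build the reference dispersion
#'   tails (three-body scaling is zero: references are strictly pairwise).
#' @param ds_fraction fraction of reactions given a density-error knob.
#'   Knobs are assigned to water-cluster association reactions first,
#'   mirroring the empirical situation where density sensitivity
#'   concentrates in water-cluster binding energies.
#' @param delta_ds knob magnitude on a density-sensitive complex, Hartree.
#'   The default 0.02 Eh makes the sensitivity about 14 kcal/mol — the
#'   scale water-cluster binding sensitivities reach, far past the
#'   2 kcal/mol cutoff — and leaves a ~1.3 kcal/mol residual bias on the
#'   HF density.
#' @param noise_sd Gaussian noise on reference energies, kcal/mol.
#' @param r_range_water sampled O-O distances for water dimers, Angstrom.
#' @param r_range_pair sampled centre separations for diatomic pairs, Angstrom.
#' @param engine_params base [toy_params()] (density knobs are filled in by
#'   the generator).
#' @return A list of class `dc4_toy_dataset_params`.
#' @export
toy_dataset_params <- function(true_params = d4_params(s6 = 1, s8 = 1.2,
                                                       s9 = 0, a1 = 0.45,
                                                       a2 = 4.5),
                               ds_fraction = 0.2,
                               delta_ds = 0.02,
                               noise_sd = 0,
                               r_range_water = c(2.7, 5.5),
                               r_range_pair = c(3.2, 6.0),
                               engine_params = toy_params()) {
  structure(
    list(true_params = true_params, ds_fraction = ds_fraction,
         delta_ds = delta_ds, noise_sd = noise_sd,
         r_range_water = r_range_water, r_range_pair = r_range_pair,
         engine_params = engine_params),
    class = "dc4_toy_dataset_params"
  )
}

toy_diatomic <- function(kind) {
  switch(kind,
    h2 = molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)), label = "h2"),
    n2 = molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.10)), label = "n2"),
    co = molecule(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.13)), label = "co"),
    abort(sprintf("unknown diatomic kind '%s'", kind))
  )
}

# rigid A..B complex: B displaced d Angstrom along x and rotated
toy_pair_complex <- function(a, b, d, angles, label) {
  rot <- euler_rotation(angles)
  bc <- b$coordinates %*% t(rot)
  bc <- sweep(bc, 2, c(d, 0, 0), `+`)
  molecule(c(a$elements, b$elements), rbind(a$coordinates, bc), label = label)
}

#' Generate a synthetic reaction set with a known dispersion tail
#'
#' Builds `n_reactions` association reactions (water ... water dimers in
#' dataset `"toy_water"`, alternating with mixed diatomic pairs in
#' `"toy_mixed"`). Reference energies are
#' `dE_base + dE_disp(true_params) + noise`, where the base part is the
#' pure toy-engine energy (no density error) and the dispersion tail is
#' computed exactly with the generating parameters — so a fit against these
#' references can recover `true_params`. A seeded fraction of complexes
#' receives the density-error knob `delta_ds`, recorded in the provenance
#' together with every generator setting.
#'
#' @param n_reactions number of reactions, `>= 1`.
#' @param seed integer seed; the set is a pure function of
#'   `(arguments, seed)`.
#' @param toy a [toy_dataset_params()].
#' @param tables [d4_reference_tables()].
#' @param name set name.
#' @return A `dc4_reaction_set`. Its provenance holds `true_params`, the
#'   per-label `delta` assignments, `noise_sd`, `seed`, and the engine
#'   parameters (with knobs filled in) under `engine_params`.
#' @export
generate_toy_dataset <- function(n_reactions, seed,
                                 toy = toy_dataset_params(),
                                 tables = d4_reference_tables(),
                                 name = "toy") {
  stopifnot(n_reactions >= 1)
  rng <- new_rng(seed)
  monomers <- list(h2o = fragment_molecules(make_water_dimer(3.0))[[1]],
                   h2 = toy_diatomic("h2"), n2 = toy_diatomic("n2"),
                   co = toy_diatomic("co"))
  monomers$h2o$label <- "h2o"
  n_ds <- round(toy$ds_fraction * n_reactions)
  # deterministic DS assignment: density sensitivity concentrates in the
  # water-cluster (odd-index) reactions, then spills over to the mixed ones
  ds_flags <- rep(FALSE, n_reactions)
  if (n_ds > 0) {
    water_first <- c(seq(1, n_reactions, by = 2), seq(2, n_reactions, by = 2))
    ds_flags[water_first[seq_len(min(n_ds, n_reactions))]] <- TRUE
  }
  delta <- c()
  molecules <- monomers
  base_par <- toy$engine_params
  base_engine_spec <- method_spec("SC", functional = "toy-base")
  pure_base <- function(m) toy_evaluate(m, base_engine_spec, base_par)$total_energy
  disp_of <- function(m) {
    dispersion_energy(m, toy$true_params, tables)$total_energy
  }
  reactions <- vector("list", n_reactions)
  pair_kinds <- list(c("co", "h2"), c("n2", "h2"), c("co", "n2"))
  for (i in seq_len(n_reactions)) {
    u <- rng(5)
    if (i %% 2 == 1) {
      r_oo <- toy$r_range_water[1] + u[1] * diff(toy$r_range_water)
      cl <- make_water_dimer(r_oo, angles = u[2:4] * 0.6)
      cplx <- cl$molecule
      cplx$label <- sprintf("cplx_%04d", i)
      species <- c(cplx$label, "h2o")
      coeffs <- c(1, -2)
      dataset <- "toy_water"
      parts <- list(monomers$h2o, monomers$h2o)
    } else {
      kinds <- pair_kinds[[1 + (i %/% 2 - 1) %% 3]]
      d <- toy$r_range_pair[1] + u[1] * diff(toy$r_range_pair)
      cplx <- toy_pair_complex(monomers[[kinds[1]]], monomers[[kinds[2]]],
                               d, u[2:4] * 2 * pi,
                               label = sprintf("cplx_%04d", i))
      species <- c(cplx$label, kinds[1], kinds[2])
      coeffs <- c(1, -1, -1)
      dataset <- "toy_mixed"
      parts <- list(monomers[[kinds[1]]], monomers[[kinds[2]]])
    }
    molecules[[cplx$label]] <- cplx
    if (ds_flags[i]) delta[cplx$label] <- toy$delta_ds
    de_base <- pure_base(cplx) - sum(vapply(parts, pure_base, 0))
    de_disp <- disp_of(cplx) +
      sum(coeffs[-1] * vapply(species[-1], function(s) disp_of(monomers[[s]]), 0))
    ref <- hartree_to_kcal(de_base + de_disp)
    if (toy$noise_sd > 0) ref <- ref + rng(1, normal = TRUE) * toy$noise_sd
    reactions[[i]] <- reaction(species, coeffs, ref,
                               tag = sprintf("%s_%04d", name, i),
                               dataset = dataset)
  }
  engine_params <- toy$engine_params
  engine_params$delta <- delta
  reaction_set(
    reactions, molecules, name = name,
    provenance = list(
      generator = "generate_toy_dataset", seed = seed,
      true_params = toy$true_params, delta = delta,
      noise_sd = toy$noise_sd, ds_fraction = toy$ds_fraction,
      delta_ds = toy$delta_ds, engine_params = engine_params
    )
  )
}

#' Water-dimer distance scan as a reaction set
#'
#' One association reaction per O-O distance, emulating the structure of
#' dimer-scan benchmark data (references from the toy engine plus the exact
#' dispersion tail; no density error, so every reaction is density
#' insensitive).
#'
#' @param r_oo numeric vector of O-O distances, Angstrom.
#' @param toy a [toy_dataset_params()].
#' @param tables [d4_reference_tables()].
#' @param name set/dataset name.
#' @return A `dc4_reaction_set` tagged with dataset `name`.
#' @export
generate_dimer_scan <- function(r_oo = seq(2.7, 6.0, by = 0.3),
                                toy = toy_dataset_params(),
                                tables = d4_reference_tables(),
                                name = "water_dimers") {
  h2o <- fragment_molecules(make_water_dimer(3.0))[[1]]
  h2o$label <- "h2o"
  molecules <- list(h2o = h2o)
  spec0 <- method_spec("SC", functional = "toy-base")
  pure_base <- function(m) toy_evaluate(m, spec0, toy$engine_params)$total_energy
  disp_of <- function(m) dispersion_energy(m, toy$true_params, tables)$total_energy
  reactions <- lapply(seq_along(r_oo), function(i) {
    cl <- make_water_dimer(r_oo[i])
    cplx <- cl$molecule
    cplx$label <- sprintf("%s_%04d", name, i)
    molecules[[cplx$label]] <<- cplx
    ref <- hartree_to_kcal(
      (pure_base(cplx) - 2 * pure_base(h2o)) +
        (disp_of(cplx) - 2 * disp_of(h2o))
    )
    reaction(c(cplx$label, "h2o"), c(1, -2), ref,
             tag = sprintf("%s_r%.2f", name, r_oo[i]), dataset = name)
  })
  reaction_set(reactions, molecules, name = name,
               provenance = list(generator = "generate_dimer_scan",
                                 r_oo = r_oo, true_params = toy$true_params,
                                 engine_params = toy$engine_params))
}
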