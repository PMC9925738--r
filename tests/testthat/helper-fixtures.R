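# shared fixtures; reference tables are deterministic, build once per run
.fixture_env <- new.env()

test_tables <- function() {
  if (is.null(.fixture_env$tables)) {
    .fixture_env$tables <- d4_reference_tables()
  }
  .fixture_env$tables
}

water_xyz_text <- function() {
  paste(
    "3",
    "water",
    "O 0.000000 0.000000 0.117300",
    "H 0.000000 0.757200 -0.469200",
    "H 0.000000 -0.757200 -0.469200",
    sep = "\n"
  )
}

# random valid molecule of H/C/N/O atoms, min separation enforced by spacing
random_molecule <- function(n, seed, box = 6) {
  rng_state <- .Random.seed_save()
  set.seed(seed)
  repeat {
    coords <- matrix(runif(3 * n, 0, box), ncol = 3)
    if (n == 1 || min(dist(coords)) > 0.8) break
  }
  elems <- sample(c("H", "C", "N", "O"), n, replace = TRUE)
  .Random.seed_restore(rng_state)
  # hydrogen count parity decides a consistent multiplicity
  nelec <- sum(c(H = 1, C = 6, N = 7, O = 8)[elems])
  molecule(elems, coords, multiplicity = if (nelec %% 2 == 0) 1L else 2L,
           label = sprintf("rand%d_%d", n, seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, globalenv())
  invisible(NULL)
}

# rigid rotation + translation of a molecule
transform_molecule <- function(mol, angles = c(0.3, 1.1, -0.7),
                               shift = c(1.5, -2.0, 0.25)) {
  rot <- dc4:::euler_rotation(angles)
  coords <- mol$coordinates %*% t(rot)
  coords <- sweep(coords, 2, shift, `+`)
  molecule(mol$elements, coords, charge = mol$charge,
           multiplicity = mol$multiplicity, label = mol$label)
}
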