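#' Construct a molecular cluster
#'
#' A cluster is a molecule plus a fragmentation: a partition of atom indices
#' into monomer index sets. Fragments must be disjoint and cover all atoms.
#'
#' @param mol a `dc4_molecule`.
#' @param fragmentation list of integer vectors of atom indices.
#' @return An object of class `dc4_cluster`.
#' @export
cluster <- function(mol, fragmentation) {
  stopifnot(inherits(mol, "dc4_molecule"))
  fragmentation <- unname(lapply(fragmentation,
                                 function(f) sort(unname(as.integer(f)))))
  idx <- sort(unlist(fragmentation, use.names = FALSE))
  if (anyDuplicated(idx) > 0) abort("fragments overlap")
  if (!identical(idx, seq_len(n_atoms(mol)))) {
    abort("fragments must cover every atom exactly once")
  }
  structure(list(molecule = mol, fragmentation = fragmentation),
            class = "dc4_cluster")
}

#' @export
print.dc4_cluster <- function(x, ...) {
  cat(sprintf("<cluster '%s': %d atoms in %d fragments>\n",
              x$molecule$label, n_atoms(x$molecule), length(x$fragmentation)))
  invisible(x)
}

#' Number of fragments in a cluster
#' @param cl a `dc4_cluster`.
#' @return integer fragment count.
#' @export
n_fragments <- function(cl) length(cl$fragmentation)

#' Extract fragment molecules from a cluster
#'
#' Each fragment keeps its in-cluster geometry (no relaxation). Charge of the
#' parent molecule is assigned to fragments only when a per-fragment charge
#' vector is supplied; by default fragments are neutral singlets, which is
#' correct for water clusters.
#'
#' @param cl a `dc4_cluster`.
#' @param which integer indices of fragments to extract (default all).
#' @param charges optional integer vector of per-fragment charges.
#' @return A list of `dc4_molecule`.
#' @export
fragment_molecules <- function(cl, which = seq_along(cl$fragmentation),
                               charges = NULL) {
  mol <- cl$molecule
  lapply(seq_along(which), function(k) {
    i <- which[k]
    f <- cl$fragmentation[[i]]
    molecule(mol$elements[f], mol$coordinates[f, , drop = FALSE],
             charge = if (is.null(charges)) 0L else charges[k],
             label = sprintf("%s/frag%d", mol$label, i))
  })
}

#' Extract the sub-molecule spanned by a set of fragments
#'
#' @param cl a `dc4_cluster`.
#' @param frags integer indices of fragments.
#' @param label optional label.
#' @return A `dc4_molecule` made of the selected fragments at their in-cluster
#'   coordinates, atom order following fragment order.
#' @export
subcluster_molecule <- function(cl, frags, label = NULL) {
  mol <- cl$molecule
  idx <- unlist(cl$fragmentation[frags])
  molecule(mol$elements[idx], mol$coordinates[idx, , drop = FALSE],
           label = label %||%
             sprintf("%s/[%s]", mol$label, paste(frags, collapse = ",")))
}

# rigid gas-phase water monomer: r(OH) = 0.9572 Angstrom, HOH angle 104.52 deg,
# O at origin, C2 axis along -x so the molecular dipole points along +x
rigid_water <- function() {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(
    c(0, 0, 0),
    c(r_oh * cos(half), r_oh * sin(half), 0),
    c(r_oh * cos(half), -r_oh * sin(half), 0)
  )
}

#' Build a rigid water dimer at a given O-O distance
#'
#' Two rigid water monomers (r(OH) = 0.9572 Angstrom, HOH angle 104.52
#' degrees) are placed with the requested oxygen-oxygen distance along the x
#' axis in a hydrogen-bond-like arrangement: the donor monomer points one O-H
#' bond toward the acceptor oxygen. Euler angles rotate the acceptor monomer.
#'
#' @param r_oo oxygen-oxygen distance in Angstrom, in `[2, 100]`.
#' @param angles optional numeric length-3 Euler angles (radians, z-y-z) for
#'   the acceptor monomer orientation.
#' @return A `dc4_cluster` with fragmentation `{1:3, 4:6}`.
#' @export
make_water_dimer <- function(r_oo, angles = c(0, 0, 0)) {
  if (!is.finite(r_oo) || r_oo < 2.0 || r_oo > 100.0) {
    abort("r_oo must lie in [2, 100] Angstrom (below 2 is unphysical overlap)")
  }
  w <- rigid_water()
  rot <- euler_rotation(angles)
  acceptor <- w %*% t(rot)
  acceptor <- sweep(acceptor, 2, c(r_oo, 0, 0), `+`)
  coords <- rbind(w, acceptor)
  mol <- molecule(rep(c("O", "H", "H"), 2), coords,
                  label = sprintf("water_dimer_roo_%.4f", r_oo))
  cluster(mol, list(1:3, 4:6))
}

euler_rotation <- function(angles) {
  stopifnot(length(angles) == 3)
  rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  rz(angles[1]) %*% ry(angles[2]) %*% rz(angles[3])
}

#' Build a compact water cluster with n rigid monomers
#'
#' Monomers are placed on a ring (n <= 6, hexamer-like) or on two stacked
#' rings, each randomly oriented. Intended as the seed structure for
#' [perturb_cluster()] fixtures; it emulates hydrogen-bonded-network topology,
#' not optimized cluster geometries.
#'
#' @param n number of water monomers.
#' @param radius ring radius in Angstrom.
#' @param seed integer seed controlling monomer orientations.
#' @return A `dc4_cluster` of `n` water fragments.
#' @export
make_water_cluster <- function(n = 6, radius = 2.8, seed = 1) {
  stopifnot(n >= 1)
  rng <- new_rng(seed)
  w <- rigid_water()
  coords <- NULL
  for (i in seq_len(n)) {
    ring <- (i - 1) %/% 6
    k <- (i - 1) %% 6
    nring <- min(n - 6 * ring, 6)
    th <- 2 * pi * k / max(nring, 1)
    centre <- c(radius * cos(th), radius * sin(th), 2.9 * ring)
    ang <- rng(3) * 2 * pi
    m <- w %*% t(euler_rotation(ang))
    coords <- rbind(coords, sweep(m, 2, centre, `+`))
  }
  mol <- molecule(rep(c("O", "H", "H"), n), coords,
                  label = sprintf("water%d_ring", n))
  cluster(mol, split(seq_len(3 * n), rep(seq_len(n), each = 3)))
}

# deterministic uniform RNG stream isolated from the global state
new_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  function(n, normal = FALSE) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- if (normal) stats::rnorm(n) else stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
}

#' Randomly perturb a cluster's coordinates
#'
#' Adds isotropic Gaussian displacements (standard deviation `sigma` per
#' Cartesian component) to every atom, reproducibly from `seed`. The
#' fragmentation is preserved. If a draw brings two atoms closer than the
#' 0.3 Angstrom validity floor, it is resampled up to `max_retries` times.
#'
#' @param cl a `dc4_cluster`.
#' @param seed integer seed.
#' @param sigma displacement standard deviation per component, Angstrom.
#' @param max_retries bounded resample count for clashing draws.
#' @return A perturbed `dc4_cluster`.
#' @export
perturb_cluster <- function(cl, seed, sigma, max_retries = 20) {
  stopifnot(inherits(cl, "dc4_cluster"), sigma >= 0)
  mol <- cl$molecule
  n <- n_atoms(mol)
  rng <- new_rng(seed)
  for (try in seq_len(max_retries + 1)) {
    disp <- matrix(rng(3 * n, normal = TRUE), ncol = 3) * sigma
    coords <- mol$coordinates + disp
    if (n == 1 || min(stats::dist(coords)) >= MIN_ATOM_SEPARATION) {
      newmol <- molecule(mol$elements, coords, charge = mol$charge,
                         multiplicity = mol$multiplicity,
                         label = sprintf("%s~s%g", mol$label, seed))
      return(cluster(newmol, cl$fragmentation))
    }
  }
  abort(sprintf("perturbation produced atomic clashes in all %d attempts",
                max_retries + 1))
}

#' Fragment a molecule into water monomers
#'
#' Groups each oxygen with its two nearest hydrogens; used by the many-body
#' expansion CLI for plain water-cluster XYZ files.
#'
#' @param mol a `dc4_molecule` with 2:1 H:O composition.
#' @return A `dc4_cluster`.
#' @export
auto_water_fragments <- function(mol) {
  o_idx <- which(mol$elements == "O")
  h_idx <- which(mol$elements == "H")
  if (length(h_idx) != 2 * length(o_idx) ||
      length(o_idx) + length(h_idx) != n_atoms(mol)) {
    abort("auto water fragmentation needs an (H2O)_n composition")
  }
  d <- as.matrix(stats::dist(mol$coordinates))
  taken <- integer(0)
  frags <- lapply(o_idx, function(o) {
    free <- setdiff(h_idx, taken)
    near <- free[order(d[o, free])][1:2]
    taken <<- c(taken, near)
    sort(c(o, near))
  })
  cluster(mol, frags)
}
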