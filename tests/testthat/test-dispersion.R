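test_that("coordination numbers: isolated atom, monotone bond stretch, oracle", {
  tab <- test_tables()
  o <- molecule("O", matrix(0, 1, 3), multiplicity = 3L)
  expect_identical(coordination_numbers(o, tab), 0)

  # CN of each H in H2 decreases as the bond stretches: strictly so until
  # the counting function saturates to zero at double precision
  rs <- seq(0.7, 5, by = 0.25)
  cns <- vapply(rs, function(r) {
    h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
    coordination_numbers(h2, tab)[1]
  }, 0)
  expect_true(all(diff(cns) <= 0))
  expect_true(all(diff(cns[rs <= 1.3]) < 0))
  expect_lt(cns[length(cns)], 1e-12)

  # brute-force double loop over all pairs on a random 10-atom cluster
  mol <- random_molecule(10, seed = 4)
  rcov <- tab$cov_radii[mol$elements]
  coords_bohr <- mol$coordinates * BOHR_PER_ANGSTROM
  expected <- vapply(1:10, function(i) {
    s <- 0
    for (j in setdiff(1:10, i)) {
      r <- sqrt(sum((coords_bohr[i, ] - coords_bohr[j, ])^2))
      s <- s + 0.5 * (1 + pracma::erf(-7.5 * (r / (rcov[i] + rcov[j]) - 1)))
    }
    s
  }, 0)
  expect_equal(coordination_numbers(mol, tab), expected, tolerance = 1e-12)
})

test_that("EEQ charges: symmetry, constraint, and minimization oracle", {
  tab <- test_tables()
  # neutral homonuclear diatomic: both charges zero
  n2 <- molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  q <- eeq_charges(n2, tab)
  expect_lt(max(abs(q)), 1e-12)

  # single atom carries the total charge exactly
  expect_identical(eeq_charges(molecule("O", matrix(0, 1, 3), charge = -2L),
                               tab), -2)

  # charge conservation on a larger charged system
  mol <- make_water_dimer(3.0)$molecule
  q <- eeq_charges(mol, tab, total_charge = 1)
  expect_lt(abs(sum(q) - 1), 1e-10)

  # independent oracle: numerical minimization of the same energy expression
  m4 <- molecule(c("O", "H", "C", "N"),
                 rbind(c(0, 0, 0), c(0.96, 0, 0), c(0, 1.4, 0),
                       c(1.1, 1.5, 0.9)), multiplicity = 1L)
  q_solve <- eeq_charges(m4, tab)
  obj <- function(qf) dc4:::eeq_energy(c(qf, -sum(qf)), m4, tab)
  opt <- optim(q_solve[1:3], obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  q_opt <- c(opt$par, -sum(opt$par))
  expect_equal(q_solve, q_opt, tolerance = 1e-5)
  expect_lte(dc4:::eeq_energy(q_solve, m4, tab), opt$value + 1e-10)
})

test_that("C6 matrix: symmetric, positive, quadrature oracle, bilinearity", {
  tab <- test_tables()
  mol <- random_molecule(6, seed = 8)
  c6 <- c6_matrix(mol, tables = tab)
  expect_equal(c6, t(c6))
  expect_true(all(c6 > 0))

  # two atoms at huge separation with zero charges: direct quadrature of the
  # CN-interpolated reference polarizabilities, re-derived in-test
  pair <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, 60)),
                   multiplicity = 2L)
  cn <- coordination_numbers(pair, tab)
  expect_lt(max(cn), 1e-12)
  got <- c6_matrix(pair, cn = cn, charges = c(0, 0), tables = tab)
  alpha_of <- function(el) {
    refs <- tab$ref_states[[el]]
    w <- exp(-tab$cn_gauss_beta * (0 - refs$cn_ref)^2)
    a0 <- sum(w / sum(w) * refs$alpha0)
    w0 <- tab$free$w0[tab$free$element == el]
    a0 / (1 + (tab$omega / w0)^2)
  }
  expected <- (3 / pi) * sum(tab$weight * alpha_of("O") * alpha_of("H"))
  expect_equal(got[1, 2], expected, tolerance = 1e-12)

  # free-atom C6 from the quadrature matches the analytic London value the
  # oscillator frequencies were derived from (quadrature accuracy)
  for (el in c("H", "C", "N", "O")) {
    a0 <- tab$free$alpha0[tab$free$element == el]
    w0 <- tab$free$w0[tab$free$element == el]
    alpha <- a0 / (1 + (tab$omega / w0)^2)
    c6_quad <- (3 / pi) * sum(tab$weight * alpha^2)
    expect_equal(c6_quad, 0.75 * a0^2 * w0, tolerance = 1e-6)
  }

  # doubling all reference polarizabilities quadruples C6 (bilinearity)
  tab2 <- tab
  tab2$ref_states <- lapply(tab$ref_states, function(r) {
    r$alpha0 <- 2 * r$alpha0
    r
  })
  c6_scaled <- c6_matrix(mol, tables = tab2)
  expect_equal(c6_scaled, 4 * c6, tolerance = 1e-12)
})

test_that("dispersion energy: single atom, asymptotic tail, s6 channel", {
  tab <- test_tables()
  atom <- molecule("C", matrix(0, 1, 3), multiplicity = 3L)
  expect_identical(dispersion_energy(atom, d4_params(), tab)$total_energy, 0)

  # at R = 50 Angstrom damping is saturated: matches -s6 C6/R^6 - s8 C8/R^8
  pms <- d4_params(s6 = 1, s8 = 1.5, s9 = 0, a1 = 0.45, a2 = 4.5)
  pair <- molecule(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 50)),
                   multiplicity = 1L)
  res <- dispersion_energy(pair, pms, tab)
  r <- 50 * BOHR_PER_ANGSTROM
  c6 <- c6_matrix(pair, tables = tab)[1, 2]
  c8 <- 3 * c6 * tab$q_factor[["O"]]
  tail <- -pms$s6 * c6 / r^6 - pms$s8 * c8 / r^8
  expect_lt(abs(res$total_energy - tail) / abs(tail), 1e-3)

  # doubling s6 changes only the C6 channel; verified against a brute-force
  # pair loop computed directly from the model quantities
  mol <- random_molecule(7, seed = 13)
  p1 <- d4_params(s6 = 1, s8 = 1.2, s9 = 0, a1 = 0.4, a2 = 4)
  p2 <- d4_params(s6 = 2, s8 = 1.2, s9 = 0, a1 = 0.4, a2 = 4)
  cn <- coordination_numbers(mol, tab)
  qq <- eeq_charges(mol, tab, cn = cn)
  c6m <- c6_matrix(mol, cn, qq, tab)
  coords <- mol$coordinates * BOHR_PER_ANGSTROM
  qf <- tab$q_factor[mol$elements]
  brute <- function(p) {
    e <- 0
    for (i in 1:6) for (j in (i + 1):7) {
      rij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      c8 <- 3 * c6m[i, j] * sqrt(qf[i] * qf[j])
      f <- p$a1 * sqrt(c8 / c6m[i, j]) + p$a2
      e <- e - p$s6 * c6m[i, j] / (rij^6 + f^6) - p$s8 * c8 / (rij^8 + f^8)
    }
    e
  }
  e1 <- dispersion_energy(mol, p1, tab)$total_energy
  e2 <- dispersion_energy(mol, p2, tab)$total_energy
  expect_equal(e1, unname(brute(p1)), tolerance = 1e-12)
  expect_equal(e2, unname(brute(p2)), tolerance = 1e-12)
  # the added energy is exactly one extra C6 channel
  extra <- sum(vapply(1:6, function(i) sum(vapply((i + 1):7, function(j) {
    rij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    c8 <- 3 * c6m[i, j] * sqrt(qf[i] * qf[j])
    f <- p1$a1 * sqrt(c8 / c6m[i, j]) + p1$a2
    -c6m[i, j] / (rij^6 + f^6)
  }, 0)), 0))
  expect_equal(e2 - e1, extra, tolerance = 1e-12)
})

test_that("dispersion energy invariances: rigid motion, permutation, decay", {
  tab <- test_tables()
  pms <- d4_params()
  mol <- random_molecule(6, seed = 21)
  e0 <- dispersion_energy(mol, pms, tab, include_atm = TRUE)$total_energy
  e_rt <- dispersion_energy(transform_molecule(mol), pms, tab,
                            include_atm = TRUE)$total_energy
  expect_lt(abs(e0 - e_rt), 1e-12)

  perm <- c(3, 1, 6, 2, 5, 4)
  mol_p <- molecule(mol$elements[perm], mol$coordinates[perm, ],
                    multiplicity = mol$multiplicity)
  e_p <- dispersion_energy(mol_p, pms, tab, include_atm = TRUE)$total_energy
  expect_lt(abs(e0 - e_p), 1e-12)

  # energy vanishes as everything is pulled apart
  far <- molecule(mol$elements, mol$coordinates * 50,
                  multiplicity = mol$multiplicity)
  expect_lt(abs(dispersion_energy(far, pms, tab)$total_energy), 1e-10)

  # two-body energy is non-positive and total = two + three body
  res <- dispersion_energy(mol, pms, tab, include_atm = TRUE)
  expect_lte(res$two_body, 0)
  expect_equal(res$total_energy, res$two_body + res$three_body,
               tolerance = 1e-14)
  expect_equal(sum(res$per_pair$energy), res$two_body, tolerance = 1e-14)
})

test_that("dispersion energy is smooth: finite-difference directional check", {
  tab <- test_tables()
  pms <- d4_params()
  mol <- random_molecule(5, seed = 31)
  set.seed(77)
  dir_vec <- matrix(rnorm(15), ncol = 3)
  dir_vec <- dir_vec / sqrt(sum(dir_vec^2))
  e_at <- function(t) {
    m <- mol
    m$coordinates <- m$coordinates + t * dir_vec
    dispersion_energy(m, pms, tab)$total_energy
  }
  g1 <- (e_at(1e-4) - e_at(-1e-4)) / 2e-4
  g2 <- (e_at(5e-5) - e_at(-5e-5)) / 1e-4
  expect_lt(abs(g1 - g2), 1e-6)
})

test_that("pure damped-C6 limit matches the closed form", {
  tab <- test_tables()
  pms <- d4_params(s6 = 1, s8 = 0, s9 = 0, a1 = 0, a2 = 6)
  mol <- random_molecule(6, seed = 41)
  cn <- coordination_numbers(mol, tab)
  qq <- eeq_charges(mol, tab, cn = cn)
  c6m <- c6_matrix(mol, cn, qq, tab)
  coords <- mol$coordinates * BOHR_PER_ANGSTROM
  expected <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    rij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    expected <- expected - c6m[i, j] / (rij^6 + 6^6)
  }
  expect_equal(dispersion_energy(mol, pms, tab)$total_energy, expected,
               tolerance = 1e-12)
})

test_that("parameter validation and JSON round trip", {
  expect_error(d4_params(s6 = -0.1), "s6")
  expect_error(d4_params(a2 = -1), "a2")
  p <- d4_params(s8 = 1.23456789, a1 = 0.321, a2 = 5.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_d4_params(p, f, provenance = list(note = "test"))
  back <- read_d4_params(f)
  expect_equal(back$s8, p$s8)
  expect_equal(back$a2, p$a2)
})
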