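#' Dispersion-model parameters
#'
#' The five tunables of the Becke-Johnson-damped two-plus-three-body
#' dispersion energy: global scalings `s6`, `s8`, `s9` and the damping
#' offsets `a1` (dimensionless) and `a2` (Bohr). Defaults are placeholder
#' values of typical magnitude for meta-GGA functionals; use [fit_dc4()] to
#' derive parameters for a specific base method under DC-DFT training rules.
#'
#' @param s6,s8,s9 dimensionless channel scalings; `s6 >= 0`.
#' @param a1 dimensionless damping slope.
#' @param a2 damping offset, Bohr; `a2 >= 0`.
#' @return An object of class `dc4_params`.
#' @export
d4_params <- function(s6 = 1, s8 = 0.6, s9 = 1, a1 = 0.4, a2 = 5.0) {
  vals <- c(s6 = s6, s8 = s8, s9 = s9, a1 = a1, a2 = a2)
  if (!all(is.finite(vals))) abort("dispersion parameters must be finite")
  if (s6 < 0) abort("s6 must be non-negative")
  if (a2 < 0) abort("a2 must be non-negative")
  structure(as.list(vals), class = "dc4_params")
}

#' @export
print.dc4_params <- function(x, ...) {
  cat(sprintf("<D4 parameters: s6=%.4f s8=%.4f s9=%.4f a1=%.4f a2=%.4f Bohr>\n",
              x$s6, x$s8, x$s9, x$a1, x$a2))
  invisible(x)
}

#' Read/write dispersion parameters as JSON
#' @param params a [d4_params()] object.
#' @param path file path.
#' @param provenance optional provenance list stored alongside the values.
#' @return `read_d4_params()` returns a `dc4_params`.
#' @export
write_d4_params <- function(params, path, provenance = list()) {
  jsonlite::write_json(
    list(s6 = params$s6, s8 = params$s8, s9 = params$s9,
         a1 = params$a1, a2 = params$a2, provenance = provenance),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_d4_params
#' @export
read_d4_params <- function(path) {
  x <- jsonlite::fromJSON(path)
  d4_params(s6 = x$s6, s8 = x$s8, s9 = x$s9, a1 = x$a1, a2 = x$a2)
}

# pairwise distance matrix in Bohr
distance_matrix_bohr <- function(mol) {
  as.matrix(stats::dist(mol$coordinates)) * BOHR_PER_ANGSTROM
}

#' Fractional coordination numbers
#'
#' Error-function pair counting with covalent radii:
#' `CN_i = sum_j 1/2 (1 + erf(-k (R_ij / R_cov,ij - 1)))` with `k = 7.5` and
#' `R_cov,ij` the sum of covalent radii. Smooth in the coordinates and zero
#' for an isolated atom.
#'
#' @param mol a `dc4_molecule`.
#' @param tables [d4_reference_tables()].
#' @param k_cn counting steepness.
#' @return Numeric per-atom coordination numbers.
#' @export
coordination_numbers <- function(mol, tables = d4_reference_tables(),
                                 k_cn = 7.5) {
  check_table_coverage(mol, tables)
  n <- n_atoms(mol)
  if (n == 1) return(0)
  rcov <- tables$cov_radii[mol$elements]
  r <- distance_matrix_bohr(mol)
  rc <- outer(rcov, rcov, `+`)
  cnt <- 0.5 * (1 + pracma::erf(-k_cn * (r / rc - 1)))
  diag(cnt) <- 0
  unname(rowSums(cnt))
}

#' Electronegativity-equilibration partial charges
#'
#' Minimizes the classical charge energy
#' `E(q) = sum_i (chi_i q_i + 1/2 J_ii q_i^2) + 1/2 sum_{i!=j} q_i q_j
#' erf(R_ij / g_ij) / R_ij` subject to `sum q_i = Q`, where
#' `J_ii = eta_i + sqrt(2/pi)/rad_i` and `g_ij = sqrt(rad_i^2 + rad_j^2)`.
#' The effective electronegativity is coordination-corrected:
#' `chi_i(CN) = chi_i - kappa_i sqrt(CN_i)`. Solved as a bordered symmetric
#' linear system (Lagrange multiplier enforcing the total charge).
#'
#' @param mol a `dc4_molecule`.
#' @param tables [d4_reference_tables()].
#' @param total_charge total charge constraint; defaults to the molecule's.
#' @param cn optional precomputed coordination numbers.
#' @return Numeric per-atom partial charges summing to `total_charge`.
#' @export
eeq_charges <- function(mol, tables = d4_reference_tables(),
                        total_charge = mol$charge, cn = NULL) {
  check_table_coverage(mol, tables)
  n <- n_atoms(mol)
  p <- tables$eeq[match(mol$elements, tables$eeq$element), ]
  if (n == 1) return(as.numeric(total_charge))
  if (is.null(cn)) cn <- coordination_numbers(mol, tables)
  r <- distance_matrix_bohr(mol)
  gij <- sqrt(outer(p$rad^2, p$rad^2, `+`))
  a <- pracma::erf(r / gij) / r
  diag(a) <- p$eta + sqrt(2 / pi) / p$rad
  chi_eff <- p$chi - p$kappa_cn * sqrt(cn)
  m <- rbind(cbind(a, rep(1, n)), c(rep(1, n), 0))
  if (rcond(m) < 1e-12) {
    abort(sprintf("EEQ system ill-conditioned for molecule '%s'", mol$label))
  }
  sol <- solve(m, c(-chi_eff, total_charge))
  q <- unname(sol[seq_len(n)])
  # enforce the constraint to solver precision
  q - (sum(q) - total_charge) / n
}

# classical EEQ energy, used by tests as the minimization oracle
eeq_energy <- function(q, mol, tables, cn = NULL) {
  n <- n_atoms(mol)
  p <- tables$eeq[match(mol$elements, tables$eeq$element), ]
  if (is.null(cn)) cn <- coordination_numbers(mol, tables)
  chi_eff <- p$chi - p$kappa_cn * sqrt(cn)
  jii <- p$eta + sqrt(2 / pi) / p$rad
  e <- sum(chi_eff * q) + 0.5 * sum(jii * q^2)
  if (n > 1) {
    r <- distance_matrix_bohr(mol)
    gij <- sqrt(outer(p$rad^2, p$rad^2, `+`))
    off <- pracma::erf(r / gij) / r
    diag(off) <- 0
    e <- e + 0.5 * sum(off * outer(q, q))
  }
  e
}

# charge-scaling of reference polarizabilities: zeta(q) = exp(b (1 -
# exp(eta_z (1 - (Z + q_ref)/(Z + q))))); equals 1 at q = q_ref, grows for
# anionic atoms, shrinks for cationic ones, and saturates at exp(b) as the
# electron count is exhausted.
zeta_charge_scale <- function(q, z_eff, beta = 3, eta_z = 1) {
  zq <- z_eff + q
  ifelse(zq <= 0, exp(beta),
         exp(beta * (1 - exp(eta_z * (1 - z_eff / zq)))))
}

# per-atom dynamic polarizabilities on the quadrature grid:
# Gaussian CN interpolation over reference states, then charge scaling
atomic_alpha_grid <- function(mol, cn, charges, tables) {
  n <- n_atoms(mol)
  nq <- length(tables$omega)
  alpha <- matrix(0, n, nq)
  for (i in seq_len(n)) {
    el <- mol$elements[i]
    refs <- tables$ref_states[[el]]
    w <- exp(-tables$cn_gauss_beta * (cn[i] - refs$cn_ref)^2)
    w <- w / sum(w)
    alpha0 <- sum(w * refs$alpha0)
    zeta <- zeta_charge_scale(charges[i], ELEMENT_NUMBERS[[el]],
                              beta = tables$zeta_beta)
    w0 <- tables$free$w0[tables$free$element == el]
    alpha[i, ] <- zeta * alpha0 / (1 + (tables$omega / w0)^2)
  }
  alpha
}

#' Pairwise C6 coefficients by Casimir-Polder quadrature
#'
#' Reference polarizabilities are interpolated to each atom's fractional
#' coordination number with Gaussian weights and scaled by the EEQ partial
#' charge, then integrated: `C6_AB = 3/pi Int alpha_A(iw) alpha_B(iw) dw`
#' on the fixed quadrature grid of the tables.
#'
#' @param mol a `dc4_molecule`.
#' @param cn per-atom coordination numbers (computed when `NULL`).
#' @param charges per-atom partial charges (computed when `NULL`).
#' @param tables [d4_reference_tables()].
#' @return Symmetric positive N x N matrix, Hartree Bohr^6.
#' @export
c6_matrix <- function(mol, cn = NULL, charges = NULL,
                      tables = d4_reference_tables()) {
  check_table_coverage(mol, tables)
  if (is.null(cn)) cn <- coordination_numbers(mol, tables)
  if (is.null(charges)) charges <- eeq_charges(mol, tables, cn = cn)
  alpha <- atomic_alpha_grid(mol, cn, charges, tables)
  (3 / pi) * (alpha %*% (tables$weight * t(alpha)))
}

# pair table (i, j, r_bohr, c6, c8) reused by the fast fitting path
dispersion_pair_table <- function(mol, tables, cn = NULL, charges = NULL) {
  n <- n_atoms(mol)
  if (n < 2) {
    return(tibble::tibble(i = integer(), j = integer(), r = numeric(),
                          c6 = numeric(), c8 = numeric()))
  }
  if (is.null(cn)) cn <- coordination_numbers(mol, tables)
  if (is.null(charges)) charges <- eeq_charges(mol, tables, cn = cn)
  c6 <- c6_matrix(mol, cn, charges, tables)
  qf <- tables$q_factor[mol$elements]
  r <- distance_matrix_bohr(mol)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  c8 <- 3 * c6 * sqrt(outer(qf, qf))
  tibble::tibble(
    i = idx[, 1], j = idx[, 2],
    r = r[idx], c6 = c6[idx], c8 = c8[idx]
  )
}

# BJ-damped two-body energy from a pair table; vectorized over pairs
pair_energy_bj <- function(pairs, params) {
  if (nrow(pairs) == 0) return(numeric(0))
  r0 <- sqrt(pairs$c8 / pairs$c6)            # critical radius, Bohr
  f <- params$a1 * r0 + params$a2
  -(params$s6 * pairs$c6 / (pairs$r^6 + f^6) +
      params$s8 * pairs$c8 / (pairs$r^8 + f^8))
}

# Axilrod-Teller-Muto triple-dipole term with BJ-type critical radii and a
# zero-damping switch; s9 scales the whole term
atm_energy <- function(mol, c6, params, tables) {
  n <- n_atoms(mol)
  if (n < 3 || params$s9 == 0) return(0)
  r <- distance_matrix_bohr(mol)
  qf <- tables$q_factor[mol$elements]
  r0m <- params$a1 * sqrt(3 * sqrt(outer(qf, qf))) + params$a2
  e <- 0
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    rab <- r[a, b]; rac <- r[a, cc]; rbc <- r[b, cc]
    c9 <- sqrt(c6[a, b] * c6[a, cc] * c6[b, cc])
    cosa <- (rab^2 + rac^2 - rbc^2) / (2 * rab * rac)
    cosb <- (rab^2 + rbc^2 - rac^2) / (2 * rab * rbc)
    cosc <- (rac^2 + rbc^2 - rab^2) / (2 * rac * rbc)
    geom <- (3 * cosa * cosb * cosc + 1) / (rab * rac * rbc)^3
    r0 <- (r0m[a, b] * r0m[a, cc] * r0m[b, cc])^(1 / 3)
    rbar <- (rab * rac * rbc)^(1 / 3)
    damp <- 1 / (1 + 6 * (r0 / rbar)^16)
    e <- e + c9 * geom * damp
  }
  params$s9 * e
}

#' Charge- and coordination-dependent dispersion energy
#'
#' Two-body Becke-Johnson-damped energy
#' `E2 = -sum_{A<B} s6 C6 / (R^6 + f^6) + s8 C8 / (R^8 + f^8)` with
#' `f = a1 sqrt(C8/C6) + a2` and `C8 = 3 C6 sqrt(Q_A Q_B)`, plus an optional
#' Axilrod-Teller-Muto three-body term scaled by `s9`.
#'
#' @param mol a `dc4_molecule`.
#' @param params [d4_params()].
#' @param tables [d4_reference_tables()].
#' @param include_atm include the three-body term (default off).
#' @return A `dc4_dispersion_result`: list with `total_energy`, `two_body`,
#'   `three_body` (Hartree), a per-pair tibble, and the charges and
#'   coordination numbers used.
#' @export
dispersion_energy <- function(mol, params = d4_params(),
                              tables = d4_reference_tables(),
                              include_atm = FALSE) {
  stopifnot(inherits(mol, "dc4_molecule"), inherits(params, "dc4_params"))
  check_table_coverage(mol, tables)
  cn <- coordination_numbers(mol, tables)
  charges <- eeq_charges(mol, tables, cn = cn)
  pairs <- dispersion_pair_table(mol, tables, cn = cn, charges = charges)
  pairs$energy <- pair_energy_bj(pairs, params)
  e2 <- sum(pairs$energy)
  e3 <- if (include_atm && n_atoms(mol) >= 3) {
    c6 <- c6_matrix(mol, cn, charges, tables)
    atm_energy(mol, c6, params, tables)
  } else 0
  structure(
    list(total_energy = e2 + e3, two_body = e2, three_body = e3,
         per_pair = pairs, charges = charges, coordination_numbers = cn,
         params = params),
    class = "dc4_dispersion_result"
  )
}

#' @export
print.dc4_dispersion_result <- function(x, ...) {
  cat(sprintf(
    "<dispersion: total %.10f Eh (two-body %.10f, three-body %.10f)>\n",
    x$total_energy, x$two_body, x$three_body))
  invisible(x)
}

#' Tidy a dispersion result into its per-pair breakdown
#' @param x a `dc4_dispersion_result`.
#' @param ... unused.
#' @return A tibble with pair indices, distance (Bohr), C6, C8 and the pair
#'   energy (Hartree).
#' @export
#' @exportS3Method generics::tidy
tidy.dc4_dispersion_result <- function(x, ...) x$per_pair
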