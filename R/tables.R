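#' Reference tables for the charge-dependent dispersion model
#'
#' This package's own compact parameterization for H, C, N and O — the
#' elements needed for water, nucleobase and small-organic chemistry. It is
#' assembled from published physical constants, not copied from any external
#' dispersion code:
#'
#' * covalent radii (Pyykkoe single-bond values, converted to Bohr), used by
#'   the error-function coordination-number count;
#' * electronegativity-equilibration (EEQ) parameters: electronegativity
#'   `chi`, chemical hardness `eta`, Gaussian charge width `rad` (Bohr) and a
#'   coordination coupling `kappa_cn`, chosen to give the familiar charge
#'   ordering (O most negative, H positive) with water charges near
#'   q(O) = -0.6 e;
#' * reference dynamic polarizabilities: per element, a small set of
#'   coordination states `(CN_ref, alpha0)` with a single-oscillator
#'   (Drude/London) frequency dependence `alpha(iw) = alpha0 / (1 + (w/w0)^2)`,
#'   where `w0` is fixed per element so that the free-atom Casimir-Polder
#'   integral reproduces the published free-atom C6 (London: C6 = 3/4
#'   alpha0^2 w0);
#' * `sqrt(Q)` multipole factors for C8 = 3 C6 sqrt(Q_A Q_B), with
#'   Q = 1/2 sqrt(Z) <r^4>/<r^2> from standard atomic expectation values.
#'
#' The imaginary-frequency quadrature is a fixed Gauss-Legendre grid mapped
#' to `[0, Inf)`, stored in the table so every C6 in a session uses the same
#' grid.
#'
#' @param n_quad number of quadrature nodes.
#' @return A list of class `dc4_reference_tables`.
#' @export
d4_reference_tables <- function(n_quad = 32) {
  ang2bohr <- BOHR_PER_ANGSTROM
  # Pyykkoe single-bond radii scaled by the customary 4/3 so that the
  # erf-counting function registers ~1 per covalent bond
  cov_radii <- (4 / 3) * c(H = 0.32, C = 0.75, N = 0.71, O = 0.63) * ang2bohr

  eeq <- tibble::tibble(
    element = c("H", "C", "N", "O"),
    chi  = c(1.18, 1.28, 1.46, 1.65),   # electronegativity, a.u.
    eta  = c(0.50, 0.40, 0.48, 0.58),   # hardness, a.u.
    rad  = c(0.80, 1.20, 1.10, 1.00),   # Gaussian charge width, Bohr
    kappa_cn = c(0.02, 0.03, 0.05, 0.06)
  )

  # free-atom static polarizabilities (a.u.) and free-atom C6 (a.u.);
  # w0 chosen so the Drude Casimir-Polder integral gives exactly that C6
  free <- tibble::tibble(
    element = c("H", "C", "N", "O"),
    alpha0 = c(4.50, 11.30, 7.40, 5.40),
    c6_free = c(6.5, 46.6, 24.2, 15.6)
  )
  free$w0 <- free$c6_free / (0.75 * free$alpha0^2)

  # in-molecule reference states: polarizability contracts with coordination
  ref_states <- list(
    H = tibble::tibble(cn_ref = c(0, 1), alpha0 = c(4.50, 2.20)),
    C = tibble::tibble(cn_ref = c(0, 2, 3, 4), alpha0 = c(11.30, 9.50, 8.60, 7.90)),
    N = tibble::tibble(cn_ref = c(0, 1, 2, 3), alpha0 = c(7.40, 6.60, 6.00, 5.60)),
    O = tibble::tibble(cn_ref = c(0, 1, 2), alpha0 = c(5.40, 4.80, 4.30))
  )

  # sqrt(Q) factors: Q = 1/2 sqrt(Z) <r^4>/<r^2>
  r4r2 <- c(H = 8.0589, C = 29.2087, N = 25.2685, O = 22.3241)
  z <- ELEMENT_NUMBERS[names(r4r2)]
  q_factor <- 0.5 * sqrt(z) * r4r2

  gl <- pracma::gaussLegendre(n_quad, 0, 1)
  # map t in (0,1) to w in (0, Inf): w = t/(1-t), dw = dt/(1-t)^2
  omega <- gl$x / (1 - gl$x)
  weight <- gl$w / (1 - gl$x)^2

  structure(
    list(cov_radii = cov_radii, eeq = eeq, free = free,
         ref_states = ref_states, q_factor = q_factor,
         omega = omega, weight = weight,
         cn_gauss_beta = 4,   # width of Gaussian CN interpolation weights
         zeta_beta = 3),      # steepness of the charge-scaling function
    class = "dc4_reference_tables"
  )
}

check_table_coverage <- function(mol, tables) {
  miss <- setdiff(unique(mol$elements), names(tables$cov_radii))
  if (length(miss) > 0) {
    abort(paste0("reference tables lack element(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}
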