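#' Unit conversion constants
#'
#' Coordinates are Angstrom in all I/O and Bohr internally; energies are
#' Hartree internally and kcal/mol in all reports.
#'
#' @format Named numeric scalars.
#' @name units
NULL

#' @rdname units
#' @export
BOHR_PER_ANGSTROM <- 1.8897259886

#' @rdname units
#' @export
KCAL_PER_HARTREE <- 627.509474

#' Convert Hartree to kcal/mol
#' @param x energy in Hartree
#' @return energy in kcal/mol
#' @export
hartree_to_kcal <- function(x) x * KCAL_PER_HARTREE

#' Convert kcal/mol to Hartree
#' @param x energy in kcal/mol
#' @return energy in Hartree
#' @export
kcal_to_hartree <- function(x) x / KCAL_PER_HARTREE
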