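#' @importFrom rlang %||% abort
NULL

ELEMENT_NUMBERS <- c(H = 1L, C = 6L, N = 7L, O = 8L)

# minimum allowed inter-atomic distance (Angstrom); closer atoms are unphysical
MIN_ATOM_SEPARATION <- 0.3

#' Construct a molecule
#'
#' The universal geometry record: element symbols, Cartesian coordinates in
#' Angstrom, total charge and spin multiplicity.
#'
#' @param elements character vector of element symbols.
#' @param coordinates numeric N x 3 matrix, Angstrom.
#' @param charge integer total charge.
#' @param multiplicity positive integer spin multiplicity (2S + 1).
#' @param label free-text identifier.
#' @return An object of class `dc4_molecule`.
#' @export
molecule <- function(elements, coordinates, charge = 0L, multiplicity = 1L,
                     label = "") {
  elements <- as.character(elements)
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  if (nrow(coordinates) != length(elements)) {
    abort("coordinate rows must equal element count")
  }
  unknown <- setdiff(unique(elements), names(ELEMENT_NUMBERS))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.finite(charge) || charge != round(charge)) abort("charge must be integer")
  if (!is.finite(multiplicity) || multiplicity < 1 ||
      multiplicity != round(multiplicity)) {
    abort("multiplicity must be a positive integer")
  }
  n_elec <- sum(ELEMENT_NUMBERS[elements]) - charge
  # multiplicity parity: n unpaired electrons = multiplicity - 1 shares parity
  # with the electron count
  if ((n_elec %% 2L) != ((multiplicity - 1L) %% 2L)) {
    abort(sprintf(
      "multiplicity %d inconsistent with %d electrons (parity)",
      multiplicity, n_elec
    ))
  }
  if (length(elements) > 1) {
    dmin <- min(stats::dist(coordinates))
    if (dmin < MIN_ATOM_SEPARATION) {
      abort(sprintf("atoms closer than %.1f Angstrom (min %.3f)",
                    MIN_ATOM_SEPARATION, dmin))
    }
  }
  structure(
    list(
      elements = elements,
      coordinates = unname(coordinates),
      charge = as.integer(charge),
      multiplicity = as.integer(multiplicity),
      label = as.character(label)
    ),
    class = "dc4_molecule"
  )
}

#' @export
print.dc4_molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule '%s': %d atoms [%s], charge %+d, multiplicity %d>\n",
    x$label, length(x$elements),
    paste(names(table(x$elements)), table(x$elements), sep = "", collapse = " "),
    x$charge, x$multiplicity
  ))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `dc4_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Tidy a molecule into an atom table
#' @param x a `dc4_molecule`.
#' @param ... unused.
#' @return A tibble with columns `element`, `x`, `y`, `z` (Angstrom).
#' @export
#' @exportS3Method generics::tidy
tidy.dc4_molecule <- function(x, ...) {
  tibble::tibble(
    element = x$elements,
    x = x$coordinates[, 1],
    y = x$coordinates[, 2],
    z = x$coordinates[, 3]
  )
}

#' Read a molecule from XYZ
#'
#' Standard two-header-line XYZ dialect, coordinates in Angstrom. The comment
#' line may carry `charge=<int>` and `mult=<int>` key-value pairs.
#'
#' @param x path to an `.xyz` file, or a character vector of XYZ text
#'   (single string with newlines, or one string per line).
#' @param label optional label; defaults to the comment line or file name.
#' @return A `dc4_molecule`.
#' @export
read_xyz <- function(x, label = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    label <- label %||% sub("\\.xyz$", "", basename(x))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 2) abort("XYZ input needs at least two header lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) abort("XYZ line 1 must be a positive atom count")
  comment <- if (length(lines) >= 2) lines[2] else ""
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    abort(sprintf("XYZ header declares %d atoms but only %d atom lines found",
                  n, length(body)))
  }
  body <- body[seq_len(n)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 4)
  if (length(bad) > 0) {
    abort(sprintf("XYZ atom line %d malformed: '%s'", bad[1] + 2L, body[bad[1]]))
  }
  elements <- vapply(parts, `[[`, "", 1L)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(coords)) abort("non-numeric coordinate in XYZ body")
  charge <- 0L
  mult <- 1L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2) charge <- as.integer(m[2])
  m <- regmatches(comment, regexec("mult=([0-9]+)", comment))[[1]]
  if (length(m) == 2) mult <- as.integer(m[2])
  molecule(elements, coords, charge = charge, multiplicity = mult,
           label = label %||% trimws(comment))
}

#' Write a molecule to XYZ text
#'
#' @param mol a `dc4_molecule`.
#' @param path optional file path; when `NULL` the XYZ text is returned.
#' @param digits coordinate digits (default preserves 1e-6 Angstrom round trip).
#' @return The XYZ text, invisibly when written to a file.
#' @export
write_xyz <- function(mol, path = NULL, digits = 10) {
  comment <- mol$label
  if (mol$charge != 0L || mol$multiplicity != 1L) {
    comment <- trimws(sprintf("%s charge=%d mult=%d", comment, mol$charge,
                              mol$multiplicity))
  }
  fmt <- sprintf("%%-2s %%.%df %%.%df %%.%df", digits, digits, digits)
  body <- sprintf(fmt, mol$elements, mol$coordinates[, 1],
                  mol$coordinates[, 2], mol$coordinates[, 3])
  txt <- paste(c(length(mol$elements), comment, body), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
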