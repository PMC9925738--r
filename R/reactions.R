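#' Construct a stoichiometric reaction
#'
#' Species are referenced by label; the molecules themselves live in the
#' enclosing [reaction_set()]. The sign convention is products positive, so a
#' bound dimer's interaction energy (`+1` dimer, `-2` monomer) is negative.
#'
#' @param species character vector of species labels.
#' @param coefficients signed numeric stoichiometric coefficients.
#' @param reference_energy reference reaction energy, kcal/mol.
#' @param tag unique reaction identifier within a set.
#' @param dataset dataset name the reaction belongs to (for grouped metrics).
#' @return An object of class `dc4_reaction`.
#' @export
reaction <- function(species, coefficients, reference_energy, tag,
                     dataset = "default") {
  coefficients <- as.numeric(coefficients)
  if (length(species) != length(coefficients)) {
    abort("species and coefficients must have equal length")
  }
  if (any(coefficients == 0)) abort("zero stoichiometric coefficient")
  if (!any(coefficients > 0) || !any(coefficients < 0)) {
    abort("a reaction needs at least one positive and one negative coefficient")
  }
  if (!is.finite(reference_energy)) abort("reference_energy must be finite")
  structure(
    list(species = as.character(species), coefficients = coefficients,
         reference_energy = as.numeric(reference_energy),
         tag = as.character(tag), dataset = as.character(dataset)),
    class = "dc4_reaction"
  )
}

#' Construct a reaction set
#'
#' The unit of benchmarking and fitting: an ordered list of reactions plus
#' the molecule table their species labels resolve to.
#'
#' @param reactions list of [reaction()] objects.
#' @param molecules named list of `dc4_molecule`, one per species label used.
#' @param name set name.
#' @param provenance free-form list recording how the set was produced.
#' @return An object of class `dc4_reaction_set`.
#' @export
reaction_set <- function(reactions, molecules, name = "reactions",
                         provenance = list()) {
  if (length(reactions) == 0) abort("reaction set must be non-empty")
  tags <- vapply(reactions, `[[`, "", "tag")
  if (anyDuplicated(tags) > 0) {
    abort(paste0("duplicate reaction tags: ",
                 paste(unique(tags[duplicated(tags)]), collapse = ", ")))
  }
  needed <- unique(unlist(lapply(reactions, `[[`, "species")))
  missing <- setdiff(needed, names(molecules))
  if (length(missing) > 0) {
    abort(paste0("species without molecules: ", paste(missing, collapse = ", ")))
  }
  structure(
    list(reactions = reactions, molecules = molecules, name = name,
         provenance = provenance),
    class = "dc4_reaction_set"
  )
}

#' @export
print.dc4_reaction_set <- function(x, ...) {
  cat(sprintf("<reaction set '%s': %d reactions, %d species>\n",
              x$name, length(x$reactions), length(x$molecules)))
  invisible(x)
}

#' @export
length.dc4_reaction_set <- function(x) length(x$reactions)

#' Tidy a reaction set into one row per reaction
#' @param x a `dc4_reaction_set`.
#' @param ... unused.
#' @return A tibble with `tag`, `dataset`, `reference_energy` (kcal/mol),
#'   `n_species` and a compact `equation` string.
#' @export
#' @exportS3Method generics::tidy
tidy.dc4_reaction_set <- function(x, ...) {
  purrr::map_dfr(x$reactions, function(r) {
    tibble::tibble(
      tag = r$tag, dataset = r$dataset,
      reference_energy = r$reference_energy,
      n_species = length(r$species),
      equation = paste(sprintf("%+g %s", r$coefficients, r$species),
                       collapse = " ")
    )
  })
}

#' Load a reaction table
#'
#' Plain-text dialect mirroring common GMTKN55 distributions: whitespace
#' separated, `#` comments, one reaction per row as
#' `tag label coeff label coeff ... reference_energy`, energies in kcal/mol.
#' Every species label must resolve to `<label>.xyz` in `geometry_dir`.
#'
#' @param path reaction table file.
#' @param geometry_dir directory of XYZ geometries.
#' @param name set name; defaults to the file name.
#' @param dataset dataset tag applied to all rows.
#' @return A `dc4_reaction_set`.
#' @export
load_reaction_table <- function(path, geometry_dir, name = NULL,
                                dataset = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty reaction table")
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  dataset <- dataset %||% name
  molecules <- list()
  reactions <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 6 || length(tok) %% 2 != 0) {
      abort(sprintf("malformed reaction row (need tag, label/coeff pairs, energy): '%s'", ln))
    }
    tag <- tok[1]
    ref <- suppressWarnings(as.numeric(tok[length(tok)]))
    if (is.na(ref)) abort(sprintf("non-numeric reference energy in row '%s'", ln))
    body <- tok[-c(1, length(tok))]
    labels <- body[seq(1, length(body), 2)]
    coeffs <- suppressWarnings(as.numeric(body[seq(2, length(body), 2)]))
    if (anyNA(coeffs)) abort(sprintf("non-numeric coefficient in row '%s'", ln))
    for (lab in labels) {
      if (is.null(molecules[[lab]])) {
        f <- file.path(geometry_dir, paste0(lab, ".xyz"))
        if (!file.exists(f)) {
          abort(sprintf("missing geometry file for species '%s': %s", lab, f))
        }
        molecules[[lab]] <<- read_xyz(f, label = lab)
      }
    }
    reaction(labels, coeffs, ref, tag = tag, dataset = dataset)
  })
  reaction_set(reactions, molecules, name = name,
               provenance = list(source = path, geometry_dir = geometry_dir))
}

#' Write a reaction set to the plain-text table dialect
#'
#' Inverse of [load_reaction_table()]: writes `<name>.res` plus one XYZ per
#' species into `dir`.
#'
#' @param rset a `dc4_reaction_set`.
#' @param dir output directory (created if needed).
#' @return The table path, invisibly.
#' @export
write_reaction_table <- function(rset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(rset$reactions, function(r) {
    paste(c(r$tag, rbind(r$species, format(r$coefficients)),
            sprintf("%.8f", r$reference_energy)), collapse = " ")
  }, "")
  path <- file.path(dir, paste0(rset$name, ".res"))
  writeLines(rows, path)
  for (lab in names(rset$molecules)) {
    write_xyz(rset$molecules[[lab]], file.path(dir, paste0(lab, ".xyz")))
  }
  invisible(path)
}
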