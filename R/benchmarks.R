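#' Canonical names of the five water-based datasets
#'
#' Hexamer isomer energies, 20-mer isomer energies, water-cluster binding
#' energies, water-small-organic interaction energies and water-dimer
#' interaction energies: the pooled-MAE "water metric" is defined over the
#' reactions of these five sets.
#'
#' @export
WATER_DATASETS <- c("hexamer_isomers", "water20_isomers", "water27_binding",
                    "water_organic", "water_dimers")

#' Run a method over a reaction dataset
#'
#' Computes the composite energy of every distinct species once, assembles
#' per-reaction errors (computed minus reference, kcal/mol), and records
#' failures per reaction without aborting the run.
#'
#' @param rset a `dc4_reaction_set`.
#' @param engine an engine.
#' @param spec a [method_spec()].
#' @param params [d4_params()].
#' @param tables [d4_reference_tables()].
#' @param include_atm include the three-body dispersion term.
#' @return A tibble: `tag`, `dataset`, `computed`, `reference`, `error`
#'   (kcal/mol), `failed` (logical), `failure` (message or `NA`).
#' @export
run_dataset <- function(rset, engine, spec, params = d4_params(),
                        tables = d4_reference_tables(), include_atm = FALSE) {
  lookup <- lapply(rset$molecules, function(m) {
    tryCatch(
      composite_energy(m, engine, spec, params, tables,
                       include_atm = include_atm),
      error = function(e) structure(conditionMessage(e), class = "dc4_failure")
    )
  })
  purrr::map_dfr(rset$reactions, function(r) {
    bad <- vapply(r$species, function(s) inherits(lookup[[s]], "dc4_failure"),
                  TRUE)
    if (any(bad)) {
      msg <- unclass(lookup[[r$species[which(bad)[1]]]])
      return(tibble::tibble(tag = r$tag, dataset = r$dataset,
                            computed = NA_real_,
                            reference = r$reference_energy,
                            error = NA_real_, failed = TRUE, failure = msg))
    }
    de <- reaction_energy(r, lookup)
    tibble::tibble(tag = r$tag, dataset = r$dataset, computed = de,
                   reference = r$reference_energy,
                   error = de - r$reference_energy,
                   failed = FALSE, failure = NA_character_)
  })
}

#' Pooled water metric
#'
#' The MAE over all reactions of the five water-based datasets pooled
#' together — not the mean of per-dataset MAEs. Failed reactions are
#' excluded with a warning; datasets absent from the input are listed in a
#' warning but do not abort the computation.
#'
#' @param errors a tibble with columns `dataset` and `error` (e.g. stacked
#'   [run_dataset()] outputs), or a named list of such tibbles.
#' @param datasets canonical dataset names expected (default
#'   [WATER_DATASETS]).
#' @return Pooled MAE, kcal/mol.
#' @export
water_metric <- function(errors, datasets = WATER_DATASETS) {
  if (is.list(errors) && !is.data.frame(errors)) {
    errors <- dplyr::bind_rows(errors)
  }
  present <- intersect(datasets, unique(errors$dataset))
  absent <- setdiff(datasets, present)
  if (length(present) == 0) abort("no water dataset present in input")
  if (length(absent) > 0) {
    warning(sprintf("water metric computed without: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  pool <- errors[errors$dataset %in% present, ]
  if ("failed" %in% names(pool) && any(pool$failed)) {
    warning(sprintf("%d failed reactions excluded from the water metric",
                    sum(pool$failed)), call. = FALSE)
    pool <- pool[!pool$failed, ]
  }
  mae(pool$error)
}

#' Weighted mean absolute deviation (WTMAD-2)
#'
#' `(sum_i N_i (56.84 / |dEbar|_i) MAD_i) / (sum_i N_i)`: per-dataset mean
#' absolute deviations weighted inversely to the dataset's mean absolute
#' reference reaction energy, making small-energy datasets count as much as
#' thermochemistry-scale ones. 56.84 kcal/mol is the grand mean absolute
#' reaction energy of the reference benchmark collection this weighting was
#' defined for.
#'
#' @param mads per-dataset mean absolute deviations, kcal/mol.
#' @param mean_abs_ref per-dataset mean `|reference energy|`, kcal/mol.
#' @param sizes per-dataset reaction counts.
#' @return WTMAD-2, kcal/mol.
#' @export
wtmad2 <- function(mads, mean_abs_ref, sizes) {
  stopifnot(length(mads) == length(mean_abs_ref),
            length(mads) == length(sizes))
  if (any(mads < 0) || any(mean_abs_ref <= 0) || any(sizes < 1)) {
    abort("wtmad2 needs non-negative MADs, positive |dE| and sizes >= 1")
  }
  sum(sizes * (56.84 / mean_abs_ref) * mads) / sum(sizes)
}

#' WTMAD-2 from a per-reaction error table
#'
#' @param errors tibble with `dataset`, `error`, `reference` columns.
#' @return WTMAD-2, kcal/mol.
#' @export
wtmad2_from_errors <- function(errors) {
  if ("failed" %in% names(errors)) errors <- errors[!errors$failed, ]
  tab <- errors |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(mad = mean(abs(.data$error)),
                     mean_abs_ref = mean(abs(.data$reference)),
                     n = dplyr::n(), .groups = "drop")
  wtmad2(tab$mad, tab$mean_abs_ref, tab$n)
}

#' Sensitivity-versus-error table
#'
#' Joins per-reaction errors of a self-consistent and a density-corrected
#' method variant with their density sensitivities; the standard diagnostic
#' for density-driven error (self-consistent errors grow with sensitivity,
#' density-corrected errors do not).
#'
#' @param errors_sc tibble `tag`, `error` for the self-consistent variant.
#' @param errors_dc tibble `tag`, `error` for the density-corrected variant.
#' @param sens sensitivity table with `tag`, `s_tilde` (and optionally
#'   `classification`).
#' @return A tibble sorted by increasing `s_tilde` with columns `tag`,
#'   `s_tilde`, `sc_error`, `dc_error` (and `classification` if supplied).
#' @export
sensitivity_error_table <- function(errors_sc, errors_dc, sens) {
  if (is.null(sens) || nrow(sens) == 0) abort("empty sensitivity input")
  out <- sens |>
    dplyr::inner_join(dplyr::select(errors_sc, "tag", sc_error = "error"),
                      by = "tag") |>
    dplyr::inner_join(dplyr::select(errors_dc, "tag", dc_error = "error"),
                      by = "tag") |>
    dplyr::arrange(.data$s_tilde)
  keep <- intersect(c("tag", "s_tilde", "classification", "sc_error",
                      "dc_error"), names(out))
  dplyr::select(out, dplyr::all_of(keep))
}
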