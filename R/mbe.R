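#' Enumerate K-fragment subclusters
#'
#' All `choose(N, K)` combinations of a cluster's fragments, in
#' deterministic lexicographic order, each extracted as a molecule at its
#' frozen in-cluster geometry.
#'
#' @param cl a `dc4_cluster` with N fragments.
#' @param k subcluster size, `1 <= k <= N`.
#' @return A list with elements `frags` (list of index vectors) and
#'   `molecules` (list of `dc4_molecule`).
#' @export
enumerate_subclusters <- function(cl, k) {
  n <- n_fragments(cl)
  if (k < 1 || k > n) abort(sprintf("k must lie in [1, %d]", n))
  combos <- utils::combn(n, k, simplify = FALSE)
  list(
    frags = combos,
    molecules = lapply(combos, function(fr) subcluster_molecule(cl, fr))
  )
}

#' Interaction energy of a cluster
#'
#' `E(cluster) - sum_i E(monomer_i)` with monomers at their frozen
#' in-cluster geometries (no relaxation), in kcal/mol.
#'
#' @param cl a `dc4_cluster`.
#' @param energy_fn function `dc4_molecule -> Hartree` (total energy).
#' @return Interaction energy, kcal/mol.
#' @export
interaction_energy <- function(cl, energy_fn) {
  e_tot <- energy_fn(cl$molecule)
  e_mono <- vapply(fragment_molecules(cl), energy_fn, 0)
  hartree_to_kcal(e_tot - sum(e_mono))
}

#' Many-body expansion of a cluster interaction energy
#'
#' Standard inclusion-exclusion decomposition: for each fragment subset `S`,
#' `eps(S) = E(S) - sum over proper subsets T of S of eps(T)`, and the
#' K-body contribution is `eps_K = sum over |S| = K of eps(S)`. When
#' `max_k` equals the fragment count, `sum_K eps_K` equals the interaction
#' energy exactly; for truncated expansions the truncation remainder is
#' reported. Subset energies are memoized, and the full `choose(N, K)`
#' enumeration is exhaustive (no cutoffs).
#'
#' @param cl a `dc4_cluster` with N fragments.
#' @param energy_fn function `dc4_molecule -> Hartree`.
#' @param max_k highest order retained (default N).
#' @return A `dc4_mbe` object: `k_terms` (named eps_K, kcal/mol),
#'   `interaction_energy` (kcal/mol), `monomer_energies` (Hartree),
#'   `truncation_error` (kcal/mol), `label`.
#' @export
mbe_decompose <- function(cl, energy_fn, max_k = n_fragments(cl)) {
  n <- n_fragments(cl)
  if (max_k < 2 || max_k > n) abort(sprintf("max_k must lie in [2, %d]", n))
  cache <- new.env(parent = emptyenv())
  eval_subset <- function(frags) {
    mol <- subcluster_molecule(cl, frags)
    tryCatch(energy_fn(mol), error = function(err) {
      abort(sprintf("energy evaluation failed for subcluster [%s]: %s",
                    paste(frags, collapse = ","), conditionMessage(err)))
    })
  }
  mono_e <- vapply(seq_len(n), function(i) eval_subset(i), 0)
  # work with monomer-subtracted subset energies: identical eps_K for K >= 2
  # but without the catastrophic cancellation of large absolute energies
  energy_of <- function(frags) {
    key <- paste(frags, collapse = ",")
    if (!exists(key, envir = cache, inherits = FALSE)) {
      e <- if (length(frags) == 1) 0 else {
        eval_subset(frags) - sum(mono_e[frags])
      }
      assign(key, e, envir = cache)
    }
    get(key, envir = cache)
  }
  eps <- new.env(parent = emptyenv())
  eps_of <- function(frags) {
    key <- paste(frags, collapse = ",")
    if (!exists(key, envir = eps, inherits = FALSE)) {
      val <- energy_of(frags)
      if (length(frags) > 1) {
        for (sz in seq_len(length(frags) - 1)) {
          for (sub in utils::combn(frags, sz, simplify = FALSE)) {
            val <- val - eps_of(sub)
          }
        }
      }
      assign(key, val, envir = eps)
    }
    get(key, envir = eps, inherits = FALSE)
  }
  k_terms <- vapply(2:max_k, function(k) {
    sum(vapply(utils::combn(n, k, simplify = FALSE), eps_of, 0))
  }, 0)
  k_terms <- hartree_to_kcal(k_terms)
  names(k_terms) <- as.character(2:max_k)
  e_int <- interaction_energy(cl, energy_fn)
  structure(
    list(label = cl$molecule$label, k_terms = k_terms,
         interaction_energy = e_int,
         monomer_energies = mono_e,
         truncation_error = e_int - sum(k_terms)),
    class = "dc4_mbe"
  )
}

#' @export
print.dc4_mbe <- function(x, ...) {
  cat(sprintf("<MBE '%s': E_int = %.6f kcal/mol>\n", x$label,
              x$interaction_energy))
  for (k in names(x$k_terms)) {
    cat(sprintf("  eps_%s = %12.6f kcal/mol\n", k, x$k_terms[[k]]))
  }
  if (abs(x$truncation_error) > 1e-10) {
    cat(sprintf("  truncation remainder = %.6f kcal/mol\n", x$truncation_error))
  }
  invisible(x)
}

#' Tidy a many-body expansion
#' @param x a `dc4_mbe`.
#' @param ... unused.
#' @return A tibble with columns `k` and `epsilon` (kcal/mol).
#' @export
#' @exportS3Method generics::tidy
tidy.dc4_mbe <- function(x, ...) {
  tibble::tibble(k = as.integer(names(x$k_terms)),
                 epsilon = unname(x$k_terms))
}
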