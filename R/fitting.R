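#' Mean absolute error
#' @param errors numeric vector of signed errors (kcal/mol).
#' @return Mean of absolute values, kcal/mol.
#' @export
mae <- function(errors) {
  if (length(errors) == 0) abort("mae of an empty error list")
  mean(abs(errors))
}

#' Fit configuration for dispersion-parameter training
#'
#' @param objective `"MAE"` (the principled DC4 choice) or `"WTMAD2"`.
#' @param training_filter `"DI-only"` (drop density-sensitive and
#'   spin-contaminated reactions) or `"all"`.
#' @param cutoff DS/DI cutoff, kcal/mol.
#' @param free which of s6, s8, s9, a1, a2 to optimize; by default
#'   `{s8, a1, a2}` with `s6` fixed at 1 (standard for functionals with
#'   correct asymptotics) and no three-body term.
#' @param lower,upper named bounds for the free parameters.
#' @param base_params [d4_params()] supplying the fixed parameters.
#' @param n_starts multi-start count (box centre plus seeded uniform draws).
#' @param seed seed for the start draws.
#' @param tol objective tolerance used for convergence and for declaring
#'   starts tied (ties broken by lexicographically smallest parameters).
#' @return A list of class `dc4_fit_config`.
#' @export
fit_config <- function(objective = c("MAE", "WTMAD2"),
                       training_filter = c("DI-only", "all"),
                       cutoff = 2.0,
                       free = c("s8", "a1", "a2"),
                       lower = c(s6 = 0, s8 = 0, s9 = 0, a1 = 0, a2 = 0),
                       upper = c(s6 = 2, s8 = 3, s9 = 2, a1 = 1, a2 = 8),
                       base_params = d4_params(s6 = 1, s8 = 0, s9 = 0,
                                               a1 = 0.4, a2 = 4),
                       n_starts = 4, seed = 1, tol = 1e-9) {
  objective <- match.arg(objective)
  training_filter <- match.arg(training_filter)
  free <- match.arg(free, c("s6", "s8", "s9", "a1", "a2"), several.ok = TRUE)
  if (length(free) == 0) abort("free parameter set must be non-empty")
  if (!all(is.finite(lower[free])) || !all(is.finite(upper[free]))) {
    abort("bounds must be finite for every free parameter")
  }
  structure(
    list(objective = objective, training_filter = training_filter,
         cutoff = cutoff, free = free, lower = lower, upper = upper,
         base_params = base_params, n_starts = n_starts, seed = seed,
         tol = tol),
    class = "dc4_fit_config"
  )
}

#' Split a reaction set into training and excluded reactions
#'
#' DC-DFT training rule: keep a reaction only if it is density-insensitive
#' at the configured cutoff and not spin-contaminated; each exclusion is
#' recorded with its reason (`"DS"` or `"spin"`). Density-sensitive
#' reactions are excluded because their errors are dominated by
#' density-driven error, which dispersion parameters must not absorb.
#'
#' @param rset a `dc4_reaction_set`.
#' @param sens sensitivity table ([sensitivity_table()] output) covering
#'   every reaction tag.
#' @return A list: `training` (a `dc4_reaction_set`) and `excluded`
#'   (tibble `tag`, `reason`).
#' @export
build_training_set <- function(rset, sens) {
  tags <- vapply(rset$reactions, `[[`, "", "tag")
  missing <- setdiff(tags, sens$tag)
  if (length(missing) > 0) {
    abort(paste0("reactions without sensitivity records: ",
                 paste(missing, collapse = ", ")))
  }
  sens <- sens[match(tags, sens$tag), ]
  reason <- dplyr::case_when(
    sens$spin_contaminated ~ "spin",
    sens$classification == "DS" ~ "DS",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  if (!any(keep)) {
    abort("training set empty after DI/spin filtering; review the cutoff")
  }
  excluded <- tibble::tibble(tag = tags[!keep], reason = reason[!keep])
  training <- reaction_set(rset$reactions[keep], rset$molecules,
                           name = paste0(rset$name, "_train"),
                           provenance = c(rset$provenance,
                                          list(filter = "DI-only")))
  list(training = training, excluded = excluded)
}

#' Build a fast per-reaction error evaluator
#'
#' Returns a factory: given a reaction set it precomputes, once, each
#' species' base energy (one engine call) and dispersion pair table
#' (distances, C6, C8 — all parameter independent), then returns a closure
#' mapping candidate [d4_params()] to signed per-reaction errors (kcal/mol).
#' Because only the damping function depends on the parameters, refits cost
#' a vectorized pair sum per reaction. The closure counts its invocations in
#' attribute `calls` (an environment), which the fit report uses to prove
#' the validation set never enters the objective.
#'
#' @param engine an engine.
#' @param spec a [method_spec()] for the base energies.
#' @param tables [d4_reference_tables()].
#' @return `function(rset)` returning `function(params) -> named errors`.
#' @export
dispersion_evaluator <- function(engine, spec, tables = d4_reference_tables()) {
  force(engine); force(spec); force(tables)
  function(rset) {
    base_e <- vapply(rset$molecules, function(m) {
      res <- evaluate_energy(engine, m, spec)
      if (!isTRUE(res$converged)) {
        abort(sprintf("engine did not converge for species '%s'", m$label))
      }
      res$total_energy
    }, 0)
    pair_tabs <- lapply(rset$molecules, function(m) {
      dispersion_pair_table(m, tables)
    })
    counter <- new.env(parent = emptyenv())
    counter$calls <- 0L
    err_fn <- function(params) {
      counter$calls <- counter$calls + 1L
      disp_e <- vapply(pair_tabs, function(p) sum(pair_energy_bj(p, params)), 0)
      tot <- base_e + disp_e
      errs <- vapply(rset$reactions, function(r) {
        hartree_to_kcal(sum(r$coefficients * tot[r$species])) -
          r$reference_energy
      }, 0)
      names(errs) <- vapply(rset$reactions, `[[`, "", "tag")
      errs
    }
    attr(err_fn, "calls") <- counter
    err_fn
  }
}

params_from_vector <- function(x, config) {
  p <- config$base_params
  for (nm in config$free) p[[nm]] <- unname(x[nm])
  d4_params(s6 = p$s6, s8 = p$s8, s9 = p$s9, a1 = p$a1, a2 = p$a2)
}

fit_objective_fn <- function(err_fn, config, meta) {
  function(x) {
    names(x) <- config$free
    errs <- err_fn(params_from_vector(x, config))
    if (config$objective == "MAE") {
      mae(errs)
    } else {
      tab <- tibble::tibble(error = errs, dataset = meta$dataset,
                            reference = meta$reference) |>
        dplyr::group_by(.data$dataset) |>
        dplyr::summarise(mad = mean(abs(.data$error)),
                         mean_abs_ref = mean(abs(.data$reference)),
                         n = dplyr::n(), .groups = "drop")
      wtmad2(tab$mad, tab$mean_abs_ref, tab$n)
    }
  }
}

#' Fit dispersion parameters under DC-DFT training rules
#'
#' Minimizes the configured objective (default MAE, the principled choice)
#' over the training reactions, reporting — but never optimizing — the MAE
#' on the validation set. The optimizer is a seeded multi-start bounded
#' local search (box-constrained quasi-Newton with a Nelder-Mead polish);
#' tied starts are resolved by lexicographically smallest free parameters.
#'
#' Pass the output of [build_training_set()] as `training` to apply the
#' DI-only filter; the excluded ledger is carried into the report.
#'
#' @param training a `dc4_reaction_set`, or the list returned by
#'   [build_training_set()].
#' @param validation optional `dc4_reaction_set` (e.g. a water-dimer scan);
#'   its MAE is evaluated once, after optimization.
#' @param config a [fit_config()].
#' @param evaluator an evaluator factory, e.g. [dispersion_evaluator()].
#' @param mode report label, `"dc4"` or `"naive"`.
#' @return A `dc4_fit` object; see [tidy.dc4_fit()] and [glance.dc4_fit()].
#' @export
fit_dc4 <- function(training, validation = NULL, config = fit_config(),
                    evaluator, mode = "dc4") {
  excluded <- tibble::tibble(tag = character(), reason = character())
  if (is.list(training) && !inherits(training, "dc4_reaction_set") &&
      !is.null(training$training)) {
    excluded <- training$excluded
    training <- training$training
  }
  stopifnot(inherits(training, "dc4_reaction_set"))
  err_fn <- evaluator(training)
  meta <- tidy.dc4_reaction_set(training) |>
    dplyr::transmute(.data$tag, .data$dataset,
                     reference = .data$reference_energy)
  obj <- fit_objective_fn(err_fn, config, meta)
  lo <- config$lower[config$free]
  hi <- config$upper[config$free]
  rng <- new_rng(config$seed)
  starts <- list((lo + hi) / 2)
  if (config$n_starts > 1) {
    for (k in seq_len(config$n_starts - 1)) {
      starts[[k + 1]] <- lo + rng(length(lo)) * (hi - lo)
    }
  }
  runs <- lapply(starts, function(x0) {
    names(x0) <- config$free
    fit <- tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) list(par = x0, value = obj(x0), convergence = 99L)
    )
    # derivative-free polish; MAE is only piecewise smooth
    pol <- if (length(fit$par) == 1) {
      stats::optim(fit$par, function(x) obj(pmin(pmax(x, lo), hi)),
                   method = "Brent", lower = lo, upper = hi)
    } else {
      stats::optim(fit$par, function(x) obj(pmin(pmax(x, lo), hi)),
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000))
    }
    par <- pmin(pmax(pol$par, lo), hi)
    names(par) <- config$free
    list(par = par, value = obj(par), start = x0,
         converged = fit$convergence %in% c(0L, 1L) || pol$convergence == 0L)
  })
  if (!any(vapply(runs, `[[`, TRUE, "converged"))) {
    abort("optimizer failed to converge from every start")
  }
  vals <- vapply(runs, `[[`, 0, "value")
  best_val <- min(vals)
  tied <- which(vals <= best_val + config$tol)
  # lexicographic tie-break on the free-parameter vector
  ord <- do.call(order, as.data.frame(t(vapply(runs[tied], `[[`,
                                               numeric(length(lo)), "par"))))
  best <- runs[[tied[ord[1]]]]
  fitted <- params_from_vector(best$par, config)
  train_errors <- err_fn(fitted)
  objective_calls <- attr(err_fn, "calls")$calls
  validation_mae <- NA_real_
  validation_errors <- NULL
  validation_calls <- NA_integer_
  if (!is.null(validation)) {
    val_fn <- evaluator(validation)
    validation_errors <- val_fn(fitted)
    validation_mae <- mae(validation_errors)
    validation_calls <- attr(val_fn, "calls")$calls
  }
  structure(
    list(
      params = fitted, mode = mode,
      objective = config$objective,
      objective_value = best$value,
      training_mae = mae(train_errors),
      validation_mae = validation_mae,
      per_reaction = tibble::tibble(
        tag = names(train_errors), error = unname(train_errors),
        set = "training"
      ) |>
        dplyr::bind_rows(if (!is.null(validation_errors)) {
          tibble::tibble(tag = names(validation_errors),
                         error = unname(validation_errors),
                         set = "validation")
        }),
      excluded = excluded,
      starts = tibble::tibble(
        start = seq_along(runs),
        value = vals,
        converged = vapply(runs, `[[`, TRUE, "converged")
      ),
      calls = list(objective = objective_calls, validation = validation_calls),
      provenance = list(config = config, seed = config$seed, mode = mode,
                        n_training = length(training),
                        n_excluded = nrow(excluded))
    ),
    class = "dc4_fit"
  )
}

#' Naive all-reaction fit (the cautionary baseline)
#'
#' Same machinery as [fit_dc4()] but with no DI filtering and the WTMAD-2
#' objective — the combination that lets density-driven errors leak into the
#' dispersion parameters. The report is labelled `"naive"` for side-by-side
#' comparison with a principled fit.
#'
#' @param all_reactions the unfiltered `dc4_reaction_set`.
#' @param validation optional validation set (reported, never optimized).
#' @param config a [fit_config()]; objective and filter are overridden.
#' @param evaluator evaluator factory.
#' @return A `dc4_fit` with `mode = "naive"`.
#' @export
naive_fit <- function(all_reactions, validation = NULL,
                      config = fit_config(), evaluator) {
  config$objective <- "WTMAD2"
  config$training_filter <- "all"
  fit_dc4(all_reactions, validation, config, evaluator, mode = "naive")
}

#' @export
print.dc4_fit <- function(x, ...) {
  cat(sprintf("<%s fit: %s = %.6f kcal/mol on %d training reactions>\n",
              x$mode, x$objective, x$objective_value,
              sum(x$per_reaction$set == "training")))
  print(x$params)
  if (!is.na(x$validation_mae)) {
    cat(sprintf("  validation MAE = %.6f kcal/mol\n", x$validation_mae))
  }
  if (nrow(x$excluded) > 0) {
    cat(sprintf("  excluded: %d (%s)\n", nrow(x$excluded),
                paste(sprintf("%s=%d", names(table(x$excluded$reason)),
                              table(x$excluded$reason)), collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a fit: per-reaction signed errors
#' @param x a `dc4_fit`.
#' @param ... unused.
#' @return A tibble with `tag`, `error` (kcal/mol) and `set`
#'   (training/validation).
#' @export
#' @exportS3Method generics::tidy
tidy.dc4_fit <- function(x, ...) x$per_reaction

#' One-row fit summary
#' @param x a `dc4_fit`.
#' @param ... unused.
#' @return A one-row tibble: mode, objective, fitted parameters, training
#'   and validation MAE, exclusion count.
#' @export
#' @exportS3Method generics::glance
glance.dc4_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, objective = x$objective,
    objective_value = x$objective_value,
    s6 = x$params$s6, s8 = x$params$s8, s9 = x$params$s9,
    a1 = x$params$a1, a2 = x$params$a2,
    training_mae = x$training_mae, validation_mae = x$validation_mae,
    n_excluded = nrow(x$excluded)
  )
}
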