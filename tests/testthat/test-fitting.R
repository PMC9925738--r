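# evaluator over the toy engine's HF-density base energies
toy_hf_evaluator <- function(tables, engine_params = toy_params()) {
  dispersion_evaluator(toy_engine(engine_params), method_spec("HF"),
                       tables)
}

test_that("mae is the mean of absolute errors", {
  expect_identical(mae(c(1, -1)), 1)
  expect_identical(mae(c(0, 0, 0)), 0)
  expect_equal(mae(c(0.25, -0.11)), 0.18)
  expect_error(mae(numeric()), "empty")
})

test_that("training-set builder applies the DI and spin rules with a ledger", {
  rset <- generate_toy_dataset(6, seed = 2, tables = test_tables(),
                               toy = toy_dataset_params(ds_fraction = 0))
  tags <- vapply(rset$reactions, `[[`, "", "tag")
  sens_all_di <- tibble::tibble(tag = tags, s_tilde = 0.5,
                                classification = "DI",
                                spin_contaminated = FALSE)
  out <- build_training_set(rset, sens_all_di)
  expect_identical(length(out$training), 6L)
  expect_identical(nrow(out$excluded), 0L)

  # S = 3 with cutoff 2: excluded as DS
  sens <- sens_all_di
  sens$s_tilde[2] <- 3
  sens$classification[2] <- classify_sensitivity(3, 2)
  out <- build_training_set(rset, sens)
  expect_identical(out$excluded$tag, tags[2])
  expect_identical(out$excluded$reason, "DS")

  # spin contamination excludes regardless of sensitivity
  sens$spin_contaminated[3] <- TRUE
  out <- build_training_set(rset, sens)
  expect_setequal(out$excluded$reason, c("DS", "spin"))
  expect_identical(out$excluded$reason[out$excluded$tag == tags[3]], "spin")

  # excluded ledger plus training set partitions the input
  expect_setequal(c(out$excluded$tag,
                    vapply(out$training$reactions, `[[`, "", "tag")), tags)

  sens_all_ds <- dplyr::mutate(sens_all_di, s_tilde = 5,
                               classification = "DS")
  expect_error(build_training_set(rset, sens_all_ds), "cutoff")
  expect_error(build_training_set(rset, sens_all_di[-1, ]), "without")
})

test_that("noiseless parameter recovery is exact to 1e-3", {
  tab <- test_tables()
  truth <- d4_params(s6 = 1, s8 = 1.2, s9 = 0, a1 = 0.45, a2 = 4.5)
  rset <- generate_toy_dataset(
    24, seed = 11,
    toy = toy_dataset_params(true_params = truth, ds_fraction = 0),
    tables = tab
  )
  cfg <- fit_config(free = c("s8", "a1", "a2"), seed = 3,
                    base_params = d4_params(s6 = 1, s8 = 0, s9 = 0,
                                            a1 = 0.4, a2 = 4))
  fit <- fit_dc4(rset, validation = NULL, config = cfg,
                 evaluator = toy_hf_evaluator(tab))
  expect_lt(abs(fit$params$s8 - truth$s8), 1e-3)
  expect_lt(abs(fit$params$a1 - truth$a1), 1e-3)
  expect_lt(abs(fit$params$a2 - truth$a2), 1e-3)
  expect_lt(fit$training_mae, 1e-6)

  # optimizer contract: optimum no worse than the default start
  ev <- toy_hf_evaluator(tab)(rset)
  start_val <- mae(ev(dc4:::params_from_vector(
    c(s8 = 1.5, a1 = 0.5, a2 = 4), cfg)))
  expect_lte(fit$objective_value, start_val + 1e-12)
})

test_that("one-dimensional s6 recovery from s6 = 1 data", {
  tab <- test_tables()
  truth <- d4_params(s6 = 1, s8 = 0, s9 = 0, a1 = 0.45, a2 = 4.5)
  rset <- generate_toy_dataset(
    12, seed = 21,
    toy = toy_dataset_params(true_params = truth, ds_fraction = 0),
    tables = tab
  )
  cfg <- fit_config(free = "s6", seed = 5,
                    base_params = d4_params(s6 = 0.5, s8 = 0, s9 = 0,
                                            a1 = 0.45, a2 = 4.5))
  fit <- fit_dc4(rset, config = cfg, evaluator = toy_hf_evaluator(tab))
  expect_lt(abs(fit$params$s6 - 1), 1e-3)
})

test_that("validation is reported but never evaluated inside the objective", {
  tab <- test_tables()
  rset <- generate_toy_dataset(10, seed = 31,
                               toy = toy_dataset_params(ds_fraction = 0),
                               tables = tab)
  val <- generate_dimer_scan(seq(2.8, 4.6, by = 0.6), tables = tab)
  fit <- fit_dc4(rset, validation = val, config = fit_config(seed = 2),
                 evaluator = toy_hf_evaluator(tab))
  expect_gt(fit$calls$objective, 1L)
  expect_identical(fit$calls$validation, 1L)  # exactly one post-fit pass
  expect_false(is.na(fit$validation_mae))
  expect_identical(
    sort(unique(tidy(fit)$set)), c("training", "validation")
  )
})

test_that("DI-filtered fit beats the naive all-reaction fit on validation", {
  tab <- test_tables()
  truth <- d4_params(s6 = 1, s8 = 1.2, s9 = 0, a1 = 0.45, a2 = 4.5)
  toy <- toy_dataset_params(true_params = truth, ds_fraction = 0.4,
                            noise_sd = 0.05)
  rset <- generate_toy_dataset(30, seed = 41, toy = toy, tables = tab)
  eng_params <- rset$provenance$engine_params
  eng <- toy_engine(eng_params)
  evaluator <- dispersion_evaluator(eng, method_spec("HF"), tab)
  sens <- sensitivity_table(rset, eng)
  expect_gt(sum(sens$classification == "DS"), 0)
  val <- generate_dimer_scan(seq(2.8, 5.2, by = 0.3),
                             toy = toy_dataset_params(true_params = truth),
                             tables = tab)

  split <- build_training_set(rset, sens)
  fit_principled <- fit_dc4(split, validation = val,
                            config = fit_config(seed = 7),
                            evaluator = evaluator)
  fit_naive <- naive_fit(rset, validation = val,
                         config = fit_config(seed = 7),
                         evaluator = evaluator)

  # the DS reactions' density-driven bias skews the naive parameters
  delta_par <- max(abs(c(fit_naive$params$s8 - fit_principled$params$s8,
                         fit_naive$params$a1 - fit_principled$params$a1,
                         fit_naive$params$a2 - fit_principled$params$a2)))
  expect_gt(delta_par, 1e-3)
  expect_lt(fit_principled$validation_mae, fit_naive$validation_mae)
  expect_lt(fit_principled$validation_mae, 0.05)
  expect_identical(fit_naive$mode, "naive")
  expect_identical(fit_principled$provenance$mode, "dc4")

  # on an all-DI set, naive-with-MAE and principled fits agree
  rset_di <- generate_toy_dataset(
    16, seed = 43, toy = toy_dataset_params(true_params = truth,
                                            ds_fraction = 0),
    tables = tab
  )
  fit_a <- fit_dc4(rset_di, config = fit_config(seed = 9),
                   evaluator = toy_hf_evaluator(tab))
  cfg_b <- fit_config(seed = 9, training_filter = "all")
  fit_b <- fit_dc4(rset_di, config = cfg_b,
                   evaluator = toy_hf_evaluator(tab), mode = "naive")
  expect_lt(abs(fit_a$params$s8 - fit_b$params$s8), 1e-3)
  expect_lt(abs(fit_a$params$a2 - fit_b$params$a2), 1e-3)
})

test_that("recovery is consistent under reference noise across seeds", {
  tab <- test_tables()
  truth <- d4_params(s6 = 1, s8 = 1.2, s9 = 0, a1 = 0.45, a2 = 4.5)
  recover <- function(n, seed) {
    rset <- generate_toy_dataset(
      n, seed = seed,
      toy = toy_dataset_params(true_params = truth, ds_fraction = 0,
                               noise_sd = 0.05),
      tables = tab
    )
    fit <- fit_dc4(rset, config = fit_config(seed = seed, n_starts = 2),
                   evaluator = toy_hf_evaluator(tab))
    c(a1 = abs(fit$params$a1 - truth$a1), a2 = abs(fit$params$a2 - truth$a2))
  }
  seeds <- 1:8
  small <- vapply(seeds, function(s) recover(10, 100 + s), numeric(2))
  large <- vapply(seeds, function(s) recover(60, 200 + s), numeric(2))
  expect_lt(median(large["a1", ]), median(small["a1", ]))
  expect_lt(median(large["a2", ]), median(small["a2", ]))
})

test_that("fit tidiers expose errors and a one-row summary", {
  tab <- test_tables()
  rset <- generate_toy_dataset(8, seed = 51,
                               toy = toy_dataset_params(ds_fraction = 0),
                               tables = tab)
  fit <- fit_dc4(rset, config = fit_config(seed = 1, n_starts = 2),
                 evaluator = toy_hf_evaluator(tab))
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$mode, "dc4")
  expect_true(all(c("s8", "a1", "a2", "training_mae") %in% names(g)))
  td <- tidy(fit)
  expect_identical(nrow(td), 8L)
  expect_true(all(is.finite(td$error)))
})
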