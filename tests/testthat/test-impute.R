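# Small configurations keep the chained-equations runs desk-scale; the
# published settings (m = 10, 500 cycles, 100 trees) remain reachable via
# imputation_config() and are exercised at scale in the acceptance suite.

test_that("a complete dataset passes through untouched", {
  d <- generate_population(spec_complete(subsample_fraction = 1), 150,
                           seed = 41)
  imp <- rf_mice_impute(d, imputation_config(m = 3, n_iterations = 2,
                                             n_trees = 10, seed = 1))
  expect_length(imp$datasets, 3)
  expect_identical(nrow(imp$trace), 0L)
  for (dj in imp$datasets) {
    expect_identical(dj$wc_measured, d$wc_measured)
    expect_identical(dj$income, d$income)
  }
})

test_that("imputed values are donor draws: observed preserved, levels closed", {
  d <- generate_population(population_spec(subsample_fraction = 0.2), 600,
                           seed = 42)
  cfg <- imputation_config(m = 2, n_iterations = 3, n_trees = 20, seed = 3)
  imp <- rf_mice_impute(d, cfg)
  obs <- which(!is.na(d$income))
  arm <- which(d$exam == 1)
  for (dj in imp$datasets) {
    expect_identical(dj$income[obs], d$income[obs])
    expect_identical(dj$weight_measured[arm], d$weight_measured[arm])
    # donor-draw closure: imputed values come from observed values
    expect_true(all(dj$income %in% unique(d$income[obs])))
    expect_false(anyNA(dj$wc_measured))
    # derived, never imputed directly
    expect_identical(dj$bmi_measured,
                     dj$weight_measured / (dj$height_measured / 100)^2)
    expect_identical(nrow(dj), nrow(d))
    expect_identical(dj$id, d$id)
  }
  # deterministic given the seed
  imp2 <- rf_mice_impute(d, cfg)
  expect_identical(imp$datasets, imp2$datasets)
  # chain trace covers every imputed variable x iteration x imputation
  expect_setequal(unique(imp$trace$variable), imp$variables)
  expect_identical(nrow(imp$trace), 2L * 3L * length(imp$variables))
})

test_that("per-imputation seed streams are independent of m", {
  d <- generate_population(population_spec(subsample_fraction = 0.2), 300,
                           seed = 43)
  i1 <- rf_mice_impute(d, imputation_config(m = 1, n_iterations = 2,
                                            n_trees = 10, seed = 5))
  i3 <- rf_mice_impute(d, imputation_config(m = 3, n_iterations = 2,
                                            n_trees = 10, seed = 5))
  expect_identical(i1$datasets[[1]], i3$datasets[[1]])
})

test_that("MCAR holes on a continuous covariate pool back to the truth", {
  d <- generate_population(spec_complete(), 5000, seed = 44)
  full_mean <- mean(d$vegetation)
  holes <- seq(1, nrow(d), by = 5) # 20% MCAR
  d$vegetation[holes] <- NA
  imp <- rf_mice_impute(d, imputation_config(m = 5, n_iterations = 5,
                                             n_trees = 30, seed = 6))
  means <- vapply(imp$datasets, function(x) mean(x$vegetation), numeric(1))
  b <- var(means)
  w <- mean(vapply(imp$datasets,
                   function(x) var(x$vegetation) / nrow(x), numeric(1)))
  se <- sqrt(w + (1 + 1 / 5) * b)
  expect_lt(abs(mean(means) - full_mean), 3 * se)
})

test_that("an all-missing variable is reported as unimputable", {
  d <- generate_population(population_spec(), 200, seed = 45)
  d$income[] <- NA
  expect_error(rf_mice_impute(d, imputation_config(m = 1, n_iterations = 1,
                                                   n_trees = 5)),
               "unimputable.*income")
})

test_that("configuration invariants are enforced", {
  expect_error(imputation_config(m = 0), "m must be")
  expect_error(imputation_config(n_iterations = 0), "n_iterations")
  expect_error(imputation_config(n_trees = 0), "n_trees")
  pm <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(imputation_config(predictor_matrix = pm), "diagonal")
})

empty_trace_for_test <- function() {
  data.frame(variable = character(0), imputation = integer(0),
             iteration = integer(0), mean = numeric(0), sd = numeric(0))
}

test_that("chain convergence rule separates flat from drifting chains", {
  flat <- data.frame(variable = "x", imputation = 1L, iteration = 1:20,
                     mean = rep(2.5, 20), sd = rep(1, 20))
  cc <- chain_converged(flat, window = 10)
  expect_true(cc$converged)
  expect_identical(cc$summary$slope, 0)

  drift <- data.frame(variable = "x", imputation = 1L, iteration = 1:20,
                      mean = 1:20 * 0.5, sd = rep(1, 20))
  expect_false(chain_converged(drift, window = 10)$converged)

  expect_error(chain_converged(flat, window = 30), "window")
  expect_error(chain_converged(empty_trace_for_test(), window = 2), "empty")

  # chains from a default-style run converge
  d <- generate_population(population_spec(subsample_fraction = 0.2), 500,
                           seed = 46)
  imp <- rf_mice_impute(d, imputation_config(m = 2, n_iterations = 12,
                                             n_trees = 20, seed = 7))
  expect_true(chain_converged(imp$trace, window = 8)$converged)
})

test_that("completed datasets persist as CSVs plus a JSON chain trace", {
  d <- generate_population(population_spec(subsample_fraction = 0.3), 150,
                           seed = 47)
  imp <- rf_mice_impute(d, imputation_config(m = 2, n_iterations = 2,
                                             n_trees = 10, seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_completed_datasets(imp, dir)
  expect_true(file.exists(file.path(dir, "imputation_01.csv")))
  expect_true(file.exists(file.path(dir, "chain_trace.json")))
  tr <- jsonlite::read_json(file.path(dir, "chain_trace.json"),
                            simplifyVector = TRUE)
  expect_setequal(unique(tr$variable), imp$variables)
  d1 <- read_survey_csv(file.path(dir, "imputation_01.csv"),
                        file.path(dir, "imputation_01.codebook.yaml"))
  expect_equal(d1$wc_measured, imp$datasets[[1]]$wc_measured,
               tolerance = 1e-12)
})
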