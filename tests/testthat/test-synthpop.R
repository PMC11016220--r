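test_that("n = 0 yields an empty dataset with the full schema", {
  d <- generate_population(default_population_spec(), 0, seed = 1)
  expect_s3_class(d, "survey_dataset")
  expect_identical(nrow(d), 0L)
  expect_true(all(c("id", "age", "sex", "education", "income", "household",
                    "smoking", "indoor_smoking", "alcohol", "activity",
                    "black_carbon", "vegetation", "road_noise", "region",
                    "year", "height_true", "weight_true", "bmi_true",
                    "wc_true", "height_self", "weight_self", "bmi_self",
                    "exam", "height_measured", "weight_measured",
                    "bmi_measured", "wc_measured", "y_diabetes",
                    "y_hypertension", "y_cvd", "y_msk", "stratum", "cluster",
                    "weight") %in% names(d)))
})

test_that("generation is deterministic given the seed", {
  spec <- default_population_spec()
  d1 <- generate_population(spec, 400, seed = 5)
  d2 <- generate_population(spec, 400, seed = 5)
  d3 <- generate_population(spec, 400, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1$bmi_true, d3$bmi_true))
})

test_that("core invariants hold on generated data", {
  d <- generate_population(default_population_spec(), 5000, seed = 2)
  # exact weight/height/BMI identity, record by record
  expect_identical(d$bmi_true, d$weight_true / (d$height_true / 100)^2)
  expect_true(all(d$weight > 0))
  expect_false(anyNA(d$stratum) || anyNA(d$cluster))
  # measured layer present exactly on the examination arm
  expect_false(anyNA(d$wc_measured[d$exam == 1]))
  expect_true(all(is.na(d$wc_measured[d$exam == 0])))
  # outcomes strictly 0/1
  for (v in grep("^y_", names(d), value = TRUE)) {
    expect_true(all(d[[v]] %in% c(0, 1)))
  }
  # design columns and outcomes never receive missingness
  expect_false(anyNA(d$weight) || anyNA(d$y_diabetes))
})

test_that("examination-arm size is binomial around n * subsample_fraction", {
  spec <- population_spec(subsample_fraction = 0.05)
  d <- generate_population(spec, 20000, seed = 3)
  expect_lt(abs(sum(d$exam) - 1000), 3 * sqrt(20000 * 0.05 * 0.95))
})

test_that("self-report layer reproduces the configured bias and noise", {
  spec <- population_spec(self_report = list(weight_bias = -2, weight_sd = 1,
                                             height_bias = 1, height_sd = 1))
  d <- generate_population(spec, 50000, seed = 4)
  dw <- d$weight_self - d$weight_true
  expect_lt(abs(mean(dw) - (-2)), 0.05)
  expect_lt(abs(sd(dw) - 1), 0.05)
  expect_lt(abs(mean(d$height_self - d$height_true) - 1), 0.05)
})

test_that("empirical outcome prevalence matches the DGP marginal risk", {
  spec <- default_population_spec()
  d <- generate_population(spec, 100000, seed = 8)
  for (out in c("diabetes", "hypertension", "cvd", "msk")) {
    # marginal risk from an independent oracle draw (identity scenario P_obs)
    orc <- true_pif(spec, scenario("identity"), out, n_mc = 2e5, seed = 99)
    prev <- mean(d[[paste0("y_", out)]])
    se <- sqrt(prev * (1 - prev) / nrow(d) + orc$p_obs * (1 - orc$p_obs) / 2e5)
    expect_lt(abs(prev - orc$p_obs), 3 * se)
  }
})

test_that("invalid specifications raise configuration errors naming the field", {
  expect_error(population_spec(subsample_fraction = 0),
               "subsample_fraction")
  expect_error(population_spec(subsample_fraction = 1.2),
               "subsample_fraction")
  expect_error(population_spec(anthropometry = list(bmi = list(sd = -1))),
               "bmi")
  expect_error(population_spec(missingness = list(rates = c(income = 1.5))),
               "missingness")
})

test_that("oracle PIF behaves as the estimand demands", {
  spec <- spec_complete()
  # identity scenario: exactly zero, for every outcome
  for (out in c("diabetes", "msk")) {
    expect_identical(true_pif(spec, scenario("identity"), out,
                              n_mc = 2000, seed = 1)$pif, 0)
  }
  # positive exposure effect + strictly decreasing scenario => positive PIF
  tp <- true_pif(spec, scenario("s2"), "diabetes", n_mc = 20000, seed = 2)
  expect_gt(tp$pif, 0)
  expect_gt(tp$se, 0)
  # deterministic given seed
  tp2 <- true_pif(spec, scenario("s2"), "diabetes", n_mc = 20000, seed = 2)
  expect_identical(tp$pif, tp2$pif)
})

test_that("population spec round-trips through YAML", {
  spec <- population_spec(subsample_fraction = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_population_spec(spec, path)
  spec2 <- read_population_spec(path)
  d1 <- generate_population(spec, 200, seed = 7)
  d2 <- generate_population(spec2, 200, seed = 7)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("survey data round-trips through CSV plus codebook", {
  d <- generate_population(default_population_spec(), 300, seed = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  cb <- withr::local_tempfile(fileext = ".yaml")
  write_survey_csv(d, csv, cb)
  d2 <- read_survey_csv(csv, cb)
  expect_identical(levels(d2$education), levels(d$education))
  expect_identical(which(is.na(d2$income)), which(is.na(d$income)))
  expect_equal(d2$bmi_true, d$bmi_true, tolerance = 1e-12)
  expect_identical(d2$y_msk, d$y_msk)
})
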