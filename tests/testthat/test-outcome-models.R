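test_that("null DGP yields null coefficients within 3 robust SEs", {
  spec <- spec_complete()
  for (nm in names(spec$outcomes)) {
    spec$outcomes[[nm]][setdiff(names(spec$outcomes[[nm]]), "intercept")] <-
      lapply(setdiff(names(spec$outcomes[[nm]]), "intercept"), function(x) 0)
    spec$outcomes[[nm]]$intercept <- -1.5
  }
  d <- generate_population(spec, 10000, seed = 51)
  fit <- fit_outcome_model(d, outcome_model_spec("diabetes", "bmi",
                                                 cols = cols_true))
  b <- fit$coef[-1]
  se <- sqrt(diag(fit$vcov))[-1]
  # joint null check over ~24 coefficients: allow the expected handful of
  # 3-SE exceedances, none extreme
  expect_lte(sum(abs(b) > 3 * se), 2)
  expect_true(all(abs(b) < 4.5 * se))
})

test_that("known coefficients are recovered within 3 SEs at n = 20 000", {
  spec <- spec_complete()
  d <- generate_population(spec, 20000, seed = 52)
  fit <- fit_outcome_model(d, outcome_model_spec("diabetes", "bmi",
                                                 cols = cols_true))
  se <- sqrt(diag(fit$vcov))
  truth <- spec$outcomes$diabetes
  expect_lt(abs(fit$coef[["bmi_true"]] - truth$bmi), 3 * se[["bmi_true"]])
  expect_lt(abs(fit$coef[["age"]] - truth$age), 3 * se[["age"]])
  expect_lt(abs(fit$coef[["black_carbon"]] - truth$black_carbon),
            3 * se[["black_carbon"]])
  # predicted risks are proper probabilities
  p <- predict_risk(fit, d)
  expect_true(all(p > 0 & p < 1))
})

test_that("coefficients are invariant to the weight scale, and equal-weight
           fits match unweighted fits", {
  d <- generate_population(spec_complete(), 4000, seed = 53)
  spec_m <- outcome_model_spec("hypertension", "bmi", cols = cols_true)
  f1 <- fit_outcome_model(d, spec_m)
  d2 <- d; d2$weight <- d$weight * 7.3
  f2 <- fit_outcome_model(d2, spec_m)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  d3 <- d; d3$weight <- rep(2, nrow(d))
  d4 <- d; d4$weight <- rep(1, nrow(d))
  expect_equal(fit_outcome_model(d3, spec_m)$coef,
               fit_outcome_model(d4, spec_m)$coef, tolerance = 1e-10)
})

test_that("OR per IQR follows the closed form", {
  d <- toy_population(bmi = c(20, 20, 28, 28))
  m <- toy_frozen_model()
  m$coef[["bmi_true"]] <- 0.05
  m$vcov[2, 2] <- 0.0001
  r <- or_per_iqr(m, d)
  expect_equal(r$iqr, 8)
  expect_equal(r$or, exp(0.4), tolerance = 1e-12)
  expect_equal(r$lo, exp((0.05 - qnorm(0.975) * 0.01) * 8), tolerance = 1e-12)
  expect_false(r$conditional)
  # doubling the IQR squares the OR
  d2 <- toy_population(bmi = c(16, 16, 32, 32))
  expect_equal(or_per_iqr(m, d2)$or, exp(0.4)^2, tolerance = 1e-12)
  # null effect
  m$coef[["bmi_true"]] <- 0
  expect_equal(or_per_iqr(m, d)$or, 1)
  # degenerate exposure
  d0 <- toy_population(bmi = rep(25, 4))
  expect_error(or_per_iqr(m, d0), "degenerate")
})

test_that("split-sample AUC is 1 for a noise-free threshold and ~0.5 at chance", {
  d <- generate_population(spec_complete(), 10000, seed = 54)
  sp <- outcome_model_spec("diabetes", "bmi", adjustment = character(0),
                           cols = cols_true)
  d$y_diabetes <- as.integer(d$bmi_true > median(d$bmi_true))
  d$weight <- rep(1, nrow(d)) # perfect ranking must not be blurred by fitting
  expect_equal(evaluate_auc(d, sp, seed = 2), 1)
  set.seed(11)
  d$y_diabetes <- rbinom(nrow(d), 1, 0.5)
  auc <- evaluate_auc(d, sp, seed = 2)
  expect_lt(abs(auc - 0.5), 0.03)
  d$y_diabetes <- rep(1L, nrow(d))
  expect_error(evaluate_auc(d, sp, seed = 2), "single outcome class")
})

test_that("weighted AUC agrees with an unweighted reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  expect_equal(weighted_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("stepwise AIC selects a strong true interaction and stays empty
           under the null", {
  base <- spec_complete()
  spec_int <- base
  spec_int$outcomes$diabetes$bmi_female <- 0.1
  hits_int <- hits_null <- 0L
  reps <- 12L
  for (r in seq_len(reps)) {
    msp <- outcome_model_spec("diabetes", "bmi", quadratic = TRUE,
                              interactions = c("sex", "road_noise"),
                              cols = cols_true)
    d1 <- generate_population(spec_int, 6000, seed = 500 + r)
    sel1 <- select_terms_aic(d1, msp)
    if ("bmi_true:sex" %in% sel1) hits_int <- hits_int + 1L
    d0 <- generate_population(base, 6000, seed = 700 + r)
    if (length(select_terms_aic(d0, msp)) == 0) hits_null <- hits_null + 1L
  }
  expect_gte(hits_int, ceiling(0.9 * reps))
  expect_gt(hits_null, reps / 2)
  # empty candidate list is a no-op
  msp0 <- outcome_model_spec("diabetes", "bmi", cols = cols_true)
  d <- generate_population(base, 500, seed = 55)
  expect_identical(select_terms_aic(d, msp0), character(0))
})

test_that("models round-trip through JSON with bit-identical predictions", {
  d <- generate_population(spec_complete(), 1500, seed = 56)
  fit <- fit_outcome_model(d, outcome_model_spec("msk", "bmi",
                                                 cols = cols_true))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  fit2 <- read_model_json(path)
  expect_identical(predict_risk(fit2, d), predict_risk(fit, d))
  expect_equal(fit2$coef, fit$coef)
  expect_equal(fit2$aic, fit$aic)
})

test_that("degenerate fits fail loudly", {
  d <- generate_population(spec_complete(), 800, seed = 57)
  d$y_diabetes <- as.integer(d$bmi_true > 25) # separation by construction
  sp <- outcome_model_spec("diabetes", "bmi", adjustment = character(0),
                           cols = cols_true)
  expect_error(fit_outcome_model(d, sp), "separation")
  d2 <- generate_population(spec_complete(), 500, seed = 58)
  d2$weight[1] <- -1
  expect_error(fit_outcome_model(d2, outcome_model_spec("msk", "bmi",
                                                        cols = cols_true)),
               "weights")
  # the adjustment set refuses metabolic mediators/colliders
  expect_error(outcome_model_spec("diabetes", "bmi",
                                  adjustment = c("age", "hypertension")),
               "collider")
})
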