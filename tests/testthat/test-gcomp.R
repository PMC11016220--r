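test_that("the identity scenario gives PIF = 0 and RD = 0 exactly", {
  d <- generate_population(spec_complete(), 2000, seed = 61)
  for (out in c("diabetes", "msk")) {
    sp <- outcome_model_spec(out, "bmi", cols = cols_true)
    e <- estimate_pif(d, sp, scenario("identity"), cols = cols_true)
    expect_identical(e$pif, 0)
    expect_identical(e$rd, 0)
  }
})

test_that("the 4-record fixture reproduces the hand-computed oracle exactly", {
  d <- toy_population()
  e <- estimate_pif(d, toy_model_spec(), scenario("s2"),
                    frozen_model = toy_frozen_model(), cols = cols_true)
  expect_equal(e$pif, TOY_S2_PIF, tolerance = 1e-12)
  expect_equal(e$p_obs, mean(plogis(-3 + 0.1 * c(20, 26, 30, 35))),
               tolerance = 1e-15)
  expect_equal(e$p_cf, mean(plogis(-3 + 0.1 * c(20, 25, 29, 34))),
               tolerance = 1e-15)
})

test_that("PIF invariants hold across scenarios and outcomes", {
  d <- generate_population(spec_complete(), 4000, seed = 62)
  for (sc in list(scenario("s1"), scenario("s2"), scenario("s3", "bmi30"),
                  scenario("s4"))) {
    for (out in c("diabetes", "hypertension")) {
      sp <- outcome_model_spec(out, sc$exposure, cols = cols_true)
      e <- estimate_pif(d, sp, sc, seed = 3, cols = cols_true)
      expect_lte(e$pif, 1)
      expect_true(e$p_obs > 0 && e$p_obs < 1)
      # RD and PIF carry opposite signs (both zero only under identity)
      expect_lt(e$rd * e$pif, 0)
      expect_equal(e$pif, 1 - e$p_cf / e$p_obs)
    }
  }
})

test_that("scenario/model exposure mismatch is caught before computing", {
  d <- generate_population(spec_complete(), 400, seed = 63)
  sp <- outcome_model_spec("diabetes", "bmi", cols = cols_true)
  expect_error(estimate_pif(d, sp, scenario("s4"), cols = cols_true),
               "does not match")
})

test_that("two-replicate bootstrap SE is the sample SD of the two PIFs", {
  d <- generate_population(spec_complete(), 1200, seed = 64)
  sp <- outcome_model_spec("hypertension", "bmi", cols = cols_true)
  b <- bootstrap_pif(d, sp, scenario("s2"), n_boot = 2, seed = 9,
                     cols = cols_true)
  expect_identical(b$n_boot, 2L)
  expect_equal(b$se_pif, abs(diff(b$replicates)) / sqrt(2), tolerance = 1e-12)
  # the point estimate is the full-data estimate, not a bootstrap average
  e <- estimate_pif(d, sp, scenario("s2"), seed = derive_seed(9, 0L),
                    cols = cols_true)
  expect_identical(b$pif, e$pif)
})

test_that("bootstrap replicate streams are seed-stable and n_boot-extensible", {
  d <- generate_population(spec_complete(), 1500, seed = 65)
  sp <- outcome_model_spec("hypertension", "bmi", cols = cols_true)
  b1 <- bootstrap_pif(d, sp, scenario("s2"), n_boot = 100, seed = 4,
                      cols = cols_true)
  b2 <- bootstrap_pif(d, sp, scenario("s2"), n_boot = 100, seed = 4,
                      cols = cols_true)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_pif(d, sp, scenario("s2"), n_boot = 200, seed = 4,
                      cols = cols_true)
  # counter-based splitting: first 100 replicates unchanged
  expect_identical(b3$replicates[seq_len(100)], b1$replicates)
  # doubling n_boot moves the SE by less than 10 percent
  expect_lt(abs(b3$se_pif - b1$se_pif) / b1$se_pif, 0.10)
})

test_that("s1 randomness propagates into the bootstrap SE", {
  d <- generate_population(spec_complete(), 1500, seed = 66)
  sp <- outcome_model_spec("diabetes", "bmi", cols = cols_true)
  b1 <- bootstrap_pif(d, sp, scenario("s1"), n_boot = 60, seed = 4,
                      cols = cols_true)
  b2 <- bootstrap_pif(d, sp, scenario("s2"), n_boot = 60, seed = 4,
                      cols = cols_true)
  expect_gt(b1$se_pif, 0)
  # replicate draws differ across replicates (fresh s1 draws)
  expect_gt(length(unique(round(b1$replicates, 10))), 50)
  expect_gt(b1$se_pif, b2$se_pif) # larger shift, larger uncertainty
})

test_that("cluster bootstrap within strata runs and yields a positive SE", {
  d <- generate_population(spec_complete(), 1500, seed = 67)
  sp <- outcome_model_spec("hypertension", "bmi", cols = cols_true)
  b <- bootstrap_pif(d, sp, scenario("s2"), n_boot = 30, seed = 4,
                     boot_unit = "cluster", cols = cols_true)
  expect_gt(b$se_pif, 0)
  expect_identical(b$n_dropped, 0L)
})

test_that("quadratic and interaction terms flow through the counterfactual
           design correctly", {
  d <- generate_population(spec_complete(), 2500, seed = 68)
  sp <- outcome_model_spec("hypertension", "bmi",
                           extra_terms = c("I(bmi_true^2)", "bmi_true:sex"),
                           cols = cols_true)
  e <- estimate_pif(d, sp, scenario("s2"), seed = 1, cols = cols_true)
  b <- bootstrap_pif(d, sp, scenario("s2"), n_boot = 10, seed = 1,
                     cols = cols_true)
  expect_identical(b$pif, e$pif) # fast path equals the general path
  expect_true(is.finite(b$se_pif))
})
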