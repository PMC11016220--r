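# Shared fixtures: built in code at test time, no stored data.

# spec without covariate missingness, for analyses on generator truth
spec_complete <- function(...) {
  population_spec(missingness = list(rates = numeric(0)), ...)
}

# column mapping reading the generator's true anthropometry directly
cols_true <- analysis_cols(bmi = "bmi_true", wc = "wc_true",
                           height = "height_true", weight = "weight_true")

# 4-record closed population with equal weights for the hand-computed oracle
toy_population <- function(bmi = c(20, 26, 30, 35)) {
  data.frame(
    id = seq_along(bmi),
    bmi_true = bmi,
    wc_true = 23 + 2.35 * bmi,
    height_true = rep(170, length(bmi)),
    weight_true = bmi * 1.7^2,
    y_toy = rep(0L, length(bmi)),
    stratum = factor("s1"),
    cluster = factor("c1"),
    weight = rep(1, length(bmi)))
}

# frozen risk model expit(-3 + 0.1 * BMI), bypassing model fitting
toy_frozen_model <- function() {
  structure(list(
    coef = c("(Intercept)" = -3, bmi_true = 0.1),
    vcov = matrix(0, 2, 2, dimnames = list(c("(Intercept)", "bmi_true"),
                                           c("(Intercept)", "bmi_true"))),
    formula = "y_toy ~ bmi_true",
    xlev = list(),
    outcome = "toy", exposure = "bmi", exposure_col = "bmi_true",
    selected = character(0), aic = NA_real_, n = 4L),
    class = "outcome_model_fit")
}

toy_model_spec <- function() {
  outcome_model_spec("toy", exposure = "bmi", adjustment = character(0),
                     cols = cols_true)
}

# PIF of the 4-record population under scenario 2, computed by exhaustively
# summing the eight expit terms (frozen independent hand computation)
TOY_S2_PIF <- 0.040454063710915533

# overlap coefficient of the overweight-vs-normal membership probabilities on
# the default generator (n = 10 000, seed 4242); run-once regression fixture
OVERLAP_FIXTURE <- 0.8745786685
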