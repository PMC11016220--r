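#' Default parametrization of the synthetic survey generator
#'
#' Returns the full specification of the synthetic data-generating process
#' emulating a cross-sectional national health-interview survey merged with a
#' small health-examination subsample: socio-demographic, lifestyle and
#' residential-environment covariates; true anthropometry (BMI, height, weight,
#' waist circumference); a biased self-reported anthropometry layer; four
#' binary chronic-disease outcomes generated from known logistic models; a
#' schematic two-stage design (strata, clusters, unequal positive weights); a
#' measured examination arm; and missing-at-random covariate gaps.
#'
#' All parameters are user-overridable via [population_spec()]. The defaults
#' put the conditional SD of true BMI given covariates at 5.3 kg/m2, the
#' conditional SD of waist circumference at about 13.2 cm, and overweight
#' prevalence (BMI > 25) near 48 percent of adults.
#'
#' @return an object of class `population_spec`.
#' @seealso [generate_population()], [true_pif()]
#' @export
default_population_spec <- function() {
  spec <- list(
    covariates = list(
      year = list(levels = c("2008", "2013", "2018"), probs = c(1, 1, 1) / 3),
      region = list(levels = c("flanders", "wallonia", "brussels"),
                    probs = c(0.58, 0.32, 0.10)),
      age = list(mean = 50, sd = 18, min = 18, max = 90),
      sex = list(p_female = 0.51),
      education = list(levels = c("primary", "lower_sec", "higher_sec", "higher"),
                       probs = c(0.15, 0.25, 0.30, 0.30)),
      income = list(education_effect = 0.55, sd = 1.05), # latent normal -> quintile 1..5
      household = list(levels = c("single", "one_parent", "couple",
                                  "couple_children", "other"),
                       probs = c(0.22, 0.08, 0.30, 0.32, 0.08)),
      smoking = list(levels = c("never", "former", "occasional", "daily"),
                     probs = c(0.45, 0.25, 0.08, 0.22)),
      indoor_smoking = list(base = -2.2, daily_effect = 1.6), # logit scale
      alcohol = list(probs = c(0.25, 0.40, 0.20, 0.10, 0.05)), # numeric 1..5
      activity = list(levels = c("intensive", "light", "sedentary"),
                      probs = c(0.25, 0.45, 0.30)),
      black_carbon = list( # annual mean exposure, ug/m3, lognormal
        log_mean = c(flanders = 0.25, wallonia = 0.10, brussels = 0.55),
        income_effect = -0.03, log_sd = 0.30),
      vegetation = list( # 1 km buffer cover fraction, logit-normal
        logit_mean = c(flanders = 0.35, wallonia = 0.90, brussels = -0.80),
        income_effect = 0.05, sd = 0.70),
      road_noise = list( # indicator Lden > 55 dB
        base = -1.2, brussels_effect = 1.4, vegetation_effect = -0.8)
    ),
    anthropometry = list(
      bmi = list(intercept = 24.55, age = 0.045, female = -0.6,
                 education = -0.35, activity_light = 0.4,
                 activity_sedentary = 0.9, sd = 5.3, min = 13, max = 65),
      height = list(male_mean = 177.5, female_mean = 164.5, age = -0.05,
                    sd = 6.5),
      wc = list(intercept = 23, bmi = 2.35, sd = 4.3) # cm
    ),
    self_report = list(weight_bias = -2, weight_sd = 2,
                       height_bias = 1, height_sd = 1),
    outcomes = list(
      diabetes = list(
        intercept = -3.45, bmi = 0.10, bmi2 = 0, bmi_female = 0,
        age = 0.045, female = -0.20, education = -0.12, income = -0.05,
        smoking_daily = 0.20, indoor_smoking = 0.10, alcohol = 0.05,
        activity_light = 0.15, activity_sedentary = 0.35,
        black_carbon = 0.15, vegetation = -0.20, road_noise = 0.10,
        wallonia = 0.10, brussels = 0.05, y2013 = 0.05, y2018 = 0.10),
      hypertension = list(
        intercept = -1.15, bmi = 0.09, bmi2 = 0, bmi_female = 0,
        age = 0.055, female = -0.15, education = -0.08, income = -0.03,
        smoking_daily = 0.15, indoor_smoking = 0.08, alcohol = 0.10,
        activity_light = 0.10, activity_sedentary = 0.25,
        black_carbon = 0.12, vegetation = -0.15, road_noise = 0.12,
        wallonia = 0.08, brussels = 0.02, y2013 = 0.02, y2018 = 0.05),
      cvd = list(
        intercept = -3.15, bmi = 0.03, bmi2 = 0, bmi_female = 0,
        age = 0.06, female = -0.25, education = -0.10, income = -0.05,
        smoking_daily = 0.35, indoor_smoking = 0.12, alcohol = 0.05,
        activity_light = 0.10, activity_sedentary = 0.30,
        black_carbon = 0.18, vegetation = -0.15, road_noise = 0.15,
        wallonia = 0.10, brussels = 0.05, y2013 = 0, y2018 = 0),
      msk = list(
        intercept = -0.70, bmi = 0.028, bmi2 = 0, bmi_female = 0,
        age = 0.022, female = 0.25, education = -0.10, income = -0.04,
        smoking_daily = 0.10, indoor_smoking = 0.05, alcohol = 0.02,
        activity_light = 0.05, activity_sedentary = 0.20,
        black_carbon = 0.05, vegetation = -0.08, road_noise = 0.08,
        wallonia = 0.12, brussels = 0.03, y2013 = 0.02, y2018 = 0.03)
    ),
    design = list(clusters_per_stratum = 20, weight_log_sd = 0.4),
    subsample_fraction = 0.043,
    missingness = list(rates = c(income = 0.06),
                       age_effect = 0.01, female_effect = 0.25)
  )
  structure(spec, class = "population_spec")
}

#' Build a population specification with overrides
#'
#' Starts from [default_population_spec()] and recursively merges any supplied
#' components, then validates the result.
#'
#' @param ... named components to override, e.g.
#'   `self_report = list(weight_bias = -2)` or `subsample_fraction = 0.05`.
#' @return a validated `population_spec`.
#' @export
population_spec <- function(...) {
  spec <- modifyList(default_population_spec(), list(...))
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat("  outcomes:          ", paste(names(x$outcomes), collapse = ", "), "\n")
  cat("  BMI conditional SD:", x$anthropometry$bmi$sd, "kg/m2\n")
  cat("  WC link:           ", sprintf("%.2f + %.2f*BMI + N(0, %.2f)",
      x$anthropometry$wc$intercept, x$anthropometry$wc$bmi,
      x$anthropometry$wc$sd), "\n")
  cat("  self-report bias:  ", sprintf("weight %+g kg, height %+g cm",
      x$self_report$weight_bias, x$self_report$height_bias), "\n")
  cat("  examination arm:   ", sprintf("%.1f%%", 100 * x$subsample_fraction), "\n")
  invisible(x)
}

validate_population_spec <- function(spec) {
  f <- spec$subsample_fraction
  if (!is.numeric(f) || length(f) != 1 || !(f > 0 && f <= 1)) {
    stop_config("subsample_fraction must lie in (0, 1], got %s", format(f))
  }
  if (spec$anthropometry$bmi$sd <= 0) {
    stop_config("anthropometry$bmi$sd must be positive")
  }
  if (spec$anthropometry$wc$sd < 0) {
    stop_config("anthropometry$wc$sd must be nonnegative")
  }
  if (spec$design$weight_log_sd < 0) {
    stop_config("design$weight_log_sd must be nonnegative")
  }
  for (nm in c("year", "region", "education", "household", "smoking", "activity")) {
    p <- spec$covariates[[nm]]$probs
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_config("covariates$%s$probs must be a probability vector", nm)
    }
  }
  r <- spec$missingness$rates
  if (length(r) && (any(r < 0) || any(r >= 1))) {
    stop_config("missingness$rates must lie in [0, 1)")
  }
  invisible(spec)
}

## Linear predictor of a true outcome model on a (possibly counterfactual)
## BMI vector; single source of truth for generation and the PIF oracle.
outcome_linpred <- function(spec, outcome, df, bmi) {
  b <- spec$outcomes[[outcome]]
  if (is.null(b)) stop_config("unknown outcome '%s'", outcome)
  bmic <- bmi - 25
  female <- as.numeric(df$sex == "female")
  b$intercept +
    b$bmi * bmic + b$bmi2 * bmic^2 + b$bmi_female * bmic * female +
    b$age * (df$age - 50) +
    b$female * female +
    b$education * (as.numeric(df$education) - 2.5) +
    b$income * (df$income - 3) +
    b$smoking_daily * (df$smoking == "daily") +
    b$indoor_smoking * df$indoor_smoking +
    b$alcohol * (df$alcohol - 2) +
    b$activity_light * (df$activity == "light") +
    b$activity_sedentary * (df$activity == "sedentary") +
    b$black_carbon * (df$black_carbon - 1.4) +
    b$vegetation * (df$vegetation - 0.5) +
    b$road_noise * df$road_noise +
    b$wallonia * (df$region == "wallonia") +
    b$brussels * (df$region == "brussels") +
    b$y2013 * (df$year == "2013") +
    b$y2018 * (df$year == "2018")
}

## covariates + true anthropometry, no self-report / design / missingness
generate_core <- function(spec, n) {
  cv <- spec$covariates
  an <- spec$anthropometry
  df <- data.frame(id = seq_len(n))
  samp <- function(cmp) factor(sample(cmp$levels, n, TRUE, cmp$probs),
                               levels = cmp$levels)
  if (n == 0) {
    samp <- function(cmp) factor(character(0), levels = cmp$levels)
  }
  df$year <- samp(cv$year)
  df$region <- samp(cv$region)
  df$age <- pmin(pmax(rnorm(n, cv$age$mean, cv$age$sd), cv$age$min), cv$age$max)
  df$sex <- factor(ifelse(runif(n) < cv$sex$p_female, "female", "male"),
                   levels = c("male", "female"))
  df$education <- samp(cv$education)
  lat <- as.numeric(df$education) * cv$income$education_effect +
    rnorm(n, 0, cv$income$sd)
  df$income <- pmin(pmax(round(lat + 1.6), 1), 5)
  df$household <- samp(cv$household)
  df$smoking <- samp(cv$smoking)
  df$indoor_smoking <- rbinom(n, 1, expit(cv$indoor_smoking$base +
    cv$indoor_smoking$daily_effect * (df$smoking == "daily")))
  df$alcohol <- sample(1:5, n, TRUE, cv$alcohol$probs)
  if (n == 0) df$alcohol <- integer(0)
  df$activity <- samp(cv$activity)
  df$black_carbon <- exp(rnorm(n,
    cv$black_carbon$log_mean[as.character(df$region)] +
      cv$black_carbon$income_effect * (df$income - 3),
    cv$black_carbon$log_sd))
  df$vegetation <- expit(rnorm(n,
    cv$vegetation$logit_mean[as.character(df$region)] +
      cv$vegetation$income_effect * (df$income - 3),
    cv$vegetation$sd))
  df$road_noise <- rbinom(n, 1, expit(cv$road_noise$base +
    cv$road_noise$brussels_effect * (df$region == "brussels") +
    cv$road_noise$vegetation_effect * df$vegetation))

  female <- as.numeric(df$sex == "female")
  mu_bmi <- an$bmi$intercept + an$bmi$age * (df$age - 50) +
    an$bmi$female * female +
    an$bmi$education * (as.numeric(df$education) - 2.5) +
    an$bmi$activity_light * (df$activity == "light") +
    an$bmi$activity_sedentary * (df$activity == "sedentary")
  bmi <- pmin(pmax(rnorm(n, mu_bmi, an$bmi$sd), an$bmi$min), an$bmi$max)
  df$height_true <- rnorm(n,
    ifelse(female == 1, an$height$female_mean, an$height$male_mean) +
      an$height$age * (df$age - 50), an$height$sd)
  df$weight_true <- bmi * (df$height_true / 100)^2
  # recompute so the weight/height/BMI identity is exact in floating point
  df$bmi_true <- df$weight_true / (df$height_true / 100)^2
  df$wc_true <- an$wc$intercept + an$wc$bmi * df$bmi_true +
    rnorm(n, 0, an$wc$sd)
  rownames(df) <- NULL
  df
}

#' Generate a synthetic survey dataset
#'
#' Simulates `n` person-level records from a [population_spec()]: covariates,
#' true anthropometry, a biased self-reported layer, measured anthropometry in
#' a random examination subsample, four binary outcomes drawn from the true
#' logistic models, a two-stage design (stratum = region x survey year,
#' clusters within strata) with unequal positive weights, and missing-at-random
#' covariate gaps. The `*_true` columns carry the generator's ground truth for
#' validation; an analysis mirroring real survey data uses the self-reported
#' and measured layers only.
#'
#' @param spec a `population_spec`.
#' @param n number of records (`n = 0` yields an empty dataset with the full
#'   schema).
#' @param seed integer seed; the same spec and seed reproduce the dataset
#'   exactly.
#' @return a `data.frame` of class `survey_dataset`.
#' @examples
#' d <- generate_population(default_population_spec(), 500, seed = 1)
#' mean(d$bmi_true > 25) # overweight share
#' @export
generate_population <- function(spec, n, seed = 1L) {
  validate_population_spec(spec)
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  with_seed(derive_seed(seed, 101L), {
    df <- generate_core(spec, n)
    sr <- spec$self_report
    df$height_self <- df$height_true + sr$height_bias + rnorm(n, 0, sr$height_sd)
    df$weight_self <- df$weight_true + sr$weight_bias + rnorm(n, 0, sr$weight_sd)
    df$bmi_self <- df$weight_self / (df$height_self / 100)^2

    exam <- rbinom(n, 1, spec$subsample_fraction)
    df$exam <- exam
    df$height_measured <- ifelse(exam == 1, df$height_true, NA_real_)
    df$weight_measured <- ifelse(exam == 1, df$weight_true, NA_real_)
    df$bmi_measured <- df$weight_measured / (df$height_measured / 100)^2
    df$wc_measured <- ifelse(exam == 1, df$wc_true, NA_real_)

    for (out in names(spec$outcomes)) {
      p <- expit(outcome_linpred(spec, out, df, df$bmi_true))
      df[[paste0("y_", out)]] <- rbinom(n, 1, p)
    }

    strat <- interaction(df$region, df$year, drop = FALSE, sep = "_")
    df$stratum <- factor(as.character(strat), levels = levels(strat))
    k <- spec$design$clusters_per_stratum
    cl <- if (n > 0) paste0(as.character(df$stratum), "_c",
                            sample.int(k, n, TRUE)) else character(0)
    df$cluster <- factor(cl)
    df$weight <- exp(rnorm(n, 0, spec$design$weight_log_sd))

    rates <- spec$missingness$rates
    for (v in names(rates)) {
      if (rates[[v]] <= 0) next
      lp <- qlogis(rates[[v]]) +
        spec$missingness$age_effect * (df$age - 50) +
        spec$missingness$female_effect * (as.numeric(df$sex == "female") - 0.5)
      df[[v]][runif(n) < expit(lp)] <- NA
    }
    class(df) <- c("survey_dataset", "data.frame")
    validate_survey_dataset(df)
    df
  })
}

#' Validate the survey-dataset contract
#'
#' Checks strictly positive weights, stratum/cluster presence, 0/1 outcome
#' coding, and that measured anthropometry is present exactly on the
#' examination arm (pre-imputation data only).
#'
#' @param data a `survey_dataset`.
#' @param completed if `TRUE`, the measured layer must be fully observed
#'   (post-imputation contract).
#' @return the data, invisibly; errors describe the violated invariant.
#' @export
validate_survey_dataset <- function(data, completed = FALSE) {
  need <- c("id", "bmi_self", "stratum", "cluster", "weight",
            "height_measured", "weight_measured", "wc_measured")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("survey_dataset lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(data$weight)) || any(data$weight <= 0)) {
    stop("survey weights must be strictly positive", call. = FALSE)
  }
  if (anyNA(data$stratum) || anyNA(data$cluster)) {
    stop("every record needs a stratum and a cluster", call. = FALSE)
  }
  for (v in grep("^y_", names(data), value = TRUE)) {
    if (!all(data[[v]] %in% c(0, 1))) {
      stop("outcome ", v, " must be coded 0/1", call. = FALSE)
    }
  }
  if (completed) {
    if (anyNA(data$height_measured) || anyNA(data$weight_measured) ||
        anyNA(data$wc_measured)) {
      stop("completed dataset still has missing measured anthropometry",
           call. = FALSE)
    }
  } else if ("exam" %in% names(data)) {
    inarm <- data$exam == 1
    if (anyNA(data$wc_measured[inarm]) || !all(is.na(data$wc_measured[!inarm]))) {
      stop("measured anthropometry must be present exactly on the examination arm",
           call. = FALSE)
    }
  }
  invisible(data)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d records, %d examined, %d outcomes\n",
              nrow(x), sum(x$exam %||% 0), length(grep("^y_", names(x)))))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Oracle potential impact fraction of a scenario under the true model
#'
#' Monte-Carlo evaluation of the estimand directly from the data-generating
#' process: simulate `n_mc` individuals, compute mean true-model risk at the
#' factual exposure (P_obs) and at the scenario-transformed exposure (P_cf),
#' and return `1 - P_cf / P_obs`. The counterfactual risk is computed from the
#' true structural model: BMI interventions act on true BMI; the
#' waist-circumference intervention (s4) holds the WC residual fixed and lowers
#' BMI through the structural WC link. Scenario-1 counterfactual BMIs are drawn
#' from the generator's own normal-BMI (18.5 <= BMI < 25) distribution. The
#' oracle never touches a fitted model, so it is independent of the estimator
#' it benchmarks.
#'
#' @param spec a `population_spec`.
#' @param scenario a [scenario()] definition.
#' @param outcome outcome id (`"diabetes"`, `"hypertension"`, `"cvd"`, `"msk"`).
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed.
#' @return list with `pif`, delta-method Monte-Carlo `se`, `p_obs`, `p_cf`.
#' @export
true_pif <- function(spec, scenario, outcome, n_mc = 2e5, seed = 1L) {
  validate_population_spec(spec)
  stopifnot(inherits(scenario, "scenario_definition"), n_mc >= 1)
  with_seed(derive_seed(seed, 202L), {
    df <- generate_core(spec, as.integer(n_mc))
    bmi <- df$bmi_true
    p_obs_i <- expit(outcome_linpred(spec, outcome, df, bmi))
    bmi_cf <- bmi
    if (scenario$id != "identity") {
      tgt <- scenario_target(scenario, bmi = bmi, wc = df$wc_true,
                             height = df$height_true)
      if (scenario$id == "s4") {
        # invert the structural WC link, holding the WC residual fixed
        wc_cf <- df$height_true / 2
        bmi_cf[tgt] <- bmi[tgt] -
          (df$wc_true[tgt] - wc_cf[tgt]) / spec$anthropometry$wc$bmi
      } else {
        bmi_cf[tgt] <- scenario_transform(scenario, bmi = bmi, w = NULL,
                                          tgt = tgt,
                                          pool_values = bmi, pool_weights = NULL)
      }
    }
    p_cf_i <- expit(outcome_linpred(spec, outcome, df, bmi_cf))
    p_obs <- mean(p_obs_i); p_cf <- mean(p_cf_i)
    if (p_obs == 0) stop("undefined estimand: P_obs is zero", call. = FALSE)
    pif <- 1 - p_cf / p_obs
    # delta-method MC standard error of the ratio
    infl <- p_cf_i / p_obs - (p_cf / p_obs^2) * p_obs_i
    se <- sd(infl) / sqrt(n_mc)
    list(pif = pif, se = se, p_obs = p_obs, p_cf = p_cf, n_mc = n_mc)
  })
}
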