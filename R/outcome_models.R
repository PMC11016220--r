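#' Default confounder adjustment set
#'
#' Socio-demographic, lifestyle and residential-environment covariates plus
#' region and survey year - the back-door adjustment set of the causal graph.
#' Metabolic factors (hypertension, hypercholesterolemia) are colliders or
#' mediators on the adiposity-disease pathway and are never adjusted for.
#'
#' @param drop covariates to omit (e.g. `"activity"` for the sensitivity
#'   analysis without physical-activity adjustment).
#' @return character vector of covariate names.
#' @export
default_adjustment <- function(drop = character(0)) {
  setdiff(c("age", "sex", "education", "income", "household", "smoking",
            "indoor_smoking", "alcohol", "activity", "black_carbon",
            "vegetation", "road_noise", "region", "year"), drop)
}

#' Specify a survey-weighted logistic outcome model
#'
#' One binary chronic-disease outcome modelled on a continuous adiposity
#' exposure (BMI or waist circumference) plus the confounder adjustment set.
#' Candidate quadratic and exposure-by-covariate interaction terms can be
#' screened by bidirectional stepwise AIC ([select_terms_aic()]).
#'
#' @param outcome outcome id; the data column is `y_<outcome>`.
#' @param exposure `"bmi"` or `"wc"`.
#' @param adjustment covariate names ([default_adjustment()]).
#' @param quadratic offer the squared exposure as a candidate term.
#' @param interactions covariates whose exposure interaction is a candidate.
#' @param selection `"none"` fits main effects (plus any `extra_terms`);
#'   `"aic"` runs stepwise selection over the candidates.
#' @param extra_terms term labels forced into the model (e.g. a previously
#'   selected set).
#' @param cols analysis column mapping ([analysis_cols()]).
#' @return an `outcome_model_spec`.
#' @export
outcome_model_spec <- function(outcome, exposure = c("bmi", "wc"),
                               adjustment = default_adjustment(),
                               quadratic = FALSE,
                               interactions = character(0),
                               selection = c("none", "aic"),
                               extra_terms = character(0),
                               cols = analysis_cols()) {
  exposure <- match.arg(exposure)
  selection <- match.arg(selection)
  if (any(c("hypertension", "hypercholesterolemia") %in% adjustment)) {
    stop_config("metabolic factors are colliders/mediators and cannot enter the adjustment set")
  }
  structure(list(outcome = outcome, exposure = exposure,
                 exposure_col = if (exposure == "bmi") cols$bmi else cols$wc,
                 adjustment = adjustment, quadratic = isTRUE(quadratic),
                 interactions = interactions, selection = selection,
                 extra_terms = extra_terms, cols = cols),
            class = "outcome_model_spec")
}

model_formula <- function(spec, terms_extra = spec$extra_terms) {
  rhs <- c(spec$exposure_col, spec$adjustment, terms_extra)
  reformulate(rhs, response = paste0("y_", spec$outcome))
}

candidate_terms <- function(spec) {
  cand <- character(0)
  if (spec$quadratic) cand <- c(cand, sprintf("I(%s^2)", spec$exposure_col))
  if (length(spec$interactions)) {
    cand <- c(cand, paste0(spec$exposure_col, ":", spec$interactions))
  }
  cand
}

## -2 * weighted Bernoulli log-likelihood + 2k, weights normalized to mean 1
weighted_aic <- function(y, p, w, k) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p))) + 2 * k
}

fit_glm_fast <- function(X, y, w, start = NULL) {
  glm.fit(X, y, weights = w, family = quasibinomial(), start = start,
          control = list(epsilon = 1e-9, maxit = 50))
}

#' Fit a survey-weighted logistic outcome model
#'
#' Maximizes the weighted quasibinomial likelihood (weights normalized to mean
#' one, so coefficients are invariant to the weight scale) and attaches a
#' robust sandwich variance. Categorical covariates use reference-level dummy
#' coding with the first level as reference. With `selection = "aic"` the
#' candidate quadratic/interaction terms are screened first by
#' [select_terms_aic()].
#'
#' @param data a completed `survey_dataset` (no missing model variables).
#' @param spec an [outcome_model_spec()].
#' @param allow_separation keep a saturated fit instead of erroring when the
#'   outcome is perfectly separated; used by rank-based consumers such as
#'   [evaluate_auc()], where a saturated fit still orders risks correctly.
#' @param compute_vcov attach the sandwich variance (skipped inside bootstrap
#'   loops, where the resampling itself provides the uncertainty).
#' @return an `outcome_model_fit`: coefficients, sandwich `vcov`, the
#'   design-expansion recipe (formula, factor levels), selected terms, AIC
#'   (weighted Bernoulli), `n`.
#' @export
fit_outcome_model <- function(data, spec, allow_separation = FALSE,
                              compute_vcov = TRUE) {
  stopifnot(inherits(spec, "outcome_model_spec"))
  if (any(data$weight <= 0)) stop("non-positive survey weights", call. = FALSE)
  selected <- spec$extra_terms
  if (spec$selection == "aic") {
    selected <- union(selected, select_terms_aic(data, spec))
  }
  form <- model_formula(spec, selected)
  mf <- model.frame(form, data, na.action = stats::na.fail)
  d2 <- data
  d2$.wn <- data$weight / mean(data$weight)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = quasibinomial(), weights = .wn, data = d2),
    warning = function(wrn) {
      msg <- conditionMessage(wrn)
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                msg)) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("model is not identifiable (aliased terms): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  if (sep && !allow_separation) {
    stop("perfect separation suspected for term ",
         names(cf[-1])[which.max(abs(cf[-1]))], call. = FALSE)
  }
  p <- fit$fitted.values
  y <- stats::model.response(mf)
  out <- list(
    coef = cf,
    vcov = if (compute_vcov) sandwich::vcovHC(fit, type = "HC0"),
    formula = deparse1(form),
    xlev = fit$xlevels,
    outcome = spec$outcome,
    exposure = spec$exposure,
    exposure_col = spec$exposure_col,
    selected = selected,
    aic = weighted_aic(y, p, d2$.wn, length(cf)),
    n = nrow(data))
  class(out) <- "outcome_model_fit"
  out
}

#' @export
print.outcome_model_fit <- function(x, ...) {
  cat(sprintf("<outcome_model_fit> y_%s ~ %s (+%d covariate terms), n=%d, AIC=%.1f\n",
              x$outcome, x$exposure_col, length(x$coef) - 2L, x$n, x$aic))
  if (length(x$selected)) cat("  selected terms:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

model_matrix_for <- function(model, data) {
  tt <- delete.response(terms(as.formula(model$formula)))
  model.matrix(tt, data, xlev = model$xlev)
}

#' Predict risks from a fitted outcome model
#'
#' Rebuilds the design matrix from the stored recipe (formula plus factor
#' levels), so predictions are reproducible after a JSON round trip.
#'
#' @param model an `outcome_model_fit` (possibly [read_model_json()]).
#' @param data new data with the model variables.
#' @return predicted risks in (0, 1).
#' @export
predict_risk <- function(model, data) {
  X <- model_matrix_for(model, data)
  as.numeric(expit(X %*% model$coef))
}

#' Odds ratio per interquartile-range increase of the exposure
#'
#' `exp(beta_exposure * IQR)` with a normal 95 percent interval, the IQR taken
#' from the survey-weighted exposure distribution. When quadratic or
#' interaction terms involving the exposure were selected, the main-term OR is
#' returned with `conditional = TRUE`: it is then the slope at the reference
#' covariate pattern, not a marginal contrast.
#'
#' @param model an `outcome_model_fit`.
#' @param data the completed dataset the IQR is computed on.
#' @param conf_level confidence level.
#' @return list with `or`, `lo`, `hi`, `iqr`, `conditional`.
#' @export
or_per_iqr <- function(model, data, conf_level = 0.95) {
  iqr <- weighted_iqr(data[[model$exposure_col]], data$weight)
  if (iqr <= 0) stop("degenerate exposure: zero interquartile range",
                     call. = FALSE)
  b <- model$coef[[model$exposure_col]]
  se <- sqrt(model$vcov[model$exposure_col, model$exposure_col])
  z <- qnorm(1 - (1 - conf_level) / 2)
  cond <- any(grepl(model$exposure_col, model$selected, fixed = TRUE))
  list(or = exp(b * iqr), lo = exp((b - z * se) * iqr),
       hi = exp((b + z * se) * iqr), iqr = iqr, conditional = cond)
}

#' Bidirectional stepwise AIC screening of quadratic/interaction terms
#'
#' Greedy bidirectional search on AIC starting from the main-effects model;
#' the scope is the candidate squared exposure plus the candidate
#' exposure-by-covariate interactions. AIC uses the explicitly
#' survey-weighted Bernoulli log-likelihood (weights normalized to mean one).
#' Deterministic: ties break toward the earlier candidate.
#'
#' @param data completed dataset.
#' @param spec an [outcome_model_spec()] with `quadratic` and/or
#'   `interactions` candidates.
#' @return character vector of selected term labels (possibly empty).
#' @export
select_terms_aic <- function(data, spec) {
  cand <- candidate_terms(spec)
  if (!length(cand)) return(character(0))
  y <- data[[paste0("y_", spec$outcome)]]
  wn <- data$weight / mean(data$weight)
  aic_of <- function(terms_in) {
    X <- model.matrix(model_formula(spec, terms_in), data)
    fit <- fit_glm_fast(X, y, wn)
    weighted_aic(y, fit$fitted.values, wn, ncol(X))
  }
  current <- character(0)
  best <- aic_of(current)
  repeat {
    moves <- c(lapply(setdiff(cand, current), function(t) union(current, t)),
               lapply(intersect(cand, current), function(t) setdiff(current, t)))
    if (!length(moves)) break
    aics <- vapply(moves, aic_of, numeric(1))
    if (min(aics) < best - 1e-8) {
      best <- min(aics)
      current <- moves[[which.min(aics)]]
    } else break
  }
  current
}

#' Split-sample discrimination of an outcome model
#'
#' Random 70/30 train/test split, model fitted on the training part, and the
#' survey-weighted AUC evaluated on the held-out part. The pipeline averages
#' this over the `m` completed datasets.
#'
#' @param data completed dataset.
#' @param spec an [outcome_model_spec()].
#' @param train_fraction fraction of records used for fitting.
#' @param seed split seed.
#' @return the weighted test-set AUC.
#' @export
evaluate_auc <- function(data, spec, train_fraction = 0.7, seed = 1L) {
  n <- nrow(data)
  idx <- with_seed(derive_seed(seed, 505L),
                   sample.int(n, size = floor(train_fraction * n)))
  train <- data[idx, , drop = FALSE]
  test <- data[-idx, , drop = FALSE]
  y <- test[[paste0("y_", spec$outcome)]]
  if (length(unique(y)) < 2) {
    stop("test split contains a single outcome class", call. = FALSE)
  }
  model <- fit_outcome_model(train, spec, allow_separation = TRUE)
  weighted_auc(predict_risk(model, test), y, test$weight)
}

#' Export / import a fitted outcome model as JSON
#'
#' Serializes coefficients, sandwich variance, the design recipe (formula and
#' factor levels), the selected terms and fit metadata with full numeric
#' precision, so that [predict_risk()] reproduces predictions bit-for-bit
#' after the round trip.
#'
#' @param model an `outcome_model_fit`.
#' @param path file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the `outcome_model_fit`.
#' @export
write_model_json <- function(model, path) {
  x <- list(coef = as.list(model$coef),
            vcov = list(names = colnames(model$vcov),
                        values = as.numeric(model$vcov)),
            formula = model$formula, xlev = model$xlev,
            outcome = model$outcome, exposure = model$exposure,
            exposure_col = model$exposure_col, selected = model$selected,
            aic = model$aic, n = model$n)
  # I(17) significant digits: decimal text that parses back to the same double
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(x$coef)
  vc <- matrix(x$vcov$values, k, k,
               dimnames = list(x$vcov$names, x$vcov$names))
  out <- list(coef = unlist(x$coef), vcov = vc, formula = x$formula,
              xlev = lapply(x$xlev, as.character), outcome = x$outcome,
              exposure = x$exposure, exposure_col = x$exposure_col,
              selected = as.character(x$selected %||% character(0)),
              aic = x$aic, n = x$n)
  class(out) <- "outcome_model_fit"
  out
}
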