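#' Counterfactual weight-reduction scenarios
#'
#' Constructs one of the four built-in intervention scenarios, or the identity
#' (no-intervention) scenario:
#'
#' * `s1` - distribution shift: each targeted person's BMI is redrawn, with
#'   replacement and survey weights, from the empirical BMI distribution of the
#'   normal-BMI reference pool (18.5 <= BMI < 25); stochastic.
#' * `s2` - a one-unit BMI reduction for the targeted population.
#' * `s3` - a 10 percent weight loss, i.e. counterfactual BMI = 0.9 x BMI
#'   (BMI is proportional to weight at fixed height).
#' * `s4` - waist circumference lowered to half the height among all people
#'   with WC:height ratio above 0.5.
#' * `identity` - no record is transformed (null intervention).
#'
#' Scenarios `s1`-`s3` act on BMI and take a target population of either all
#' people with overweight (`"bmi25"`, BMI > 25) or with obesity (`"bmi30"`,
#' BMI > 30); `s4` acts on waist circumference with its single WC:height > 0.5
#' target. Targets use strict inequalities. Custom interventions are defined
#' with `id = "custom"` plus a `target_fn(bmi, wc, height)` predicate and a
#' deterministic `transform_fn(x)` on the exposure.
#'
#' @param id one of `"s1"`, `"s2"`, `"s3"`, `"s4"`, `"identity"`, `"custom"`.
#' @param target `"bmi25"` or `"bmi30"` (s1-s3 only).
#' @param exposure exposure for custom scenarios, `"bmi"` or `"wc"`.
#' @param target_fn,transform_fn predicate and transform for custom scenarios.
#' @return an object of class `scenario_definition`.
#' @examples
#' scenario("s2", target = "bmi25")
#' @export
scenario <- function(id = c("s1", "s2", "s3", "s4", "identity", "custom"),
                     target = c("bmi25", "bmi30"),
                     exposure = c("bmi", "wc"),
                     target_fn = NULL, transform_fn = NULL) {
  id <- match.arg(id)
  target <- match.arg(target)
  s <- list(id = id, target = target, stochastic = FALSE)
  if (id %in% c("s1", "s2", "s3")) {
    s$exposure <- "bmi"
    s$stochastic <- id == "s1"
  } else if (id == "s4") {
    s$exposure <- "wc"
    s$target <- "whtr"
  } else if (id == "identity") {
    s$exposure <- match.arg(exposure)
    s$target <- "none"
  } else {
    if (!is.function(target_fn) || !is.function(transform_fn)) {
      stop("custom scenarios need target_fn and transform_fn", call. = FALSE)
    }
    s$exposure <- match.arg(exposure)
    s$target <- "custom"
    s$target_fn <- target_fn
    s$transform_fn <- transform_fn
  }
  structure(s, class = "scenario_definition")
}

#' @export
print.scenario_definition <- function(x, ...) {
  desc <- switch(x$id,
    s1 = "distribution shift to the normal-BMI reference pool",
    s2 = "one-unit BMI reduction",
    s3 = "10% weight loss (BMI x 0.9)",
    s4 = "waist circumference lowered to height/2",
    identity = "null intervention",
    custom = "custom intervention")
  cat(sprintf("<scenario %s> %s; exposure %s; target %s%s\n", x$id, desc,
              x$exposure, x$target, if (x$stochastic) " (stochastic)" else ""))
  invisible(x)
}

scenario_label <- function(s) {
  if (s$id %in% c("s1", "s2", "s3")) paste0(s$id, "_", s$target) else s$id
}

## target mask from raw vectors (strict inequalities, as printed)
scenario_target <- function(s, bmi, wc, height) {
  switch(s$target,
    bmi25 = bmi > 25,
    bmi30 = bmi > 30,
    whtr = wc / height > 0.5,
    none = rep(FALSE, length(bmi)),
    custom = s$target_fn(bmi = bmi, wc = wc, height = height),
    stop("unknown scenario target '", s$target, "'", call. = FALSE)
  )
}

## counterfactual values for target records only (callers assign into a copy);
## s1 draws expect a seeded RNG state
scenario_transform <- function(s, bmi, w, tgt, pool_values, pool_weights,
                               height = NULL, wc = NULL) {
  switch(s$id,
    s1 = {
      pool <- pool_values >= 18.5 & pool_values < 25
      if (!any(pool)) {
        stop("scenario infeasible: empty normal-BMI reference pool",
             call. = FALSE)
      }
      pv <- pool_values[pool]
      pw <- if (is.null(pool_weights)) NULL else pool_weights[pool]
      pv[sample.int(length(pv), sum(tgt), replace = TRUE, prob = pw)]
    },
    s2 = bmi[tgt] - 1,
    s3 = 0.9 * bmi[tgt],
    s4 = height[tgt] / 2,
    custom = s$transform_fn(if (s$exposure == "bmi") bmi[tgt] else wc[tgt]),
    stop("unknown scenario id '", s$id, "'", call. = FALSE)
  )
}

#' Apply a scenario to a completed dataset
#'
#' Computes the counterfactual exposure column and the target mask. Records
#' outside the target keep their factual exposure bit-identically. Scenario-1
#' draws are taken, with replacement and survey weights, from the dataset's own
#' normal-BMI reference pool and are reproducible given `seed`.
#'
#' @param data a completed `survey_dataset` (no missing exposure or height).
#' @param scenario a [scenario()] definition.
#' @param seed integer seed (needed for the stochastic `s1`).
#' @param cols column mapping from [analysis_cols()].
#' @return list with `exposure` (`"bmi"` or `"wc"`), `column` (data column
#'   transformed), `cf` (counterfactual values), and logical `target`.
#' @export
apply_scenario <- function(data, scenario, seed = 1L, cols = analysis_cols()) {
  stopifnot(inherits(scenario, "scenario_definition"))
  bmi <- data[[cols$bmi]]
  wc <- data[[cols$wc]]
  height <- data[[cols$height]]
  xcol <- if (scenario$exposure == "bmi") cols$bmi else cols$wc
  x <- data[[xcol]]
  if (anyNA(x) || (scenario$target == "whtr" && anyNA(height))) {
    stop("apply_scenario needs completed (imputed) exposure and height columns",
         call. = FALSE)
  }
  tgt <- scenario_target(scenario, bmi = bmi, wc = wc, height = height)
  cf <- x
  if (scenario$id != "identity" && any(tgt)) {
    cf[tgt] <- with_seed(derive_seed(seed, 303L),
      scenario_transform(scenario, bmi = bmi, w = data$weight, tgt = tgt,
                         pool_values = bmi, pool_weights = data$weight,
                         height = height, wc = wc))
  }
  list(exposure = scenario$exposure, column = xcol, cf = cf, target = tgt)
}

#' Survey-weighted mean exposure reduction under a scenario
#'
#' The weighted mean of (factual minus counterfactual exposure),
#' `sum(w_i (x_i - x_i^cf)) / sum(w_i)`. By default the average runs over the
#' target population, which makes the scenario-2 value exactly 1 BMI unit by
#' construction; `basis = "population"` averages over everyone (non-targets
#' contribute zero reduction).
#'
#' @inheritParams apply_scenario
#' @param basis `"target"` (default) or `"population"`.
#' @return weighted mean reduction in exposure units (BMI units or cm). An
#'   empty target yields 0 with a warning.
#' @export
mean_exposure_reduction <- function(data, scenario, seed = 1L,
                                    cols = analysis_cols(),
                                    basis = c("target", "population")) {
  basis <- match.arg(basis)
  app <- apply_scenario(data, scenario, seed = seed, cols = cols)
  if (!any(app$target)) {
    warning("empty target population; mean exposure reduction is 0",
            call. = FALSE)
    return(0)
  }
  x <- data[[app$column]]
  d <- x - app$cf
  keep <- if (basis == "target") app$target else rep(TRUE, nrow(data))
  weighted_mean(d[keep], data$weight[keep])
}

#' Analysis column mapping
#'
#' Names the dataset columns used as analysis BMI, waist circumference, height
#' and weight. The defaults point at the measured (imputation-completed)
#' layer, matching an analysis that corrects self-report bias; pass
#' `analysis_cols(bmi = "bmi_true", ...)` to work directly on generator truth
#' in simulations without the imputation step.
#'
#' @param bmi,wc,height,weight column names.
#' @return a named list.
#' @export
analysis_cols <- function(bmi = "bmi_measured", wc = "wc_measured",
                          height = "height_measured",
                          weight = "weight_measured") {
  list(bmi = bmi, wc = wc, height = height, weight = weight)
}
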