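#' Positivity (overlap) diagnostic
#'
#' Counterfactual shifts of the exposed group are identifiable only if every
#' confounder stratum containing target records also contains reference
#' records. As a practical check, a logistic membership model for the exposed
#' class is fitted on the confounders, membership probabilities are predicted
#' separately for each group, and the overlap of the two probability
#' distributions is summarized by the overlap coefficient (integrated minimum
#' of the two densities) on a fixed 50-bin histogram over [0, 1]. The
#' coefficient is symmetric in the group labels; values near 0 signal
#' structural separation.
#'
#' @param data completed dataset.
#' @param confounders covariate names ([default_adjustment()]).
#' @param exposure_class_rule predicate on the data returning the exposed-class
#'   indicator; default: BMI above 25.
#' @param cols analysis column mapping.
#' @param bins number of histogram bins.
#' @param threshold overlap below which positivity is flagged implausible
#'   (documented convention, default 0.2).
#' @return an `overlap_report`: `overlap`, `plausible`, per-group summaries,
#'   bin probabilities.
#' @export
positivity_overlap <- function(data, confounders = default_adjustment(),
                               exposure_class_rule = NULL,
                               cols = analysis_cols(), bins = 50L,
                               threshold = 0.2) {
  g <- if (is.null(exposure_class_rule)) {
    as.numeric(data[[cols$bmi]] > 25)
  } else {
    as.numeric(exposure_class_rule(data))
  }
  if (length(unique(g)) < 2) {
    stop("positivity diagnostic needs both classes present", call. = FALSE)
  }
  form <- reformulate(confounders, response = ".exposed")
  d <- data
  d$.exposed <- g
  wn <- d$weight / mean(d$weight)
  fit <- suppressWarnings(glm(form, family = quasibinomial(), weights = wn,
                              data = d))
  p <- fit$fitted.values
  brk <- seq(0, 1, length.out = bins + 1)
  h <- function(x) {
    ct <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE), bins),
                   nbins = bins)
    ct / sum(ct)
  }
  p1 <- h(p[g == 1]); p0 <- h(p[g == 0])
  ovl <- sum(pmin(p1, p0))
  structure(list(
    overlap = ovl, plausible = ovl >= threshold, threshold = threshold,
    bins = bins, prob_exposed = p1, prob_reference = p0,
    summary = rbind(exposed = summary(p[g == 1]),
                    reference = summary(p[g == 0]))),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> overlap coefficient %.3f (%d bins): positivity %s\n",
              x$overlap, x$bins,
              if (x$plausible) "plausible" else "questionable"))
  invisible(x)
}

#' Residual (conditional) SD of an anthropometric variable given covariates
#'
#' Survey-weighted linear regression of BMI or waist circumference on the
#' covariates; returns the weighted residual SD
#' `sqrt(sum(w e^2) / sum(w) * n / (n - p))`. Aliased (collinear) columns are
#' dropped with a warning. This is the scale against which the scenarios'
#' mean exposure reductions are judged.
#'
#' @param data completed dataset.
#' @param variable `"bmi"` or `"wc"`.
#' @param covariates covariate names.
#' @param cols analysis column mapping.
#' @return residual SD in the variable's units.
#' @export
conditional_sd <- function(data, variable = c("bmi", "wc"),
                           covariates = default_adjustment(),
                           cols = analysis_cols()) {
  variable <- match.arg(variable)
  vcol <- if (variable == "bmi") cols$bmi else cols$wc
  form <- reformulate(covariates, response = vcol)
  fit <- lm(form, data = data, weights = data$weight)
  if (anyNA(coef(fit))) {
    warning("collinear design: dropped ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
            call. = FALSE)
  }
  e <- stats::residuals(fit)
  w <- data$weight
  n <- length(e)
  p <- sum(!is.na(coef(fit)))
  sqrt(sum(w * e^2) / sum(w) * n / (n - p))
}

#' Simulation study of the PIF estimator
#'
#' Repeats generate -> (optionally impute) -> estimate with bootstrap SE ->
#' pool, and benchmarks the estimates against the known-truth oracle
#' [true_pif()]: bias, RMSE, empirical SE of the point estimates, mean
#' bootstrap/pooled SE, and 95 percent CI coverage, per scenario x outcome.
#' Fully reproducible from the single master seed. Replicates failing at any
#' stage are tallied; more than 5 percent failures aborts the study.
#'
#' @param spec a `population_spec`.
#' @param scenarios list of [scenario()] definitions.
#' @param outcomes outcome ids.
#' @param n records per replicate.
#' @param replicates number of simulation replicates (>= 2).
#' @param n_boot bootstrap replicates per estimate.
#' @param seed master seed.
#' @param impute run the RF-MICE correction inside each replicate; if `FALSE`
#'   the estimator reads the generator's true anthropometry directly.
#' @param config [imputation_config()] used when `impute = TRUE`.
#' @param n_mc_oracle Monte-Carlo size for the oracle.
#' @param conf_level CI level for the coverage assessment.
#' @return a `simulation_study` data frame: one row per scenario x outcome
#'   with `truth`, `bias`, `rmse`, `empirical_se`, `mean_se`, `coverage`,
#'   `n_fail`.
#' @export
run_simulation_study <- function(spec, scenarios, outcomes, n = 2000L,
                                 replicates = 100L, n_boot = 200L, seed = 1L,
                                 impute = FALSE,
                                 config = imputation_config(m = 5L,
                                                            n_iterations = 20L),
                                 n_mc_oracle = 2e5, conf_level = 0.95) {
  stopifnot(replicates >= 2)
  if (inherits(scenarios, "scenario_definition")) scenarios <- list(scenarios)
  cols <- if (impute) analysis_cols() else
    analysis_cols(bmi = "bmi_true", wc = "wc_true", height = "height_true",
                  weight = "weight_true")
  if (!impute) {
    # the no-imputation route reads generator truth and needs complete covariates
    spec$missingness$rates <- numeric(0)
  }
  combos <- expand.grid(s = seq_along(scenarios), o = seq_along(outcomes))
  res <- vector("list", nrow(combos))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  for (k in seq_len(nrow(combos))) {
    sc <- scenarios[[combos$s[k]]]
    out <- outcomes[combos$o[k]]
    truth <- true_pif(spec, sc, out, n_mc = n_mc_oracle,
                      seed = derive_seed(seed, 707L, k))$pif
    mspec <- outcome_model_spec(out, exposure = sc$exposure, cols = cols)
    est <- lo <- hi <- se <- rep(NA_real_, replicates)
    fails <- 0L
    for (r in seq_len(replicates)) {
      rseed <- derive_seed(seed, 808L, k, r)
      ok <- tryCatch({
        d <- generate_population(spec, n, seed = rseed)
        if (impute) {
          cfg <- config
          cfg$seed <- derive_seed(rseed, 1L)
          comp <- rf_mice_impute(d, cfg)
          es <- lapply(comp$datasets, function(dj) {
            bootstrap_pif(dj, mspec, sc, n_boot = n_boot,
                          seed = derive_seed(rseed, 2L), cols = cols)
          })
          pl <- pool_pif_estimates(es, conf_level = conf_level)$pif
          est[r] <- pl$estimate; se[r] <- pl$se
          lo[r] <- pl$lo; hi[r] <- pl$hi
        } else {
          e <- bootstrap_pif(d, mspec, sc, n_boot = n_boot,
                             seed = derive_seed(rseed, 2L), cols = cols)
          est[r] <- e$pif; se[r] <- e$se_pif
          lo[r] <- e$pif - zc * e$se_pif; hi[r] <- e$pif + zc * e$se_pif
        }
        TRUE
      }, error = function(e) FALSE)
      if (!ok) fails <- fails + 1L
    }
    if (fails > 0.05 * replicates) {
      stop(sprintf("simulation study error: %d of %d replicates failed",
                   fails, replicates), call. = FALSE)
    }
    use <- is.finite(est)
    res[[k]] <- data.frame(
      scenario = scenario_label(sc), outcome = out, truth = truth,
      bias = mean(est[use]) - truth,
      rmse = sqrt(mean((est[use] - truth)^2)),
      empirical_se = sd(est[use]), mean_se = mean(se[use]),
      coverage = mean(lo[use] <= truth & truth <= hi[use]),
      n_fail = fails, replicates = sum(use))
  }
  out <- do.call(rbind, res)
  class(out) <- c("simulation_study", "data.frame")
  out
}
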