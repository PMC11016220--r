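#' Point estimate of the potential impact fraction by g-computation
#'
#' Model-based standardization: (i) fit the survey-weighted logistic outcome
#' model; (ii) predict each record's risk at its factual exposure and take the
#' weighted average, P_obs; (iii) apply the scenario; (iv) predict at the
#' counterfactual exposure with all covariates held fixed and average, P_cf;
#' (v) PIF = 1 - P_cf / P_obs and RD = P_cf - P_obs. With the model-predicted
#' denominator (default) the identity scenario gives PIF = 0 exactly, because
#' identical predictions enter numerator and denominator;
#' `denominator = "empirical"` swaps in the weighted observed prevalence.
#'
#' @param data a completed `survey_dataset`.
#' @param model_spec an [outcome_model_spec()].
#' @param scenario a [scenario()]; its exposure must match the model's.
#' @param seed seed feeding scenario-1 draws only.
#' @param frozen_model optionally, a fixed `outcome_model_fit` used instead of
#'   fitting (no estimation step; for validation against closed-form oracles).
#' @param denominator `"model"` (predicted prevalence) or `"empirical"`.
#' @param cols analysis column mapping.
#' @return a `pif_estimate` with `p_obs`, `p_cf`, `rd`, `pif` (fractions).
#' @export
estimate_pif <- function(data, model_spec, scenario, seed = 1L,
                         frozen_model = NULL,
                         denominator = c("model", "empirical"),
                         cols = analysis_cols()) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(scenario, "scenario_definition"))
  if (scenario$id != "identity" && scenario$exposure != model_spec$exposure) {
    stop_config("scenario exposure '%s' does not match model exposure '%s'",
                scenario$exposure, model_spec$exposure)
  }
  model <- frozen_model %||% fit_outcome_model(data, model_spec)
  w <- data$weight
  p <- predict_risk(model, data)
  p_obs <- if (denominator == "model") weighted_mean(p, w)
           else weighted_mean(data[[paste0("y_", model$outcome)]], w)
  if (p_obs == 0) stop("undefined estimand: P_obs is zero", call. = FALSE)
  app <- apply_scenario(data, scenario, seed = seed, cols = cols)
  cf_data <- data
  cf_data[[app$column]] <- app$cf
  p_cf <- weighted_mean(predict_risk(model, cf_data), w)
  new_pif_estimate(scenario, model_spec, p_obs = p_obs, p_cf = p_cf,
                   n = nrow(data), seed = seed)
}

new_pif_estimate <- function(scenario, model_spec, p_obs, p_cf, n, seed,
                             se_pif = NA_real_, se_rd = NA_real_,
                             n_boot = 0L, n_dropped = 0L, replicates = NULL) {
  structure(list(
    scenario = scenario_label(scenario), outcome = model_spec$outcome,
    p_obs = p_obs, p_cf = p_cf, rd = p_cf - p_obs, pif = 1 - p_cf / p_obs,
    se_pif = se_pif, se_rd = se_rd, n = n, n_boot = n_boot,
    n_dropped = n_dropped, seed = seed, replicates = replicates),
    class = "pif_estimate")
}

#' @export
print.pif_estimate <- function(x, ...) {
  cat(sprintf("<pif_estimate> %s / %s: PIF = %.2f%%, RD = %.2f pp (P_obs %.3f -> P_cf %.3f)\n",
              x$scenario, x$outcome, 100 * x$pif, 100 * x$rd, x$p_obs, x$p_cf))
  if (is.finite(x$se_pif)) {
    cat(sprintf("  bootstrap SE(PIF) = %.2f pp over %d replicates (%d dropped)\n",
                100 * x$se_pif, x$n_boot, x$n_dropped))
  }
  invisible(x)
}

## Newton-Raphson weighted logistic fit on a fixed design matrix; much faster
## than glm.fit inside tight bootstrap loops. Returns NULL on failure.
fast_logit_fit <- function(X, y, w, start, maxit = 30L, tol = 1e-9) {
  beta <- start
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  dev <- -2 * sum(w * (y * log(pmax(mu, 1e-12)) +
                         (1 - y) * log(pmax(1 - mu, 1e-12))))
  for (it in seq_len(maxit)) {
    wm <- w * mu * (1 - mu)
    if (!all(is.finite(wm))) return(NULL)
    H <- crossprod(X * sqrt(wm)) # dsyrk: half the flops of a full gemm
    g <- crossprod(X, w * (y - mu))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    for (half in 0:10) {
      bn <- beta + drop(step) / 2^half
      eta_n <- drop(X %*% bn)
      mu_n <- plogis(eta_n)
      dev_n <- -2 * sum(w * (y * log(pmax(mu_n, 1e-12)) +
                               (1 - y) * log(pmax(1 - mu_n, 1e-12))))
      if (is.finite(dev_n) && dev_n <= dev + 1e-8) break
    }
    moved <- abs(dev_n - dev)
    beta <- bn; mu <- mu_n; dev <- dev_n
    if (moved < tol * (abs(dev) + 0.1)) {
      return(list(coefficients = beta, fitted = mu, converged = TRUE))
    }
  }
  NULL
}

## columns of the design matrix whose terms involve the exposure, with the
## power of the exposure in each (1 for x and x:z, 2 for I(x^2) and I(x^2):z);
## lets the counterfactual design be formed by scaling, since exposure > 0
exposure_columns <- function(tt, X, exposure_col) {
  fac <- attr(tt, "factors")
  vars <- rownames(fac)
  involved <- vapply(vars, function(v) grepl(exposure_col, v, fixed = TRUE),
                     logical(1))
  if (!any(involved)) {
    stop_config("exposure '%s' does not appear in the model terms", exposure_col)
  }
  aff_terms <- which(colSums(fac[involved, , drop = FALSE] != 0) > 0)
  pow <- vapply(aff_terms, function(tm) {
    v <- vars[involved & fac[, tm] != 0]
    if (any(grepl("^I\\(.*\\^2\\)$", v))) 2L else 1L
  }, integer(1))
  asg <- attr(X, "assign")
  list(cols = lapply(aff_terms, function(tm) which(asg == tm)),
       power = pow)
}

#' Bootstrap standard errors for the PIF within one completed dataset
#'
#' Nonparametric bootstrap: records (default) or clusters within strata are
#' resampled with replacement, the whole estimation pipeline is re-run per
#' replicate - the outcome model is refit and the scenario re-applied,
#' including fresh scenario-1 draws from the replicate's own reference pool -
#' and the SE is the SD of the replicate PIFs. The point estimate remains the
#' full-data estimate. Per-replicate seeds derive from `seed` by counter
#' splitting, so the replicate stream is independent of `n_boot`. Replicates
#' whose resampled outcome is single-class are dropped and counted; more than
#' 10 percent dropped is an error.
#'
#' @inheritParams estimate_pif
#' @param n_boot number of replicates (>= 2; the published analysis uses
#'   1000).
#' @param boot_unit `"record"` (i.i.d. records with their weights) or
#'   `"cluster"` (clusters resampled within strata).
#' @return a `pif_estimate` with `se_pif`, `se_rd` and the replicate PIFs.
#' @export
bootstrap_pif <- function(data, model_spec, scenario, n_boot = 1000L,
                          seed = 1L, boot_unit = c("record", "cluster"),
                          denominator = c("model", "empirical"),
                          cols = analysis_cols()) {
  boot_unit <- match.arg(boot_unit)
  denominator <- match.arg(denominator)
  stopifnot(n_boot >= 2)
  model <- fit_outcome_model(data, model_spec, compute_vcov = FALSE)
  point <- estimate_pif(data, model_spec, scenario,
                        seed = derive_seed(seed, 0L), frozen_model = model,
                        denominator = denominator, cols = cols)
  form <- as.formula(model$formula)
  tt_x <- delete.response(terms(form))
  ycol <- paste0("y_", model_spec$outcome)
  X <- model.matrix(tt_x, data, xlev = model$xlev)
  y <- data[[ycol]]
  w <- data$weight
  n <- nrow(data)
  bmi <- data[[cols$bmi]]; wc <- data[[cols$wc]]; ht <- data[[cols$height]]
  x <- data[[model_spec$exposure_col]]
  exp_cols <- exposure_columns(tt_x, X, model_spec$exposure_col)
  cl_index <- if (boot_unit == "cluster") {
    split(seq_len(n), list(data$stratum, data$cluster), drop = TRUE)
  }
  strat_of <- if (boot_unit == "cluster") {
    vapply(cl_index, function(i) as.character(data$stratum[i[1]]), character(1))
  }
  pif_b <- rd_b <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    bseed <- derive_seed(seed, 606L, b)
    idx <- with_seed(bseed, {
      if (boot_unit == "record") sample.int(n, n, replace = TRUE)
      else {
        picked <- unlist(lapply(split(seq_along(cl_index), strat_of),
                                function(ii) sample(ii, length(ii),
                                                    replace = TRUE)),
                         use.names = FALSE)
        unlist(cl_index[picked], use.names = FALSE)
      }
    })
    yb <- y[idx]
    if (all(yb == yb[1])) next # single-class replicate: dropped and counted
    wb <- w[idx]
    Xb <- X[idx, , drop = FALSE]
    fit <- fast_logit_fit(Xb, yb, wb / mean(wb), start = model$coef)
    if (is.null(fit)) next
    p_obs_b <- if (denominator == "model") weighted_mean(fit$fitted, wb)
               else weighted_mean(yb, wb)
    if (p_obs_b == 0) next
    # re-apply the scenario on the replicate, incl. fresh s1 draws from the
    # replicate's own reference pool
    bmib <- bmi[idx]; xb <- x[idx]
    tgt <- scenario_target(scenario, bmi = bmib, wc = wc[idx],
                           height = ht[idx])
    cfb <- xb
    if (any(tgt)) {
      cfb[tgt] <- with_seed(derive_seed(bseed, 1L, 303L),
        scenario_transform(scenario, bmi = bmib, w = wb, tgt = tgt,
                           pool_values = bmib, pool_weights = wb,
                           height = ht[idx], wc = wc[idx]))
    }
    r <- cfb / xb # exposure strictly positive
    for (k in seq_along(exp_cols$cols)) {
      rk <- if (exp_cols$power[k] == 2L) r * r else r
      for (jc in exp_cols$cols[[k]]) Xb[, jc] <- Xb[, jc] * rk
    }
    p_cf_b <- weighted_mean(as.numeric(expit(Xb %*% fit$coefficients)), wb)
    pif_b[b] <- 1 - p_cf_b / p_obs_b
    rd_b[b] <- p_cf_b - p_obs_b
  }
  ok <- is.finite(pif_b)
  n_drop <- sum(!ok)
  if (n_drop > 0.1 * n_boot) {
    stop(sprintf("bootstrap failure: %d of %d replicates dropped",
                 n_drop, n_boot), call. = FALSE)
  }
  new_pif_estimate(scenario, model_spec, p_obs = point$p_obs,
                   p_cf = point$p_cf, n = n, seed = seed,
                   se_pif = sd(pif_b[ok]), se_rd = sd(rd_b[ok]),
                   n_boot = as.integer(n_boot), n_dropped = n_drop,
                   replicates = pif_b[ok])
}
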