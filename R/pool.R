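#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` per-imputation point estimates and their (squared-SE)
#' variances: pooled point is the mean, within-imputation variance `W` the
#' mean of the variances, between-imputation variance `B` the sample variance
#' of the points, total variance `T = W + (1 + 1/m) B` (the finite-m
#' correction), and classical Rubin degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2`; with `B = 0` (or `m = 1`) the
#' normal reference is used. The interval is `Qbar +/- t_{df, .975} sqrt(T)`.
#'
#' @param points numeric vector of per-imputation estimates.
#' @param variances per-imputation variances (same length, nonnegative).
#' @param conf_level confidence level.
#' @return a `pooled_estimate`: `estimate`, `within`, `between`, `total`,
#'   `df`, `se`, `lo`, `hi`, `m`.
#' @examples
#' rubin_pool(c(0.1, 0.2, 0.3), rep(0.01, 3))
#' @export
rubin_pool <- function(points, variances, conf_level = 0.95) {
  if (!length(points)) stop("rubin_pool: empty input", call. = FALSE)
  if (length(points) != length(variances)) {
    stop("rubin_pool: points and variances differ in length", call. = FALSE)
  }
  if (any(variances < 0)) stop("rubin_pool: negative variance", call. = FALSE)
  m <- length(points)
  qbar <- mean(points)
  w <- mean(variances)
  if (m == 1L) {
    warning("single imputation: total variance equals the within variance",
            call. = FALSE)
    b <- NA_real_
    tot <- w
    df <- Inf
  } else {
    b <- var(points)
    tot <- w + (1 + 1 / m) * b
    df <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  }
  alpha <- 1 - conf_level
  tcrit <- if (is.finite(df)) qt(1 - alpha / 2, df) else qnorm(1 - alpha / 2)
  se <- sqrt(tot)
  structure(list(estimate = qbar, within = w, between = b, total = tot,
                 df = df, se = se, lo = qbar - tcrit * se,
                 hi = qbar + tcrit * se, m = m, conf_level = conf_level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> %.4g [%.4g, %.4g] (m=%d, W=%.3g, B=%.3g, T=%.3g, df=%.3g)\n",
              x$estimate, x$lo, x$hi, x$m, x$within,
              if (is.na(x$between)) NA else x$between, x$total, x$df))
  invisible(x)
}

#' Pool per-imputation PIF estimates
#'
#' Applies [rubin_pool()] to the PIF and the risk difference of `m`
#' [bootstrap_pif()] results for the same scenario and outcome, on the raw
#' fraction scale.
#'
#' @param estimates list of `pif_estimate`s (one per completed dataset).
#' @param conf_level confidence level.
#' @return list with `pif` and `rd` `pooled_estimate`s plus scenario/outcome
#'   labels.
#' @export
pool_pif_estimates <- function(estimates, conf_level = 0.95) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "pif_estimate")))
  lab <- unique(vapply(estimates, function(e) paste(e$scenario, e$outcome),
                       character(1)))
  if (length(lab) != 1) {
    stop("pool_pif_estimates: estimates mix scenarios/outcomes", call. = FALSE)
  }
  g <- function(f, sef) rubin_pool(
    vapply(estimates, `[[`, numeric(1), f),
    vapply(estimates, function(e) e[[sef]]^2, numeric(1)),
    conf_level = conf_level)
  list(scenario = estimates[[1]]$scenario, outcome = estimates[[1]]$outcome,
       pif = g("pif", "se_pif"), rd = g("rd", "se_rd"))
}
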