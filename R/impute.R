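#' Configuration for random-forest chained-equations imputation
#'
#' Defaults follow the published analysis settings: `m = 10` imputations,
#' `n_iterations = 500` chained-equation cycles and `n_trees = 100` per
#' conditional forest. Desk-scale runs (tests, the shipped example pipeline)
#' use reduced cycles via these arguments; the full settings remain one call
#' away.
#'
#' @param m number of imputations (>= 1).
#' @param n_iterations chained-equation cycles (>= 1).
#' @param n_trees trees per conditional forest (>= 1).
#' @param predictor_matrix optional 0/1 matrix (rows = imputed variables,
#'   columns = predictors, zero diagonal); `NULL` means every eligible
#'   variable predicts every other, including design variables.
#' @param donor_rule `"leaf"`: for each missing cell pick one tree uniformly,
#'   locate the cell's terminal leaf, and draw one observed donor uniformly
#'   from that leaf. Preserves distributional spread, unlike mean prediction.
#' @param mtry candidate predictors per split. The default `NULL` is
#'   adaptive: all predictors when the observed pool is small (< 2000
#'   records, e.g. a measured validation subsample), where the donor scheme
#'   relies on every single tree conditioning well, and the ranger default
#'   (square root) when training records are plentiful and leaves are tight
#'   regardless.
#' @param min_node_size ranger terminal-node size for the conditional forests.
#' @param seed master seed; per-imputation seeds are derived from it so that
#'   completed dataset j is invariant to `m`.
#' @return an `imputation_config`.
#' @export
imputation_config <- function(m = 10L, n_iterations = 500L, n_trees = 100L,
                              predictor_matrix = NULL, donor_rule = "leaf",
                              mtry = NULL, min_node_size = 5L, seed = 1L) {
  if (!is.numeric(m) || m < 1) stop_config("m must be >= 1")
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop_config("n_iterations must be >= 1")
  }
  if (!is.numeric(n_trees) || n_trees < 1) stop_config("n_trees must be >= 1")
  donor_rule <- match.arg(donor_rule, "leaf")
  if (!is.null(predictor_matrix)) {
    if (any(diag(as.matrix(predictor_matrix)) != 0)) {
      stop_config("predictor_matrix must have a zero diagonal")
    }
  }
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 n_trees = as.integer(n_trees),
                 predictor_matrix = predictor_matrix,
                 donor_rule = donor_rule, mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' @export
print.imputation_config <- function(x, ...) {
  cat(sprintf("<imputation_config> m=%d, iterations=%d, trees=%d, donor=%s\n",
              x$m, x$n_iterations, x$n_trees, x$donor_rule))
  invisible(x)
}

## columns never imputed and never used as predictors
impute_excluded <- function(data) {
  c("id", "cluster", "exam",
    grep("_true$", names(data), value = TRUE), # generator truth: not data
    "bmi_measured", "bmi_self")                # derived, recomputed instead
}

## default predictor set: everything observed-ish except exclusions and self
impute_predictors <- function(data, var) {
  setdiff(names(data), c(impute_excluded(data), var))
}

#' Correct measurement error and fill gaps by random-forest MICE
#'
#' Chained-equations multiple imputation with random-forest conditional
#' models. Measured height, weight and waist circumference - observed only on
#' the examination arm - are imputed for everyone else from the self-reported
#' layer, covariates, outcomes and design variables; covariate missing values
#' are imputed in the same chained process. Measured BMI is then derived from
#' imputed measured height and weight, never imputed directly.
#'
#' For each variable in turn (visited in order of increasing missingness), a
#' forest is grown on the currently observed records; each missing cell picks
#' one tree at random, drops to its terminal leaf, and copies the value of one
#' observed donor drawn uniformly from that leaf. Missing cells are
#' cold-started from uniform draws of observed values. Chain means and SDs of
#' the freshly imputed values are recorded per variable, iteration and
#' imputation for convergence monitoring ([chain_converged()]).
#'
#' @param data a `survey_dataset`.
#' @param config an [imputation_config()].
#' @return a `completed_datasets` object: `datasets` (list of `m` completed
#'   copies, observed cells preserved bit-exactly), `trace` (a `chain_trace`
#'   data frame), `variables`, `config`.
#' @export
rf_mice_impute <- function(data, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  excl <- impute_excluded(data)
  candidates <- setdiff(names(data), excl)
  vars <- candidates[vapply(data[candidates], anyNA, logical(1))]
  all_na <- vars[vapply(data[vars], function(x) all(is.na(x)), logical(1))]
  if (length(all_na)) {
    stop("unimputable variable (no observed values): ",
         paste(all_na, collapse = ", "), call. = FALSE)
  }
  derive_bmi <- function(d) {
    d$bmi_measured <- d$weight_measured / (d$height_measured / 100)^2
    d
  }
  if (!length(vars)) {
    out <- list(datasets = replicate(config$m, derive_bmi(data),
                                     simplify = FALSE),
                trace = empty_trace(), variables = character(0),
                config = config)
    class(out) <- "completed_datasets"
    return(out)
  }
  # visit order: increasing missingness fraction
  frac <- vapply(data[vars], function(x) mean(is.na(x)), numeric(1))
  vars <- vars[order(frac, seq_along(vars))]
  miss_idx <- lapply(data[vars], function(x) which(is.na(x)))
  names(miss_idx) <- vars

  pm <- config$predictor_matrix
  preds_of <- function(v) {
    if (is.null(pm)) return(impute_predictors(data, v))
    colnames(pm)[pm[v, ] == 1]
  }

  trace <- vector("list", config$m)
  datasets <- vector("list", config$m)
  for (j in seq_len(config$m)) {
    jseed <- derive_seed(config$seed, 404L, j)
    datasets[[j]] <- with_seed(jseed, {
      d <- data
      # cold start: uniform draws from observed values
      for (v in vars) {
        obs <- d[[v]][!is.na(d[[v]])]
        d[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                        replace = TRUE)
      }
      rows <- vector("list", config$n_iterations * length(vars))
      r <- 0L
      for (it in seq_len(config$n_iterations)) {
        for (v in vars) {
          mi <- miss_idx[[v]]
          oi <- setdiff(seq_len(nrow(d)), mi)
          xv <- preds_of(v)
          mtry_v <- config$mtry
          if (is.null(mtry_v) && length(oi) < 2000L) mtry_v <- length(xv)
          fit <- ranger::ranger(
            x = d[oi, xv, drop = FALSE], y = d[[v]][oi],
            num.trees = config$n_trees, num.threads = 1L,
            mtry = mtry_v, min.node.size = config$min_node_size,
            respect.unordered.factors = "order",
            seed = derive_seed(jseed, it, match(v, vars)))
          tn_obs <- stats::predict(fit, data = d[oi, xv, drop = FALSE],
                                   type = "terminalNodes",
                                   num.threads = 1L)$predictions
          tn_mis <- stats::predict(fit, data = d[mi, xv, drop = FALSE],
                                   type = "terminalNodes",
                                   num.threads = 1L)$predictions
          pick_tree <- sample.int(config$n_trees, length(mi), replace = TRUE)
          donor_row <- integer(length(mi))
          for (t in unique(pick_tree)) {
            leaf_members <- split(oi, tn_obs[, t])
            sel <- which(pick_tree == t)
            leaves <- as.character(tn_mis[sel, t])
            donor_row[sel] <- vapply(leaves, function(lf) {
              mem <- leaf_members[[lf]]
              mem[sample.int(length(mem), 1L)]
            }, integer(1), USE.NAMES = FALSE)
          }
          d[[v]][mi] <- d[[v]][donor_row]
          z <- as.numeric(d[[v]][mi])
          r <- r + 1L
          rows[[r]] <- data.frame(variable = v, imputation = j,
                                  iteration = it, mean = mean(z),
                                  sd = sd(z))
        }
      }
      attr(d, "chain_rows") <- do.call(rbind, rows)
      d
    })
    trace[[j]] <- attr(datasets[[j]], "chain_rows")
    attr(datasets[[j]], "chain_rows") <- NULL
    datasets[[j]] <- derive_bmi(datasets[[j]])
  }
  tr <- do.call(rbind, trace)
  rownames(tr) <- NULL
  class(tr) <- c("chain_trace", "data.frame")
  out <- list(datasets = datasets, trace = tr, variables = vars,
              config = config)
  class(out) <- "completed_datasets"
  out
}

empty_trace <- function() {
  tr <- data.frame(variable = character(0), imputation = integer(0),
                   iteration = integer(0), mean = numeric(0), sd = numeric(0))
  class(tr) <- c("chain_trace", "data.frame")
  tr
}

#' @export
print.completed_datasets <- function(x, ...) {
  cat(sprintf("<completed_datasets> m=%d, %d records, imputed: %s\n",
              length(x$datasets), nrow(x$datasets[[1]]),
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "(nothing)"))
  invisible(x)
}

#' Numeric convergence check for imputation chains
#'
#' The published approach monitors convergence by plotting the chain mean and
#' SD of the freshly imputed values against the iteration number; automated
#' testing needs a numeric rule. A chain counts as converged when the absolute
#' OLS slope of its mean over the final `window` iterations is below half the
#' SD of the detrended chain means (a flat-chain criterion: no monotone drift
#' large relative to the chain's own wobble; detrending is what lets a pure
#' drift, whose raw SD is proportional to its slope, be flagged). A chain with
#' zero wobble converges only with a zero slope.
#'
#' @param trace a `chain_trace` from [rf_mice_impute()].
#' @param window number of final iterations to assess (>= 2, at most the
#'   number of iterations in the trace).
#' @return list with `converged` (logical, all chains) and `summary` (slope,
#'   SD and verdict per variable x imputation).
#' @export
chain_converged <- function(trace, window = 10L) {
  stopifnot(inherits(trace, "data.frame"))
  if (!nrow(trace)) stop("empty chain trace", call. = FALSE)
  n_it <- max(trace$iteration)
  if (window > n_it) stop("window exceeds the number of iterations",
                          call. = FALSE)
  if (window < 2) stop("window must be at least 2", call. = FALSE)
  keep <- trace$iteration > n_it - window
  parts <- split(trace[keep, ], list(trace$variable[keep],
                                     trace$imputation[keep]), drop = TRUE)
  summ <- do.call(rbind, lapply(parts, function(p) {
    it <- p$iteration - mean(p$iteration)
    slope <- if (sum(it^2) > 0) sum(it * p$mean) / sum(it^2) else 0
    s <- sd(p$mean - slope * it) # wobble around the fitted trend
    data.frame(variable = p$variable[1], imputation = p$imputation[1],
               slope = slope, sd_means = s,
               converged = if (s > 1e-12) abs(slope) < 0.5 * s else
                 abs(slope) < 1e-12)
  }))
  rownames(summ) <- NULL
  list(converged = all(summ$converged), summary = summ)
}

#' Plot imputation chains
#'
#' @param x a `chain_trace`.
#' @param what `"mean"` or `"sd"`.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.chain_trace <- function(x, what = c("mean", "sd"), ...) {
  what <- match.arg(what)
  vars <- unique(x$variable)
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    p <- x[x$variable == v, ]
    m <- tapply(p[[what]], list(p$iteration, p$imputation), identity)
    graphics::matplot(as.numeric(rownames(m)), m, type = "l", lty = 1,
                      xlab = "iteration", ylab = what, main = v, ...)
  }
  invisible(x)
}
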