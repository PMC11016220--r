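#' @importFrom stats plogis qlogis rnorm rbinom runif sd var quantile
#'   model.matrix model.frame terms delete.response glm glm.fit binomial
#'   quasibinomial coef vcov as.formula reformulate lm qt qnorm pnorm
#'   complete.cases approx setNames na.omit
#' @importFrom utils write.csv read.csv modifyList head
NULL

expit <- function(x) plogis(x)

#' Derive a child RNG seed from a master seed
#'
#' Deterministic counter-based seed splitting: the master seed and any number
#' of integer keys (imputation index, bootstrap replicate, stage id) are folded
#' into a single seed below 2^31, so that seed streams for different stages and
#' replicates are independent of how many of them are consumed elsewhere.
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the sub-stream.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.double(abs(seed)) %% m
  for (k in c(1, as.double(c(...)))) {
    # affine mix; all intermediates < 2^53 so exact in doubles
    x <- (x * 48271 + (k %% m) * 69621 + 12345) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Weighted quantiles and interquartile range
#'
#' Quantiles of a survey-weighted empirical distribution, by linear
#' interpolation of the midpoint cumulative-weight function (reduces to the
#' usual type-5 sample quantile at equal weights).
#'
#' @param x numeric values.
#' @param w positive weights (recycled if scalar).
#' @param probs probabilities.
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs = c(.25, .5, .75)) {
  stopifnot(length(x) > 0, all(w > 0), length(w) %in% c(1L, length(x)))
  if (length(w) == 1L) w <- rep(w, length(x))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  p <- (cw - 0.5 * w) / sum(w)
  approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' @rdname weighted_quantile
#' @export
weighted_iqr <- function(x, w = rep(1, length(x))) {
  q <- weighted_quantile(x, w, c(.25, .75))
  q[2] - q[1]
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

#' Survey-weighted area under the ROC curve
#'
#' Weighted concordance (Mann-Whitney) statistic: the probability, under the
#' weighted distribution, that a randomly chosen case scores above a randomly
#' chosen non-case, counting ties as 1/2.
#'
#' @param score numeric risk scores.
#' @param y 0/1 outcome.
#' @param w positive weights.
#' @return AUC in `[0, 1]`.
#' @export
weighted_auc <- function(score, y, w = rep(1, length(y))) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (!any(y == 1) || !any(y == 0)) {
    stop("weighted_auc: both outcome classes must be present", call. = FALSE)
  }
  o <- order(score)
  s <- score[o]; y <- y[o]; w <- w[o]
  wneg <- w * (y == 0)
  # group by tied score values
  grp <- cumsum(c(1L, diff(s) != 0))
  cum_neg_before <- cumsum(wneg) - unsplit(lapply(split(wneg, grp), cumsum), grp)
  neg_in_grp <- unsplit(lapply(split(wneg, grp), function(z) rep(sum(z), length(z))), grp)
  num <- sum((w * (y == 1)) * (cum_neg_before + 0.5 * neg_in_grp))
  num / (sum(w[y == 1]) * sum(wneg))
}

## FNV-1a hash over a serialized object; used for provenance manifests.
config_hash <- function(x) {
  r <- serialize(x, NULL, version = 2)[-(1:14)] # skip header (R version bytes)
  h <- 2166136261
  for (byte in as.integer(r)) {
    h <- bitwXor(as.integer(h %% 2^31), byte)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_config <- function(fmt, ...) {
  stop(sprintf(paste0("configuration error: ", fmt), ...), call. = FALSE)
}
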