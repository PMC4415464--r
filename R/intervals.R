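#' Exact conditional model for the pooled count
#'
#' Builds the conditional probability mass function of the pooled count
#' `Z1 = X[M] + Y` given the selection event (futility cut-off and ranking
#' against the observed runner-up), as a function of the selected
#' classifier's true sensitivity `s`:
#' `f(z1 | s) = h(z1) s^z1 (1-s)^(n1M + n2 - z1) / C(s)` where
#' `h(z1)` sums `choose(n2, y) * choose(n1M, z1 - y)` over the restricted
#' support of `y` at that `z1`, and `C(s)` normalizes over the achievable
#' `z1`.  This is the distribution inverted to obtain exact conditional
#' confidence intervals and the median-unbiased estimate.
#'
#' @param object a fitted [twostage()] object, or `NULL` if the raw
#'   quantities are supplied directly.
#' @param n1M,n2,min_x alternative direct specification: the selected
#'   classifier's stage-1 size, the stage-2 size and the smallest admissible
#'   stage-1 count implied by the conditioning (see [restricted_support()]).
#' @return an object of class `"ss_model"`: a list with `support` (achievable
#'   z1), `logh` (log weights), `N` (total size `n1M + n2`), and functions
#'   `pmf(s)`, `p_ge(z, s)` = P(Z1 >= z | s) and `p_le(z, s)` = P(Z1 <= z | s).
#' @export
ss_model <- function(object = NULL, n1M = NULL, n2 = NULL, min_x = NULL) {
  if (!is.null(object)) {
    if (inherits(object, "twostage_stopped")) {
      stop("the trial stopped at the interim analysis; no conditional model")
    }
    stopifnot(inherits(object, "twostage"))
    n1M <- object$design$n1[object$selection$M]
    n2 <- object$design$n2
    min_x <- object$support$min_x
  }
  stopifnot(min_x <= n1M)
  N <- n1M + n2
  z <- min_x:N
  logh <- vapply(z, function(z1) {
    lo <- max(0L, z1 - n1M)
    hi <- min(z1 - min_x, n2)
    yy <- lo:hi
    lw <- lchoose(n2, yy) + lchoose(n1M, z1 - yy)
    m <- max(lw)
    m + log(sum(exp(lw - m)))
  }, numeric(1))
  pmf <- function(s) {
    s <- min(max(s, 1e-12), 1 - 1e-12)
    lf <- logh + z * log(s) + (N - z) * log1p(-s)
    lf <- lf - max(lf)
    f <- exp(lf)
    f / sum(f)
  }
  structure(
    list(support = z, logh = logh, N = N, n1M = n1M, n2 = n2, min_x = min_x,
         pmf = pmf,
         p_ge = function(zobs, s) sum(pmf(s)[z >= zobs]),
         p_le = function(zobs, s) sum(pmf(s)[z <= zobs])),
    class = "ss_model")
}

#' @export
print.ss_model <- function(x, ...) {
  cat("Exact conditional model for the pooled count Z1\n")
  cat(sprintf("  n1M = %d, n2 = %d, minimal admissible stage-1 count = %d\n",
              x$n1M, x$n2, x$min_x))
  cat(sprintf("  support of Z1: {%d, ..., %d}\n", min(x$support), x$N))
  invisible(x)
}

interval_result <- function(lower, upper, level, method, ...) {
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, ...),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("%.0f%% %s interval: (%.4f, %.4f)\n",
              100 * x$level, x$method, x$lower, x$upper))
  invisible(x)
}

# Solve P(Z1 >= zobs | s) = target (increasing in s) for the lower bound,
# and P(Z1 <= zobs | s) = target (decreasing in s) for the upper bound.
ss_root_lower <- function(model, zobs, target) {
  if (zobs <= min(model$support)) return(0)
  f <- function(s) model$p_ge(zobs, s) - target
  if (f(1e-10) >= 0) return(0)
  stats::uniroot(f, c(1e-10, 1 - 1e-10), tol = 1e-9)$root
}

ss_root_upper <- function(model, zobs, target) {
  if (zobs >= max(model$support)) return(1)
  f <- function(s) model$p_le(zobs, s) - target
  if (f(1 - 1e-10) >= 0) return(1)
  stats::uniroot(f, c(1e-10, 1 - 1e-10), tol = 1e-9)$root
}

#' Exact conditional (Sill-Sampson type) confidence interval
#'
#' Inverts the conditional distribution of the pooled count given the
#' selection event ([ss_model()]) to obtain an exact two-sided interval for
#' the selected classifier's sensitivity.  The lower bound solves
#' `P(Z1 >= z_obs | s) = alpha1` and the upper bound
#' `P(Z1 <= z_obs | s) = alpha2`, with `alpha1 + alpha2 = alpha` (equal split
#' by default).  The bound is clamped to 0 (resp. 1) when `z_obs` sits at the
#' support minimum (resp. maximum) and the tail equation has no root.
#'
#' @param object a fitted [twostage()] object (continued).
#' @param alpha two-sided non-coverage level in (0,1).
#' @param split optional length-2 vector `(alpha1, alpha2)` summing to
#'   `alpha`.
#' @param model optionally a precomputed [ss_model()]; `z_obs` is then taken
#'   from `object` unless `zobs` is given.
#' @param zobs optional observed pooled count (with `model`).
#' @return an `"interval_result"` with `lower`, `upper`, `level`, `method`
#'   and `alpha_split`.
#' @export
ss_ci <- function(object = NULL, alpha = 0.05, split = NULL, model = NULL,
                  zobs = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(split)) split <- c(alpha / 2, alpha / 2)
  if (abs(sum(split) - alpha) > 1e-12 || any(split <= 0)) {
    stop("`split` must be two positive values summing to `alpha`")
  }
  if (is.null(model)) model <- ss_model(object)
  if (is.null(zobs)) {
    zobs <- object$x[object$selection$M] + object$y
  }
  interval_result(
    lower = ss_root_lower(model, zobs, split[1]),
    upper = ss_root_upper(model, zobs, split[2]),
    level = 1 - alpha, method = "Sill-Sampson exact conditional",
    alpha_split = split)
}

#' Optimised-split exact conditional confidence interval
#'
#' As [ss_ci()], but chooses the split `(alpha1, alpha - alpha1)` to minimise
#' the interval length, by golden-section search over `alpha1`.  The result
#' is never wider than the equal-split interval (up to solver tolerance), at
#' a substantially greater computational cost.
#'
#' @inheritParams ss_ci
#' @export
ss_ci_optimised <- function(object = NULL, alpha = 0.05, model = NULL,
                            zobs = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(model)) model <- ss_model(object)
  if (is.null(zobs)) zobs <- object$x[object$selection$M] + object$y
  eps <- 1e-6 * alpha
  width <- function(a1) {
    ss_root_upper(model, zobs, alpha - a1) - ss_root_lower(model, zobs, a1)
  }
  opt <- stats::optimize(width, c(eps, alpha - eps), tol = 1e-4 * alpha)
  a1 <- opt$minimum
  # never return worse than the equal split
  if (width(alpha / 2) < opt$objective) a1 <- alpha / 2
  interval_result(
    lower = ss_root_lower(model, zobs, a1),
    upper = ss_root_upper(model, zobs, alpha - a1),
    level = 1 - alpha, method = "Sill-Sampson exact conditional (optimised)",
    alpha_split = c(a1, alpha - a1))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The standard exact interval obtained by inverting the binomial tail
#' probabilities (equivalently, from beta quantiles).  Used around the pooled
#' MLE and the stage-specific estimates; it ignores the selection event.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param alpha two-sided non-coverage level.
#' @return an `"interval_result"`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n,
            alpha > 0, alpha < 1)
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  interval_result(lower = lower, upper = upper, level = 1 - alpha,
                  method = "Clopper-Pearson exact", alpha_split = rep(alpha / 2, 2))
}

#' Selection-aware nonparametric bootstrap confidence interval
#'
#' Percentile bootstrap that mirrors the conditioning event.  Each replicate
#' resamples the selected classifier's stage-1 responses (a binomial draw
#' with success fraction `x[M]/n1[M]`, distributionally identical to
#' resampling the individual binary responses with replacement) and is
#' accepted only if the resampled count passes the futility cut-off and
#' still beats the ORIGINAL observed runner-up under the ranking rule; the
#' stage-2 responses are then resampled likewise and the chosen estimator is
#' recomputed from the replicate counts and the original runner-up value.
#'
#' @param object a fitted [twostage()] object (continued).
#' @param estimator `"umvcue"`, `"mle"`, `"stage1"` or `"stage2"`.
#' @param B number of accepted bootstrap replicates.
#' @param alpha two-sided non-coverage level.
#' @param seed optional integer seed.
#' @param max_tries cap on total resampling attempts before giving up.
#' @return an `"interval_result"` with `replicates = B` and the realized
#'   `acceptance_rate`.
#' @export
bootstrap_ci <- function(object, estimator = c("umvcue", "mle", "stage1",
                                               "stage2"),
                         B = 10000, alpha = 0.05, seed = NULL,
                         max_tries = 1000 * B) {
  estimator <- match.arg(estimator)
  if (inherits(object, "twostage_stopped")) {
    stop("the trial stopped at the interim analysis; nothing to bootstrap")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- object$design
  M <- object$selection$M
  n1M <- d$n1[M]
  n2 <- d$n2
  b <- object$support$min_x     # futility + ranking bound vs original runner-up
  p1 <- object$x[M] / n1M
  est <- numeric(0)
  tries <- 0
  while (length(est) < B && tries < max_tries) {
    todo <- B - length(est)
    batch <- max(todo * 2L, 100L)
    tries <- tries + batch
    xb <- stats::rbinom(batch, n1M, p1)
    xb <- xb[xb >= b]
    if (length(xb) == 0) next
    xb <- xb[seq_len(min(length(xb), todo))]
    yb <- stats::rbinom(length(xb), n2, object$y / n2)
    vals <- switch(
      estimator,
      mle = (xb + yb) / (n1M + n2),
      stage1 = xb / n1M,
      stage2 = yb / n2,
      umvcue = mapply(function(xx, yy) {
        z1 <- xx + yy
        lo <- max(0L, z1 - n1M)
        hi <- min(z1 - b, n2)
        umvcue_from_support(lo:hi, z1, n1M, n2)
      }, xb, yb))
    est <- c(est, vals)
  }
  if (length(est) == 0) {
    stop("bootstrap acceptance rate was zero after ", max_tries, " attempts")
  }
  acc <- length(est) / tries
  q <- stats::quantile(est, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  interval_result(lower = q[1], upper = q[2], level = 1 - alpha,
                  method = sprintf("nonparametric bootstrap (%s)", estimator),
                  replicates = length(est), acceptance_rate = acc,
                  seed = seed)
}

#' Confidence intervals for a fitted two-stage trial
#'
#' @param object a fitted [twostage()] object.
#' @param parm ignored (the single estimand is the selected classifier's
#'   sensitivity).
#' @param level confidence level.
#' @param method `"sill-sampson"` (exact conditional, the default),
#'   `"ss-optimised"`, `"clopper-pearson"` (on the pooled MLE) or
#'   `"bootstrap"`.
#' @param ... passed on to the underlying constructor (e.g. `estimator`,
#'   `B`, `seed` for the bootstrap; `split` for the exact conditional
#'   interval).
#' @return an `"interval_result"`.
#' @export
confint.twostage <- function(object, parm, level = 0.95,
                             method = c("sill-sampson", "ss-optimised",
                                        "clopper-pearson", "bootstrap"),
                             ...) {
  method <- match.arg(method)
  alpha <- 1 - level
  switch(method,
         "sill-sampson" = ss_ci(object, alpha = alpha, ...),
         "ss-optimised" = ss_ci_optimised(object, alpha = alpha, ...),
         "clopper-pearson" = {
           M <- object$selection$M
           clopper_pearson(object$x[M] + object$y,
                           object$design$n1[M] + object$design$n2, alpha)
         },
         "bootstrap" = bootstrap_ci(object, alpha = alpha, ...))
}

#' Approximate median-unbiased estimate
#'
#' Solves the two half-probability equations of the exact conditional model,
#' `P(Z1 >= z_obs | s) = 0.5` and `P(Z1 <= z_obs | s) = 0.5`, and returns the
#' midpoint of the two roots.  When a tail equation has no root in (0,1)
#' (observed count at a support boundary) the corresponding root is taken at
#' the boundary, with a warning.
#'
#' @param object a fitted [twostage()] object (continued).
#' @return the point estimate (numeric), with the two roots as attribute
#'   `"roots"`.
#' @export
median_unbiased <- function(object) {
  model <- ss_model(object)
  zobs <- object$x[object$selection$M] + object$y
  lo <- ss_root_lower(model, zobs, 0.5)
  hi <- ss_root_upper(model, zobs, 0.5)
  if (zobs <= min(model$support) || zobs >= max(model$support)) {
    warning("observed pooled count at the boundary of its support; ",
            "median-unbiased root taken at the boundary")
  }
  structure((lo + hi) / 2, roots = c(lo, hi))
}
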