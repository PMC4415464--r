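#' Generate correlated binary data
#'
#' Emrich-Piedmonte construction: each binary variable is obtained by
#' thresholding a latent standard normal, and the latent correlation of each
#' pair is solved numerically so that the induced binary correlation matches
#' the target.  The bivariate normal orthant probability is computed by
#' one-dimensional quadrature of `phi(x) * Phi((rho*x - b)/sqrt(1 - rho^2))`.
#'
#' @param n number of subjects (rows).
#' @param p vector of marginal success probabilities, in (0,1).
#' @param R target correlation matrix (symmetric, unit diagonal).  Each
#'   pairwise target must be feasible for its margins (Frechet bounds).
#' @return an `n x length(p)` 0/1 matrix, with the solved latent correlation
#'   matrix as attribute `"latent"`.
#' @examples
#' set.seed(1)
#' z <- rcorrbin(500, p = c(0.3, 0.6), R = matrix(c(1, .4, .4, 1), 2))
#' cor(z)
#' @export
rcorrbin <- function(n, p, R) {
  K <- length(p)
  stopifnot(all(p > 0), all(p < 1), is.matrix(R), nrow(R) == K,
            ncol(R) == K, isTRUE(all.equal(R, t(R), tolerance = 1e-8)),
            all(abs(diag(R) - 1) < 1e-12))
  q <- stats::qnorm(1 - p)   # threshold: latent > q  =>  success
  sdp <- sqrt(p * (1 - p))
  L <- diag(K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    r <- R[i, j]
    lo_r <- (max(0, p[i] + p[j] - 1) - p[i] * p[j]) / (sdp[i] * sdp[j])
    hi_r <- (min(p[i], p[j]) - p[i] * p[j]) / (sdp[i] * sdp[j])
    if (r < lo_r - 1e-9 || r > hi_r + 1e-9) {
      stop(sprintf(
        "target correlation %.3f for pair (%d, %d) is infeasible for margins (%.3f, %.3f)",
        r, i, j, p[i], p[j]))
    }
    L[i, j] <- L[j, i] <- solve_latent_rho(r, p[i], p[j], q[i], q[j])
  }
  ev <- eigen(L, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    # ridge to the nearest usable positive-definite latent matrix
    vals <- pmax(ev$values, 1e-8)
    L2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    L <- stats::cov2cor(L2)
    ev <- eigen(L, symmetric = TRUE)
  }
  Zl <- matrix(stats::rnorm(n * K), n, K) %*%
    (ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors))
  out <- (Zl > matrix(q, n, K, byrow = TRUE)) + 0L
  attr(out, "latent") <- L
  out
}

# P(X1 > a, X2 > b) for standard bivariate normal with correlation rho.
bvn_upper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) {
    return(stats::pnorm(a, lower.tail = FALSE) *
             stats::pnorm(b, lower.tail = FALSE))
  }
  if (rho > 1 - 1e-9) {
    return(stats::pnorm(max(a, b), lower.tail = FALSE))
  }
  if (rho < -1 + 1e-9) {
    return(max(0, stats::pnorm(a, lower.tail = FALSE) -
                 stats::pnorm(-b)))
  }
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((rho * x - b) / s)
  }, lower = a, upper = Inf, rel.tol = 1e-10)$value
}

# Solve for the latent normal correlation inducing binary correlation r.
solve_latent_rho <- function(r, pi_, pj, qi, qj) {
  target <- pi_ * pj + r * sqrt(pi_ * (1 - pi_) * pj * (1 - pj))
  f <- function(rho) bvn_upper(qi, qj, rho) - target
  if (abs(f(0)) < 1e-12) return(0)
  stats::uniroot(f, c(-1 + 1e-8, 1 - 1e-8), tol = 1e-6)$root
}

#' Summarise a correlation matrix
#'
#' Reports the mean absolute pairwise correlation (over the strict upper
#' triangle) and the maximum off-diagonal entry with the labels of the pair
#' attaining it.
#'
#' @param R square symmetric correlation matrix, optionally with
#'   dimnames.
#' @return a list with `mean_abs`, `max` and `max_pair` (character length 2).
#' @export
correlation_summary <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("`R` must be a square matrix")
  }
  ut <- upper.tri(R)
  if (!any(ut)) return(list(mean_abs = 0, max = NA_real_, max_pair = NULL))
  mean_abs <- mean(abs(R[ut]))
  idx <- which(ut & R == max(R[ut]), arr.ind = TRUE)[1, ]
  labs <- if (is.null(rownames(R))) as.character(idx) else
    rownames(R)[idx]
  list(mean_abs = mean_abs, max = max(R[ut]), max_pair = labs)
}

#' Stage-1 response correlations from the family-history questionnaire study
#'
#' The observed pairwise correlation matrix (pairwise-complete responses)
#' among the 11 retained items of the motivating family-history
#' questionnaire validation study, used to drive the correlated-binary
#' robustness simulations.  Shipped as a plain-text table under
#' `inst/extdata/`.
#'
#' @return an 11 x 11 named correlation matrix.
#' @export
fhq_correlations <- function() {
  path <- system.file("extdata", "fhq_stage1_correlations.csv",
                      package = "twostageval", mustWork = TRUE)
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}
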