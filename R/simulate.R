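#' Simulate a single two-stage trial
#'
#' Draws independent stage-1 counts `X[i] ~ Bin(n1[i], S[i])`, applies the
#' design's futility and ranking rules, and — when at least one classifier
#' survives — draws the selected classifier's stage-2 count
#' `Y ~ Bin(n2, S[M])`.
#'
#' @param design a [two_stage_design()].
#' @param S vector of true sensitivities (length K).
#' @return a fitted [twostage()] object (class `"twostage_stopped"` when the
#'   trial stops early).
#' @export
simulate_trial <- function(design, S) {
  stopifnot(length(S) == design$K)
  x <- stats::rbinom(design$K, design$n1, S)
  sel <- select_classifier(x, design)
  y <- if (sel$continued) stats::rbinom(1, design$n2, S[sel$M]) else NULL
  twostage(x = x, y = y, design = design)
}

#' Simulate many trials from a two-stage design
#'
#' `simulate()` method: returns a data frame of simulated trial outcomes
#' (one row per replicate) rather than fitted objects, for use by the study
#' drivers.
#'
#' @param object a [two_stage_design()].
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param S vector of true sensitivities (length K).
#' @param ... unused.
#' @return data frame with columns `continued`, `M`, `xM`, `y`, `z1`,
#'   `runner_up`, `z2`, `min_x` (smallest admissible stage-1 count under the
#'   conditioning event) and `sM` (the selected classifier's true
#'   sensitivity; `NA` when stopped).
#' @export
simulate.two_stage_design <- function(object, nsim = 1, seed = NULL, S, ...) {
  if (!is.null(seed)) set.seed(seed)
  sim_trials(object, S, nsim)
}

# Precompute, for each ordered pair (i, j) and each runner-up count z2, the
# smallest stage-1 count of i consistent with i being selected over j.
min_count_tables <- function(design) {
  K <- design$K
  tab <- vector("list", K)
  for (i in seq_len(K)) {
    tab[[i]] <- vector("list", K)
    for (j in seq_len(K)) {
      if (i == j) next
      tab[[i]][[j]] <- vapply(0:design$n1[j], function(z2) {
        min_selected_count(design, i, j, z2)
      }, integer(1))
    }
  }
  tab
}

# Vectorized trial simulator used by all study drivers.
sim_trials <- function(design, S, nsim) {
  stopifnot(length(S) == design$K)
  K <- design$K
  n1 <- design$n1
  cc <- ceiling(design$c)
  x <- matrix(stats::rbinom(K * nsim, rep(n1, nsim), rep(S, nsim)),
              nrow = K)
  # per-classifier score lookup over the achievable grid
  score_grid <- lapply(seq_len(K), function(i) {
    round(vapply(0:n1[i], function(v) rule_score(design$ranking, v, i),
                 numeric(1)), 12)
  })
  sc <- matrix(-Inf, nrow = K, ncol = nsim)
  for (i in seq_len(K)) {
    pass <- x[i, ] >= cc[i]
    sc[i, pass] <- score_grid[[i]][x[i, pass] + 1L]
  }
  continued <- colSums(sc > -Inf) > 0
  M <- rep(NA_integer_, nsim)
  runner <- rep(NA_integer_, nsim)
  if (K == 1L) {
    M[continued] <- 1L
  } else {
    best <- max.col(t(sc), ties.method = "first")
    M[continued] <- best[continued]
    sc2 <- sc
    sc2[cbind(best, seq_len(nsim))] <- -Inf
    second <- max.col(t(sc2), ties.method = "first")
    has2 <- continued & sc2[cbind(second, seq_len(nsim))] > -Inf
    runner[has2] <- second[has2]
  }
  xM <- rep(NA_integer_, nsim)
  z2 <- rep(NA_integer_, nsim)
  xM[continued] <- x[cbind(M[continued], which(continued))]
  hasr <- !is.na(runner)
  z2[hasr] <- x[cbind(runner[hasr], which(hasr))]
  y <- rep(NA_integer_, nsim)
  ncont <- sum(continued)
  if (ncont > 0) {
    y[continued] <- stats::rbinom(ncont, design$n2, S[M[continued]])
  }
  # smallest admissible stage-1 count under the conditioning event
  min_x <- rep(NA_integer_, nsim)
  min_x[continued] <- cc[M[continued]]
  if (any(hasr)) {
    tab <- min_count_tables(design)
    idx <- which(hasr)
    key <- paste(M[idx], runner[idx], z2[idx])
    uk <- !duplicated(key)
    bu <- vapply(idx[uk], function(t) {
      tab[[M[t]]][[runner[t]]][z2[t] + 1L]
    }, integer(1))
    min_x[idx] <- bu[match(key, key[uk])]
  }
  data.frame(
    continued = continued, M = M, xM = xM, y = y, z1 = xM + y,
    runner_up = runner, z2 = z2, min_x = min_x,
    sM = ifelse(continued, S[ifelse(is.na(M), 1L, M)], NA_real_))
}

# UMVCUE for many trials at once, de-duplicated over (M, z1, min_x).
umvcue_many <- function(design, M, z1, min_x) {
  key <- paste(M, z1, min_x)
  uk <- !duplicated(key)
  vals <- vapply(which(uk), function(i) {
    n1M <- design$n1[M[i]]
    lo <- max(0L, z1[i] - n1M)
    hi <- min(z1[i] - min_x[i], design$n2)
    umvcue_from_support(lo:hi, z1[i], n1M, design$n2)
  }, numeric(1))
  vals[match(key, key[uk])]
}

#' Bias and mean squared error study of the point estimators
#'
#' Simulates the design `nsim` times and summarises, over the continuing
#' replicates, the conditional mean bias and MSE of the pooled MLE, the
#' stage-2-only estimate and the UMVCUE about the selected classifier's true
#' sensitivity.  Also reports `P(continue)` (with its closed-form value
#' `1 - prod_i P(Bin(n1i, Si) < ceiling(ci))`) and `P(best)`, the
#' probability that a truly (joint-)best classifier is the one selected,
#' conditional on continuing.
#'
#' @param design a [two_stage_design()].
#' @param S vector of true sensitivities.
#' @param nsim number of simulated trials (total, including stopped ones).
#' @param seed optional integer seed.
#' @param scale multiplier applied to bias and MSE in the returned table
#'   (use 100 for tables reported "times 100"); standard errors are scaled
#'   the same way.
#' @return a list of class `"estimator_study"` with elements `table` (one
#'   row per estimator: bias, MSE, their Monte-Carlo standard errors),
#'   `p_continue`, `p_continue_exact`, `p_best`, `n_continued`, `nsim`.
#' @export
estimator_study <- function(design, S, nsim = 100000, seed = NULL,
                            scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  tr <- sim_trials(design, S, nsim)
  cont <- tr$continued
  n <- sum(cont)
  if (n == 0) stop("no simulated trial continued to stage 2")
  mle <- (tr$xM[cont] + tr$y[cont]) / (design$n1[tr$M[cont]] + design$n2)
  st2 <- tr$y[cont] / design$n2
  umv <- umvcue_many(design, tr$M[cont], tr$z1[cont], tr$min_x[cont])
  sM <- tr$sM[cont]
  summ <- function(est) {
    err <- est - sM
    c(bias = mean(err), bias_se = stats::sd(err) / sqrt(n),
      mse = mean(err^2), mse_se = stats::sd(err^2) / sqrt(n))
  }
  tab <- rbind(mle = summ(mle), stage2 = summ(st2), umvcue = summ(umv)) *
    scale
  p_exact <- 1 - prod(stats::pbinom(ceiling(design$c) - 1, design$n1, S))
  best <- S[tr$M[cont]] >= max(S) - 1e-12
  structure(
    list(table = tab, p_continue = mean(cont), p_continue_exact = p_exact,
         p_best = mean(best), n_continued = n, nsim = nsim, scale = scale),
    class = "estimator_study")
}

#' @export
print.estimator_study <- function(x, ...) {
  cat(sprintf("Estimator study: %d simulated trials, %d continued (P = %.3f;",
              x$nsim, x$n_continued, x$p_continue))
  cat(sprintf(" closed form %.3f)\n", x$p_continue_exact))
  cat(sprintf("P(best selected | continue) = %.3f\n", x$p_best))
  if (x$scale != 1) cat(sprintf("bias and MSE scaled by %g\n", x$scale))
  print(round(x$table, 4))
  invisible(x)
}

#' Coverage study of the confidence interval constructions
#'
#' Simulates continuing trials (replicates are drawn until `n_continuing`
#' continue to stage 2, since intervals exist only then) and reports, per
#' method, the empirical coverage of the selected classifier's true
#' sensitivity and the mean interval width.
#'
#' @param design a [two_stage_design()].
#' @param S vector of true sensitivities.
#' @param methods subset of `"sill-sampson"`, `"ss-optimised"`,
#'   `"clopper-pearson"`, `"boot-mle"`, `"boot-umvcue"`.
#' @param n_continuing number of continuing trials required.
#' @param alpha two-sided non-coverage level.
#' @param B accepted bootstrap replicates per trial (bootstrap methods).
#' @param seed optional integer seed.
#' @return a list of class `"coverage_study"`: `table` (coverage, its
#'   binomial SE, mean width, width SE per method), `n_continuing`, `alpha`,
#'   `B`.
#' @export
coverage_study <- function(design, S,
                           methods = c("sill-sampson", "clopper-pearson"),
                           n_continuing = 10000, alpha = 0.05, B = 10000,
                           seed = NULL) {
  ok <- c("sill-sampson", "ss-optimised", "clopper-pearson", "boot-mle",
          "boot-umvcue")
  stopifnot(all(methods %in% ok))
  if (!is.null(seed)) set.seed(seed)
  # draw in batches until enough continuing replicates
  p_exact <- 1 - prod(stats::pbinom(ceiling(design$c) - 1, design$n1, S))
  acc <- NULL
  while (is.null(acc) || nrow(acc) < n_continuing) {
    need <- n_continuing - if (is.null(acc)) 0 else nrow(acc)
    batch <- ceiling(need / max(p_exact, 0.01) * 1.1) + 100
    tr <- sim_trials(design, S, batch)
    acc <- rbind(acc, tr[tr$continued, , drop = FALSE])
  }
  acc <- acc[seq_len(n_continuing), ]
  res <- lapply(methods, function(m) {
    ci <- switch(
      m,
      "sill-sampson" = exact_ci_many(design, acc, alpha, optimised = FALSE),
      "ss-optimised" = exact_ci_many(design, acc, alpha, optimised = TRUE),
      "clopper-pearson" = {
        n <- design$n1[acc$M] + design$n2
        lo <- ifelse(acc$z1 == 0, 0, stats::qbeta(alpha / 2, acc$z1,
                                                  n - acc$z1 + 1))
        hi <- ifelse(acc$z1 == n, 1, stats::qbeta(1 - alpha / 2, acc$z1 + 1,
                                                  n - acc$z1))
        cbind(lo, hi)
      },
      "boot-mle" = boot_ci_many(design, acc, "mle", B, alpha),
      "boot-umvcue" = boot_ci_many(design, acc, "umvcue", B, alpha))
    cover <- ci[, 1] <= acc$sM & acc$sM <= ci[, 2]
    width <- ci[, 2] - ci[, 1]
    c(coverage = mean(cover),
      coverage_se = sqrt(mean(cover) * (1 - mean(cover)) / n_continuing),
      width = mean(width), width_se = stats::sd(width) / sqrt(n_continuing))
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- methods
  structure(list(table = tab, n_continuing = n_continuing, alpha = alpha,
                 B = B),
            class = "coverage_study")
}

#' @export
print.coverage_study <- function(x, ...) {
  cat(sprintf("Coverage study: %d continuing trials, nominal %.0f%%\n",
              x$n_continuing, 100 * (1 - x$alpha)))
  print(round(x$table, 4))
  invisible(x)
}

# Exact conditional intervals for many simulated trials, de-duplicated over
# the conditioning key (M, z1, min_x).
exact_ci_many <- function(design, acc, alpha, optimised = FALSE) {
  key <- paste(acc$M, acc$z1, acc$min_x)
  uk <- !duplicated(key)
  ci <- vapply(which(uk), function(i) {
    model <- ss_model(n1M = design$n1[acc$M[i]], n2 = design$n2,
                      min_x = acc$min_x[i])
    r <- if (optimised) {
      ss_ci_optimised(model = model, zobs = acc$z1[i], alpha = alpha)
    } else {
      ss_ci(model = model, zobs = acc$z1[i], alpha = alpha)
    }
    c(r$lower, r$upper)
  }, numeric(2))
  t(ci)[match(key, key[uk]), , drop = FALSE]
}

# Percentile bootstrap intervals for many simulated trials (no caching: each
# trial gets its own resampling noise).
boot_ci_many <- function(design, acc, estimator, B, alpha) {
  n2 <- design$n2
  out <- matrix(NA_real_, nrow = nrow(acc), ncol = 2)
  for (i in seq_len(nrow(acc))) {
    n1M <- design$n1[acc$M[i]]
    b <- acc$min_x[i]
    p1 <- acc$xM[i] / n1M
    p_acc <- 1 - stats::pbinom(b - 1, n1M, p1)
    draw <- max(ceiling(B / max(p_acc, 1e-3) * 1.1), B)
    xb <- stats::rbinom(draw, n1M, p1)
    xb <- xb[xb >= b]
    while (length(xb) < B) {
      xb <- c(xb, Filter(function(v) v >= b,
                         stats::rbinom(draw, n1M, p1)))
    }
    xb <- xb[seq_len(B)]
    yb <- stats::rbinom(B, n2, acc$y[i] / n2)
    vals <- if (estimator == "mle") {
      (xb + yb) / (n1M + n2)
    } else {
      zb <- xb + yb
      umvcue_many(design, rep(acc$M[i], B), zb, rep(b, B))
    }
    out[i, ] <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2),
                                names = FALSE, type = 7)
  }
  out
}
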