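#' One-sided test of the selected classifier's sensitivity
#'
#' Tests `H0: s_M <= s_star` against `H1: s_M > s_star` by inverting a
#' one-sided (1 - alpha) lower confidence bound: `H0` is rejected exactly
#' when the lower bound exceeds `s_star` (strict inequality; ties favour
#' `H0`).  The bound is either the exact conditional (Sill-Sampson type)
#' lower bound with the full `alpha` spent on the lower tail, or the
#' Clopper-Pearson lower bound around the pooled MLE, which ignores the
#' selection and can inflate the type-I error rate.
#'
#' @param object a fitted [twostage()] object (continued).
#' @param s_star null boundary sensitivity in (0,1).
#' @param alpha one-sided level.
#' @param method `"sill-sampson"` or `"clopper-pearson"`.
#' @return a list of class `"twostage_test"` with `reject`, `lower`,
#'   `s_star`, `alpha`, `method`.
#' @export
one_sided_test <- function(object, s_star, alpha = 0.05,
                           method = c("sill-sampson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(s_star > 0, s_star < 1, alpha > 0, alpha < 1)
  if (inherits(object, "twostage_stopped")) {
    stop("the trial stopped at the interim analysis; no test is performed")
  }
  M <- object$selection$M
  zobs <- object$x[M] + object$y
  lower <- switch(
    method,
    "sill-sampson" = ss_root_lower(ss_model(object), zobs, alpha),
    "clopper-pearson" = {
      n <- object$design$n1[M] + object$design$n2
      if (zobs == 0) 0 else stats::qbeta(alpha, zobs, n - zobs + 1)
    })
  structure(list(reject = lower > s_star, lower = lower, s_star = s_star,
                 alpha = alpha, method = method),
            class = "twostage_test")
}

#' @export
print.twostage_test <- function(x, ...) {
  cat(sprintf("One-sided test of H0: s_M <= %.3f (%s, alpha = %.3f)\n",
              x$s_star, x$method, x$alpha))
  cat(sprintf("  lower %.1f%% bound: %.4f  ->  %s\n", 100 * (1 - x$alpha),
              x$lower, if (x$reject) "reject H0" else "do not reject H0"))
  invisible(x)
}

#' Conditional and unconditional operating characteristics
#'
#' Monte-Carlo estimates of the error rates of the interval-backed one-sided
#' test over a grid of null boundaries `s_star`.  With `S0 = {s in S : s <=
#' s_star}`, the conditional type-I error is `P(reject | s_M in S0, trial
#' continues)` and the unconditional one is `P(reject, s_M in S0)` with no
#' conditioning on continuation (a stopped trial never rejects); powers are
#' defined analogously on the complement of `S0`.  A probability whose
#' conditioning event is empty in the simulation is reported as `NA`.
#'
#' The same simulated trials are reused across the grid, as when tracing an
#' operating-characteristic curve.
#'
#' @param design a [two_stage_design()].
#' @param S vector of true sensitivities (length K).
#' @param s_star numeric vector: grid of null boundaries.
#' @param alpha one-sided level.
#' @param method `"sill-sampson"` or `"clopper-pearson"`.
#' @param nsim number of simulated trials.
#' @param seed optional integer seed.
#' @return a data frame with one row per `s_star`: `cond_t1`, `uncond_t1`,
#'   `cond_power`, `uncond_power`, plus the continuation rate as attribute
#'   `"continue_rate"` and `nsim`.
#' @export
operating_characteristics <- function(design, S, s_star, alpha = 0.05,
                                      method = c("sill-sampson",
                                                 "clopper-pearson"),
                                      nsim = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(S) == design$K, all(S > 0), all(S < 1), nsim >= 1)
  if (!is.null(seed)) set.seed(seed)
  tr <- sim_trials(design, S, nsim)
  cont <- tr$continued
  lower <- rep(NA_real_, nsim)
  if (any(cont)) {
    zobs <- tr$z1[cont]
    b <- tr$min_x[cont]
    Mv <- tr$M[cont]
    key <- paste(Mv, zobs, b)
    uk <- !duplicated(key)
    lb <- vapply(which(uk), function(i) {
      switch(method,
             "sill-sampson" = ss_root_lower(
               ss_model(n1M = design$n1[Mv[i]], n2 = design$n2,
                        min_x = b[i]),
               zobs[i], alpha),
             "clopper-pearson" = {
               n <- design$n1[Mv[i]] + design$n2
               if (zobs[i] == 0) 0 else
                 stats::qbeta(alpha, zobs[i], n - zobs[i] + 1)
             })
    }, numeric(1))
    lower[cont] <- lb[match(key, key[uk])]
  }
  sM <- tr$sM
  res <- lapply(s_star, function(ss) {
    null_true <- !is.na(sM) & sM <= ss        # defined only when continued
    reject <- cont & lower > ss
    in_null_cont <- cont & null_true
    in_alt_cont <- cont & !null_true
    # unconditional membership uses the classifier that WOULD be selected;
    # for stopped trials no classifier is selected and no rejection occurs
    data.frame(
      s_star = ss,
      cond_t1 = if (any(in_null_cont)) mean(reject[in_null_cont]) else NA_real_,
      uncond_t1 = mean(reject & null_true, na.rm = FALSE),
      cond_power = if (any(in_alt_cont)) mean(reject[in_alt_cont]) else NA_real_,
      uncond_power = mean(reject & cont & !null_true))
  })
  out <- do.call(rbind, res)
  out$uncond_t1 <- vapply(s_star, function(ss) {
    sum(cont & lower > ss & sM <= ss, na.rm = TRUE) / nsim
  }, numeric(1))
  out$uncond_power <- vapply(s_star, function(ss) {
    sum(cont & lower > ss & sM > ss, na.rm = TRUE) / nsim
  }, numeric(1))
  attr(out, "continue_rate") <- mean(cont)
  attr(out, "nsim") <- nsim
  attr(out, "method") <- method
  out
}
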