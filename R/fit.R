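#' Fit the two-stage selection model to observed trial data
#'
#' The central model is: stage-1 true-positive counts `X[i] ~ Bin(n1[i], s[i])`
#' independently across the K candidate classifiers; the classifier selected
#' at the interim analysis (futility cut-offs, then ranking, ties to the
#' smaller index) is validated at stage 2 where `Y ~ Bin(n2, s[M])`,
#' independent of the stage-1 data.  `twostage()` reproduces the selection
#' from `(x, design)`, checks `y` against it, and computes the point
#' estimators of the selected classifier's sensitivity `s[M]`:
#'
#' * the pooled MLE `(x[M] + y) / (n1[M] + n2)`, which is biased high because
#'   it ignores the selection;
#' * the stage-specific estimates `x[M]/n1[M]` and `y/n2` (the latter exactly
#'   conditionally unbiased but imprecise);
#' * the UMVCUE, the Rao-Blackwellized stage-2 estimate
#'   `E[Y/n2 | Z, selection]` computed over the restricted hypergeometric
#'   support, which is conditionally unbiased and minimum variance among
#'   conditionally unbiased estimators.
#'
#' Conditional on the pooled count `z1 = x[M] + y`, `Y` is hypergeometric;
#' the selection event further restricts its support from above because
#' `x[M] = z1 - y` must both pass the futility cut-off and beat the observed
#' runner-up under the ranking rule (a score tie is admissible only when the
#' selected index is smaller than the runner-up's).  When the restricted
#' support still reaches the unrestricted hypergeometric maximum, the UMVCUE
#' collapses to the pooled MLE: selection then exerts no biasing effect.
#'
#' @param x integer vector of stage-1 true-positive counts (length K).
#' @param y integer stage-2 true-positive count for the selected classifier;
#'   must be `NULL` when no classifier passes futility.
#' @param design a [two_stage_design()].
#' @return an object of class `"twostage"` (or `"twostage_stopped"` when the
#'   trial stops at the interim analysis) with components `design`, `x`, `y`,
#'   `selection`, `support` (the restricted conditional support of `Y`) and
#'   `estimates` (named vector: `mle`, `stage1`, `stage2`, `umvcue`).
#' @examples
#' d <- two_stage_design(n1 = c(50, 50), c = c(35, 35), n2 = 50)
#' fit <- twostage(x = c(30, 38), y = 32, design = d)
#' coef(fit)
#' confint(fit, method = "sill-sampson")
#' @export
twostage <- function(x, y = NULL, design) {
  sel <- select_classifier(x, design)
  if (!sel$continued) {
    if (!is.null(y)) {
      stop("no classifier passed futility: the trial stopped and there is ",
           "no stage-2 count; `y` must be NULL")
    }
    out <- structure(
      list(design = design, x = as.integer(x), y = NULL, selection = sel,
           support = NULL, estimates = NULL),
      class = c("twostage_stopped", "twostage"))
    return(out)
  }
  if (is.null(y)) {
    stop("the trial continued to stage 2; a stage-2 count `y` is required")
  }
  y <- as.integer(y)
  if (y < 0 || y > design$n2) stop("`y` must satisfy 0 <= y <= n2")
  M <- sel$M
  z1 <- x[M] + y
  z2 <- if (sel$L > 1L) x[sel$runner_up] else NA_integer_
  supp <- restricted_support(
    z1 = z1, design = design, M = M,
    runner_up = sel$runner_up, z2 = z2)
  if (!(y %in% supp$values)) {
    stop("internal error: observed y is outside the restricted support")
  }
  est <- c(
    mle = z1 / (design$n1[M] + design$n2),
    stage1 = x[M] / design$n1[M],
    stage2 = y / design$n2,
    umvcue = umvcue_from_support(supp$values, z1, design$n1[M], design$n2))
  structure(
    list(design = design, x = as.integer(x), y = y, selection = sel,
         support = supp, estimates = est),
    class = "twostage")
}

#' Restricted conditional support of the stage-2 count
#'
#' Given the pooled count `z1` of the selected classifier and the observed
#' runner-up, returns the set of stage-2 counts `y` compatible with the
#' conditioning: the hypergeometric base support
#' `max(0, z1 - n1[M]) <= y <= min(z1, n2)` intersected with the selection
#' constraints on `x[M] = z1 - y` (futility: `x[M] >= ceiling(c[M])`;
#' ranking: `x[M]` at least the dominance bound against the runner-up, tie
#' admitted only when the selected index is the smaller).  With no runner-up
#' only the futility bound applies.
#'
#' @param z1 pooled true-positive count `x[M] + y`.
#' @param design a [two_stage_design()].
#' @param M index of the selected classifier.
#' @param runner_up index of the second-ranked survivor, or `NA` when L = 1.
#' @param z2 the runner-up's observed stage-1 count (ignored when
#'   `runner_up` is `NA`).
#' @return a list with `values` (admissible y, increasing), `kind` (`"A"`
#'   tie-excluded, `"B"` tie-admitted, `"A'"` single survivor), `bounds`
#'   (`c(lower, upper)`) and `min_x` (the smallest admissible `x[M]`).
#' @export
restricted_support <- function(z1, design, M, runner_up = NA_integer_,
                               z2 = NA_integer_) {
  n1M <- design$n1[M]
  n2 <- design$n2
  stopifnot(z1 >= 0, z1 <= n1M + n2)
  b <- min_selected_count(design, M, runner_up, z2)
  lo <- max(0L, z1 - n1M)
  hi <- min(z1 - b, n2)
  if (hi < lo) {
    stop("empty restricted support: z1 = ", z1, " is inconsistent with the ",
         "minimal admissible stage-1 count ", b, " for classifier ", M)
  }
  kind <- if (is.na(runner_up)) "A'" else if (M < runner_up) "B" else "A"
  list(values = lo:hi, kind = kind, bounds = c(lower = lo, upper = hi),
       min_x = b)
}

# UMVCUE = E[Y/n2 | Z, selection]: ratio of hypergeometric-weighted sums over
# the restricted support, in log space so binomial coefficients at n in the
# hundreds cannot overflow.
umvcue_from_support <- function(values, z1, n1M, n2) {
  lw <- lchoose(n2, values) + lchoose(n1M, z1 - values)
  w <- exp(lw - max(lw))
  sum(values * w) / (n2 * sum(w))
}

#' @export
coef.twostage <- function(object, ...) {
  if (inherits(object, "twostage_stopped")) {
    stop("the trial stopped at the interim analysis; no estimate is defined")
  }
  object$estimates
}

#' @export
print.twostage <- function(x, ...) {
  if (inherits(x, "twostage_stopped")) {
    cat("Two-stage validation trial: stopped at the interim analysis",
        "(no classifier passed its futility cut-off).\n")
    return(invisible(x))
  }
  sel <- x$selection
  d <- x$design
  cat("Two-stage validation trial\n")
  cat(sprintf("  selected classifier M = %d (of K = %d; L = %d survivors)\n",
              sel$M, d$K, sel$L))
  cat(sprintf("  stage 1: %d/%d   stage 2: %d/%d   pooled z1 = %d\n",
              x$x[sel$M], d$n1[sel$M], x$y, d$n2, x$x[sel$M] + x$y))
  cat(sprintf("  restricted support of Y (set %s): {%d, ..., %d}\n",
              x$support$kind, min(x$support$values), max(x$support$values)))
  cat("Estimates of the selected classifier's sensitivity:\n")
  print(round(x$estimates, 4))
  if (max(x$support$values) == min(x$x[sel$M] + x$y, d$n2) &&
      max(x$support$values) == d$n2 ||
      isTRUE(all.equal(x$estimates[["umvcue"]], x$estimates[["mle"]]))) {
    cat("  (UMVCUE equals the MLE: selection exerts no biasing effect here)\n")
  }
  invisible(x)
}

#' @export
summary.twostage <- function(object, level = 0.95, ...) {
  if (inherits(object, "twostage_stopped")) {
    return(structure(list(fit = object), class = "summary.twostage"))
  }
  M <- object$selection$M
  d <- object$design
  ci <- rbind(
    mle = unlist(clopper_pearson(object$x[M] + object$y,
                                 d$n1[M] + d$n2, 1 - level)[c("lower", "upper")]),
    stage1 = unlist(clopper_pearson(object$x[M], d$n1[M],
                                    1 - level)[c("lower", "upper")]),
    stage2 = unlist(clopper_pearson(object$y, d$n2,
                                    1 - level)[c("lower", "upper")]),
    umvcue = unlist(ss_ci(object, alpha = 1 - level)[c("lower", "upper")]))
  structure(list(fit = object, level = level,
                 table = cbind(estimate = object$estimates[rownames(ci)], ci)),
            class = "summary.twostage")
}

#' @export
print.summary.twostage <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$table)) {
    cat(sprintf("\n%.0f%% intervals (Clopper-Pearson; exact conditional for the UMVCUE):\n",
                100 * x$level))
    print(round(x$table, 4))
  }
  invisible(x)
}

#' @export
residuals.twostage <- function(object, ...) {
  if (inherits(object, "twostage_stopped")) return(numeric(0))
  # stage-wise raw residuals of observed counts about the UMVCUE
  M <- object$selection$M
  s <- object$estimates[["umvcue"]]
  c(stage1 = object$x[M] - object$design$n1[M] * s,
    stage2 = object$y - object$design$n2 * s)
}
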