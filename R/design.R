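#' Ranking rule for interim selection
#'
#' A ranking rule scores each candidate classifier's stage-1 true-positive
#' count and, dually, expresses the comparison "classifier i ranks at least
#' as high as classifier j" as a lower bound on classifier i's count that
#' depends only on classifier j's count and fixed constants.  The dual
#' (dominance) form is what the restricted conditional support of the
#' UMVCUE and the exact conditional interval need in closed form.
#'
#' @param score function of `(x, lambda)` returning a real ranking score,
#'   strictly increasing in `x` for fixed `lambda`.
#' @param dominance function of `(xj, lambda_i, lambda_j)` returning the real
#'   threshold `t` such that `score(xi, lambda_i) >= score(xj, lambda_j)`
#'   exactly when `xi >= t` (with equality iff the scores tie).  Must not
#'   depend on `xi`.
#' @param lambda list (or vector) of per-classifier constants.
#' @param label short method label.
#' @param validate_n1 integer vector of stage-1 sizes; when supplied, the
#'   score/dominance pair is cross-checked for mutual consistency over the
#'   full achievable count grid and construction fails on any mismatch.
#'
#' @return an object of class `"ranking_rule"`.
#' @seealso [rank_by_sensitivity()], [rank_by_balanced_accuracy()]
#' @export
ranking_rule <- function(score, dominance, lambda, label = "custom",
                         validate_n1 = NULL) {
  stopifnot(is.function(score), is.function(dominance))
  rule <- structure(
    list(score = score, dominance = dominance, lambda = lambda,
         label = label),
    class = "ranking_rule")
  if (!is.null(validate_n1)) {
    validate_ranking_rule(rule, validate_n1)
  }
  rule
}

#' @export
print.ranking_rule <- function(x, ...) {
  cat("Ranking rule:", x$label, "(", length(x$lambda), "classifiers )\n")
  invisible(x)
}

rule_lambda <- function(rule, i) {
  if (is.list(rule$lambda)) rule$lambda[[i]] else rule$lambda[i]
}

rule_score <- function(rule, x, i) rule$score(x, rule_lambda(rule, i))

# Exhaustive cross-check of score vs dominance over the achievable grid.
validate_ranking_rule <- function(rule, n1) {
  K <- length(n1)
  for (i in seq_len(K)) {
    si <- vapply(0:n1[i], function(x) rule_score(rule, x, i), numeric(1))
    if (any(diff(si) <= 0)) {
      stop("ranking rule score is not strictly increasing in the count ",
           "for classifier ", i)
    }
  }
  tol <- 1e-9
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    for (xj in 0:n1[j]) {
      thr <- rule$dominance(xj, rule_lambda(rule, i), rule_lambda(rule, j))
      sj <- rule_score(rule, xj, j)
      for (xi in 0:n1[i]) {
        si <- rule_score(rule, xi, i)
        ge_score <- si >= sj - tol
        ge_dom <- xi >= thr - tol
        if (ge_score != ge_dom) {
          stop(sprintf(
            "ranking rule score/dominance mismatch at i=%d, j=%d, xi=%d, xj=%d",
            i, j, xi, xj))
        }
        tie_score <- abs(si - sj) <= tol
        tie_dom <- abs(xi - thr) <= tol
        if (tie_score != tie_dom) {
          stop(sprintf(
            "ranking rule tie structure mismatch at i=%d, j=%d, xi=%d, xj=%d",
            i, j, xi, xj))
        }
      }
    }
  }
  invisible(TRUE)
}

#' Sensitivity ranking rule
#'
#' Ranks classifiers by their estimated stage-1 sensitivity `x / n1`.  The
#' constants are the stage-1 case counts, and the dominance threshold for
#' classifier i against classifier j observed at `xj` is `n1i * xj / n1j`.
#'
#' @param n1 integer vector of stage-1 case counts.
#' @return a `"ranking_rule"`.
#' @export
rank_by_sensitivity <- function(n1) {
  ranking_rule(
    score = function(x, lambda) x / lambda,
    dominance = function(xj, lambda_i, lambda_j) lambda_i * xj / lambda_j,
    lambda = as.numeric(n1),
    label = "sensitivity")
}

#' Balanced-accuracy ranking rule
#'
#' Ranks classifiers by balanced accuracy `(x/n1 + specificity)/2` where each
#' classifier's specificity is a fixed constant (held fixed by conditioning on
#' the observed control-arm results).  Classifier i ranks at least as high as
#' classifier j observed at `xj` exactly when
#' `xi >= n1i * (xj/n1j + spec_j - spec_i)`.
#'
#' @param n1 integer vector of stage-1 case counts.
#' @param specificity numeric vector of fixed per-classifier specificities.
#' @return a `"ranking_rule"`.
#' @export
rank_by_balanced_accuracy <- function(n1, specificity) {
  stopifnot(length(n1) == length(specificity),
            all(specificity >= 0), all(specificity <= 1))
  lambda <- lapply(seq_along(n1),
                   function(i) c(n1 = n1[i], spec = specificity[i]))
  ranking_rule(
    score = function(x, lambda) (x / lambda[["n1"]] + lambda[["spec"]]) / 2,
    dominance = function(xj, lambda_i, lambda_j) {
      lambda_i[["n1"]] *
        (xj / lambda_j[["n1"]] + lambda_j[["spec"]] - lambda_i[["spec"]])
    },
    lambda = lambda,
    label = "balanced accuracy")
}

#' Two-stage validation design
#'
#' Fixes the design of a two-stage diagnostic validation study: K candidate
#' binary classifiers are evaluated on `n1[i]` cases at stage 1; classifier i
#' is dropped for futility unless its true-positive count reaches the fixed
#' cut-off `c[i]`; survivors are ranked by `ranking` (ties to the smaller
#' index) and the top-ranked classifier alone is validated on `n2` further
#' cases at stage 2.  If no classifier passes its cut-off, the whole study
#' stops early.
#'
#' @param n1 positive integer vector of stage-1 case counts.
#' @param c numeric vector of futility cut-offs, `0 <= c[i]`; a count passes
#'   when `x[i] >= c[i]` (equivalently `x[i] >= ceiling(c[i])`).  A cut-off
#'   above `n1[i]` is permitted and simply can never be passed.
#' @param n2 positive integer stage-2 case count, fixed in advance.
#' @param ranking a [ranking_rule()]; defaults to [rank_by_sensitivity()].
#' @return an object of class `"two_stage_design"`.
#' @examples
#' d <- two_stage_design(n1 = c(50, 50), c = c(35, 35), n2 = 50)
#' select_classifier(c(36, 40), d)
#' @export
two_stage_design <- function(n1, c, n2, ranking = rank_by_sensitivity(n1)) {
  n1 <- as.integer(n1)
  stopifnot(length(n1) >= 1, all(n1 >= 1),
            length(c) == length(n1), all(c >= 0),
            length(n2) == 1, n2 >= 1)
  if (!inherits(ranking, "ranking_rule")) {
    stop("`ranking` must be a ranking_rule object")
  }
  nl <- if (is.list(ranking$lambda)) length(ranking$lambda) else
    length(ranking$lambda)
  if (nl != length(n1)) {
    stop("ranking rule has constants for ", nl, " classifiers but the design",
         " has ", length(n1))
  }
  structure(
    list(K = length(n1), n1 = n1, c = as.numeric(c), n2 = as.integer(n2),
         ranking = ranking),
    class = "two_stage_design")
}

#' @export
print.two_stage_design <- function(x, ...) {
  cat("Two-stage validation design\n")
  cat("  K  =", x$K, "candidate classifiers\n")
  cat("  n1 =", paste(x$n1, collapse = ", "), "stage-1 cases\n")
  cat("  c  =", paste(format(x$c), collapse = ", "), "futility cut-offs\n")
  cat("  n2 =", x$n2, "stage-2 cases\n")
  cat("  ranking:", x$ranking$label, "(ties to the smaller index)\n")
  invisible(x)
}

#' Apply futility cut-offs
#'
#' Returns the indices (in original order) of classifiers whose stage-1
#' count meets its futility cut-off, `x[i] >= c[i]`.
#'
#' @param x integer vector of stage-1 true-positive counts.
#' @param design a [two_stage_design()].
#' @return integer vector of surviving indices (possibly empty).
#' @export
apply_futility <- function(x, design) {
  check_counts(x, design)
  which(x >= ceiling(design$c))
}

check_counts <- function(x, design) {
  if (length(x) != design$K) {
    stop("stage-1 count vector has length ", length(x),
         " but the design has K = ", design$K)
  }
  if (any(x < 0) || any(x > design$n1)) {
    stop("stage-1 counts must satisfy 0 <= x[i] <= n1[i]")
  }
  invisible(TRUE)
}

#' Rank survivors and select the classifier carried to stage 2
#'
#' Applies the futility cut-offs, ranks the survivors by the design's
#' ranking rule (best first, exact score ties broken in favour of the
#' smaller original index) and selects the top-ranked survivor for stage-2
#' validation.
#'
#' @inheritParams apply_futility
#' @return an object of class `"selection_outcome"` with elements
#'   `survivors` (original indices, original order), `ranked` (survivor
#'   indices best to worst), `M` (selected index, `NA` if stopped), `L`
#'   (number of survivors), `runner_up` (second-ranked survivor or `NA`) and
#'   `continued` (logical).
#' @export
select_classifier <- function(x, design) {
  survivors <- apply_futility(x, design)
  L <- length(survivors)
  if (L == 0L) {
    out <- list(survivors = integer(0), ranked = integer(0), M = NA_integer_,
                L = 0L, runner_up = NA_integer_, continued = FALSE)
    return(structure(out, class = "selection_outcome"))
  }
  sc <- vapply(survivors, function(i) rule_score(design$ranking, x[i], i),
               numeric(1))
  # order by score descending, exact/near ties by smaller original index
  sc <- round(sc, 12)
  ord <- order(-sc, survivors)
  ranked <- survivors[ord]
  out <- list(survivors = survivors, ranked = ranked, M = ranked[1L],
              L = L,
              runner_up = if (L > 1L) ranked[2L] else NA_integer_,
              continued = TRUE)
  structure(out, class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  if (!x$continued) {
    cat("Trial stopped at the interim analysis: no classifier passed its",
        "futility cut-off.\n")
  } else {
    cat("Interim selection: classifier", x$M, "selected for stage 2\n")
    cat("  survivors (ranked):", paste(x$ranked, collapse = " > "), "\n")
  }
  invisible(x)
}

# Smallest admissible stage-1 count for the selected classifier implied by
# the conditioning event: the futility cut-off plus, when there is a
# runner-up, the dominance bound against the runner-up's observed count
# (tie admitted only when the selected index is smaller).  Closed-form from
# the dominance map, then nudged against the score function to be safe
# against floating-point edge cases.
min_selected_count <- function(design, M, runner_up = NA_integer_,
                               z2 = NA_integer_) {
  rule <- design$ranking
  b <- ceiling(design$c[M])
  if (!is.na(runner_up)) {
    tie_ok <- M < runner_up
    thr <- rule$dominance(z2, rule_lambda(rule, M),
                          rule_lambda(rule, runner_up))
    m <- if (tie_ok) ceiling(thr - 1e-9) else floor(thr + 1e-9) + 1
    beats <- function(xi) {
      si <- rule_score(rule, xi, M)
      sj <- rule_score(rule, z2, runner_up)
      si > sj + 1e-9 || (tie_ok && si >= sj - 1e-9)
    }
    m <- max(m, 0)
    while (m > 0 && beats(m - 1)) m <- m - 1
    while (m <= design$n1[M] && !beats(m)) m <- m + 1
    b <- max(b, m)
  }
  as.integer(b)
}
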