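#' Fisher's-exact-test futility cut-off
#'
#' For a question assessed on `n1` cases against a fixed control result
#' (`fp` false positives, `tn` true negatives, held fixed by conditioning so
#' that the cut-off stays independent of the case counts), returns the
#' smallest cut-off `c` in `{0, ..., n1}` such that the two-sided Fisher's
#' exact test of the 2x2 table `(x, n1 - x; fp, tn)` has p-value below
#' `alpha` for EVERY `x >= c`.  When even `x = n1` is not significant the
#' cut-off is unattainable and `Inf` is returned (such a question can never
#' qualify).
#'
#' Only the upper threshold is used: a count so low as to be significant in
#' the other direction would imply a low sensitivity and is not of interest
#' for selection.
#'
#' @param n1 number of stage-1 cases.
#' @param fp,tn fixed stage-1 control counts (false positives, true
#'   negatives).
#' @param alpha significance level of the test.
#' @param convention `"minlik"` (two-sided p sums all tables at most as
#'   probable as the observed one, the mainstream software convention) or
#'   `"midp"` (subtracts half the point probability).
#' @return the cut-off (integer, or `Inf` when unattainable).
#' @export
fisher_threshold <- function(n1, fp, tn, alpha = 0.05,
                             convention = c("minlik", "midp")) {
  convention <- match.arg(convention)
  stopifnot(n1 >= 1, fp >= 0, tn >= 0)
  if (fp + tn == 0) stop("degenerate control margin: fp + tn must be > 0")
  p <- vapply(0:n1, function(x) {
    fisher_p(x, n1, fp, tn, convention)
  }, numeric(1))
  # alpha >= 1 qualifies every table (a p-value can be exactly 1)
  sig <- p < alpha | alpha >= 1
  # element i of sig corresponds to x = i - 1; the cut-off is one above the
  # largest non-significant x
  notsig <- which(!sig)
  if (length(notsig) == 0) return(0L)
  if (max(notsig) == n1 + 1L) return(Inf)
  as.integer(max(notsig))
}

# Two-sided Fisher's exact p-value for the table (x, n1-x; fp, tn),
# conditioning on all margins.  X is hypergeometric over its margin range.
fisher_p <- function(x, n1, fp, tn, convention = "minlik") {
  # number of case-positives k ~ Hyper(m = n1 cases, n = fp+tn controls,
  # k draws = x + fp positives), all margins fixed
  kk <- max(0, (x + fp) - (fp + tn)):min(n1, x + fp)
  d <- stats::dhyper(kk, n1, fp + tn, x + fp)
  dobs <- stats::dhyper(x, n1, fp + tn, x + fp)
  p <- sum(d[d <= dobs * (1 + 1e-7)])
  if (convention == "midp") p <- p - 0.5 * dobs
  min(p, 1)
}

#' Balanced accuracy of a question's stage-1 table
#'
#' The arithmetic mean of sensitivity `tp/(tp+fn)` and specificity
#' `tn/(tn+fp)`.
#'
#' @param tp,fn stage-1 case counts (true positives, false negatives).
#' @param fp,tn stage-1 control counts.
#' @return value in `[0, 1]`.
#' @export
balanced_accuracy <- function(tp, fn, fp, tn) {
  if (tp + fn == 0) stop("no cases: tp + fn must be > 0")
  if (fp + tn == 0) stop("no controls: fp + tn must be > 0")
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Pearson chi-squared test of stage concordance
#'
#' Compares the sensitivity between the two stages of the study for the
#' selected question via a chi-squared test on the 2x2 stage-by-outcome
#' table.  A supporting diagnostic only: the test is known to be very
#' conservative as a detector of interim selection bias.
#'
#' @param tp1,n1 stage-1 true positives and cases.
#' @param tp2,n2 stage-2 true positives and cases.
#' @param correct apply the Yates continuity correction (default `TRUE`,
#'   matching standard software output for 2x2 tables).
#' @return the p-value.
#' @export
stage_concordance_chisq <- function(tp1, n1, tp2, n2, correct = TRUE) {
  stopifnot(n1 >= 1, n2 >= 1, tp1 >= 0, tp1 <= n1, tp2 >= 0, tp2 <= n2)
  tab <- matrix(c(tp1, n1 - tp1, tp2, n2 - tp2), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) stop("degenerate margin in the 2x2 table")
  suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
}

#' Read per-question stage tables
#'
#' Reads a CSV with one row per (condition, question): columns `condition`,
#' `question`, `excluded` (0/1, questions dropped for sparse responses),
#' stage-1 counts `tp`, `fn`, `fp`, `tn`, and stage-2 counts `tp2`, `fn2`
#' (present only on the selected question's row).  Lines starting with `#`
#' are comments.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_fhq_tables <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("condition", "question", "tp", "fn", "fp", "tn")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(tab$excluded)) tab$excluded <- 0L
  tab
}

#' Bias-adjusted analysis of a questionnaire validation study
#'
#' Runs the full selection-aware analysis for each condition: derives each
#' question's Fisher's-exact-test cut-off (controls held fixed), ranks the
#' qualifying questions by balanced accuracy (ties to the smaller index),
#' identifies the selected question, and reports the stage-1, stage-2 and
#' pooled (MLE) sensitivity estimates with Clopper-Pearson intervals
#' alongside the UMVCUE with its exact conditional interval.  When the
#' restricted support is unrestricted the UMVCUE equals the MLE exactly —
#' the diagnostic that interim selection exerted no bias for that condition.
#'
#' @param tables data frame as returned by [read_fhq_tables()] (one
#'   condition or several).
#' @param alpha Fisher's-exact-test significance level used for the
#'   cut-offs.
#' @param level confidence level of the reported intervals.
#' @param convention p-value convention passed to [fisher_threshold()].
#' @return a list of class `"fhq_analysis"`, one element per condition:
#'   either a `"stopped"` report (no qualifying question) or a list with the
#'   selection, the fitted [twostage()] object and an `estimates` table.
#' @export
fhq_analyze <- function(tables, alpha = 0.05, level = 0.95,
                        convention = "minlik") {
  out <- lapply(split(tables, tables$condition), function(tab) {
    tab <- tab[order(tab$question), , drop = FALSE]
    keep <- !(tab$excluded %in% c(1, TRUE))
    tab <- tab[keep, , drop = FALSE]
    n1 <- tab$tp + tab$fn
    spec <- tab$tn / (tab$tn + tab$fp)
    cc <- vapply(seq_len(nrow(tab)), function(i) {
      fisher_threshold(n1[i], tab$fp[i], tab$tn[i], alpha = alpha,
                       convention = convention)
    }, numeric(1))
    if (all(tab$tp < ceiling(cc))) {
      return(list(condition = tab$condition[1], stopped = TRUE,
                  thresholds = cc))
    }
    sel_row <- which(!is.na(tab$tp2))
    if (length(sel_row) != 1) {
      stop("stage-2 counts must be present for exactly one question in ",
           "condition ", tab$condition[1])
    }
    n2 <- tab$tp2[sel_row] + tab$fn2[sel_row]
    design <- two_stage_design(
      n1 = n1, c = cc, n2 = n2,
      ranking = rank_by_balanced_accuracy(n1, spec))
    sel <- select_classifier(tab$tp, design)
    if (sel$M != sel_row) {
      stop("stage-2 data is attached to question ", tab$question[sel_row],
           " but the selection rules pick question ", tab$question[sel$M],
           " in condition ", tab$condition[1])
    }
    fit <- twostage(x = tab$tp, y = tab$tp2[sel_row], design = design)
    sm <- summary(fit, level = level)
    list(condition = tab$condition[1], stopped = FALSE,
         questions = tab$question, thresholds = cc,
         selected = tab$question[sel$M],
         survivors = tab$question[sel$survivors],
         fit = fit, estimates = sm$table,
         umvcue_equals_mle = isTRUE(all.equal(
           fit$estimates[["umvcue"]], fit$estimates[["mle"]],
           tolerance = 1e-12)))
  })
  structure(out, class = "fhq_analysis")
}

#' @export
print.fhq_analysis <- function(x, ...) {
  for (cond in x) {
    cat("==", cond$condition, "==\n")
    if (isTRUE(cond$stopped)) {
      cat("  no question qualified; analysis stops at stage 1\n\n")
      next
    }
    cat("  qualifying questions:", paste(cond$survivors, collapse = ", "),
        " selected:", cond$selected, "\n")
    print(round(cond$estimates, 3))
    if (cond$umvcue_equals_mle) {
      cat("  UMVCUE = MLE: no selection bias detected for this condition\n")
    } else {
      cat("  UMVCUE < MLE: interim selection biased the pooled estimate\n")
    }
    cat("\n")
  }
  invisible(x)
}
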