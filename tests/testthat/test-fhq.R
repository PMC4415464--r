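test_that("Fisher cut-off is the minimal count with all larger counts significant", {
  # exhaustive-scan oracle via fisher.test
  scan_oracle <- function(n1, fp, tn, alpha = 0.05) {
    p <- vapply(0:n1, function(x) {
      fisher.test(matrix(c(x, n1 - x, fp, tn), 2, byrow = TRUE))$p.value
    }, numeric(1))
    sig <- p < alpha
    if (all(sig)) return(0L)
    if (!sig[n1 + 1]) return(Inf)
    max(which(!sig))
  }
  cases <- list(c(20, 0, 20), c(26, 39, 191), c(15, 10, 40), c(30, 25, 75))
  for (cs in cases) {
    expect_equal(fisher_threshold(cs[1], cs[2], cs[3]),
                 scan_oracle(cs[1], cs[2], cs[3]))
  }
  # minimality: the count below the cut-off is not significant
  c8 <- fisher_threshold(26, 39, 191)
  expect_gte(fisher.test(matrix(c(c8 - 1, 26 - c8 + 1, 39, 191), 2,
                                byrow = TRUE))$p.value, 0.05)
  expect_lt(fisher.test(matrix(c(c8, 26 - c8, 39, 191), 2,
                               byrow = TRUE))$p.value, 0.05)
})

test_that("Fisher cut-off degenerate and sentinel cases", {
  expect_identical(fisher_threshold(20, 10, 30, alpha = 1.0), 0L)
  # tiny balanced table: no count reaches significance
  expect_identical(fisher_threshold(3, 2, 2), Inf)
  expect_error(fisher_threshold(10, 0, 0), "control margin")
  # mid-p convention is less conservative: cut-off never larger
  expect_lte(fisher_threshold(26, 39, 191, convention = "midp"),
             fisher_threshold(26, 39, 191, convention = "minlik"))
})

test_that("balanced accuracy arithmetic and ranking rule consistency", {
  expect_equal(balanced_accuracy(tp = 10, fn = 0, fp = 0, tn = 20), 1)
  expect_equal(balanced_accuracy(tp = 6, fn = 4, fp = 2, tn = 8), 0.7)
  expect_error(balanced_accuracy(0, 0, 2, 8), "cases")
  # with equal sizes and specificities the rule is the sensitivity ranking
  n1 <- c(10, 10)
  rule_eq <- rank_by_balanced_accuracy(n1, c(0.8, 0.8))
  rule_sens <- rank_by_sensitivity(n1)
  for (xi in 0:10) for (xj in 0:10) {
    ge_ba <- rule_eq$score(xi, rule_eq$lambda[[1]]) >=
      rule_eq$score(xj, rule_eq$lambda[[2]])
    ge_s <- rule_sens$score(xi, 10) >= rule_sens$score(xj, 10)
    expect_identical(ge_ba, ge_s)
  }
  # score and dominance are mutually consistent over the achievable grid
  expect_silent(twostageval:::validate_ranking_rule(
    rank_by_balanced_accuracy(c(6, 8), c(0.9, 0.75)), c(6, 8)))
})

test_that("balanced-accuracy ranking reproduces a direct sort with index tie-break", {
  n1 <- c(8, 8, 8)
  spec <- c(0.80, 0.90, 0.85)
  d <- two_stage_design(n1 = n1, c = c(0, 0, 0), n2 = 5,
                        ranking = rank_by_balanced_accuracy(n1, spec))
  set.seed(6)
  for (i in 1:50) {
    x <- rbinom(3, n1, 0.6)
    ba <- round(x / n1 / 2 + spec / 2, 12)
    ord <- order(-ba, seq_along(ba))
    expect_identical(select_classifier(x, d)$ranked, ord)
    expect_identical(select_classifier(x, d)$M, ord[1])
  }
  # leader/runner-up dominance bound matches exhaustive search
  for (z2 in 0:8) {
    b <- twostageval:::min_selected_count(d, 1L, runner_up = 2L, z2 = z2)
    feasible <- which(vapply(0:8, function(xm) {
      (xm / 8 + spec[1]) / 2 >= (z2 / 8 + spec[2]) / 2 - 1e-12
    }, logical(1))) - 1L
    expected <- if (length(feasible)) min(feasible) else 9L
    expect_identical(b, as.integer(max(expected, 0L)))
  }
})

test_that("stage concordance chi-squared matches standard software output", {
  expect_equal(stage_concordance_chisq(19, 26, 14, 22), 0.696,
               tolerance = 5e-4)
  expect_equal(stage_concordance_chisq(10, 20, 10, 20), 1)
  expect_lt(stage_concordance_chisq(19, 26, 0, 22), 0.001)
  expect_error(stage_concordance_chisq(0, 5, 0, 5), "margin")
})

test_that("questionnaire analysis identifies bias only where selection restricted the support", {
  tab <- read_fhq_tables(system.file("extdata", "fhq_synthetic.csv",
                                     package = "twostageval"))
  rep <- fhq_analyze(tab)
  breast <- rep[["breast"]]
  expect_false(breast$stopped)
  expect_identical(breast$selected, "q8")
  est <- coef(breast$fit)
  expect_lt(est[["umvcue"]], est[["mle"]])
  expect_equal(est[["mle"]], 33 / 48, tolerance = 1e-12)
  # the other conditions have unrestricted supports: UMVCUE equals MLE
  for (cond in c("diabetes", "ihd", "colorectal")) {
    expect_true(rep[[cond]]$umvcue_equals_mle)
  }
  # excluded questions are dropped before threshold derivation
  expect_false("q4a" %in% rep[["diabetes"]]$questions)
})

test_that("a condition with no qualifying question yields a stopped report", {
  tab <- data.frame(condition = "toy", question = c("qa", "qb"),
                    excluded = 0L, tp = c(1, 0), fn = c(9, 10),
                    fp = c(5, 5), tn = c(15, 15),
                    tp2 = NA_integer_, fn2 = NA_integer_)
  rep <- fhq_analyze(tab)
  expect_true(rep[["toy"]]$stopped)
})

test_that("a synthetic condition with one dominant question is well-formed", {
  tab <- data.frame(condition = "toy", question = c("qa", "qb"),
                    excluded = 0L, tp = c(18, 4), fn = c(2, 16),
                    fp = c(4, 6), tn = c(76, 74),
                    tp2 = c(13L, NA), fn2 = c(2L, NA))
  rep <- fhq_analyze(tab)
  expect_identical(rep[["toy"]]$selected, "qa")
  expect_true(all(rep[["toy"]]$estimates[, "lower"] <=
                    rep[["toy"]]$estimates[, "upper"]))
})
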