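test_that("conditional pmf normalizes and matches exhaustive enumeration", {
  d <- two_stage_design(n1 = c(5, 5), c = c(2, 2), n2 = 5)
  x_rest <- 3L   # runner-up's observed stage-1 count
  for (M in 1:2) {
    b <- twostageval:::min_selected_count(d, M, runner_up = 3 - M, z2 = x_rest)
    model <- ss_model(n1M = 5, n2 = 5, min_x = b)
    for (s in c(0.1, 0.5, 0.9)) {
      expect_equal(sum(model$pmf(s)), 1, tolerance = 1e-12)
      oracle <- enum_z1_pmf_oracle(d, M, x_rest, s)
      f <- numeric(length(oracle))
      f[model$support + 1] <- model$pmf(s)
      expect_equal(f, oracle, tolerance = 1e-10)
    }
  }
  # K = 1, no cut-off: the pooled count is plain binomial
  d1 <- two_stage_design(n1 = 6, c = 0, n2 = 4)
  m1 <- ss_model(n1M = 6, n2 = 4, min_x = 0)
  expect_equal(m1$pmf(0.3), dbinom(0:10, 10, 0.3), tolerance = 1e-12)
})

test_that("tail probabilities are monotone in s", {
  model <- ss_model(n1M = 20, n2 = 15, min_x = 12)
  grid <- seq(0.02, 0.98, by = 0.02)
  for (zobs in c(13, 20, 30)) {
    p1 <- vapply(grid, function(s) model$p_ge(zobs, s), numeric(1))
    p2 <- vapply(grid, function(s) model$p_le(zobs, s), numeric(1))
    expect_true(all(diff(p1) >= -1e-10))
    expect_true(all(diff(p2) <= 1e-10))
  }
})

test_that("exact conditional interval inverts back to its alpha split", {
  d <- two_stage_design(n1 = c(50, 50), c = c(35, 35), n2 = 50)
  fit <- twostage(x = c(30, 40), y = 30, design = d)
  ci <- ss_ci(fit, alpha = 0.05)
  model <- ss_model(fit)
  zobs <- 70
  expect_equal(model$p_ge(zobs, ci$lower), 0.025, tolerance = 1e-6)
  expect_equal(model$p_le(zobs, ci$upper), 0.025, tolerance = 1e-6)
  expect_true(ci$lower >= 0 && ci$lower <= ci$upper && ci$upper <= 1)
})

test_that("with vacuous conditioning the exact conditional interval is Clopper-Pearson", {
  d <- two_stage_design(n1 = 50, c = 0, n2 = 50)
  for (z in c(0, 1, 35, 70, 99, 100)) {
    y <- min(z, 50)
    fit <- twostage(x = z - y, y = y, design = d)
    ss <- ss_ci(fit, alpha = 0.05)
    cp <- clopper_pearson(z, 100, alpha = 0.05)
    expect_equal(ss$lower, cp$lower, tolerance = 1e-7)
    expect_equal(ss$upper, cp$upper, tolerance = 1e-7)
  }
})

test_that("bounds clamp at the support boundaries", {
  model <- ss_model(n1M = 20, n2 = 10, min_x = 14)
  zmax <- max(model$support)
  zmin <- min(model$support)
  expect_equal(ss_ci(model = model, zobs = zmax, alpha = 0.05)$upper, 1)
  expect_equal(ss_ci(model = model, zobs = zmin, alpha = 0.05)$lower, 0)
})

test_that("Clopper-Pearson matches the beta closed form and boundary cases", {
  expect_equal(unlist(clopper_pearson(0, 20)[c("lower", "upper")]),
               c(lower = 0, upper = 1 - 0.025^(1 / 20)), tolerance = 1e-12)
  expect_equal(unlist(clopper_pearson(20, 20)[c("lower", "upper")]),
               c(lower = 0.025^(1 / 20), upper = 1), tolerance = 1e-12)
  # tail-inversion oracle for an interior case
  lo <- uniroot(function(p) 1 - pbinom(69, 100, p) - 0.025, c(1e-6, 1 - 1e-6),
                tol = 1e-12)$root
  hi <- uniroot(function(p) pbinom(70, 100, p) - 0.025, c(1e-6, 1 - 1e-6),
                tol = 1e-12)$root
  cp <- clopper_pearson(70, 100)
  expect_equal(cp$lower, lo, tolerance = 1e-8)
  expect_equal(cp$upper, hi, tolerance = 1e-8)
  expect_error(clopper_pearson(5, 4), "k <= n")
})

test_that("optimised split is never wider than the equal split", {
  d <- two_stage_design(n1 = c(50, 50), c = c(35, 35), n2 = 50)
  for (xy in list(c(38, 30), c(36, 40), c(45, 25))) {
    fit <- twostage(x = c(30, xy[1]), y = xy[2], design = d)
    eq <- ss_ci(fit, alpha = 0.05)
    op <- ss_ci_optimised(fit, alpha = 0.05)
    expect_lte(op$upper - op$lower, eq$upper - eq$lower + 1e-6)
    expect_equal(sum(op$alpha_split), 0.05, tolerance = 1e-10)
  }
  # symmetric pmf: the optimum is (numerically) the equal split
  m <- ss_model(n1M = 10, n2 = 10, min_x = 0)
  op <- ss_ci_optimised(model = m, zobs = 10, alpha = 0.05)
  eq <- ss_ci(model = m, zobs = 10, alpha = 0.05)
  expect_equal(op$upper - op$lower, eq$upper - eq$lower, tolerance = 1e-4)
})

test_that("bootstrap mirrors the selection event and handles degenerate data", {
  d <- two_stage_design(n1 = c(10, 10), c = c(5, 5), n2 = 10)
  fit <- twostage(x = c(4, 10), y = 10, design = d)
  ci <- bootstrap_ci(fit, estimator = "mle", B = 200, seed = 1)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  # acceptance respects the futility/ranking bound: resampled stage-1 counts
  # below the conditioning bound can never enter, so the lower interval end
  # of the stage-1 estimator never drops below bound/n1
  fit2 <- twostage(x = c(6, 9), y = 5, design = d)
  b <- fit2$support$min_x
  ci2 <- bootstrap_ci(fit2, estimator = "stage1", B = 500, seed = 2)
  expect_gte(ci2$lower, b / 10)
  expect_gt(ci2$acceptance_rate, 0)
  expect_lte(ci2$acceptance_rate, 1)
})

test_that("confint dispatches on method and respects the level", {
  d <- two_stage_design(n1 = c(50, 50), c = c(35, 35), n2 = 50)
  fit <- twostage(x = c(30, 38), y = 32, design = d)
  ss <- confint(fit, level = 0.9, method = "sill-sampson")
  expect_equal(ss$level, 0.9)
  cp <- confint(fit, level = 0.95, method = "clopper-pearson")
  expect_equal(unlist(cp[c("lower", "upper")]),
               unlist(clopper_pearson(70, 100)[c("lower", "upper")]))
  bs <- confint(fit, method = "bootstrap", estimator = "mle", B = 200,
                seed = 3)
  expect_equal(bs$replicates, 200)
})
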