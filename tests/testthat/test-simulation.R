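test_that("single-trial simulation is faithful to the model", {
  d <- two_stage_design(n1 = c(10, 10), c = c(1, 1), n2 = 8)
  set.seed(2)
  fit <- simulate_trial(d, S = c(1, 1))   # degenerate margins
  expect_identical(fit$x, c(10L, 10L))
  expect_identical(fit$selection$M, 1L)   # tie to the smaller index
  expect_identical(fit$y, 8L)
  fit0 <- simulate_trial(d, S = c(1e-12, 1e-12))
  expect_s3_class(fit0, "twostage_stopped")
})

test_that("study tables are reproducible bit-for-bit under a fixed seed", {
  d <- two_stage_design(n1 = c(20, 20), c = c(12, 12), n2 = 20)
  a <- estimator_study(d, S = c(0.6, 0.7), nsim = 2000, seed = 99)
  b <- estimator_study(d, S = c(0.6, 0.7), nsim = 2000, seed = 99)
  expect_identical(a, b)
  ca <- coverage_study(d, S = c(0.6, 0.7), n_continuing = 300, seed = 21)
  cb <- coverage_study(d, S = c(0.6, 0.7), n_continuing = 300, seed = 21)
  expect_identical(ca, cb)
})

test_that("continuation probability matches the closed form", {
  scenarios <- list(
    list(S = c(0.5, 0.7), n1 = c(50, 50)),
    list(S = c(0.6, 0.8), n1 = c(15, 25)),
    list(S = c(0.58, 0.60, 0.62, 0.64), n1 = c(40, 35, 30, 30)))
  for (sc in scenarios) {
    d <- two_stage_design(n1 = sc$n1, c = 0.7 * sc$n1, n2 = 50)
    st <- estimator_study(d, S = sc$S, nsim = 20000, seed = 4)
    p <- st$p_continue_exact
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(st$p_continue - p), 3 * se + 1e-12)
    expect_equal(p, 1 - prod(pbinom(ceiling(d$c) - 1, d$n1, sc$S)),
                 tolerance = 1e-12)
  }
})

test_that("vectorized simulation is internally consistent with the selection rules", {
  d <- two_stage_design(n1 = c(12, 9, 15), c = c(5, 4, 6), n2 = 10)
  S <- c(0.55, 0.6, 0.5)
  tr <- simulate(d, nsim = 500, seed = 8, S = S)
  cc <- ceiling(d$c)
  for (i in which(tr$continued)) {
    M <- tr$M[i]
    expect_gte(tr$xM[i], cc[M])
    expect_identical(tr$z1[i], tr$xM[i] + tr$y[i])
    expect_equal(tr$sM[i], S[M])
    if (!is.na(tr$runner_up[i])) {
      ru <- tr$runner_up[i]
      # the selected classifier outranks the runner-up under the tie rule
      sM <- tr$xM[i] / d$n1[M]; sR <- tr$z2[i] / d$n1[ru]
      expect_true(sM > sR - 1e-12 || (M < ru && abs(sM - sR) < 1e-12))
      # reconstructing the trial gives the same conditioning bound
      x <- integer(3); x[M] <- tr$xM[i]; x[ru] <- tr$z2[i]
      fit <- twostage(x = x, y = tr$y[i], design = d)
      if (fit$selection$runner_up %in% ru) {
        expect_identical(as.integer(tr$min_x[i]), fit$support$min_x)
      }
    } else {
      expect_identical(as.integer(tr$min_x[i]), as.integer(cc[M]))
    }
  }
  # stopped replicates carry no stage-2 draw
  expect_true(all(is.na(tr$y[!tr$continued])))
})

test_that("selection bias grows as the sensitivity gap shrinks and persists without stopping", {
  st_gap <- estimator_study(
    two_stage_design(n1 = c(50, 50), c = c(35, 35), n2 = 50),
    S = c(0.50, 0.70), nsim = 30000, seed = 12, scale = 100)
  st_close <- estimator_study(
    two_stage_design(n1 = c(40, 35, 30, 30), c = 0.7 * c(40, 35, 30, 30),
                     n2 = 50),
    S = c(0.58, 0.60, 0.62, 0.64), nsim = 30000, seed = 12, scale = 100)
  expect_gt(st_close$table["mle", "bias"], st_gap$table["mle", "bias"])
  # near-certain continuation still leaves selection-among-candidates bias
  st6 <- estimator_study(
    two_stage_design(n1 = rep(50, 4), c = rep(35, 4), n2 = 50),
    S = rep(0.7, 4), nsim = 30000, seed = 13, scale = 100)
  expect_gt(st6$p_continue, 0.95)
  expect_gt(st6$table["mle", "bias"], 1)
})

test_that("correlated binary generator hits its margins and correlations", {
  set.seed(14)
  # independence
  z0 <- rcorrbin(10000, p = c(0.3, 0.6, 0.8), R = diag(3))
  expect_true(all(abs(cor(z0)[upper.tri(diag(3))]) < 0.03))
  expect_true(all(abs(colMeans(z0) - c(0.3, 0.6, 0.8)) < 0.02))
  # a solved pair: binary correlation 0.5 at p = (0.5, 0.5)
  z1 <- rcorrbin(10000, p = c(0.5, 0.5),
                 R = matrix(c(1, 0.5, 0.5, 1), 2))
  expect_lt(abs(cor(z1)[1, 2] - 0.5), 0.03)
  # the solved latent correlation satisfies the orthant equation
  L <- attr(z1, "latent")
  orthant <- twostageval:::bvn_upper(qnorm(0.5), qnorm(0.5), L[1, 2])
  expect_equal(orthant, 0.25 + 0.5 * 0.25, tolerance = 1e-6)
  # infeasible pair is refused with a clear message
  expect_error(rcorrbin(10, p = c(0.05, 0.95),
                        R = matrix(c(1, 0.9, 0.9, 1), 2)),
               "infeasible")
})

test_that("correlation summaries report mean absolute and maximal pairs", {
  expect_equal(correlation_summary(diag(4))$mean_abs, 0)
  R <- matrix(c(1, 0.3, 0.3, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  cs <- correlation_summary(R)
  expect_equal(cs$mean_abs, 0.3)
  expect_equal(cs$max, 0.3)
  expect_identical(cs$max_pair, c("a", "b"))
  expect_error(correlation_summary(matrix(0, 2, 3)), "square")
})

test_that("questionnaire-like correlated data keeps the UMVCUE usable", {
  # margins and correlations patterned on the questionnaire study; checks
  # that mild correlation does not break the generator or the estimator
  R <- fhq_correlations()[1:4, 1:4]
  p <- c(0.55, 0.6, 0.5, 0.45)
  set.seed(15)
  z <- rcorrbin(5000, p = p, R = R)
  emp <- cor(z)
  expect_true(max(abs(emp[upper.tri(emp)] - R[upper.tri(R)])) < 0.05)
})
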