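cfg <- default_config()

test_that("odds ratio and Wald interval match hand computation", {
  # trigger-vs-mortality table reconstructed from the cohort margins
  r <- odds_ratio(c(26, 404, 26, 307), cfg)
  expect_equal(r$or, (26 * 307) / (404 * 26))
  expect_equal(round(r$or, 2), 0.76)
  expect_equal(round(r$ci_low, 2), 0.43)
  expect_equal(round(r$ci_high, 1), 1.3)
  # hand-derived cross-product for the dichotomized bundle table
  r2 <- odds_ratio(c(50, 481, 2, 230), cfg)
  expect_equal(r2$or, 50 * 230 / (481 * 2))
  expect_equal(r2$or, 11.954, tolerance = 1e-3)
  # symmetric table
  r3 <- odds_ratio(c(1, 1, 1, 1), cfg)
  expect_equal(r3$or, 1.0)
  expect_lt(r3$ci_low, 1); expect_gt(r3$ci_high, 1)
})

test_that("odds-ratio reciprocity and zero-cell policy", {
  set.seed(1)
  for (i in 1:25) {
    t <- rpois(4, 20) + 1
    a <- odds_ratio(t, cfg)
    b <- odds_ratio(t[c(3, 4, 1, 2)], cfg)
    expect_equal(a$or * b$or, 1, tolerance = 1e-12)
  }
  expect_error(odds_ratio(c(0, 5, 3, 2), cfg), "zero cell")
  withcorr <- odds_ratio(c(0, 5, 3, 2), cfg, correction = TRUE)
  expect_equal(withcorr$or, (0.5 * 2.5) / (5.5 * 3.5))
})

test_that("chi-square equals the direct formula and base-R oracle", {
  t0 <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi_square(t0)$statistic, 0)
  expect_equal(chi_square(t0)$p_value, 1)
  set.seed(2)
  for (i in 1:50) {
    tab <- matrix(rpois(6, 15) + 1, nrow = 2)
    ours <- chi_square(tab)
    orc <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(orc$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, orc$p.value, tolerance = 1e-12)
    # transpose invariance
    expect_equal(chi_square(t(tab))$statistic, ours$statistic)
  }
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("wilcoxon exact branch matches brute-force enumeration", {
  # frozen case: x = {1,2}, y = {3,4}; one-sided exact p = 1/6
  orc <- oracle_wilcoxon(c(1, 2), c(3, 4))
  expect_equal(orc$p_lower, 1 / 6)
  got <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(got$method, "exact")
  expect_equal(got$p_value, orc$p_two_sided)
  # random n = 6 vs 6, no ties
  set.seed(3)
  for (i in 1:20) {
    x <- sample(1000, 6); y <- sample(2000:3000, 6)
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_wilcoxon(x, y)$p_two_sided)
  }
})

test_that("wilcoxon approximate branch agrees with base R under ties", {
  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:8, 15, replace = TRUE)
    y <- sample(3:10, 18, replace = TRUE)
    got <- wilcoxon_rank_sum(x, y)
    orc <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(got$method, "normal")
    expect_equal(got$statistic, unname(orc$statistic))
    expect_equal(got$p_value, orc$p.value, tolerance = 1e-10)
  }
  # identical samples: two-sided p near 1
  expect_gt(wilcoxon_rank_sum(c(1, 5, 9), c(1, 5, 9))$p_value, 0.9)
  # fully tied data degenerates with p = 1
  deg <- wilcoxon_rank_sum(rep(3, 20), rep(3, 25))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("logistic IRLS reproduces the closed-form 2x2 odds ratio", {
  x <- c(rep(1, 430), rep(0, 333))
  y <- c(rep(1, 26), rep(0, 404), rep(1, 26), rep(0, 307))
  fit <- logistic_fit(cbind(intercept = 1, exposure = x), y, cfg)
  or <- odds_ratio(c(26, 404, 26, 307), cfg)
  expect_true(fit$converged)
  expect_equal(unname(fit$or_ci["exposure", "or"]), or$or, tolerance = 1e-10)
  expect_equal(unname(fit$or_ci["exposure", "ci_low"]), or$ci_low,
               tolerance = 1e-10)
  expect_equal(unname(fit$or_ci["exposure", "ci_high"]), or$ci_high,
               tolerance = 1e-10)
})

test_that("logistic IRLS matches glm and direct likelihood maximization", {
  set.seed(5)
  for (i in 1:8) {
    n <- 200
    X <- cbind(1, matrix(rnorm(n * 3), n))
    beta <- c(-0.5, runif(3, -1, 1))
    y <- rbinom(n, 1, plogis(drop(X %*% beta)))
    fit <- logistic_fit(X, y, cfg)
    ref <- glm.fit(X, y, family = binomial())
    expect_equal(unname(coef(fit)), unname(ref$coefficients),
                 tolerance = 1e-6)
    expect_equal(unname(coef(fit)), oracle_logistic(X, y), tolerance = 1e-4)
  }
})

test_that("logistic diagnostics: rank deficiency, separation, degenerate outcome", {
  X <- cbind(1, x1 = rep(c(0, 1), 25), x2 = rep(c(0, 2), 25))
  y <- rbinom(50, 1, 0.4)
  expect_error(logistic_fit(X, y, cfg), "rank-deficient")
  # perfectly separated predictor
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  fit <- logistic_fit(cbind(1, xs), ys, cfg)
  expect_true(fit$diagnostics$quasi_separation)
  # all-zero outcome has no interior MLE
  fit0 <- logistic_fit(cbind(1, rnorm(30)), rep(0, 30), cfg)
  expect_true(fit0$diagnostics$quasi_separation ||
                fit0$diagnostics$non_convergence)
})

test_that("model wrappers report unadjusted and adjusted exposure ORs", {
  run <- get_run()
  ft <- run$fit_trigger
  expect_s3_class(ft$unadjusted, "respaudit_fit")
  expect_equal(unname(ft$exposure_or["unadjusted", "or"]), 0.76,
               tolerance = 1e-2 / 0.76)
  # no contrast in the exposure is an error
  coh <- run$cohort
  coh$has_trigger <- TRUE
  expect_error(fit_trigger_mortality_model(coh, cfg), "no contrast")
  # a degenerate covariate is dropped with a warning, fit proceeds
  coh2 <- run$cohort
  coh2$lods <- 0L
  expect_warning(ft2 <- fit_trigger_mortality_model(coh2, cfg), "lods_gt0")
  expect_true(ft2$adjusted$converged)
})

test_that("adjusted and unadjusted ORs agree when covariates are pure noise", {
  set.seed(6)
  n <- 6000
  x <- rbinom(n, 1, 0.5)
  z1 <- rbinom(n, 1, 0.5); z2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2 + 0.4 * x))
  un <- logistic_fit(cbind(i = 1, x = x), y, cfg)
  adj <- logistic_fit(cbind(i = 1, x = x, z1 = z1, z2 = z2), y, cfg)
  expect_equal(coef(adj)[["x"]], coef(un)[["x"]], tolerance = 0.05)
})
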