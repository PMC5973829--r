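# Fitting, behavioral scoring and the condition-comparison statistics.

test_that("null data recover zero weights", {
  set.seed(201)
  p <- ddm_params(c(taste = 0, health = 0))
  beh <- sim_subject("food", "NC", params = p)
  fit <- fit_ddm(beh, "food", control = fast_control())
  expect_lt(abs(coef(fit)["taste"]), 0.002)
  expect_lt(abs(coef(fit)["health"]), 0.002)
})

test_that("fitted likelihood is at least the generating likelihood", {
  set.seed(202)
  p <- ddm_params(c(taste = 0.0163, health = -0.0003))
  beh <- sim_subject("food", "NC", params = p)
  fit <- fit_ddm(beh, "food", control = fast_control())
  expect_gte(fit$loglik, log_likelihood(p, beh) - 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$n_trials, 90)
})

test_that("healthy choices follow the default-relative definition", {
  expect_equal(classify_healthy_choice("yes", 5, 3), "healthy")
  expect_equal(classify_healthy_choice("yes", 2, 3), "unhealthy")
  expect_equal(classify_healthy_choice("no", 3, 3), "undefined")
  expect_equal(classify_healthy_choice("no", 2, 3), "healthy")
  expect_equal(classify_healthy_choice("missed", 5, 3), "undefined")
})

test_that("altruistic choices follow the trade-off definition", {
  expect_equal(classify_altruistic_choice("yes", 13, 27), "altruistic")
  expect_equal(classify_altruistic_choice("no", 31, 9), "altruistic")
  expect_equal(classify_altruistic_choice("yes", 31, 9), "selfish")
  expect_equal(classify_altruistic_choice("no", 13, 27), "selfish")
  expect_equal(classify_altruistic_choice("missed", 13, 27), "undefined")
  expect_error(classify_altruistic_choice("yes", 25, 25), "trade-off")
})

test_that("regulatory success is the condition difference and antisymmetric", {
  expect_equal(regulatory_success(c(HC = 78.83, NC = 44.31), c("HC", "NC")),
               34.52)
  expect_equal(regulatory_success(c(PC = 66.97, EC = 49.94), c("PC", "EC")),
               17.03)
  expect_equal(regulatory_success(c(A = 10, B = 10), c("A", "B")), 0)
  x <- c(NC = 31, PC = 62)
  expect_equal(regulatory_success(x, c("PC", "NC")),
               -regulatory_success(x, c("NC", "PC")))
  expect_error(regulatory_success(c(NC = 1), c("HC", "NC")), "missing")
})

test_that("partial correlation matches its closed forms", {
  set.seed(203)
  x <- rnorm(40); y <- x + rnorm(40, sd = 0.5); z <- rnorm(40)
  # a covariate orthogonalized against both leaves plain r
  zo <- resid(lm(z ~ x + y))
  expect_equal(partial_correlation(x, y, zo), cor(x, y), tolerance = 1e-6)
  expect_equal(partial_correlation(x, x, z), 1)
  # inverse-correlation-matrix oracle on correlated data
  z2 <- x + rnorm(40)
  R <- cor(cbind(x, y, z2))
  P <- solve(R)
  oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(partial_correlation(x, y, z2), oracle, tolerance = 1e-10)
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(204)
  m <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  res <- rm_anova(m)
  # brute-force two-way decomposition via aov with a subject factor
  d <- data.frame(y = as.vector(m), cond = factor(rep(colnames(m), each = 5)),
                  subj = factor(rep(1:5, 3)))
  a <- summary(stats::aov(y ~ cond + Error(subj/cond), data = d))
  tab <- a[["Error: subj:cond"]][[1]]
  expect_equal(res$F, tab["cond", "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab["cond", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 8)
  expect_equal(rm_anova(matrix(5, 4, 3))$F, 0)
})

test_that("repeated-measures ANOVA is calibrated under the null", {
  set.seed(205)
  p <- replicate(500, rm_anova(matrix(rnorm(24), 8, 3))$p)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.03)
})

test_that("paired t-tests use the pair-count Bonferroni factor", {
  set.seed(206)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  res <- paired_tests_bonferroni(m)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_corrected, pmin(res$p * 3, 1))
  # closed-form paired t on a 10 x 2 matrix
  m2 <- matrix(rnorm(20), 10, 2)
  r2 <- paired_tests_bonferroni(m2)
  d <- m2[, 1] - m2[, 2]
  expect_equal(r2$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-10)
  same <- cbind(m[, 1], m[, 1])
  r3 <- paired_tests_bonferroni(same)
  expect_equal(r3$t, 0)
  expect_equal(r3$p_corrected, 1)
})

test_that("posterior predictive check is self-consistent", {
  set.seed(207)
  p <- ddm_params(c(taste = 0.0163, health = 0.005))
  beh <- sim_subject("food", "NC", params = p)
  fit <- list(params = p, task = "food", data = beh,
              control = ddm_fit_control(), payoff_reference = 20,
              n_trials = nrow(beh))
  class(fit) <- "ddm_fit"
  ppc <- posterior_predictive_check(fit, n_rep = 50)
  for (a in names(ppc$p_yes))
    expect_lt(max(abs(ppc$p_yes[[a]]$observed - ppc$p_yes[[a]]$predicted)),
              0.2)
  expect_true(all(diff(ppc$rt_quantiles$predicted) >= 0))
  expect_true(all(diff(ppc$rt_quantiles$observed) >= 0))
  # predicted acceptance monotone in the positively weighted attribute
  tastecurve <- ppc$p_yes$taste$predicted
  expect_true(all(diff(tastecurve) > 0))
})

test_that("success scores combine choice- and weight-based contrasts", {
  set.seed(208)
  conds <- c("NC", "HC", "TC")
  pars <- list(NC = mean_params("food", "NC"),
               HC = mean_params("food", "HC"),
               TC = mean_params("food", "TC"))
  stim <- gen_stimuli("food")
  beh <- gen_behavior(pars, stim, 1, "food")
  fits <- lapply(pars, function(p)
    structure(list(params = p, task = "food"), class = "ddm_fit"))
  sc <- success_scores(beh, fits, task = "food")
  expect_true(all(c("d_choice_HC_NC", "dw_health_HC_NC") %in% names(sc)))
  expect_equal(sc$dw_health_HC_NC, 0.0121 - (-0.0003))
  # the health-goal cohort chooses healthier under HC than NC
  expect_gt(sc$d_choice_HC_NC, 0)
  expect_true(all(abs(sc[grep("d_choice", names(sc))]) <= 100))
})
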