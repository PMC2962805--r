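test_that("intercept-only fit has the closed-form MLE and log-likelihood", {
  y <- rep(c(1, 0), c(20, 60))
  f <- fit_logistic(y, matrix(1, 80, 1))
  expect_equal(unname(f$coefficients), log(0.25 / 0.75), tolerance = 1e-9)
  expect_equal(f$loglik, 80 * (0.25 * log(0.25) + 0.75 * log(0.75)),
               tolerance = 1e-9)
  expect_true(f$converged)
  expect_lte(f$loglik, 0)
})

test_that("binary-covariate slope equals the 2x2-table log odds ratio", {
  # layout (a, b, c, d) = (30, 70, 50, 50): slope = log(30*50 / (70*50))
  y <- c(rep(1, 30), rep(0, 50), rep(1, 70), rep(0, 50))
  x <- c(rep(1, 80), rep(0, 120))
  f <- fit_logistic(y, cbind(1, x = x))
  expect_equal(unname(f$coefficients["x"]), log((30 * 50) / (70 * 50)),
               tolerance = 1e-8)
})

test_that("fits agree with glm() on random data", {
  set.seed(40)
  X <- cbind(1, rnorm(300), rbinom(300, 2, 0.3))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- rbinom(300, 1, plogis(-0.5 + 0.4 * X[, 2] - 0.3 * X[, 3]))
  f <- fit_logistic(y, X)
  g <- stats::glm(y ~ X[, 2] + X[, 3], family = stats::binomial())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-7)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_logistic(rep(1, 10), matrix(1, 10, 1)), "single class")
  X <- cbind(`(Intercept)` = 1, a = rnorm(20), b = 0)
  X <- cbind(X, a2 = X[, "a"])
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(y, X), "rank deficient")
})

test_that("likelihood-ratio tests have the chi-square calibration", {
  mkfit <- function(ll, df) {
    structure(list(loglik = ll, df = df, converged = TRUE),
              class = "logistic_fit")
  }
  lrt0 <- likelihood_ratio_test(mkfit(-100, 1), mkfit(-100, 2), df = 1)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)

  # statistic at the 5% critical value of chi-square(1)
  lrt <- likelihood_ratio_test(mkfit(-100, 1),
                               mkfit(-100 + 3.841459 / 2, 2), df = 1)
  expect_equal(lrt$p_value, 0.05, tolerance = 1e-6)

  # optimizer-failure signal
  expect_error(likelihood_ratio_test(mkfit(-100, 1), mkfit(-101, 2)),
               "below the null")
})

test_that("trend test equals an independent optimizer at tight tolerance", {
  set.seed(41)
  m <- disease_model(het_grr = 1.5, risk_allele_freq = 0.3)
  cc <- sample_case_control_genotypes(m, 150, 150)
  y <- rep(c(1, 0), c(150, 150))
  g <- c(cc$case, cc$control)
  r <- trend_test(y, g)
  X <- cbind(1, g)
  o <- optim(c(0, 0), neg_loglik_logistic, y = y, X = X, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(r$odds_ratio, exp(o$par[2]), tolerance = 1e-6)
  expect_equal(r$statistic, max(
    0, 2 * (-o$value - fit_logistic(y, X[, 1, drop = FALSE])$loglik)
  ), tolerance = 1e-6)
})

test_that("trend test handles degenerate SNPs and covariate perturbations", {
  y <- rep(c(1, 0), c(30, 30))
  r <- trend_test(y, rep(2, 60))
  expect_equal(r$status, "degenerate")
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$odds_ratio))

  set.seed(42)
  g <- sample(0:2, 400, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  yy <- rbinom(400, 1, plogis(-0.3 + 0.3 * g))

  # axis-rescaling invariance of the LRT
  x <- rnorm(400)
  r1 <- trend_test(yy, g, covariates = cbind(ax = x))
  r2 <- trend_test(yy, g, covariates = cbind(ax = 1000 * x))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)

  # a covariate orthogonal to y and g barely moves the statistic
  x_orth <- residuals(lm(rnorm(400) ~ yy + g))
  r3 <- trend_test(yy, g, covariates = cbind(ax = x_orth))
  r0 <- trend_test(yy, g)
  expect_lt(abs(r3$statistic - r0$statistic), 0.1)
})

test_that("alternative genotype codings recode the dosage", {
  y <- rep(c(1, 0), 30)
  g <- rep(c(0, 1, 2), 20)
  r_dom <- trend_test(y, g, coding = "dominant")
  r_man <- trend_test(y, as.integer(g > 0))
  expect_equal(r_dom$statistic, r_man$statistic)
  r_rec <- trend_test(y, g, coding = "recessive")
  r_man2 <- trend_test(y, as.integer(g == 2))
  expect_equal(r_rec$statistic, r_man2$statistic)
})

test_that("null coefficients stay near zero on permuted labels", {
  set.seed(43)
  x <- rnorm(400)
  y <- sample(rep(c(0, 1), 200))
  f <- fit_logistic(y, cbind(1, x = x))
  # SE of the slope is about 2/sqrt(n) at balanced y
  expect_lt(abs(f$coefficients["x"]), 3 * 2 / sqrt(400))
})
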