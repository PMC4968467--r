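test_that("balanced one-way fits match the closed-form ML solution", {
  set.seed(71)
  for (cfg in list(c(5, 4), c(8, 6), c(14, 42))) {
    d <- make_oneway(cfg[1], cfg[2], mu = 2, sd_b = 0.3, sd_e = 0.5)
    fit <- fit_lmm(y ~ 1, d)
    oracle <- balanced_oneway_ml(d$y, d$participant)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
    expect_equal(fit$sigma2_resid, oracle$sigma2_resid, tolerance = 1e-6)
    expect_equal(fit$sigma2_group, oracle$sigma2_group, tolerance = 1e-5)
    expect_equal(unname(fit$coefficients[1]), mean(d$y), tolerance = 1e-8)
  }
})

test_that("profiled fits agree with a brute-force joint-likelihood oracle", {
  set.seed(72)
  for (r in 1:20) {
    d <- make_lmm_data(g = 5, m = 6)
    fit <- fit_lmm(y ~ x + f, d)
    X <- model.matrix(~ x + f, d)
    oracle <- brute_force_ml(X, d$y, d$participant)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-6)
  }
})

test_that("fits agree with the reference mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(73)
  d <- make_lmm_data(g = 10, m = 12)
  fit <- fit_lmm(y ~ x + f, d)
  ref <- lme4::lmer(y ~ x + f + (1 | participant), data = d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-7)
  expect_equal(fit$AIC, stats::AIC(ref), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_group, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-4)
})

test_that("AIC identity holds and boundary fits reduce to OLS", {
  set.seed(74)
  # no between-group variance: the random intercept collapses
  d <- data.frame(participant = rep(1:8, each = 10), x = rnorm(80))
  d$y <- 1 + 0.3 * d$x + rnorm(80, 0, 0.5)
  fit <- fit_lmm(y ~ x, d)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$n_params)
  if (fit$singular) {
    ols <- lm(y ~ x, d)
    expect_equal(fit$sigma2_group, 0)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ols)),
                 tolerance = 1e-8)
  }
  # a fit with real grouping structure also satisfies the identity
  d2 <- make_oneway(6, 9, sd_b = 0.6, sd_e = 0.3)
  fit2 <- fit_lmm(y ~ 1, d2)
  expect_equal(fit2$AIC, -2 * fit2$loglik + 2 * fit2$n_params)
  expect_false(fit2$singular)
  expect_true(fit2$sigma2_group > 0 && fit2$sigma2_resid > 0)
})

test_that("likelihood-ratio tests behave and check nesting", {
  set.seed(75)
  d <- make_lmm_data(g = 8, m = 10)
  full <- fit_lmm(y ~ x + f, d)
  red <- fit_lmm(y ~ x, d)
  out <- lrt(full, red)
  expect_gte(out$chi2, 0)
  expect_equal(out$df, 1)
  expect_true(out$p >= 0 && out$p <= 1)
  # identical models: zero deviance change, p = 1
  same <- lrt(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # non-nested pair rejected
  other <- fit_lmm(y ~ f, d)
  expect_error(lrt(other, red), "not nested")
  # different data rejected
  d2 <- d
  d2$y <- d2$y + 1
  expect_error(lrt(full, fit_lmm(y ~ x, d2)), "different response")
})

test_that("LRT statistics are invariant to affine predictor recoding", {
  set.seed(76)
  d <- make_lmm_data(g = 8, m = 10)
  chi_raw <- lrt(fit_lmm(y ~ x + f, d), fit_lmm(y ~ f, d))$chi2
  d$x2 <- 100 * d$x - 7
  chi_rec <- lrt(fit_lmm(y ~ x2 + f, d), fit_lmm(y ~ f, d))$chi2
  expect_equal(chi_raw, chi_rec, tolerance = 1e-6)
})

test_that("orthogonal polynomial coding is orthonormal and equivalent", {
  x <- rep(c(1, 10, 20, 30, 40, 50, 60), times = 12)
  B <- orthogonal_poly(x, 2)
  expect_equal(ncol(B), 2L)
  expect_lt(abs(sum(B[, 1] * B[, 2])), 1e-10)
  expect_lt(abs(sum(B[, 1])), 1e-10)
  expect_lt(abs(sum(B[, 2])), 1e-10)
  expect_equal(abs(cor(B[, 1], x - mean(x))), 1, tolerance = 1e-12)
  expect_error(orthogonal_poly(rep(1, 10), 2), "distinct")

  # raw vs orthogonal coding: identical likelihood
  set.seed(77)
  d <- data.frame(participant = rep(1:7, each = 14),
                  set_size = rep(c(1, 10, 20, 30, 40, 50, 60), 14))
  d$y <- 2 + 0.03 * d$set_size - 3e-4 * d$set_size^2 +
    rep(rnorm(7, 0, 0.3), each = 14) + rnorm(98, 0, 0.3)
  f_orth <- fit_lmm(y ~ poly(set_size, 2), d)
  f_raw <- fit_lmm(y ~ set_size + I(set_size^2), d)
  expect_equal(f_orth$loglik, f_raw$loglik, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- make_lmm_data(g = 4, m = 5)
  expect_error(fit_lmm(y ~ x, d, group = "nope"), "not found")
  d1 <- d
  d1$participant <- 1
  expect_error(fit_lmm(y ~ x, d1), "at least 2 groups")
  d$x_dup <- d$x
  expect_error(fit_lmm(y ~ x + x_dup, d), "rank deficient")
})

test_that("predictions reproduce the fitted design and handle new data", {
  set.seed(78)
  d <- data.frame(participant = rep(1:6, each = 14),
                  set_size = rep(c(1, 10, 20, 30, 40, 50, 60), 12),
                  coloration = rep(c("parallel", "binary"), each = 7,
                                   times = 6))
  d$y <- 1 + 0.02 * d$set_size + 0.3 * (d$coloration == "parallel") +
    rep(rnorm(6, 0, 0.2), each = 14) + rnorm(84, 0, 0.2)
  d$coloration <- factor(d$coloration)
  fit <- fit_lmm(y ~ poly(set_size, 2) + coloration, d)
  expect_equal(predict(fit), predict(fit, d), tolerance = 1e-10)
  # the orthogonal-poly basis must be anchored to the fitted data
  sub <- d[1:3, ]
  expect_equal(predict(fit, sub), predict(fit)[1:3], tolerance = 1e-10)
})
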