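test_that("censored response containers validate their invariants", {
  r <- mixed_censored_fixture()
  expect_identical(r$tag, c("exact", "left", "right", "interval"))
  expect_error(cens_response(1, 0), "invalid bounds")
  expect_error(cens_response(1, 2, "exact"), "invalid bounds")
  expect_error(ordinal_response(5, 4), "1..4")
  # tags are inferred from the bounds
  expect_identical(cens_response(c(1, -Inf), c(1, 2))$tag, c("exact", "left"))
})

test_that("log-likelihood contributions: closed forms and degenerate cases", {
  lm0 <- trafo_model("probit", linear_basis(c(-10, 10)), c(0, 1), 0)
  # Lm, exact y = 0, x = 0: log phi(0) = -0.5 log(2 pi)
  expect_equal(log_lik(lm0, cens_response(0), matrix(0, 1, 1)),
               -0.918939, tolerance = 1e-6)
  # uninformative interval (-Inf, Inf] contributes 0 for any model/link
  for (nm in c("probit", "logit", "mev")) {
    m <- fixture_model(nm)
    expect_equal(log_lik(m, cens_response(-Inf, Inf, "interval"),
                         matrix(0, 1, 2)), 0)
  }
})

test_that("exact contribution is the limit of a shrinking interval", {
  m <- fixture_model("logit")
  x <- matrix(c(0.3, -1), 1)
  y <- 0.7; eps <- 1e-6
  exact <- log_lik(m, cens_response(y), x)
  intv <- log_lik(m, cens_response(y - eps, y, "interval"), x)
  expect_equal(intv - log(eps), exact, tolerance = 1e-3)
})

test_that("score residuals match the closed forms of the augmented score", {
  # 3 links x 4 censoring types against the finite-difference oracle
  resp <- mixed_censored_fixture()
  x <- matrix(c(0.3, -1, 0.5, 0.2, -0.7, 1.1, 0, 0.4), 4, 2)
  for (nm in c("probit", "logit", "mev")) {
    m <- fixture_model(nm)
    r <- score_residuals(m, resp, x)
    fd <- fd_score_residual(m, resp, x)
    expect_lt(max(abs(r - fd)), 1e-6)
  }
  # probit, exact, latent value 0 -> residual 0
  m <- trafo_model("probit", linear_basis(c(-10, 10)), c(0, 1), 0)
  expect_equal(score_residuals(m, cens_response(0), matrix(0, 1, 1)), 0)
})

test_that("ordinal score residuals match the finite-difference oracle", {
  K <- 5
  m <- trafo_model("logit", ordinal_basis(K), c(-2, -0.5, 0.5, 2), c(0.8))
  resp <- ordinal_response(1:5, K)
  x <- matrix(seq(-1, 1, length.out = 5), 5, 1)
  expect_lt(max(abs(score_residuals(m, resp, x) -
                      fd_score_residual(m, resp, x))), 1e-6)
})

test_that("mev-link residuals are signed martingale residuals", {
  set.seed(8)
  bs <- bernstein_basis(4, c(0, 6))
  m <- trafo_model("mev", bs, theta_from_free(c(-2, rep(0.5, 4))), 0.5)
  y <- runif(50, 0.5, 5)
  tag <- ifelse(seq_len(50) %% 2 == 0, "right", "exact")
  resp <- cens_response(y, ifelse(tag == "right", Inf, y), tag)
  x <- matrix(rnorm(50), 50)
  # Lambda-hat = exp(h) at the observed time
  h <- drop(eval_basis(bs, y) %*% m$theta) - x[, 1] * 0.5
  Lam <- exp(h)
  delta <- as.numeric(tag == "exact")
  r <- score_residuals(m, resp, x)
  expect_equal(r, Lam - delta, tolerance = 1e-10)
  mg <- martingale_residuals(m, resp, x)
  expect_equal(mg, delta - Lam, tolerance = 1e-10)
  expect_true(all(mg <= 1))
  expect_error(martingale_residuals(fixture_model("probit"), resp, x), "mev")
})

test_that("Lm maximum likelihood equals the OLS oracle", {
  fx <- gaussian_fixture(n = 200, seed = 11)
  f <- fit_tm(fx$y, fx$x, link = "probit", basis = fx$basis, gtol = 1e-8)
  expect_true(f$converged)
  ols <- stats::lm(fx$y ~ fx$x)
  cl <- coef_lm(f)
  expect_equal(cl$slopes, unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(cl$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
  sig_mle <- sqrt(mean(stats::residuals(ols)^2))  # divisor n
  expect_equal(cl$sigma, sig_mle, tolerance = 1e-6)
  # score residuals at the MLE are the scaled least-squares residuals
  r <- score_residuals(f$model, fx$y, fx$x)
  expect_equal(r, unname(stats::residuals(ols)) / sig_mle, tolerance = 1e-5)
  # interior MLE on exact data: residuals sum to zero
  expect_lt(abs(sum(r)), 1e-6)
})

test_that("unconditional ordinal MLE equals empirical cumulative quantiles", {
  set.seed(12)
  K <- 6
  y <- sample(1:K, 400, replace = TRUE, prob = c(1, 2, 3, 3, 2, 1))
  f <- fit_tm(ordinal_response(y, K), NULL, link = "logit", gtol = 1e-8)
  emp <- stats::qlogis(cumsum(tabulate(y, K))[-K] / length(y))
  expect_equal(f$model$theta, emp, tolerance = 1e-6)
})

test_that("degenerate and undersized data are rejected", {
  all_flat <- cens_response(rep(-Inf, 30), rep(Inf, 30), rep("interval", 30))
  expect_error(fit_tm(all_flat, NULL, basis = bernstein_basis(4, c(0, 1))),
               "constant")
  expect_error(fit_tm(rnorm(3), matrix(rnorm(9), 3),
                      basis = bernstein_basis(6, c(-3, 3))),
               "at least")
})

test_that("score residuals have near-zero mean at the MLE across replicates", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 300
    x <- matrix(rnorm(n))
    y <- drop(0.5 * x + rnorm(n))
    tag <- ifelse(runif(n) < 0.2, "right", "exact")
    resp <- cens_response(y, ifelse(tag == "right", Inf, y), tag)
    f <- fit_tm(resp, x, link = "probit", order = 4)
    r <- score_residuals(f$model, resp, x)
    expect_lt(abs(mean(r)), 3 / sqrt(n))
  }
})

test_that("prediction: CDF/quantile round trip and closed forms", {
  fx <- gaussian_fixture(n = 150, seed = 14)
  f <- fit_tm(fx$y, fx$x, link = "probit", basis = fx$basis)
  cl <- coef_lm(f)
  x0 <- fx$x[3, ]
  # Gaussian median = conditional mean
  expect_equal(predict_quantile(f$model, 0.5, x0),
               cl$intercept + sum(x0 * cl$slopes), tolerance = 1e-7)
  # Bernstein model round trip at several probabilities
  m <- fixture_model("logit")
  for (p in c(0.1, 0.5, 0.9)) {
    q <- predict_quantile(m, p, c(0.2, -0.4))
    expect_lt(abs(predict_cdf(m, q, c(0.2, -0.4)) - p), 1e-6)
  }
  # known transformation: CDF equals F_Z(h) on a grid
  cfg <- scenario_preset("iv1")
  grid <- seq(-2, 2, length.out = 51)
  hval <- drop(eval_basis(cfg$response_basis, grid) %*% cfg$theta) - 0.7 * 1
  mtrue <- trafo_model("probit", cfg$response_basis, cfg$theta, 1)
  expect_equal(predict_cdf(mtrue, grid, 0.7), stats::pnorm(hval),
               tolerance = 1e-8)
  expect_error(predict_quantile(m, 1.2, c(0, 0)), "strictly inside")
})

test_that("vcov_beta gives plausible standard errors", {
  fx <- gaussian_fixture(n = 400, seed = 15)
  f <- fit_tm(fx$y, fx$x, link = "probit", basis = fx$basis)
  V <- vcov_beta(f)
  ols <- stats::lm(fx$y ~ fx$x)
  se_ols <- summary(ols)$coefficients[-1, 2]
  # beta = slope/sigma; delta-method scale comparison within 15%
  expect_equal(unname(sqrt(diag(V)) * coef_lm(f)$sigma), unname(se_ols),
               tolerance = 0.15)
})
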