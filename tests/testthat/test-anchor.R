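test_that("anchor design: encoding, centering, projector algebra", {
  set.seed(21)
  n <- 40
  g <- factor(rep(c("a", "b"), each = n / 2))
  ad <- anchor_design(g)
  expect_lt(max(abs(colMeans(ad$encoded))), 1e-10)
  # balanced binary anchor: projection recovers centered group means
  v <- rnorm(n)
  pv <- project_anchors(ad, v)
  gm <- ave(v, g) - mean(v)
  expect_equal(pv, gm, tolerance = 1e-10)
  # projector is symmetric and idempotent
  P <- project_anchors(ad, diag(n))
  expect_lt(max(abs(P - t(P))), 1e-8)
  expect_lt(max(abs(P %*% P - P)), 1e-8)
  expect_lte(ad$rank, ncol(ad$encoded))
})

test_that("anchor design: rank deficiency and orthogonal complements", {
  set.seed(22)
  n <- 30
  A <- matrix(rnorm(n * 2), n)
  P1 <- project_anchors(anchor_design(A), diag(n))
  P2 <- project_anchors(anchor_design(cbind(A, A[, 1])), diag(n))
  expect_lt(max(abs(P1 - P2)), 1e-8)
  # v orthogonal to all encoded columns projects to zero
  ad <- anchor_design(A)
  v <- rnorm(n)
  v <- v - project_anchors(ad, v)
  expect_lt(max(abs(project_anchors(ad, v))), 1e-10)
  expect_error(anchor_design(rep(2, 10)), "no variation")
})

test_that("linear L2 anchor regression: gamma limits", {
  fx <- anchor_fixture()
  Xi <- cbind(1, fx$X)
  # gamma = 1: OLS of y on X
  expect_equal(unname(l2_anchor_fit(fx$y, Xi, fx$design, 1)),
               unname(coef(stats::lm(fx$y ~ fx$X))), tolerance = 1e-10)
  # gamma = 0: partialling out (X-coefficients of OLS of y on X and A)
  joint_x <- unname(coef(stats::lm(fx$y ~ fx$X + fx$A))[2:4])
  expect_equal(unname(l2_anchor_fit(fx$y, Xi, fx$design, 0))[2:4], joint_x,
               tolerance = 1e-8)
  # gamma -> Inf: two-stage least squares on a just-identified valid-IV
  # simulation (q = p so the 2SLS oracle is well defined)
  set.seed(43)
  n <- 400
  A2 <- matrix(rnorm(n * 2), n)
  H2 <- rnorm(n)
  X2 <- A2 + H2 + matrix(rnorm(n * 2), n)
  y2 <- drop(X2 %*% c(1, -1)) + 2 * H2 + rnorm(n)
  des2 <- anchor_design(A2)
  Xi2 <- cbind(1, X2)
  Ahat <- cbind(1, A2)
  Xhat <- Ahat %*% solve(crossprod(Ahat), crossprod(Ahat, Xi2))
  b2sls <- drop(solve(crossprod(Xhat, Xi2), crossprod(Xhat, y2)))
  expect_equal(unname(l2_anchor_fit(y2, Xi2, des2, 1e8)), b2sls,
               tolerance = 1e-3)
  expect_error(l2_anchor_fit(fx$y, cbind(Xi, Xi[, 2]), fx$design, 1),
               "singular")
})

test_that("anchor loss reduces to the NLL when the penalty vanishes", {
  fx <- gaussian_fixture(n = 120, seed = 23)
  f <- fit_tm(fx$y, fx$x, link = "probit", basis = fx$basis)
  set.seed(24)
  A <- matrix(rnorm(240), 120)
  des <- anchor_design(A)
  l0 <- anchor_loss(f$model, fx$y, fx$x, des, xi = 0)
  expect_equal(as.numeric(l0), f$nll, tolerance = 1e-10)
  expect_equal(attr(l0, "penalty"), 0)
  # anchors orthogonal to the residuals: loss equals NLL for every xi
  r <- score_residuals(f$model, fx$y, fx$x)
  a_orth <- stats::residuals(stats::lm(rnorm(120) ~ r))
  des_o <- anchor_design(a_orth)
  for (xi in c(0, 5, 50)) {
    l <- anchor_loss(f$model, fx$y, fx$x, des_o, xi = xi)
    expect_equal(as.numeric(l), f$nll, tolerance = 1e-12)
  }
  expect_gte(attr(anchor_loss(f$model, fx$y, fx$x, des, 3), "penalty"), 0)
})

test_that("penalized objective gradient matches finite differences", {
  set.seed(25)
  n <- 60
  A <- matrix(rnorm(n * 2), n)
  X <- matrix(rnorm(n * 2), n)
  resp <- mixed_censored_fixture()
  resp <- cens_response(rep(resp$lower, length.out = n),
                        rep(resp$upper, length.out = n),
                        rep(resp$tag, length.out = n))
  des <- anchor_design(A)
  for (nm in c("probit", "logit", "mev")) {
    prep <- anchortm:::prepare_tm_data(resp, X, bernstein_basis(4, c(-6, 6)))
    obj <- anchortm:::tm_objective(prep, make_link(nm), design = des, xi = 3)
    par <- c(-1, rep(0.2, 4), 0.3, -0.2)
    gfd <- vapply(seq_along(par), function(i) {
      e <- rep(0, length(par)); e[i] <- 1e-6
      (obj$nll(par + e) - obj$nll(par - e)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(obj$grad(par) - gfd)), 1e-6)
  }
})

test_that("Lm anchor TM is equivalent to linear L2 anchor regression", {
  # Example-4 equivalence: xi = (gamma - 1) / 2
  cfg <- scenario_preset("la")
  sim <- simulate_scenario(cfg, 300, seed = 26)
  des <- anchor_design(sim$A)
  bas <- linear_basis(default_support(sim$y))
  Xi <- cbind(1, sim$X)
  start <- NULL
  for (xi in c(0, 2, 6, 20)) {
    fa <- fit_anchor_tm(sim$response, sim$X, des, xi = xi, link = "probit",
                        basis = bas, start = start)
    start <- fa$par
    cl <- coef_lm(fa)
    bl <- unname(l2_anchor_fit(sim$y, Xi, des, gamma = 2 * xi + 1))
    expect_equal(c(cl$intercept, cl$slopes), bl, tolerance = 1e-4)
  }
})

test_that("fit_anchor_tm: xi = 0 equals the MLE; huge xi decorrelates", {
  cfg <- scenario_preset("la")
  sim <- simulate_scenario(cfg, 300, seed = 27)
  des <- anchor_design(sim$A)
  bas <- linear_basis(default_support(sim$y))
  fm <- fit_tm(sim$response, sim$X, link = "probit", basis = bas)
  f0 <- fit_anchor_tm(sim$response, sim$X, des, xi = 0, link = "probit",
                      basis = bas)
  expect_equal(coef(f0), coef(fm), tolerance = 1e-6)
  fb <- fit_anchor_tm(sim$response, sim$X, des, xi = 1e4, link = "probit",
                      basis = bas, start = f0$par)
  expect_true(fb$converged)
  expect_lt(max(abs(fb$residual_anchor_corr)), 0.01)
})

test_that("xi_path: warm starts, monotone penalty, iv1 bias direction", {
  cfg <- scenario_preset("la")
  sim <- simulate_scenario(cfg, 250, seed = 28)
  des <- anchor_design(sim$A)
  bas <- linear_basis(default_support(sim$y))
  # singleton grid reduces to the MLE
  p1 <- xi_path(sim$response, sim$X, des, xi_grid = 0, link = "probit",
                basis = bas)
  expect_length(p1, 1L)
  expect_equal(coef(p1[[1]]),
               coef(fit_tm(sim$response, sim$X, link = "probit",
                           basis = bas)), tolerance = 1e-6)
  # penalty non-increasing along an ascending grid
  grid <- c(0, 1, 5, 20, 100)
  pa <- xi_path(sim$response, sim$X, des, xi_grid = grid, link = "probit",
                basis = bas)
  pen <- vapply(pa, function(f) f$penalty / f$xi, numeric(1))  # ||Pi r||^2/n
  pen[1] <- sum(project_anchors(des,
    score_residuals(pa[[1]]$model, sim$response, sim$X))^2) / 250
  expect_true(all(diff(pen) <= 1e-6))
  # iv1: coefficient moves monotonically away from its MLE value
  cfg2 <- scenario_preset("iv1")
  sim2 <- simulate_scenario(cfg2, 600, seed = 29)
  des2 <- anchor_design(sim2$A)
  pb <- xi_path(sim2$response, sim2$X, des2, xi_grid = c(0, 1, 10, 100),
                link = "probit")
  betas <- vapply(pb, function(f) f$model$beta, numeric(1))
  steps <- diff(betas)
  expect_true(all(steps > 0) || all(steps < 0))
})
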