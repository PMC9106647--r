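test_that("simulation is bit-identical for identical config and seed", {
  cfg <- scenario_preset("la")
  s1 <- simulate_scenario(cfg, 100, seed = 31)
  s2 <- simulate_scenario(cfg, 100, seed = 31)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$X, s2$X)
  expect_identical(s1$A, s2$A)
  s3 <- simulate_scenario(cfg, 100, seed = 32)
  expect_false(identical(s1$y, s3$y))
})

test_that("disconnected anchors leave (Y, X) unchanged under do-interventions", {
  cfg <- scenario_preset("la")
  cfg$M_X[] <- 0; cfg$M_H[] <- 0; cfg$M_Y[] <- 0
  s0 <- simulate_scenario(apply_intervention(cfg, "do", 0), 500, seed = 33)
  s5 <- simulate_scenario(apply_intervention(cfg, "do", 5), 500, seed = 33)
  expect_identical(s0$y, s5$y)
  expect_identical(s0$X, s5$X)
  expect_false(identical(s0$A, s5$A))
})

test_that("probability integral transform: F_Z(h(Y| parents)) is uniform", {
  cfg <- scenario_preset("iv1")
  sim <- simulate_scenario(cfg, 1e4, seed = 34)
  h <- drop(eval_basis(cfg$response_basis, sim$y) %*% cfg$theta) -
    drop(sim$X %*% cfg$beta) - drop(sim$H %*% cfg$B_YH)
  expect_gt(stats::ks.test(stats::pnorm(h), "punif")$p.value, 0.01)
  # same check for the linear la transformation
  cfgl <- scenario_preset("la")
  siml <- simulate_scenario(cfgl, 1e4, seed = 35)
  hl <- cfgl$theta[1] + cfgl$theta[2] * siml$y - drop(siml$X %*% cfgl$beta) -
    drop(siml$H %*% cfgl$B_YH) - drop(siml$A %*% cfgl$M_Y)
  expect_gt(stats::ks.test(stats::pnorm(hl), "punif")$p.value, 0.01)
})

test_that("scenario presets carry the stated settings", {
  expect_equal(scenario_preset("iv2")$beta, 0.5)
  la <- scenario_preset("la")
  expect_identical(la$n_train, 300L)
  expect_identical(la$n_test, 2000L)
  expect_equal(la$beta[2:3], c(1, 1))
  expect_true(all(la$beta[-(2:3)] == 0))
  iv1 <- scenario_preset("iv1")
  expect_identical(iv1$n_train, 1000L)
  expect_equal(iv1$default_test_intervention,
               list(kind = "do", value = 3.6))
  # valid-instrument structure: no anchor path to H or Y
  for (nm in c("iv1", "iv2")) {
    cfg <- scenario_preset(nm)
    expect_true(all(cfg$M_H == 0))
    expect_true(all(cfg$M_Y == 0))
  }
  expect_error(scenario_preset("xyz"))
})

test_that("iv2 produces ordinal classes in 1..K", {
  sim <- simulate_scenario(scenario_preset("iv2", overrides = list(K = 10)),
                           2000, seed = 36)
  expect_true(all(sim$y %in% 1:10))
  expect_identical(sim$response$n_classes, 10L)
  sim4 <- simulate_scenario(scenario_preset("iv2", overrides = list(K = 4)),
                            500, seed = 36)
  expect_true(all(sim4$y %in% 1:4))
})

test_that("interventions: do fixes anchors, zero push leaves the law", {
  cfg <- scenario_preset("iv1")
  sdo <- simulate_scenario(apply_intervention(cfg, "do", 3.6), 200, seed = 37)
  expect_true(all(sdo$A == 3.6))
  # push with the training law reproduces the training anchors (same seed)
  cfgl <- scenario_preset("la")
  spush <- simulate_scenario(
    apply_intervention(cfgl, "push", list(kind = "normal", mean = 0, sd = 1)),
    200, seed = 38)
  sref <- simulate_scenario(cfgl, 200, seed = 38)
  expect_identical(spush$A, sref$A)
})

test_that("do-intervention shifts E[X] by M_X times the anchor change", {
  cfg <- scenario_preset("iv1")
  s0 <- simulate_scenario(apply_intervention(cfg, "do", 0), 1e4, seed = 39)
  s36 <- simulate_scenario(apply_intervention(cfg, "do", 3.6), 1e4, seed = 40)
  shift <- mean(s36$X) - mean(s0$X)
  expect_equal(shift, cfg$M_X[1, 1] * 3.6, tolerance = 0.1)
})

test_that("anchors are exogenous: uncorrelated with the structural noise", {
  cfg <- scenario_preset("la")
  sim <- simulate_scenario(cfg, 5e3, seed = 41)
  n <- length(sim$y)
  eps_H <- sim$H - sim$A %*% t(cfg$M_H)             # reconstructed noise
  eps_X <- sim$X - sim$H %*% t(cfg$B_XH) - sim$A %*% t(cfg$M_X)
  z <- cfg$theta[1] + cfg$theta[2] * sim$y - drop(sim$X %*% cfg$beta) -
    drop(sim$H %*% cfg$B_YH) - drop(sim$A %*% cfg$M_Y)
  for (v in list(eps_H, eps_X[, 4], z))
    expect_lt(max(abs(stats::cor(sim$A, v))), 3 / sqrt(n))
})

test_that("out-of-range latent targets trigger the rejection guard", {
  basis <- bernstein_basis(3, c(-0.3, 0.3))   # tiny transformation range
  cfg <- scenario_config("tiny", p = 1, q = 1, d = 1,
                         anchor_law = list(kind = "normal", sd = 1),
                         M_X = 1, M_H = 0, M_Y = 0, B_XH = 0, B_YH = 0,
                         beta = 1, link = "probit", response_basis = basis,
                         theta = theta_from_h(function(y) y, basis),
                         seed = 42)
  expect_error(simulate_scenario(cfg, 500, seed = 42), "1%")
})
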