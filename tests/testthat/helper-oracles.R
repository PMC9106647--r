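# Independent oracles and small fixture builders used across the suite.

# central finite difference of a scalar-to-vector function
fd_central <- function(f, x, eps = 1e-6) (f(x + eps) - f(x - eps)) / (2 * eps)

# finite-difference score residual: derivative of the log-likelihood with
# respect to an added intercept alpha (transformation h - alpha), at 0.
# Exploits that the constant lies in the span of every basis: shifting all
# theta components by -alpha realizes h - alpha exactly.
fd_score_residual <- function(model, response, x, eps = 1e-5) {
  ll <- function(a) {
    m2 <- trafo_model(model$link, model$basis, model$theta - a, model$beta)
    log_lik(m2, response, x)
  }
  (ll(eps) - ll(-eps)) / (2 * eps)
}

# one observation of each censoring type inside (-3, 3)
mixed_censored_fixture <- function() {
  cens_response(lower = c(0.5, -Inf, -1.0, -0.5),
                upper = c(0.5, 1.2, Inf, 1.5),
                tag = c("exact", "left", "right", "interval"))
}

# a generic non-trivial Bernstein model on (-3, 3)
fixture_model <- function(link = "probit", beta = c(0.5, -0.3)) {
  bs <- bernstein_basis(5, c(-3, 3))
  trafo_model(link, bs, theta_from_free(c(-2, rep(0.3, 5))), beta)
}

# exact Gaussian linear data for Lm oracles
gaussian_fixture <- function(n = 200, p = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n)
  y <- drop(1 + x %*% seq(-1, 1, length.out = p) + stats::rnorm(n))
  list(y = y, x = x,
       basis = linear_basis(c(min(y) - 5, max(y) + 5)))
}

# fixed linear-SEM dataset with continuous anchors (t1/t2 setting)
anchor_fixture <- function(n = 200, p = 3, q = 2, seed = 42) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * q), n)
  H <- stats::rnorm(n)
  X <- A %*% matrix(stats::rnorm(q * p), q) + H +
    matrix(stats::rnorm(n * p), n)
  y <- drop(X %*% seq(1, -1, length.out = p)) + 2 * H + drop(A %*% rep(1, q)) +
    stats::rnorm(n)
  list(y = y, X = X, A = A, design = anchor_design(A))
}
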