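#' Scenario configuration for structural equation transformation models
#'
#' Describes the data-generating process
#' \deqn{A \leftarrow \varepsilon_A,\quad
#'   H \leftarrow M_H A + \varepsilon_H,\quad
#'   X \leftarrow B_{XH} H + M_X A + \varepsilon_X,\quad
#'   Y \leftarrow h^{-1}(Z \mid X, H, A),\ Z \sim F_Z,}
#' with transformation \eqn{h(y) = b(y)^\top\theta - \beta^\top X - B_{YH} H
#' - M_Y A} (or, for scenario `nla`, a response generated directly on the
#' observation scale as \eqn{Y = f(X) + B_{YH} H + M_Y A + \varepsilon_Y}).
#' `X`-`X` and `H`-`H` couplings are zero, matching the simulation settings.
#'
#' @param name scenario label.
#' @param p,q,d numbers of covariates, anchors and hidden confounders.
#' @param anchor_law a list: `list(kind = "normal", sd = )`,
#'   `list(kind = "binary", prob = , levels = c(0, 1))` or
#'   `list(kind = "const", value = )`.
#' @param M_X,M_H,M_Y anchor effect blocks (`p x q`, `d x q`, length-`q`).
#' @param B_XH,B_YH confounder effect blocks (`p x d`, length-`d`).
#' @param beta causal shift coefficients (length `p`), or `NULL` when `f`
#'   is given.
#' @param f optional non-linear causal function of the covariate matrix
#'   (used instead of `beta`; response then generated directly with
#'   Gaussian noise `sd_Y`).
#' @param link link name for the latent scale.
#' @param response_basis a [basis_spec] for the transformation (continuous
#'   kinds), or an ordinal basis with `n_classes = K`.
#' @param theta baseline coefficients of the generating transformation;
#'   for a Bernstein basis these are conventionally fixed by applying an
#'   analytic `h_fun` to `P + 1` evenly spaced points of the support (see
#'   [theta_from_h]).
#' @param sd_X,sd_H,sd_Y Gaussian noise standard deviations.
#' @param intervention `NULL`, or a list created by [apply_intervention].
#' @param n_train,n_test default sample sizes.
#' @param seed mandatory base seed for [simulate_scenario].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name, p, q, d, anchor_law,
                            M_X, M_H, M_Y, B_XH, B_YH,
                            beta = NULL, f = NULL,
                            link = "probit", response_basis, theta = NULL,
                            sd_X = 1, sd_H = 1, sd_Y = 1,
                            intervention = NULL,
                            n_train = 300L, n_test = 2000L, seed = 1L) {
  M_X <- matrix(M_X, nrow = p, ncol = q)
  M_H <- matrix(M_H, nrow = d, ncol = q)
  M_Y <- rep_len(as.numeric(M_Y), q)
  B_XH <- matrix(B_XH, nrow = p, ncol = d)
  B_YH <- rep_len(as.numeric(B_YH), d)
  if (is.null(beta) && is.null(f))
    stop2("one of 'beta' or 'f' must be given")
  if (!is.null(beta)) beta <- rep_len(as.numeric(beta), p)
  if (is.null(seed)) stop2("a 'seed' is mandatory in a scenario config")
  structure(list(name = name, p = p, q = q, d = d, anchor_law = anchor_law,
                 M_X = M_X, M_H = M_H, M_Y = M_Y, B_XH = B_XH, B_YH = B_YH,
                 beta = beta, f = f, link = link,
                 response_basis = response_basis, theta = theta,
                 sd_X = rep_len(sd_X, p), sd_H = rep_len(sd_H, d),
                 sd_Y = sd_Y, intervention = intervention,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario '%s': p = %d, q = %d, d = %d, link = %s\n",
              x$name, x$p, x$q, x$d, x$link))
  if (!is.null(x$intervention))
    cat("intervention:", x$intervention$kind, "\n")
  invisible(x)
}

#' Baseline coefficients from an analytic transformation
#'
#' Fixes the Bernstein coefficients by applying the analytic transformation
#' `h_fun` to `P + 1` evenly spaced points of the support; the resulting
#' basis approximation to `h_fun` is then used as the exact generating
#' transformation.
#'
#' @param h_fun strictly increasing function.
#' @param basis a Bernstein [basis_spec].
#' @return numeric coefficient vector of length `P + 1`.
#' @export
theta_from_h <- function(h_fun, basis) {
  stopifnot(basis$kind == "bernstein")
  h_fun(seq(basis$support[1L], basis$support[2L], length.out = basis$dim))
}

#' Interventions on the anchor variables
#'
#' A `do`-intervention replaces the anchor law by a constant value; a
#' `push`-intervention replaces (shifts) the anchor distribution. The
#' structural coefficients are untouched.
#'
#' @param config a [scenario_config].
#' @param kind `"do"` or `"push"`.
#' @param value for `do`: the constant anchor value (recycled to length
#'   `q`); for `push`: an anchor-law list as in [scenario_config].
#' @return the modified config.
#' @examples
#' cfg <- scenario_preset("iv1")
#' cfg36 <- apply_intervention(cfg, "do", 3.6)
#' @export
apply_intervention <- function(config, kind = c("do", "push"), value) {
  stopifnot(inherits(config, "scenario_config"))
  kind <- match.arg(kind)
  config$intervention <- if (kind == "do")
    list(kind = "do", value = rep_len(as.numeric(value), config$q))
  else list(kind = "push", law = value)
  config
}

draw_anchors <- function(config, n) {
  law <- if (!is.null(config$intervention)) {
    if (config$intervention$kind == "do")
      list(kind = "const", value = config$intervention$value)
    else config$intervention$law
  } else config$anchor_law
  q <- config$q
  switch(law$kind,
    normal = matrix(stats::rnorm(n * q, mean = law$mean %||% 0,
                                 sd = law$sd %||% 1), n, q),
    binary = {
      lv <- law$levels %||% c(0, 1)
      matrix(lv[1L + stats::rbinom(n * q, 1L, law$prob %||% 0.5)], n, q)
    },
    const = matrix(rep_len(law$value, q), n, q, byrow = TRUE),
    stop2("unknown anchor law '", law$kind, "'"))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Simulate from a structural equation transformation model
#'
#' Draws anchors (honoring any intervention), hidden confounders,
#' covariates and the response. Continuous transformation-model responses
#' are obtained by monotone root-finding \eqn{Y = h^{-1}(Z + \mathrm{shift})}
#' (closed form for the linear basis, bisection to `1e-10` for Bernstein);
#' ordinal responses by threshold comparison on the latent scale. Rows whose
#' latent target falls outside the range of \eqn{b(y)^\top\theta} are
#' resampled (an error is raised if more than 1% of draws are rejected).
#'
#' @param config a [scenario_config].
#' @param n number of observations.
#' @param seed seed; defaults to `config$seed`. Identical config and seed
#'   give bit-identical data.
#' @return a list of class `tm_sim` with elements `response` (a
#'   `tm_response`), `y` (numeric or class vector), `X`, `H`, `A`
#'   (matrices), `config` and `truth` (generating coefficients).
#' @export
simulate_scenario <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"), n >= 1)
  with_seed(seed, {
    sim <- sim_once(config, n)
    rejected <- 0L
    bad <- sim$bad
    while (any(bad)) {
      rejected <- rejected + sum(bad)
      if (rejected > 0.01 * n + 10)
        stop2("more than 1% of simulated draws fall outside the range of ",
              "the generating transformation")
      repl <- sim_once(config, sum(bad))
      for (nm in c("A", "H", "X", "shift", "target"))
        sim[[nm]][bad, ] <- repl[[nm]]
      sim$bad[bad] <- repl$bad
      bad <- sim$bad
    }
    y <- solve_response(config, sim)
    response <- if (response_kind(config) == "ordinal")
      ordinal_response(y, config$response_basis$n_classes)
    else cens_response(y)
    structure(list(response = response, y = y, X = sim$X, H = sim$H,
                   A = sim$A, config = config, n_rejected = rejected,
                   truth = list(beta = config$beta, f = config$f,
                                theta = config$theta,
                                M_X = config$M_X, M_H = config$M_H,
                                M_Y = config$M_Y, B_XH = config$B_XH,
                                B_YH = config$B_YH)),
              class = "tm_sim")
  })
}

# response kind helper attached to the config
response_kind <- function(config) {
  if (!is.null(config$f)) "direct"
  else if (config$response_basis$kind == "ordinal") "ordinal"
  else "trafo"
}

sim_once <- function(config, n) {
  A <- draw_anchors(config, n)
  H <- A %*% t(config$M_H) +
    matrix(stats::rnorm(n * config$d), n) %*% diag(config$sd_H, config$d)
  X <- H %*% t(config$B_XH) + A %*% t(config$M_X) +
    matrix(stats::rnorm(n * config$p), n) %*% diag(config$sd_X, config$p)
  causal <- if (!is.null(config$f)) config$f(X) else drop(X %*% config$beta)
  shift <- causal + drop(H %*% config$B_YH) + drop(A %*% config$M_Y)
  kind <- response_kind(config)
  if (kind == "direct") {
    target <- matrix(shift + config$sd_Y * stats::rnorm(n))
    bad <- rep(FALSE, n)
  } else {
    z <- as_link(config$link)$sampler(n)
    target <- matrix(z + shift)
    bad <- if (config$response_basis$kind == "bernstein") {
      th <- config$theta
      target[, 1L] <= th[1L] | target[, 1L] >= th[length(th)]
    } else rep(FALSE, n)
  }
  list(A = A, H = H, X = X, shift = matrix(shift), target = target,
       bad = bad)
}

solve_response <- function(config, sim) {
  kind <- response_kind(config)
  target <- sim$target[, 1L]
  if (kind == "direct") return(target)
  basis <- config$response_basis
  th <- config$theta
  if (kind == "ordinal")                     # smallest k with target <= theta_k
    return(1L + rowSums(outer(target, th, ">")))
  if (basis$kind == "linear")
    return((target - th[1L]) / th[2L])
  s <- basis$support
  lo <- rep(s[1L], length(target)); hi <- rep(s[2L], length(target))
  for (it in seq_len(ceiling(log2(diff(s) / 1e-10)) + 2L)) {
    mid <- (lo + hi) / 2
    hm <- drop(eval_basis(basis, mid) %*% th)
    below <- hm < target
    lo[below] <- mid[below]; hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Built-in simulation scenario presets
#'
#' Four scenarios covering the regimes used to evaluate distributional
#' anchor regression:
#' \describe{
#'   \item{la}{linear Gaussian; two continuous anchors influence response,
#'     covariates and the hidden confounder (invalid instruments); `p = 10`
#'     with only covariates 2 and 3 causal (`beta_2 = beta_3 = 1`);
#'     `n_train = 300`, `n_test = 2000`. Default test intervention: push
#'     anchors to `N(0, 3^2)`.}
#'   \item{nla}{same skeleton, but the causal effect is the non-linear
#'     `f(X) = X2 + X3 + 1(X2 <= 0) + 1(X2 <= -0.5) 1(X3 <= 1)` with the
#'     response generated directly on the observation scale.}
#'   \item{iv1}{one binary anchor as a valid instrument (no direct path to
#'     the confounder or the response); continuous response generated from
#'     a probit transformation model with an order-6 Bernstein
#'     transformation; `n_train = 1000`. Default test intervention
#'     `do(A = 3.6)`.}
#'   \item{iv2}{valid-instrument skeleton with an ordinal response
#'     (`K = 10` classes by default), logistic link, instrument strength
#'     `M_X = 0.5` and ground truth `beta = 0.5`; `n_train = 1000`.
#'     Default test intervention `do(A = 3)`.}
#' }
#' Coefficients beyond the printed ones (sample sizes, `beta` patterns,
#' `K`, `M_X`, intervention values) are package defaults chosen once to
#' reproduce the qualitative regimes; see the methods vignette.
#'
#' @param name one of `"la"`, `"nla"`, `"iv1"`, `"iv2"`.
#' @param overrides named list of config fields to replace.
#' @return a [scenario_config].
#' @export
scenario_preset <- function(name = c("la", "nla", "iv1", "iv2"),
                            overrides = list()) {
  name <- match.arg(name)
  cfg <- switch(name,
    la = {
      p <- 10L; q <- 2L; d <- 1L
      M_X <- matrix(0, p, q); M_X[1:5, 1L] <- 1; M_X[6:10, 2L] <- 1
      scenario_config("la", p, q, d,
        anchor_law = list(kind = "normal", sd = 1),
        M_X = M_X, M_H = matrix(1, d, q), M_Y = c(1, 0),
        B_XH = matrix(1, p, d), B_YH = 1,
        beta = c(0, 1, 1, rep(0, 7)),
        link = "probit", response_basis = linear_basis(c(-60, 60)),
        theta = c(0, 1), n_train = 300L, n_test = 2000L,
        intervention = NULL, seed = 1L)
    },
    nla = {
      p <- 10L; q <- 2L; d <- 1L
      M_X <- matrix(0, p, q); M_X[1:5, 1L] <- 1; M_X[6:10, 2L] <- 1
      f_nla <- function(X)
        X[, 2L] + X[, 3L] + (X[, 2L] <= 0) +
          (X[, 2L] <= -0.5) * (X[, 3L] <= 1)
      scenario_config("nla", p, q, d,
        anchor_law = list(kind = "normal", sd = 1),
        M_X = M_X, M_H = matrix(1, d, q), M_Y = c(1, 0),
        B_XH = matrix(1, p, d), B_YH = 1,
        f = f_nla, sd_Y = 1,
        link = "probit", response_basis = bernstein_basis(6L, c(-25, 25)),
        n_train = 300L, n_test = 2000L, intervention = NULL, seed = 1L)
    },
    iv1 = {
      basis <- bernstein_basis(6L, c(-8, 8))
      h_iv1 <- function(y) y + y^3 / 10
      scenario_config("iv1", p = 1L, q = 1L, d = 1L,
        anchor_law = list(kind = "binary", prob = 0.5, levels = c(0, 1)),
        M_X = 1, M_H = 0, M_Y = 0, B_XH = 1, B_YH = 1,
        beta = 1, link = "probit", response_basis = basis,
        theta = theta_from_h(h_iv1, basis),
        n_train = 1000L, n_test = 2000L, intervention = NULL, seed = 1L)
    },
    iv2 = {
      K <- 10L
      scenario_config("iv2", p = 1L, q = 1L, d = 1L,
        anchor_law = list(kind = "binary", prob = 0.5, levels = c(0, 1)),
        M_X = 0.5, M_H = 0, M_Y = 0, B_XH = 1, B_YH = 1,
        beta = 0.5, link = "logit", response_basis = ordinal_basis(K),
        theta = seq(-4, 4, length.out = K - 1L),
        n_train = 1000L, n_test = 2000L, intervention = NULL, seed = 1L)
    })
  if (name == "iv2" && !is.null(overrides$K)) {
    K <- as.integer(overrides$K)
    cfg$response_basis <- ordinal_basis(K)
    cfg$theta <- seq(-4, 4, length.out = K - 1L)
    overrides$K <- NULL
  }
  cfg$default_test_intervention <- switch(name,
    la = , nla = list(kind = "push",
                      law = list(kind = "normal", mean = 0, sd = 3)),
    iv1 = list(kind = "do", value = 3.6),
    iv2 = list(kind = "do", value = 3))
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}
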