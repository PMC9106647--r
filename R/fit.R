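# Likelihood engine: unconstrained parametrization, analytic gradients.
#
# par = c(free, beta). The baseline coefficients are reparametrized so the
# monotonicity constraints of the basis hold for every par:
#   linear:     theta = (free1, exp(free2))          (slope > 0)
#   bernstein:  theta = cumulative log-increments    (non-decreasing)
#   ordinal:    theta = cumulative log-increments    (strictly increasing)

reparam_theta <- function(basis, free) {
  if (basis$kind == "linear") c(free[1L], exp(free[2L]))
  else theta_from_free(free)
}

reparam_free <- function(basis, theta) {
  if (basis$kind == "linear") {
    if (theta[2L] <= 0) stop2("linear basis requires theta[2] > 0")
    c(theta[1L], log(theta[2L]))
  } else free_from_theta(theta)
}

reparam_grad <- function(basis, grad_theta, free) {
  if (basis$kind == "linear")
    c(grad_theta[1L], grad_theta[2L] * exp(free[2L]))
  else grad_free_from_theta(grad_theta, free)
}

# Builds closures for the (penalized) objective on prepared data.
# design/xi may be NULL/0 for plain maximum likelihood.
tm_objective <- function(prep, link, design = NULL, xi = 0) {
  m <- prep$m; p <- ncol(prep$X); n <- prep$n
  split_par <- function(par) {
    free <- par[seq_len(m)]
    beta <- if (p) par[m + seq_len(p)] else numeric(0)
    list(free = free, beta = beta,
         theta = reparam_theta(prep$basis, free))
  }
  nll <- function(par) {
    pp <- split_par(par)
    ll <- loglik_vector(prep, link, pp$theta, pp$beta,
                        warn_nonmonotone = FALSE)
    val <- -sum(ll) / n
    if (!is.finite(val)) return(1e10)
    if (xi > 0) {
      r <- score_vector(prep, link, pp$theta, pp$beta)
      val <- val + xi * sum(project_anchors(design, r)^2) / n
    }
    val
  }
  grad <- function(par) {
    pp <- split_par(par)
    theta <- pp$theta; beta <- pp$beta
    g_theta <- numeric(m); g_beta <- numeric(p)
    if (length(prep$idx_e)) {
      shift <- if (p) drop(prep$X_e %*% beta) else 0
      h <- drop(prep$B_e %*% theta) - shift
      hp <- drop(prep$Bp_e %*% theta)
      dlogf <- -neg_dlogdens(link, h)
      g_theta <- g_theta + drop(crossprod(prep$B_e, dlogf)) +
        drop(crossprod(prep$Bp_e, 1 / hp))
      if (p) g_beta <- g_beta - drop(crossprod(prep$X_e, dlogf))
    }
    if (length(prep$idx_c)) {
      b <- cens_bounds(prep, theta, beta)
      logD <- log_prob_interval(link, b$lo, b$up)
      fl <- ifelse(prep$lo_fin, exp(link$log_pdf(b$lo) - logD), 0)
      fu <- ifelse(prep$up_fin, exp(link$log_pdf(b$up) - logD), 0)
      g_theta <- g_theta + drop(crossprod(prep$B_up, fu)) -
        drop(crossprod(prep$B_lo, fl))
      if (p) g_beta <- g_beta - drop(crossprod(prep$X_c, fu - fl))
    }
    g <- -c(reparam_grad(prep$basis, g_theta, pp$free), g_beta) / n
    if (xi > 0) {
      sc <- score_vector(prep, link, theta, beta, deriv = TRUE)
      w <- 2 * xi * project_anchors(design, sc$r) / n
      pg_theta <- numeric(m); pg_beta <- numeric(p)
      if (length(prep$idx_e)) {
        we <- w[prep$idx_e] * sc$du[prep$idx_e]
        pg_theta <- pg_theta + drop(crossprod(prep$B_e, we))
        if (p) pg_beta <- pg_beta - drop(crossprod(prep$X_e, we))
      }
      if (length(prep$idx_c)) {
        wc_u <- w[prep$idx_c] * sc$du[prep$idx_c]
        wc_l <- w[prep$idx_c] * sc$dl[prep$idx_c]
        pg_theta <- pg_theta + drop(crossprod(prep$B_up, wc_u)) +
          drop(crossprod(prep$B_lo, wc_l))
        if (p) pg_beta <- pg_beta - drop(crossprod(prep$X_c, wc_u + wc_l))
      }
      g <- g + c(reparam_grad(prep$basis, pg_theta, pp$free), pg_beta)
    }
    g
  }
  list(nll = nll, grad = grad, split_par = split_par, m = m, p = p, n = n)
}

# starting values for the baseline coefficients (unconditional)
init_free <- function(prep, link) {
  basis <- prep$basis
  m <- prep$m
  if (basis$kind == "ordinal") {
    K <- basis$n_classes
    cls <- ifelse(prep$up_fin, max.col(prep$B_up, "first"), K)
    cnt <- tabulate(cls, K) + 0.5                  # smoothed class counts
    cum <- cumsum(cnt)[-K] / sum(cnt)
    return(reparam_free(basis, link$quantile(cum)))
  }
  # continuous: map support evenly onto central latent quantiles
  q <- link$quantile(seq_len(m) / (m + 1))
  if (basis$kind == "linear") {
    mid <- c(prep$B_e[, 2L], prep$B_lo[prep$lo_fin, 2L],
             prep$B_up[prep$up_fin, 2L])
    mu <- mean(mid); s <- max(stats::sd(mid), 1e-3)
    return(reparam_free(basis, c(-mu / s, 1 / s)))
  }
  reparam_free(basis, q)
}

# Quasi-Newton stage followed by damped Newton polishing (numerical
# Hessian from the analytic gradient); the polish handles the flat
# directions a wide Bernstein support induces.
run_optim <- function(obj, par0, maxit = 1000L, gtol = 1e-6) {
  fit <- stats::optim(par0, fn = obj$nll, gr = obj$grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  par <- fit$par
  n_iter <- fit$counts[["function"]]
  gn <- max(abs(obj$grad(par)))
  num_hess <- function(par) {
    np <- length(par)
    H <- matrix(0, np, np)
    for (i in seq_len(np)) {
      h <- 1e-6 * (1 + abs(par[i]))
      e <- rep(0, np); e[i] <- h
      H[, i] <- (obj$grad(par + e) - obj$grad(par - e)) / (2 * h)
    }
    (H + t(H)) / 2
  }
  for (k in seq_len(50L)) {
    if (is.finite(gn) && gn < gtol) break
    H <- num_hess(par)
    scale <- max(abs(diag(H)), 1)
    ridge <- 1e-8 * scale
    f0 <- obj$nll(par); accepted <- FALSE
    while (ridge <= 1e2 * scale) {      # Levenberg-Marquardt damping
      step <- tryCatch(solve(H + diag(ridge, length(par)), obj$grad(par)),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        t <- 1
        while (t > 1e-8) {
          parn <- par - t * step
          fn <- obj$nll(parn)
          gnn <- max(abs(obj$grad(parn)))
          if (is.finite(fn) && is.finite(gnn) &&
              (fn < f0 - 1e-14 || gnn < gn)) {
            par <- parn; gn <- gnn; accepted <- TRUE; break
          }
          t <- t / 4
        }
      }
      if (accepted) break
      ridge <- ridge * 100
    }
    n_iter <- n_iter + 1L
    if (!accepted) break
  }
  list(par = par, value = obj$nll(par), grad_norm = gn,
       converged = is.finite(gn) && gn < gtol, n_iter = n_iter)
}

#' Maximum-likelihood estimation of a transformation model
#'
#' Jointly estimates the baseline coefficients `theta` and covariate shifts
#' `beta` by maximizing the (censored) log-likelihood with a quasi-Newton
#' method on the unconstrained reparametrized space, using analytic
#' gradients. The baseline is initialized from the unconditional model
#' (`beta = 0`) fitted first.
#'
#' @param response a [cens_response], [ordinal_response], numeric vector or
#'   factor.
#' @param x covariate matrix (or `NULL` for an unconditional model).
#' @param link link name or [make_link] object.
#' @param basis a [basis_spec]; when `NULL`, a Bernstein basis of order
#'   `order` on [default_support] of the data is used for continuous
#'   responses, an ordinal basis for ordinal ones.
#' @param order Bernstein order used when `basis` is `NULL`.
#' @param maxit,gtol optimizer iteration cap and gradient sup-norm
#'   tolerance.
#' @return an object of class `tm_fit`: list with elements `model` (a
#'   [trafo_model]), `nll` (mean negative log-likelihood), `logLik`,
#'   `converged`, `n_iter`, `grad_norm`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100)
#' y <- 1 + x %*% c(1, -1) + rnorm(100)
#' f <- fit_tm(drop(y), x, link = "probit",
#'             basis = linear_basis(default_support(y)))
#' coef_lm(f)  # intercept, slopes, sigma on the response scale
#' @export
fit_tm <- function(response, x = NULL, link = "probit", basis = NULL,
                   order = 6L, maxit = 1000L, gtol = 1e-6) {
  link <- as_link(link)
  response <- as_response(response)
  if (is.null(basis)) {
    basis <- if (response$type == "ordinal")
      ordinal_basis(response$n_classes)
    else bernstein_basis(order, default_support(c(response$lower,
                                                  response$upper)))
  }
  prep <- prepare_tm_data(response, x, basis)
  check_informative(prep)
  p <- ncol(prep$X)
  if (prep$n < prep$m + p)
    stop2("need at least ", prep$m + p, " observations to fit ",
          prep$m + p, " parameters")
  # stage 1: unconditional baseline
  prep0 <- prep; prep0$X <- prep$X[, 0, drop = FALSE]
  prep0$X_e <- prep$X_e[, 0, drop = FALSE]
  prep0$X_c <- prep$X_c[, 0, drop = FALSE]
  obj0 <- tm_objective(prep0, link)
  st0 <- run_optim(obj0, init_free(prep, link), maxit = maxit, gtol = 1e-4)
  # stage 2: full model
  obj <- tm_objective(prep, link)
  res <- run_optim(obj, c(st0$par, rep(0, p)), maxit = maxit, gtol = gtol)
  pp <- obj$split_par(res$par)
  model <- trafo_model(link, basis, pp$theta, pp$beta)
  structure(list(model = model, nll = res$value,
                 logLik = -res$value * prep$n,
                 converged = res$converged, n_iter = res$n_iter,
                 grad_norm = res$grad_norm, par = res$par,
                 objective = obj),
            class = "tm_fit")
}

check_informative <- function(prep) {
  if (!length(prep$idx_e) && !any(prep$lo_fin) && !any(prep$up_fin))
    stop2("the likelihood is constant: no observation has a finite ",
          "response bound")
  invisible(TRUE)
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("tm_fit: mean NLL %.4f, %sconverged (|grad| = %.2e)\n",
              x$nll, if (x$converged) "" else "NOT ", x$grad_norm))
  print(x$model)
  invisible(x)
}

#' @export
coef.tm_fit <- function(object, ...)
  c(theta = object$model$theta, beta = object$model$beta)

#' Covariance matrix of the shift coefficients
#'
#' Observed-information standard errors: the Hessian of the total negative
#' log-likelihood at the optimum is computed numerically from the analytic
#' gradient; the `beta` block of its inverse is returned (invariant to the
#' monotone reparametrization of the baseline).
#'
#' @param fit a `tm_fit` (or `anchor_tm_fit`) object.
#' @return covariance matrix of `beta`.
#' @export
vcov_beta <- function(fit) {
  obj <- fit$objective
  if (!obj$p) stop2("model has no shift coefficients")
  H <- stats::optimHess(fit$par, fn = obj$nll, gr = obj$grad) * obj$n
  V <- solve(H)
  idx <- obj$m + seq_len(obj$p)
  V[idx, idx, drop = FALSE]
}

#' Normal-linear coefficients from an Lm transformation model fit
#'
#' Converts the transformation parametrization
#' \eqn{(\vartheta_1, \vartheta_2, \beta)} of the normal linear model to the
#' familiar \eqn{(\beta_0, \tilde\beta, \sigma)}:
#' \eqn{\sigma = 1/\vartheta_2}, \eqn{\beta_0 = -\vartheta_1 \sigma},
#' \eqn{\tilde\beta = \beta \sigma}.
#'
#' @param fit a `tm_fit` with probit link and linear basis.
#' @return named list with `intercept`, `slopes`, `sigma`.
#' @export
coef_lm <- function(fit) {
  m <- if (inherits(fit, "trafo_model")) fit else fit$model
  if (m$basis$kind != "linear" || m$link$name != "probit")
    stop2("coef_lm applies to the probit link with linear basis")
  sigma <- 1 / m$theta[2L]
  list(intercept = -m$theta[1L] * sigma,
       slopes = m$beta * sigma,
       sigma = sigma)
}
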