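#' Transformation model objects
#'
#' A transformation model is the triple (inverse link \eqn{F_Z}, response
#' basis \eqn{b}, coefficients \eqn{\vartheta}) defining the conditional
#' distribution \eqn{F_{Y|x}(y|x) = F_Z(h(y|x))} with transformation
#' \eqn{h(y|x) = b(y)^\top \theta - x^\top \beta}. The baseline coefficients
#' `theta` must satisfy the monotonicity constraint of their basis
#' (`theta[2] > 0` for the linear basis, non-decreasing for Bernstein,
#' strictly increasing for ordinal thresholds).
#'
#' @param link a [make_link] object or link name.
#' @param basis a [basis_spec].
#' @param theta numeric baseline coefficients, length `basis$dim`.
#' @param beta numeric shift coefficients, one per covariate (may be
#'   length 0 for an unconditional model).
#' @return an object of class `trafo_model`.
#' @export
trafo_model <- function(link, basis, theta, beta = numeric(0)) {
  link <- as_link(link)
  stopifnot(inherits(basis, "basis_spec"))
  theta <- as.numeric(theta)
  if (length(theta) != basis$dim)
    stop2("'theta' must have length ", basis$dim, " for this basis")
  switch(basis$kind,
    linear = if (theta[2L] <= 0) stop2("linear basis requires theta[2] > 0"),
    bernstein = if (any(diff(theta) < 0))
      stop2("Bernstein coefficients must be non-decreasing"),
    ordinal = if (any(diff(theta) <= 0))
      stop2("ordinal thresholds must be strictly increasing"))
  structure(list(link = link, basis = basis, theta = theta,
                 beta = as.numeric(beta)),
            class = "trafo_model")
}

#' @export
print.trafo_model <- function(x, ...) {
  cat("transformation model:", x$link$name, "link,", x$basis$kind, "basis\n")
  cat("theta:", signif(x$theta, 4), "\n")
  if (length(x$beta)) cat("beta: ", signif(x$beta, 4), "\n")
  invisible(x)
}

# --- internal data preparation ------------------------------------------

as_X <- function(x, n, p = NULL) {
  if (is.null(x)) x <- matrix(0, nrow = n, ncol = 0L)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = n)
  if (!is.matrix(x) || nrow(x) != n)
    stop2("covariates must be a matrix with one row per observation")
  storage.mode(x) <- "double"
  if (!is.null(p) && ncol(x) != p)
    stop2("covariate matrix has ", ncol(x), " columns; model expects ", p)
  x
}

# Build the case-grouped basis matrices used by the likelihood engine.
# Every censored/ordinal observation is treated as an interval (l, u] with
# possibly infinite bounds; exact observations keep their density form.
prepare_tm_data <- function(response, x, basis, extrapolate = FALSE) {
  response <- as_response(response)
  n <- length(response)
  X <- as_X(x, n)
  m <- basis$dim
  if (response$type == "ordinal") {
    if (basis$kind != "ordinal")
      stop2("ordinal responses require an ordinal basis")
    if (response$n_classes != basis$n_classes)
      stop2("response has ", response$n_classes, " classes; basis expects ",
            basis$n_classes)
    k <- response$class_index
    K <- basis$n_classes
    B_up <- matrix(0, n, m); B_lo <- matrix(0, n, m)
    up_fin <- k < K; lo_fin <- k > 1L
    B_up[cbind(which(up_fin), k[up_fin])] <- 1
    B_lo[cbind(which(lo_fin), k[lo_fin] - 1L)] <- 1
    return(list(n = n, m = m, X = X, basis = basis,
                idx_e = integer(0), B_e = matrix(0, 0, m),
                Bp_e = matrix(0, 0, m), X_e = X[integer(0), , drop = FALSE],
                idx_c = seq_len(n), B_lo = B_lo, B_up = B_up,
                lo_fin = lo_fin, up_fin = up_fin,
                X_c = X))
  }
  if (basis$kind == "ordinal")
    stop2("continuous responses require a linear or Bernstein basis")
  lower <- response$lower; upper <- response$upper
  ex <- response$tag == "exact"
  idx_e <- which(ex); idx_c <- which(!ex)
  y_e <- upper[idx_e]
  B_e <- eval_basis(basis, y_e, extrapolate = extrapolate)
  Bp_e <- eval_basis_deriv(basis, y_e, extrapolate = extrapolate)
  lo <- lower[idx_c]; up <- upper[idx_c]
  lo_fin <- is.finite(lo); up_fin <- is.finite(up)
  B_lo <- matrix(0, length(idx_c), m); B_up <- matrix(0, length(idx_c), m)
  if (any(lo_fin))
    B_lo[lo_fin, ] <- eval_basis(basis, lo[lo_fin], extrapolate = extrapolate)
  if (any(up_fin))
    B_up[up_fin, ] <- eval_basis(basis, up[up_fin], extrapolate = extrapolate)
  list(n = n, m = m, X = X, basis = basis,
       idx_e = idx_e, B_e = B_e, Bp_e = Bp_e,
       X_e = X[idx_e, , drop = FALSE],
       idx_c = idx_c, B_lo = B_lo, B_up = B_up,
       lo_fin = lo_fin, up_fin = up_fin,
       X_c = X[idx_c, , drop = FALSE])
}

# latent-scale bounds for the censored group
cens_bounds <- function(prep, theta, beta) {
  shift <- if (length(beta)) drop(prep$X_c %*% beta) else 0
  h_lo <- drop(prep$B_lo %*% theta) - shift
  h_up <- drop(prep$B_up %*% theta) - shift
  h_lo[!prep$lo_fin] <- -Inf
  h_up[!prep$up_fin] <- Inf
  list(lo = h_lo, up = h_up)
}

loglik_vector <- function(prep, link, theta, beta, warn_nonmonotone = TRUE) {
  out <- numeric(prep$n)
  if (length(prep$idx_e)) {
    shift <- if (length(beta)) drop(prep$X_e %*% beta) else 0
    h <- drop(prep$B_e %*% theta) - shift
    hp <- drop(prep$Bp_e %*% theta)
    ll <- link$log_pdf(h) + ifelse(hp > 0, log(pmax(hp, 0)), -Inf)
    if (warn_nonmonotone && any(hp <= 0))
      warning("non-positive transformation derivative at an exact datum; ",
              "contribution set to -Inf", call. = FALSE)
    out[prep$idx_e] <- ll
  }
  if (length(prep$idx_c)) {
    b <- cens_bounds(prep, theta, beta)
    out[prep$idx_c] <- log_prob_interval(link, b$lo, b$up)
  }
  out
}

score_vector <- function(prep, link, theta, beta, deriv = FALSE) {
  r <- numeric(prep$n)
  dl <- du <- NULL
  if (deriv) { dl <- numeric(prep$n); du <- numeric(prep$n) }
  if (length(prep$idx_e)) {
    shift <- if (length(beta)) drop(prep$X_e %*% beta) else 0
    h <- drop(prep$B_e %*% theta) - shift
    r[prep$idx_e] <- neg_dlogdens(link, h)
    if (deriv) du[prep$idx_e] <- neg_dlogdens_prime(link, h)
  }
  if (length(prep$idx_c)) {
    b <- cens_bounds(prep, theta, beta)
    logD <- log_prob_interval(link, b$lo, b$up)
    if (any(is.infinite(logD) & (prep$lo_fin | prep$up_fin)))
      stop2("zero-probability censored observation: F_Z(upper) == F_Z(lower)")
    fl <- ifelse(prep$lo_fin, exp(link$log_pdf(b$lo) - logD), 0)
    fu <- ifelse(prep$up_fin, exp(link$log_pdf(b$up) - logD), 0)
    rc <- fl - fu
    r[prep$idx_c] <- rc
    if (deriv) {
      # d r / d l and d r / d u; f'(z)/D = -G(z) f(z)/D
      Gl <- ifelse(prep$lo_fin, neg_dlogdens(link, b$lo), 0)
      Gu <- ifelse(prep$up_fin, neg_dlogdens(link, b$up), 0)
      dl[prep$idx_c] <- -Gl * fl + rc * fl
      du[prep$idx_c] <- Gu * fu - rc * fu
    }
  }
  if (deriv) list(r = r, dl = dl, du = du) else r
}

# --- user-facing likelihood / residuals ---------------------------------

#' Log-likelihood contributions of a transformation model
#'
#' Returns the per-observation log-likelihood contribution for potentially
#' censored or ordinal responses: the density form
#' \eqn{\log f_Z(h(y|x)) + \log h'(y|x)} for exact observations,
#' \eqn{\log F_Z} of the upper bound for left-censored,
#' \eqn{\log(1 - F_Z)} of the lower bound for right-censored, and the log of
#' the \eqn{F_Z} difference for interval-censored data. Ordinal class
#' \eqn{k} is the interval between adjacent thresholds. Contributions are
#' finite or `-Inf`.
#'
#' Finite response bounds falling outside the basis support are handled by
#' linear continuation of the transformation beyond the boundary (see
#' [eval_basis]), so models can be scored on shifted test data.
#'
#' @param model a [trafo_model].
#' @param response a [cens_response], [ordinal_response], numeric vector or
#'   factor.
#' @param x covariate matrix (one row per observation) or `NULL`.
#' @return numeric vector of log-likelihood contributions.
#' @export
log_lik <- function(model, response, x = NULL) {
  stopifnot(inherits(model, "trafo_model"))
  response <- as_response(response)
  prep <- prepare_tm_data(response, x, model$basis, extrapolate = TRUE)
  if (ncol(prep$X) != length(model$beta))
    stop2("covariate matrix has ", ncol(prep$X), " columns; model expects ",
          length(model$beta))
  loglik_vector(prep, model$link, model$theta, model$beta)
}

#' Score residuals
#'
#' The score residual of an observation is the derivative of its
#' log-likelihood contribution with respect to an artificially added
#' intercept \eqn{\alpha} in the transformation \eqn{h - \alpha}, evaluated
#' at \eqn{\alpha = 0}. Closed forms per censoring type:
#' exact \eqn{-f_Z'(u)/f_Z(u)}; left \eqn{-f_Z(\bar u)/F_Z(\bar u)};
#' right \eqn{f_Z(\underline u)/(1 - F_Z(\underline u))}; interval
#' \eqn{(f_Z(\underline u) - f_Z(\bar u))/(F_Z(\bar u) - F_Z(\underline u))}.
#' Under this sign convention the minimum-extreme-value residual equals
#' \eqn{\hat\Lambda - \delta}; use [martingale_residuals] for the survival
#' convention \eqn{\delta - \hat\Lambda}.
#'
#' @inheritParams log_lik
#' @return numeric vector of residuals.
#' @export
score_residuals <- function(model, response, x = NULL) {
  stopifnot(inherits(model, "trafo_model"))
  response <- as_response(response)
  prep <- prepare_tm_data(response, x, model$basis, extrapolate = TRUE)
  if (ncol(prep$X) != length(model$beta))
    stop2("covariate matrix has ", ncol(prep$X), " columns; model expects ",
          length(model$beta))
  score_vector(prep, model$link, model$theta, model$beta)
}

#' Martingale residuals
#'
#' For a minimum-extreme-value link and exact or right-censored data,
#' returns \eqn{\delta - \hat\Lambda(y|x)} (event indicator minus estimated
#' cumulative hazard), the negative of the [score_residuals] under this
#' package's sign convention.
#'
#' @inheritParams log_lik
#' @return numeric vector in \eqn{(-\infty, 1]}.
#' @export
martingale_residuals <- function(model, response, x = NULL) {
  stopifnot(inherits(model, "trafo_model"))
  if (model$link$name != "mev")
    stop2("martingale residuals are defined for the 'mev' link")
  response <- as_response(response)
  if (response$type == "ordinal" ||
      !all(response$tag %in% c("exact", "right")))
    stop2("martingale residuals require exact or right-censored responses")
  -score_residuals(model, response, x)
}

# --- prediction ----------------------------------------------------------

#' Conditional distribution and quantile function
#'
#' `predict_cdf()` evaluates \eqn{F_{Y|x}(y|x) = F_Z(b(y)^\top\theta -
#' x^\top\beta)} on a response grid. `predict_quantile()` inverts the
#' conditional CDF, solving \eqn{h(y|x) = F_Z^{-1}(p)} by bisection on the
#' basis support to `1e-8` in response units (closed form for the linear
#' basis); the conditional median (`p = 0.5`) is the point predictor used
#' for absolute prediction errors. Quantiles falling outside the support
#' are computed from the linear continuation of the transformation, with a
#' warning.
#'
#' @param model a [trafo_model] with continuous basis.
#' @param y_grid numeric vector of response values.
#' @param x a single covariate vector (or `NULL`); for
#'   `predict_quantile`, alternatively a matrix of covariate rows.
#' @param p probability (scalar or vector) strictly inside (0, 1).
#' @return `predict_cdf`: vector of CDF values; `predict_quantile`: vector
#'   of response quantiles.
#' @export
predict_cdf <- function(model, y_grid, x = NULL) {
  stopifnot(inherits(model, "trafo_model"))
  if (model$basis$kind == "ordinal")
    stop2("predict_cdf on a grid requires a continuous basis")
  shift <- if (length(model$beta)) sum(as.numeric(x) * model$beta) else 0
  h <- drop(eval_basis(model$basis, y_grid, extrapolate = TRUE) %*%
              model$theta) - shift
  model$link$cdf(h)
}

#' @rdname predict_cdf
#' @export
predict_quantile <- function(model, p, x = NULL) {
  stopifnot(inherits(model, "trafo_model"))
  if (model$basis$kind == "ordinal")
    stop2("quantiles of an ordinal model are class labels; not supported")
  if (any(p <= 0 | p >= 1)) stop2("'p' must lie strictly inside (0, 1)")
  X <- if (is.matrix(x) || is.data.frame(x)) as.matrix(x)
       else if (is.null(x)) matrix(0, 1, 0) else matrix(as.numeric(x), nrow = 1)
  shift <- if (length(model$beta)) drop(X %*% model$beta) else rep(0, nrow(X))
  nn <- max(length(p), length(shift))
  p <- rep_len(p, nn); shift <- rep_len(shift, nn)
  target <- model$link$quantile(p) + shift     # solve b(y)' theta = target
  s <- model$basis$support
  if (model$basis$kind == "linear") {
    yq <- (target - model$theta[1L]) / model$theta[2L]
  } else {
    lo <- rep(s[1L], nn); hi <- rep(s[2L], nn)
    for (it in seq_len(ceiling(log2(diff(s) / 1e-8)) + 2L)) {
      mid <- (lo + hi) / 2
      hm <- drop(eval_basis(model$basis, mid) %*% model$theta)
      below <- hm < target
      lo[below] <- mid[below]; hi[!below] <- mid[!below]
    }
    yq <- (lo + hi) / 2
    # linear continuation beyond the support with the boundary slope
    h_a <- sum(eval_basis(model$basis, s[1L]) * model$theta)
    h_b <- sum(eval_basis(model$basis, s[2L]) * model$theta)
    hp_a <- sum(eval_basis_deriv(model$basis, s[1L]) * model$theta)
    hp_b <- sum(eval_basis_deriv(model$basis, s[2L]) * model$theta)
    below <- target <= h_a; above <- target >= h_b
    yq[below] <- s[1L] + (target[below] - h_a) / max(hp_a, 1e-12)
    yq[above] <- s[2L] + (target[above] - h_b) / max(hp_b, 1e-12)
    if (any(below | above))
      warning("requested quantile falls outside the basis support; ",
              "using linear continuation of the transformation",
              call. = FALSE)
  }
  yq
}
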