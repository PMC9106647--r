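#' Per-observation negative log-likelihood and its quantiles
#'
#' `nll_contributions()` returns \eqn{-\ell(\hat\vartheta; y_i, x_i)} per
#' observation (`+Inf` for zero-likelihood observations, reported, never
#' dropped). `nll_quantiles()` evaluates the empirical quantile function of
#' such a vector on a grid; larger quantiles probe harder-to-predict
#' observations, the worst-case view of predictive performance. The
#' inverse-empirical-CDF (type 1) quantile estimator is used.
#'
#' @param model a [trafo_model] (or `tm_fit`).
#' @param response,x data to score (see [log_lik]).
#' @return `nll_contributions`: numeric vector.
#' @export
nll_contributions <- function(model, response, x = NULL) {
  if (inherits(model, "tm_fit")) model <- model$model
  -log_lik(model, response, x)
}

#' @rdname nll_contributions
#' @param nll numeric vector of NLL contributions.
#' @param alpha_grid probabilities in [0, 1].
#' @return `nll_quantiles`: named numeric vector, non-decreasing in
#'   `alpha`.
#' @export
nll_quantiles <- function(nll, alpha_grid = c(0.05, 0.5, 0.9, 0.95, 1)) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1))
  q <- stats::quantile(nll, probs = alpha_grid, type = 1, names = FALSE)
  stats::setNames(q, paste0("q", alpha_grid))
}

#' Absolute prediction error at the conditional median
#'
#' \eqn{APE_i = |y_i - \hat y_i|} where \eqn{\hat y_i} is the conditional
#' median [predict_quantile]`(model, 0.5, x_i)`. Defined for exact
#' continuous responses only.
#'
#' @inheritParams nll_contributions
#' @return numeric vector of absolute errors.
#' @export
ape <- function(model, response, x = NULL) {
  if (inherits(model, "tm_fit")) model <- model$model
  response <- as_response(response)
  if (response$type == "ordinal" || !all(response$tag == "exact"))
    stop2("APE is defined for exact continuous responses only")
  n <- length(response)
  X <- as_X(x, n)
  med <- predict_quantile(model, 0.5, if (ncol(X)) X else NULL)
  abs(response$upper - med)
}

#' Leave-one-environment-out cross-validation
#'
#' For each environment label: train on all other environments, with the
#' environments serving as the (dummy-encoded, centered) anchor variable —
#' the held-out level is absent from the training anchors — then score the
#' mean NLL on the held-out environment, for every value of the causal
#' regularization grid. `xi = 0` is the unpenalized maximum-likelihood
#' model.
#'
#' @param response,x training data (see [fit_tm]).
#' @param env factor (or coercible) of environment labels, one per
#'   observation; at least two distinct levels.
#' @param xi_grid ascending vector of regularization strengths.
#' @inheritParams fit_tm
#' @return a data.frame with columns `env`, `n`, and one `xi_*` column of
#'   held-out mean NLL per grid value.
#' @export
loeo_cv <- function(response, x = NULL, env, xi_grid = c(0, 1, 10),
                    link = "probit", basis = NULL, order = 6L, ...) {
  env <- factor(env)
  if (nlevels(env) < 2L) stop2("need at least two distinct environments")
  response <- as_response(response)
  n <- length(response)
  X <- as_X(x, n)
  if (is.null(basis)) {
    basis <- if (response$type == "ordinal")
      ordinal_basis(response$n_classes)
    else bernstein_basis(order, default_support(c(response$lower,
                                                  response$upper)))
  }
  rows <- lapply(levels(env), function(e) {
    hold <- env == e
    if (!sum(hold)) {
      warning("environment '", e, "' has no observations; skipped",
              call. = FALSE)
      return(NULL)
    }
    tr_resp <- subset_response(response, !hold)
    tr_X <- X[!hold, , drop = FALSE]
    design <- anchor_design(droplevels(env[!hold]))
    path <- xi_path(tr_resp, if (ncol(tr_X)) tr_X else NULL, design,
                    xi_grid = xi_grid, link = link, basis = basis, ...)
    te_resp <- subset_response(response, hold)
    te_X <- X[hold, , drop = FALSE]
    nlls <- vapply(path, function(f) {
      if (inherits(f, "try-error")) return(NA_real_)
      mean(nll_contributions(f, te_resp, if (ncol(te_X)) te_X else NULL))
    }, numeric(1))
    out <- data.frame(env = e, n = sum(hold))
    out[paste0("xi_", xi_grid)] <- as.list(nlls)
    out
  })
  do.call(rbind, rows)
}
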