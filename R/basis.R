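#' Response basis specifications
#'
#' A basis specification describes how the baseline transformation
#' \eqn{h(y) = b(y)^\top \theta} depends on the response. Three kinds are
#' supported: a linear basis \eqn{b(y) = (1, y)} on a finite support, a
#' Bernstein polynomial basis of order \eqn{P} (dimension \eqn{P + 1}) on a
#' finite support, and an ordinal basis for a response with \eqn{K} ordered
#' classes (\eqn{K - 1} free thresholds; the top threshold is \eqn{+\infty}).
#'
#' @param kind one of `"linear"`, `"bernstein"`, `"ordinal"`.
#' @param order Bernstein polynomial order `P >= 1` (ignored otherwise).
#' @param n_classes number of ordinal classes `K >= 2` (ordinal only).
#' @param support numeric pair `(a, b)` with `a < b`, the finite response
#'   support (linear and bernstein only).
#'
#' @return an object of class `basis_spec` with elements `kind`, `order`,
#'   `n_classes`, `support` and `dim` (the number of basis functions).
#' @examples
#' bs <- bernstein_basis(order = 6, support = c(0, 1))
#' rowSums(eval_basis(bs, c(0.2, 0.7)))  # partition of unity
#' @export
basis_spec <- function(kind = c("linear", "bernstein", "ordinal"),
                       order = 6L, n_classes = NULL, support = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("linear", "bernstein")) {
    if (is.null(support) || length(support) != 2L || !all(is.finite(support)) ||
        support[1L] >= support[2L])
      stop2("'support' must be a finite pair (a, b) with a < b")
  }
  if (kind == "bernstein") {
    order <- as.integer(order)
    if (order < 1L) stop2("Bernstein 'order' must be >= 1")
  }
  if (kind == "ordinal") {
    if (is.null(n_classes)) stop2("'n_classes' is required for an ordinal basis")
    n_classes <- as.integer(n_classes)
    if (n_classes < 2L) stop2("'n_classes' must be >= 2")
  }
  dim <- switch(kind,
    linear = 2L,
    bernstein = order + 1L,
    ordinal = n_classes - 1L)
  structure(list(kind = kind,
                 order = if (kind == "bernstein") order else NULL,
                 n_classes = if (kind == "ordinal") n_classes else NULL,
                 support = support, dim = dim),
            class = "basis_spec")
}

#' @rdname basis_spec
#' @export
linear_basis <- function(support) basis_spec("linear", support = support)

#' @rdname basis_spec
#' @export
bernstein_basis <- function(order = 6L, support)
  basis_spec("bernstein", order = order, support = support)

#' @rdname basis_spec
#' @export
ordinal_basis <- function(n_classes) basis_spec("ordinal", n_classes = n_classes)

#' @export
print.basis_spec <- function(x, ...) {
  cat(switch(x$kind,
    linear = sprintf("linear basis on [%g, %g]", x$support[1], x$support[2]),
    bernstein = sprintf("Bernstein basis of order %d on [%g, %g]",
                        x$order, x$support[1], x$support[2]),
    ordinal = sprintf("ordinal basis with %d classes", x$n_classes)), "\n")
  invisible(x)
}

#' Default Bernstein support from observed response bounds
#'
#' The support is the range of all finite response bounds, padded by 5% of
#' the range on each side, so that training responses lie strictly inside.
#'
#' @param bounds numeric vector of finite response values / interval bounds.
#' @return numeric pair `(a, b)`.
#' @export
default_support <- function(bounds) {
  bounds <- bounds[is.finite(bounds)]
  if (!length(bounds)) stop2("no finite response bounds to derive a support from")
  r <- range(bounds)
  pad <- 0.05 * max(diff(r), .Machine$double.eps)
  c(r[1L] - pad, r[2L] + pad)
}

#' Evaluate a response basis
#'
#' `eval_basis()` returns the matrix of basis functions \eqn{b(y)} evaluated
#' at each element of `y`; `eval_basis_deriv()` returns the exact derivative
#' \eqn{b'(y)} with respect to `y` (continuous bases only), including the
#' chain-rule factor from rescaling to the support.
#'
#' For the ordinal basis, class `k < K` maps to the unit vector selecting
#' threshold `k`; class `K` maps to the zero row (its upper bound is
#' \eqn{+\infty}), flagged in the `"upper_inf"` attribute.
#'
#' @param spec a [basis_spec].
#' @param y numeric vector (continuous) or integer class indices (ordinal).
#' @param extrapolate Bernstein polynomials extrapolate badly; by default a
#'   response outside the support is an error. With `extrapolate = TRUE`
#'   the basis (and hence the transformation) is continued linearly beyond
#'   the support boundary with the boundary slope, the standard device for
#'   scoring transformation models on shifted data.
#' @return numeric matrix, `length(y)` rows by `spec$dim` columns.
#' @export
eval_basis <- function(spec, y, extrapolate = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  switch(spec$kind,
    linear = {
      if (!extrapolate) check_support(spec, y)  # h is globally linear anyway
      cbind(1, y)
    },
    bernstein = {
      if (!extrapolate) check_support(spec, y)
      yc <- pmin(pmax(y, spec$support[1L]), spec$support[2L])
      P <- spec$order
      t <- (yc - spec$support[1L]) / diff(spec$support)
      j <- 0:P
      # C(P, j) t^j (1-t)^(P-j), computed on the log scale via dbinom
      B <- matrix(vapply(j, function(jj) stats::dbinom(jj, P, t),
                         numeric(length(t))),
                  nrow = length(y), ncol = P + 1L)
      out <- which(yc != y)
      if (length(out)) {      # first-order continuation at the boundary
        D <- eval_basis_deriv(spec, yc[out])
        B[out, ] <- B[out, , drop = FALSE] + D * (y[out] - yc[out])
      }
      B
    },
    ordinal = {
      if (any(y != round(y)) || any(y < 1L) || any(y > spec$n_classes))
        stop2("ordinal class indices must be integers in 1..", spec$n_classes)
      K <- spec$n_classes
      B <- matrix(0, nrow = length(y), ncol = K - 1L)
      kk <- which(y < K)
      B[cbind(kk, y[kk])] <- 1
      attr(B, "upper_inf") <- y == K
      B
    })
}

#' @rdname eval_basis
#' @export
eval_basis_deriv <- function(spec, y, extrapolate = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$kind == "ordinal")
    stop2("the ordinal basis is a step function; no derivative is available")
  if (!extrapolate) check_support(spec, y)
  if (spec$kind == "linear")
    return(cbind(0, rep(1, length(y))))
  y <- pmin(pmax(y, spec$support[1L]), spec$support[2L])
  P <- spec$order
  w <- diff(spec$support)
  t <- (y - spec$support[1L]) / w
  # d/dt C(P,j) t^j (1-t)^(P-j) = P * (B_{j-1,P-1}(t) - B_{j,P-1}(t))
  lower <- function(jj) if (jj >= 1L && jj <= P) stats::dbinom(jj - 1L, P - 1L, t) else rep(0, length(t))
  upper <- function(jj) if (jj <= P - 1L) stats::dbinom(jj, P - 1L, t) else rep(0, length(t))
  D <- vapply(0:P, function(jj) P * (lower(jj) - upper(jj)) / w,
              numeric(length(t)))
  matrix(D, nrow = length(y), ncol = P + 1L)
}

check_support <- function(spec, y) {
  s <- spec$support
  if (any(y < s[1L] - 1e-12 | y > s[2L] + 1e-12, na.rm = TRUE))
    stop2("response value outside the basis support [",
          signif(s[1L], 6), ", ", signif(s[2L], 6), "]")
  invisible(TRUE)
}

#' Monotone reparametrization of baseline coefficients
#'
#' Maps unconstrained parameters to a strictly increasing coefficient vector
#' via log-increments: \eqn{\theta_1 = \gamma_1},
#' \eqn{\theta_{k+1} = \theta_k + \exp(\gamma_{k+1})}. `free_from_theta()` is
#' the exact inverse, defined on strictly increasing vectors. The round trip
#' is the identity to machine precision.
#'
#' @param free,theta numeric vectors of equal basis dimension.
#' @return numeric vector of the same length.
#' @examples
#' theta_from_free(c(0, 0, 0))  # c(0, 1, 2)
#' @export
theta_from_free <- function(free) {
  if (length(free) == 1L) return(free)
  cumsum(c(free[1L], exp(free[-1L])))
}

#' @rdname theta_from_free
#' @export
free_from_theta <- function(theta) {
  if (length(theta) == 1L) return(theta)
  d <- diff(theta)
  if (any(d <= 0)) stop2("'theta' must be strictly increasing")
  c(theta[1L], log(d))
}

# Jacobian-vector product: given grad wrt theta, return grad wrt free.
# dtheta_k/dfree_1 = 1 (all k); dtheta_k/dfree_j = exp(free_j) for 2 <= j <= k.
grad_free_from_theta <- function(grad_theta, free) {
  m <- length(free)
  if (m == 1L) return(grad_theta)
  rev_cum <- rev(cumsum(rev(grad_theta)))   # sum_{k >= j} grad_theta_k
  c(rev_cum[1L], rev_cum[-1L] * exp(free[-1L]))
}
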