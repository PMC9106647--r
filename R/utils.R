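# Internal numerical helpers.

# log(1 - exp(x)) for x <= 0, stable near 0 and -Inf.
log1mexp <- function(x) {
  stopifnot(all(x <= 0 | is.nan(x)))
  out <- x
  small <- x > -log(2)           # exp(x) close to 1
  out[small] <- log(-expm1(x[small]))
  out[!small] <- log1p(-exp(x[!small]))
  out
}

# log(exp(la) - exp(lb)) for la >= lb; -Inf when equal.
logdiffexp <- function(la, lb) {
  out <- la + log1mexp(pmin(lb - la, 0))
  out[is.infinite(la) & is.infinite(lb) & la < 0] <- -Inf
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)
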