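#' Censored and ordinal response containers
#'
#' `cens_response()` stores each observation's response as a half-open
#' interval \eqn{(\underline{y}, \overline{y}]} with a censoring tag:
#' \describe{
#'   \item{exact}{`lower == upper`, both finite;}
#'   \item{left}{`lower == -Inf`, finite `upper`;}
#'   \item{right}{finite `lower`, `upper == Inf`;}
#'   \item{interval}{finite or infinite bounds with `lower < upper`.}
#' }
#' `ordinal_response()` stores integer class labels `1..K`; internally the
#' class is an interval between adjacent thresholds on the latent scale.
#'
#' @param lower,upper numeric vectors of interval bounds (`-Inf`/`Inf`
#'   allowed as appropriate); `upper` defaults to `lower` (exact).
#' @param tag optional character vector of tags; inferred from the bounds
#'   when missing.
#' @return an object of class `tm_response`.
#' @examples
#' cens_response(c(1, 2), c(1, Inf))        # exact, right-censored
#' ordinal_response(c(1, 3, 2), n_classes = 3)
#' @export
cens_response <- function(lower, upper = lower, tag = NULL) {
  n <- length(lower)
  if (length(upper) != n) stop2("'lower' and 'upper' must have equal length")
  if (is.null(tag)) {
    tag <- rep("interval", n)
    tag[is.finite(lower) & lower == upper] <- "exact"
    tag[is.infinite(lower) & lower < 0 & is.finite(upper)] <- "left"
    tag[is.finite(lower) & is.infinite(upper) & upper > 0] <- "right"
  }
  tag <- as.character(tag)
  if (!all(tag %in% c("exact", "left", "right", "interval")))
    stop2("censoring tags must be exact/left/right/interval")
  ok <- switch_all(tag, lower, upper)
  if (!all(ok)) stop2("invalid bounds for tags at positions: ",
                      paste(utils::head(which(!ok), 5L), collapse = ", "))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 tag = tag, type = "continuous"),
            class = "tm_response")
}

switch_all <- function(tag, lower, upper) {
  ok <- logical(length(tag))
  ok[tag == "exact"] <- is.finite(lower[tag == "exact"]) &
    lower[tag == "exact"] == upper[tag == "exact"]
  ok[tag == "left"] <- is.infinite(lower[tag == "left"]) &
    lower[tag == "left"] < 0 & is.finite(upper[tag == "left"])
  ok[tag == "right"] <- is.finite(lower[tag == "right"]) &
    is.infinite(upper[tag == "right"]) & upper[tag == "right"] > 0
  ok[tag == "interval"] <- lower[tag == "interval"] < upper[tag == "interval"]
  ok
}

#' @rdname cens_response
#' @param class_index integer vector of ordinal classes in `1..n_classes`.
#' @param n_classes number of classes `K`.
#' @export
ordinal_response <- function(class_index, n_classes) {
  class_index <- as.integer(class_index)
  n_classes <- as.integer(n_classes)
  if (any(class_index < 1L | class_index > n_classes))
    stop2("class indices must lie in 1..", n_classes)
  structure(list(class_index = class_index, n_classes = n_classes,
                 type = "ordinal"),
            class = "tm_response")
}

#' @export
length.tm_response <- function(x)
  if (x$type == "ordinal") length(x$class_index) else length(x$lower)

#' @export
print.tm_response <- function(x, ...) {
  if (x$type == "ordinal") {
    cat(sprintf("ordinal response: %d observations, %d classes\n",
                length(x), x$n_classes))
  } else {
    cat(sprintf("censored response: %d observations (%s)\n", length(x),
                paste(names(table(x$tag)), table(x$tag),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

# subset a response
subset_response <- function(r, idx) {
  if (r$type == "ordinal")
    ordinal_response(r$class_index[idx], r$n_classes)
  else
    cens_response(r$lower[idx], r$upper[idx], r$tag[idx])
}

#' Coerce to a response object
#'
#' Plain numeric vectors become exact responses; integer-valued factors and
#' `tm_response` objects pass through.
#' @param y numeric vector, factor or `tm_response`.
#' @param n_classes optional; treat `y` as ordinal with `K = n_classes`.
#' @return a `tm_response`.
#' @export
as_response <- function(y, n_classes = NULL) {
  if (inherits(y, "tm_response")) return(y)
  if (is.factor(y)) return(ordinal_response(as.integer(y), nlevels(y)))
  if (!is.null(n_classes)) return(ordinal_response(y, n_classes))
  cens_response(y)
}
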