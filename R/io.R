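# Delimited-text data interchange.
#
# Continuous (possibly censored) responses travel as two bound columns plus
# a censoring tag column (exact/left/right/interval); empty bound fields
# mean -Inf / +Inf. Ordinal responses travel as a single integer class
# column. Covariates and anchors are plain numeric / string columns.

#' Read and write transformation-model datasets
#'
#' @param path CSV file path (header row, '.' decimal, UTF-8).
#' @param response_cols one column name (exact continuous or ordinal
#'   integer classes) or two (lower, upper interval bounds).
#' @param cens_col optional censoring tag column
#'   (`exact/left/right/interval`); inferred from the bounds when absent.
#' @param covariate_cols,anchor_cols character vectors of column names
#'   (anchors may be non-numeric: they are treated as categorical).
#' @param n_classes when given, the single response column is read as
#'   ordinal classes `1..n_classes`.
#' @return `read_tm_data`: list with `response` (a `tm_response`), `X`
#'   (numeric matrix or `NULL`), `anchors` (data.frame or `NULL`), `data`
#'   (the raw data.frame).
#' @export
read_tm_data <- function(path, response_cols, cens_col = NULL,
                         covariate_cols = character(0),
                         anchor_cols = character(0), n_classes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(response_cols, cens_col, covariate_cols,
                            anchor_cols), names(df))
  if (length(missing_cols))
    stop2("columns not found in ", path, ": ",
          paste(missing_cols, collapse = ", "))
  if (length(response_cols) == 1L) {
    yc <- df[[response_cols]]
    response <- if (!is.null(n_classes)) ordinal_response(yc, n_classes)
      else cens_response(as.numeric(yc))
  } else {
    lo <- suppressWarnings(as.numeric(df[[response_cols[1L]]]))
    up <- suppressWarnings(as.numeric(df[[response_cols[2L]]]))
    lo[is.na(lo)] <- -Inf
    up[is.na(up)] <- Inf
    tag <- if (!is.null(cens_col)) df[[cens_col]] else NULL
    response <- cens_response(lo, up, tag)
  }
  X <- if (length(covariate_cols))
    as.matrix(df[covariate_cols]) else NULL
  anchors <- if (length(anchor_cols)) df[anchor_cols] else NULL
  list(response = response, X = X, anchors = anchors, data = df)
}

#' @rdname read_tm_data
#' @param sim a `tm_sim` object from [simulate_scenario].
#' @export
write_sim_data <- function(sim, path) {
  stopifnot(inherits(sim, "tm_sim"))
  r <- sim$response
  df <- if (r$type == "ordinal") data.frame(y = r$class_index)
    else data.frame(y_lower = r$lower, y_upper = r$upper, cens = r$tag)
  X <- sim$X; colnames(X) <- paste0("x", seq_len(ncol(X)))
  A <- sim$A; colnames(A) <- paste0("a", seq_len(ncol(A)))
  df <- cbind(df, X, A)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# serialize a model / basis / config for the JSON manifest
basis_to_list <- function(b)
  list(kind = b$kind, order = b$order, n_classes = b$n_classes,
       support = b$support)

basis_from_list <- function(l)
  basis_spec(l$kind, order = l$order %||% 6L, n_classes = l$n_classes,
             support = unlist(l$support))

model_to_list <- function(m)
  list(link = m$link$name, basis = basis_to_list(m$basis),
       theta = m$theta, beta = m$beta)

model_from_list <- function(l)
  trafo_model(l$link, basis_from_list(l$basis), unlist(l$theta),
              unlist(l$beta %||% numeric(0)))

#' Write and read a run manifest
#'
#' A manifest records the command, its configuration snapshot, the seed,
#' the package version, timestamps, output paths and convergence
#' summaries, plus (for `fit`) the full fitted model so a run can be
#' re-scored.
#'
#' @param manifest named list.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path)
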