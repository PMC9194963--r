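# The development sample: n rows of encoded (numeric) covariates plus a
# binary outcome.  Everything downstream conditions on this one dataset.

#' Construct a development sample
#'
#' Bundles an encoded covariate table and a binary outcome vector.  Covariates
#' must already be numeric (see [read_sample()] for one-hot encoding of
#' categorical columns).  At least one event and one non-event are required at
#' model-fitting time, not at construction.
#'
#' @param data Data frame containing the outcome column and numeric predictor
#'   columns.
#' @param outcome Name of the 0/1 outcome column. Default `"outcome"`.
#' @return An object of class `development_sample` with elements
#'   `covariates` (data frame), `outcomes` (integer 0/1 vector) and `n`.
#' @examples
#' d <- data.frame(x = rnorm(20), outcome = rbinom(20, 1, 0.3))
#' s <- development_sample(d)
#' s$n
#' @export
development_sample <- function(data, outcome = "outcome") {
  if (!is.data.frame(data)) stop("'data' must be a data frame", call. = FALSE)
  if (nrow(data) < 1L) stop("'data' must have at least one row", call. = FALSE)
  if (!outcome %in% names(data))
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  bad <- which(is.na(y) | !(y %in% c(0, 1)))
  if (length(bad))
    stop("outcome column '", outcome, "' must be coded 0/1; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  covs <- data[setdiff(names(data), outcome)]
  if (ncol(covs) < 1L)
    stop("at least one predictor column is required", call. = FALSE)
  not_num <- names(covs)[!vapply(covs, is.numeric, logical(1))]
  if (length(not_num))
    stop("non-numeric predictor column(s): ",
         paste(not_num, collapse = ", "),
         " (encode them first, e.g. with read_sample())", call. = FALSE)
  structure(
    list(covariates = covs, outcomes = as.integer(y), n = nrow(covs)),
    class = "development_sample"
  )
}

#' @export
print.development_sample <- function(x, ...) {
  cat("Development sample: n =", x$n,
      "| events =", sum(x$outcomes),
      "| predictors =", ncol(x$covariates), "\n")
  cat("  ", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.development_sample <- function(x, ...) {
  cbind(x$covariates, outcome = x$outcomes)
}

n_events <- function(sample) sum(sample$outcomes == 1L)
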