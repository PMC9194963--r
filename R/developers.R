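# The model-developer contract.  A developer encapsulates the whole model
# development process (including any variable selection or shrinkage), so
# that re-running it inside every bootstrap draw propagates all of that
# uncertainty into the posterior of correct risks.
#
# fit(sample, weights, indices) -> fitted object
#   weights : length-n nonnegative weights summing to 1 (Bayesian bootstrap),
#             or NULL for an unweighted fit on the full sample;
#   indices : integer row indices of an ordinary-bootstrap resample.  When
#             given, developers fit on those rows directly, which is exactly
#             resample-rows-then-fit (and identical to a count-weighted fit
#             for likelihood-based developers).
# predict(fitted, covariates) -> risk vector in [0, 1] for the given rows.

#' Define a model developer
#'
#' @param fit Function `(sample, weights, indices) -> fitted object`.  Either
#'   `weights` (continuous, summing to 1) or `indices` (a bootstrap resample)
#'   or neither (full-sample fit) is supplied.
#' @param predict Function `(fitted, covariates) -> numeric risks` in
#'   `[0, 1]`, one per row of `covariates`.
#' @param label Short description used in printed output.
#' @return An object of class `model_developer`.
#' @seealso [logistic_developer()], [lasso_developer()],
#'   [intercept_developer()]
#' @export
model_developer <- function(fit, predict, label = "custom developer") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(fit = fit, predict = predict, label = label),
            class = "model_developer")
}

#' @export
print.model_developer <- function(x, ...) {
  cat("Model developer:", x$label, "\n")
  invisible(x)
}

# internal: fit on the full, unweighted sample and predict on it
fit_proposed <- function(developer, sample) {
  fitted <- developer$fit(sample, weights = NULL, indices = NULL)
  pi <- developer$predict(fitted, sample$covariates)
  .check_risks(pi, "proposed-model predictions")
  list(fitted = fitted, risks = as.numeric(pi))
}

.resolve_fit_data <- function(sample, weights, indices) {
  y <- sample$outcomes
  covs <- sample$covariates
  if (!is.null(indices)) {
    list(covariates = covs[indices, , drop = FALSE], y = y[indices], w = NULL)
  } else if (!is.null(weights)) {
    # scale to total mass n so the weighted log-likelihood carries the
    # information of n observations
    list(covariates = covs, y = y, w = weights * length(y))
  } else {
    list(covariates = covs, y = y, w = NULL)
  }
}

#' Maximum-likelihood logistic developer
#'
#' Fits an (unpenalized) logistic regression on all predictor columns, or on
#' a user-supplied right-hand side.  Accepts continuous case weights, as
#' required by the Bayesian bootstrap.
#'
#' @param rhs Optional one-sided formula (or character) giving the linear
#'   predictor, e.g. `~ age + killip`; default uses every predictor column
#'   linearly.
#' @return A `model_developer`.
#' @export
logistic_developer <- function(rhs = NULL) {
  rhs_txt <- if (is.null(rhs)) "." else {
    f <- if (is.character(rhs)) rhs else paste(deparse(rhs), collapse = "")
    sub("^~", "", f)
  }
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) {
      d <- .resolve_fit_data(sample, weights, indices)
      if (sum(d$y == 1) < 1L || sum(d$y == 0) < 1L)
        stop("cannot fit a logistic model without both events and non-events",
             call. = FALSE)
      df <- cbind(d$covariates, .y = d$y)
      .wvec <- if (is.null(d$w)) rep(1, length(d$y)) else d$w
      fml <- stats::as.formula(paste(".y ~", rhs_txt),
                               env = environment())
      suppressWarnings(
        stats::glm(fml, family = stats::binomial(), data = df,
                   weights = .wvec)
      )
    },
    predict = function(fitted, covariates) {
      as.numeric(stats::predict(fitted, newdata = covariates,
                                type = "response"))
    },
    label = sprintf("logistic (ML), rhs = %s", rhs_txt)
  )
}

#' Cross-validated lasso logistic developer
#'
#' Fits a logistic model by the lasso with the shrinkage parameter chosen by
#' k-fold cross-validation (as is standard for penalized risk models).  The
#' cross-validation — including its random fold assignment — is re-run inside
#' every bootstrap draw, so selection and shrinkage uncertainty propagate
#' into the posterior of correct risks.
#'
#' @param nfolds Number of cross-validation folds. Default 10.
#' @param s Which penalty to use for prediction: `"lambda.min"` (default,
#'   the CV-optimal shrinkage) or `"lambda.1se"`.
#' @return A `model_developer`.
#' @export
lasso_developer <- function(nfolds = 10, s = "lambda.min") {
  s <- match.arg(s, c("lambda.min", "lambda.1se"))
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) {
      d <- .resolve_fit_data(sample, weights, indices)
      if (sum(d$y == 1) < 1L || sum(d$y == 0) < 1L)
        stop("cannot fit a lasso model without both events and non-events",
             call. = FALSE)
      x <- as.matrix(d$covariates)
      suppressWarnings(glmnet::cv.glmnet(
        x, d$y, family = "binomial",
        weights = if (is.null(d$w)) rep(1, length(d$y)) else d$w,
        nfolds = nfolds
      ))
    },
    predict = function(fitted, covariates) {
      as.numeric(stats::predict(fitted, newx = as.matrix(covariates),
                                type = "response", s = s))
    },
    label = sprintf("lasso logistic, %d-fold CV, %s", nfolds, s)
  )
}

#' Fixed-penalty ridge logistic developer
#'
#' Logistic regression with a fixed L2 penalty.  Unpenalized refits on
#' bootstrap resamples of a rare outcome can quasi-separate and produce
#' unbounded coefficient draws; a small fixed ridge penalty keeps every
#' refit stable, and involves no cross-validation randomness, which makes
#' this the reference developer for comparing posterior sampling schemes.
#'
#' @param lambda Penalty strength on glmnet's scale. Default 0.01.
#' @return A `model_developer`.
#' @export
ridge_developer <- function(lambda = 0.01) {
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) {
      d <- .resolve_fit_data(sample, weights, indices)
      if (sum(d$y == 1) < 1L || sum(d$y == 0) < 1L)
        stop("cannot fit a ridge model without both events and non-events",
             call. = FALSE)
      glmnet::glmnet(as.matrix(d$covariates), d$y, family = "binomial",
                     alpha = 0, lambda = lambda,
                     weights = if (is.null(d$w)) rep(1, length(d$y)) else d$w)
    },
    predict = function(fitted, covariates) {
      as.numeric(stats::predict(fitted, newx = as.matrix(covariates),
                                type = "response", s = lambda))
    },
    label = sprintf("ridge logistic, lambda = %g", lambda)
  )
}

#' Intercept-only developer
#'
#' Predicts the (weighted) event rate for everyone.  Useful as a baseline and
#' for calibration tests: under the Bayesian bootstrap its posterior of the
#' constant risk is the Dirichlet-weighted event rate.
#'
#' @return A `model_developer`.
#' @export
intercept_developer <- function() {
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) {
      d <- .resolve_fit_data(sample, weights, indices)
      if (is.null(d$w)) mean(d$y) else sum(d$w * d$y) / sum(d$w)
    },
    predict = function(fitted, covariates) rep(fitted, nrow(covariates)),
    label = "intercept only (event rate)"
  )
}

#' Constant-risk developer
#'
#' Ignores the data entirely and predicts a fixed risk.  A data-independent
#' developer has zero optimism and a point-mass posterior.
#'
#' @param risk The constant predicted risk, in `[0, 1]`.
#' @return A `model_developer`.
#' @export
constant_developer <- function(risk) {
  .check_risks(risk, "'risk'")
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) risk,
    predict = function(fitted, covariates) rep(fitted, nrow(covariates)),
    label = sprintf("constant risk %.3f", risk)
  )
}

#' Point-mass (no-uncertainty) developer
#'
#' Wraps another developer but ignores bootstrap weights and indices, always
#' refitting on the full unweighted sample.  Every posterior draw therefore
#' returns the proposed model itself, so the EVPI is identically zero — the
#' degenerate "no parameter uncertainty" case.
#'
#' @param base A `model_developer` to freeze.
#' @return A `model_developer`.
#' @export
point_mass_developer <- function(base) {
  stopifnot(inherits(base, "model_developer"))
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) {
      base$fit(sample, weights = NULL, indices = NULL)
    },
    predict = base$predict,
    label = paste("point mass:", base$label)
  )
}

#' Oracle developer returning fixed true risks
#'
#' For simulation studies only: returns a stored vector of true risks for the
#' original sample regardless of the data, emulating access to the correct
#' model.  Prediction is only defined on covariate tables with the same
#' number of rows as the stored vector.
#'
#' @param true_risks Numeric vector of true risks aligned with the original
#'   sample rows.
#' @return A `model_developer`.
#' @export
oracle_developer <- function(true_risks) {
  .check_risks(true_risks, "'true_risks'")
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) true_risks,
    predict = function(fitted, covariates) {
      if (nrow(covariates) != length(fitted))
        stop("oracle developer can only predict on the original sample rows",
             call. = FALSE)
      fitted
    },
    label = "oracle (true risks)"
  )
}
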