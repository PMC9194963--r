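# Sampling from the posterior of the correct model, P(theta | D), expressed
# as correct-risk vectors on the original sample.  Three schemes:
#   bayesian_bootstrap — Dirichlet(1,...,1) observation weights;
#   ordinary_bootstrap — multinomial counts/n, i.e. resampling rows;
#   likelihood_mvn     — multivariate-normal coefficient draws around the
#                        logistic MLE (flat-prior large-sample posterior).

SAMPLING_SCHEMES <- c("ordinary_bootstrap", "bayesian_bootstrap",
                      "likelihood_mvn")

#' Bayesian-bootstrap (Dirichlet) weights
#'
#' Draws one weight vector distributed Dirichlet(1, ..., 1) by the
#' ordered-uniform gaps construction: draw `n - 1` standard uniforms, sort
#' them, and take successive differences with endpoints 0 and 1.  Uses the
#' current RNG state.
#'
#' @param n Number of observations (>= 1).
#' @return Numeric vector of `n` nonnegative weights summing to 1.
#' @export
bayesian_bootstrap_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (n == 1L) return(1)
  diff(c(0, sort(stats::runif(n - 1L)), 1))
}

#' Ordinary-bootstrap (multinomial) weights
#'
#' Draws one weight vector from Multinomial(n; 1/n, ..., 1/n) scaled by
#' `1/n` — equivalent to resampling `n` rows with replacement.  Uses the
#' current RNG state.
#'
#' @inheritParams bayesian_bootstrap_weights
#' @return Numeric vector of `n` weights, each a multiple of `1/n`, summing
#'   to 1.
#' @export
ordinary_bootstrap_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  tabulate(sample.int(n, n, replace = TRUE), nbins = n) / n
}

# Per-draw substream seeds derived from one master seed, so draw i is
# reproducible independently of execution order.
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

#' Likelihood-based multivariate-normal posterior of logistic coefficients
#'
#' Fits a maximum-likelihood logistic regression and packages the coefficient
#' vector and covariance matrix as a multivariate-normal posterior (the
#' flat-prior, large-sample approximation).  Non-convergence, aliased
#' coefficients or a non-positive-definite covariance are explicit errors.
#'
#' @param sample A [development_sample()].
#' @param rhs Optional one-sided formula for the linear predictor; default
#'   uses all predictor columns linearly.
#' @return An object of class `mvn_posterior` with elements `coef`, `vcov`,
#'   the Cholesky factor `chol` and the design matrix `X` on the original
#'   sample.
#' @export
mvn_posterior <- function(sample, rhs = NULL) {
  stopifnot(inherits(sample, "development_sample"))
  rhs_txt <- if (is.null(rhs)) "." else {
    f <- if (is.character(rhs)) rhs else paste(deparse(rhs), collapse = "")
    sub("^~", "", f)
  }
  fml <- stats::as.formula(paste(".y ~", rhs_txt))
  df <- cbind(sample$covariates, .y = sample$outcomes)
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df))
  if (!fit$converged)
    stop("maximum-likelihood logistic fit did not converge", call. = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("aliased (rank-deficient) coefficients; covariance is singular",
         call. = FALSE)
  V <- stats::vcov(fit)
  R <- tryCatch(chol(V), error = function(e)
    stop("coefficient covariance matrix is not positive definite",
         call. = FALSE))
  X <- stats::model.matrix(fit)
  structure(list(coef = beta, vcov = V, chol = R, X = X, formula = fml),
            class = "mvn_posterior")
}

#' Draw coefficient vectors from an MVN posterior
#'
#' @param posterior An [mvn_posterior()] object.
#' @param n_draws Number of draws.
#' @param scale Multiplier on the covariance Cholesky factor; `scale = 0`
#'   collapses every draw onto the MLE.
#' @return Matrix with `n_draws` rows, one coefficient vector per row.  Uses
#'   the current RNG state.
#' @export
draw_coefficients <- function(posterior, n_draws = 1, scale = 1) {
  stopifnot(inherits(posterior, "mvn_posterior"))
  k <- length(posterior$coef)
  zmat <- matrix(stats::rnorm(n_draws * k), n_draws, k)
  sweep(scale * (zmat %*% posterior$chol), 2, posterior$coef, "+")
}

#' One likelihood-based coefficient draw
#'
#' Convenience wrapper: fit the MVN posterior on `sample` and return a single
#' coefficient draw.
#'
#' @inheritParams mvn_posterior
#' @return Named numeric coefficient vector.
#' @export
likelihood_mvn_sampler <- function(sample, rhs = NULL) {
  post <- mvn_posterior(sample, rhs)
  drop(draw_coefficients(post, 1))
}

mvn_risks <- function(posterior, beta) {
  as.numeric(stats::plogis(posterior$X %*% as.numeric(beta)))
}

# one ordinary-bootstrap iteration: resample indices under the events guard,
# fit, predict on the original sample.  Shared by the VoI engine, Harrell
# optimism correction and the joint loop, so a common seed gives a common
# draw stream.
ordinary_iteration <- function(sample, developer, min_events = 1L,
                               max_redraws = 100L) {
  n <- sample$n
  y <- sample$outcomes
  for (attempt in seq_len(max_redraws)) {
    idx <- sample.int(n, n, replace = TRUE)
    ev <- sum(y[idx] == 1L)
    if (ev < min_events || ev > n - 1L) next
    fitted <- tryCatch(
      developer$fit(sample, weights = NULL, indices = idx),
      error = function(e) NULL
    )
    if (is.null(fitted)) next
    p <- tryCatch(developer$predict(fitted, sample$covariates),
                  error = function(e) NULL)
    if (is.null(p) || anyNA(p) || any(p < 0 | p > 1)) next
    return(list(ok = TRUE, risks = as.numeric(p), indices = idx,
                fitted = fitted, attempts = attempt))
  }
  list(ok = FALSE, risks = NULL, indices = NULL, fitted = NULL,
       attempts = max_redraws)
}

bayesian_iteration <- function(sample, developer, min_events = 1L,
                               max_redraws = 100L) {
  n <- sample$n
  y <- sample$outcomes
  for (attempt in seq_len(max_redraws)) {
    w <- bayesian_bootstrap_weights(n)
    ev <- sum(w > 0 & y == 1L)       # Dirichlet weights are a.s. positive
    nev <- sum(w > 0 & y == 0L)
    if (ev < min_events || nev < 1L) next
    fitted <- tryCatch(
      developer$fit(sample, weights = w, indices = NULL),
      error = function(e) NULL
    )
    if (is.null(fitted)) next
    p <- tryCatch(developer$predict(fitted, sample$covariates),
                  error = function(e) NULL)
    if (is.null(p) || anyNA(p) || any(p < 0 | p > 1)) next
    return(list(ok = TRUE, risks = as.numeric(p), weights = w,
                fitted = fitted, attempts = attempt))
  }
  list(ok = FALSE, risks = NULL, weights = NULL, fitted = NULL,
       attempts = max_redraws)
}

#' Draw one correct-risk vector from the posterior
#'
#' One Monte Carlo draw of the correct risks on the original sample: obtain a
#' (Bayesian) bootstrap sample, redo model development on it, and apply the
#' refitted model to the original covariates.  For `likelihood_mvn` a
#' coefficient vector is drawn from the MVN posterior instead and pushed
#' through the inverse-logit link.
#'
#' A drawn weighted sample with fewer than `min_events` events (or no
#' non-events) is redrawn, up to `max_redraws` attempts; persistent failure
#' is reported via `ok = FALSE`, never silently.
#'
#' Uses the current RNG state; seed it for reproducibility.
#'
#' @param sample A [development_sample()].
#' @param developer A [model_developer()].
#' @param scheme One of `"ordinary_bootstrap"`, `"bayesian_bootstrap"`,
#'   `"likelihood_mvn"`.
#' @param min_events Minimum number of events required in a (weighted)
#'   resample. Default 1.
#' @param max_redraws Redraw budget before the draw is declared failed.
#' @param mvn Optional precomputed [mvn_posterior()] (required inside loops
#'   for `likelihood_mvn` so the MLE is fit once).
#' @return A list with `ok`, `risks` (length-n vector in `[0, 1]` or NULL)
#'   and `attempts`.
#' @export
draw_correct_risks <- function(sample, developer,
                               scheme = SAMPLING_SCHEMES,
                               min_events = 1L, max_redraws = 100L,
                               mvn = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(sample, "development_sample"))
  if (scheme == "likelihood_mvn") {
    if (is.null(mvn)) mvn <- mvn_posterior(sample)
    beta <- draw_coefficients(mvn, 1)
    return(list(ok = TRUE, risks = mvn_risks(mvn, beta), attempts = 1L))
  }
  it <- switch(scheme,
    ordinary_bootstrap = ordinary_iteration(sample, developer, min_events,
                                            max_redraws),
    bayesian_bootstrap = bayesian_iteration(sample, developer, min_events,
                                            max_redraws)
  )
  list(ok = it$ok, risks = it$risks, attempts = it$attempts)
}
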