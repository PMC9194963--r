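# Synthetic logistic-model development samples with known truth, so the full
# pipeline (development, posterior sampling, EVPI, optimism) is testable
# end-to-end.  Covariate transforms mirror common risk-model practice:
# truncation (min(x, cap)) and a linear spline with one knot.

#' Covariate transform: truncate above a cap
#'
#' Elementwise `min(x, cap)` — e.g. systolic blood pressure modeled as
#' `min(X, 100)` so the effect is confined to the hypotensive range.
#'
#' @param x Numeric vector.
#' @param cap Upper cap.
#' @return Numeric vector.
#' @export
truncate_above <- function(x, cap) pmin(x, cap)

#' Covariate transform: linear-spline basis with one knot
#'
#' Returns the two-column basis `(x, max(0, x - knot))` so the slope can
#' differ below and above the knot.
#'
#' @param x Numeric vector.
#' @param knot Knot location.
#' @return Two-column numeric matrix.
#' @export
linear_spline_basis <- function(x, knot) {
  cbind(x, pmax(0, x - knot))
}

apply_transform <- function(x, transform, name) {
  kind <- transform$kind
  if (kind == "identity") {
    out <- matrix(x, ncol = 1, dimnames = list(NULL, name))
  } else if (kind == "truncate_above") {
    out <- matrix(truncate_above(x, transform$cap), ncol = 1,
                  dimnames = list(NULL, name))
  } else if (kind == "linear_spline") {
    out <- linear_spline_basis(x, transform$knot)
    colnames(out) <- c(name, paste0(name, "_hi"))
  } else {
    stop("unknown transform kind: ", kind, call. = FALSE)
  }
  out
}

n_basis_cols <- function(transform) {
  if (transform$kind == "linear_spline") 2L else 1L
}

#' Define a logistic data-generating process
#'
#' Each predictor has a marginal distribution (`normal(mean, sd)` or
#' `binary(prob)`), an optional transform applied before the linear
#' predictor (`identity`, `truncate_above(cap)`, `linear_spline(knot)` —
#' the spline contributes two basis columns) and one coefficient per basis
#' column.  The outcome is Bernoulli with probability
#' `plogis(intercept + basis %*% coefficients)`.
#'
#' @param intercept Intercept of the linear predictor.
#' @param predictors Named list; each element is a list with fields `dist`
#'   (list with `kind` and its parameters), optional `transform` (list with
#'   `kind` and its parameters; default identity) and `coef` (numeric,
#'   length equal to the number of basis columns).
#' @return An object of class `logistic_dgp`.
#' @examples
#' dgp <- logistic_dgp(
#'   intercept = -2,
#'   predictors = list(
#'     age = list(dist = list(kind = "normal", mean = 60, sd = 10),
#'                coef = 0.03),
#'     pulse = list(dist = list(kind = "normal", mean = 75, sd = 15),
#'                  transform = list(kind = "linear_spline", knot = 50),
#'                  coef = c(0.02, -0.01))
#'   )
#' )
#' @export
logistic_dgp <- function(intercept, predictors) {
  if (!is.list(predictors) || length(predictors) < 1L ||
      is.null(names(predictors)) || any(names(predictors) == ""))
    stop("'predictors' must be a non-empty named list", call. = FALSE)
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    if (is.null(p$transform)) p$transform <- list(kind = "identity")
    if (!p$dist$kind %in% c("normal", "binary"))
      stop("predictor '", nm, "': unknown distribution kind '",
           p$dist$kind, "'", call. = FALSE)
    if (p$dist$kind == "binary" &&
        (p$dist$prob <= 0 || p$dist$prob >= 1))
      stop("predictor '", nm, "': binary probability must be in (0, 1)",
           call. = FALSE)
    if (!p$transform$kind %in% c("identity", "truncate_above",
                                 "linear_spline"))
      stop("predictor '", nm, "': unknown transform kind '",
           p$transform$kind, "'", call. = FALSE)
    if (length(p$coef) != n_basis_cols(p$transform))
      stop("predictor '", nm, "': need ", n_basis_cols(p$transform),
           " coefficient(s) for its basis", call. = FALSE)
    predictors[[nm]] <- p
  }
  structure(list(intercept = intercept, predictors = predictors),
            class = "logistic_dgp")
}

#' @export
print.logistic_dgp <- function(x, ...) {
  cat("Logistic DGP: intercept", format(x$intercept, digits = 4), "and",
      length(x$predictors), "predictor(s)\n")
  invisible(x)
}

#' Generate a development sample from a logistic truth
#'
#' Draws covariates per the DGP, applies the transforms, and simulates the
#' binary outcome from the true risks.  The returned sample's predictor
#' columns are the transformed basis columns (model-ready), so a developer
#' using them linearly matches the true model structure.  `true_risks` is
#' returned separately for oracle testing and is never part of the sample a
#' developer can see.
#'
#' @param dgp A [logistic_dgp()].
#' @param n Number of observations.
#' @param seed Optional seed; default uses the current RNG state.
#' @return List with `sample` (a [development_sample()]) and `true_risks`.
#' @export
generate_sample <- function(dgp, n, seed = NULL) {
  stopifnot(inherits(dgp, "logistic_dgp"))
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cols <- list()
  for (nm in names(dgp$predictors)) {
    p <- dgp$predictors[[nm]]
    x <- switch(p$dist$kind,
      normal = stats::rnorm(n, p$dist$mean, p$dist$sd),
      binary = stats::rbinom(n, 1L, p$dist$prob)
    )
    cols[[nm]] <- apply_transform(x, p$transform, nm)
  }
  basis <- do.call(cbind, cols)
  beta <- unlist(lapply(dgp$predictors, function(p) p$coef),
                 use.names = FALSE)
  lp <- dgp$intercept + as.numeric(basis %*% beta)
  p_true <- stats::plogis(lp)
  y <- stats::rbinom(n, 1L, p_true)
  df <- as.data.frame(basis)
  df$outcome <- y
  list(sample = development_sample(df), true_risks = p_true)
}

#' Calibrate a DGP intercept to a target event rate
#'
#' Solves for the intercept that gives a requested marginal event rate,
#' using one large Monte Carlo covariate sample and root finding.
#'
#' @param dgp A [logistic_dgp()].
#' @param target_rate Desired marginal event rate in (0, 1).
#' @param n_mc Monte Carlo sample size used in the calibration.
#' @param seed Seed for the calibration sample.
#' @return The input DGP with its intercept replaced.
#' @export
calibrate_intercept <- function(dgp, target_rate, n_mc = 200000,
                                seed = 761L) {
  stopifnot(inherits(dgp, "logistic_dgp"),
            target_rate > 0, target_rate < 1)
  set.seed(seed)
  cols <- list()
  for (nm in names(dgp$predictors)) {
    p <- dgp$predictors[[nm]]
    x <- switch(p$dist$kind,
      normal = stats::rnorm(n_mc, p$dist$mean, p$dist$sd),
      binary = stats::rbinom(n_mc, 1L, p$dist$prob)
    )
    cols[[nm]] <- apply_transform(x, p$transform, nm)
  }
  basis <- do.call(cbind, cols)
  beta <- unlist(lapply(dgp$predictors, function(p) p$coef),
                 use.names = FALSE)
  off <- as.numeric(basis %*% beta)
  f <- function(a) mean(stats::plogis(a + off)) - target_rate
  dgp$intercept <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
  dgp
}

#' Preset DGP emulating a post-MI mortality development setting
#'
#' A seven-predictor logistic truth with a low (about 7%) marginal event
#' rate, chosen to exercise every transform: a continuous age-like predictor,
#' a blood-pressure-like predictor truncated above 100, a pulse-like
#' predictor with a linear-spline knot at 50, and four binary comorbidity
#' indicators (two of them pure noise).  Coefficient values are package
#' defaults on plausible clinical scales; they are not estimates from any
#' real trial.
#'
#' @param coef_scale Multiplier applied to all non-intercept coefficients
#'   (discrimination knob); the intercept is recalibrated to `event_rate`
#'   when `coef_scale != 1` or `event_rate != 0.07`.
#' @param event_rate Target marginal event rate. Default 0.07.
#' @return A [logistic_dgp()].
#' @export
gusto_like_dgp <- function(coef_scale = 1, event_rate = 0.07) {
  preds <- list(
    age = list(dist = list(kind = "normal", mean = 61, sd = 11),
               coef = 0.05),
    sbp = list(dist = list(kind = "normal", mean = 130, sd = 25),
               transform = list(kind = "truncate_above", cap = 100),
               coef = -0.07),
    pulse = list(dist = list(kind = "normal", mean = 75, sd = 15),
                 transform = list(kind = "linear_spline", knot = 50),
                 coef = c(0.026, -0.012)),
    killip = list(dist = list(kind = "binary", prob = 0.15), coef = 0.70),
    prev_mi = list(dist = list(kind = "binary", prob = 0.17), coef = 0.25),
    hypertension = list(dist = list(kind = "binary", prob = 0.38), coef = 0),
    diabetes = list(dist = list(kind = "binary", prob = 0.15), coef = 0)
  )
  for (nm in names(preds)) preds[[nm]]$coef <- preds[[nm]]$coef * coef_scale
  dgp <- logistic_dgp(intercept = GUSTO_LIKE_INTERCEPT, predictors = preds)
  if (coef_scale != 1 || event_rate != 0.07) {
    dgp <- calibrate_intercept(dgp, event_rate)
  }
  dgp
}

# intercept of the default preset, solved once with calibrate_intercept()
# (target marginal event rate 0.07)
GUSTO_LIKE_INTERCEPT <- -0.776547

#' Null (no-signal) DGP
#'
#' `k` independent standard-normal predictors with zero coefficients and a
#' fixed event rate: nothing to learn, so any apparent discrimination is
#' optimism.
#'
#' @param k Number of noise predictors.
#' @param event_rate Marginal event rate.
#' @return A [logistic_dgp()].
#' @export
null_dgp <- function(k = 10, event_rate = 0.2) {
  preds <- stats::setNames(
    rep(list(list(dist = list(kind = "normal", mean = 0, sd = 1),
                  coef = 0)), k),
    paste0("x", seq_len(k))
  )
  logistic_dgp(intercept = stats::qlogis(event_rate), predictors = preds)
}
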