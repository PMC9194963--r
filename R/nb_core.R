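# Pure net-benefit arithmetic at a risk threshold z.  All estimators are
# per-patient means in true-positive units; the treat-none default has NB = 0
# (the "opt-in" convention).  Thresholds live in [0, 1): at z = 1 the
# false-positive exchange rate z/(1-z) diverges.

.check_threshold <- function(z) {
  if (!is.numeric(z) || length(z) < 1L || anyNA(z))
    stop("threshold 'z' must be numeric and non-missing", call. = FALSE)
  if (any(z < 0 | z >= 1))
    stop("threshold 'z' must satisfy 0 <= z < 1", call. = FALSE)
  invisible(z)
}

.check_risks <- function(p, what = "risks") {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p))
    stop(what, " must be a non-empty numeric vector without missing values",
         call. = FALSE)
  if (any(p < 0 | p > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

.check_outcomes <- function(y) {
  if (!is.numeric(y) || length(y) < 1L || anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcomes must be a non-empty 0/1 vector without missing values",
         call. = FALSE)
  invisible(y)
}

#' False-positive exchange rate at a risk threshold
#'
#' At threshold `z` the harm of a false-positive classification is weighted
#' `z/(1-z)` relative to the benefit of a true positive.  A threshold of 2%
#' therefore corresponds to a benefit:harm ratio of 49:1.
#'
#' @param z Risk threshold(s) in `[0, 1)`.
#' @return Numeric vector of exchange rates, `z/(1-z)`.
#' @examples
#' exchange_rate(0.02)       # 1/49
#' 1 / exchange_rate(0.02)   # benefit:harm = 49
#' @export
exchange_rate <- function(z) {
  .check_threshold(z)
  z / (1 - z)
}

# shared kernel: per-patient NB contribution p - (1 - p) * z/(1-z)
.nb_terms <- function(p, z) p - (1 - p) * (z / (1 - z))

.nb_over_z <- function(z, f) {
  .check_threshold(z)
  vapply(z, f, numeric(1))
}

#' Empirical net benefit of a risk model
#'
#' The standard decision-curve estimator
#' \deqn{\hat{NB}_{Model}(z) = \frac{1}{n}\sum_i I(\pi_i > z)\,
#'   [Y_i - (1-Y_i)\,z/(1-z)],}
#' i.e. the per-patient rate of true positives net of exchange-rate-weighted
#' false positives among patients whose predicted risk exceeds the threshold.
#' The indicator is strict: a patient whose predicted risk equals `z` exactly
#' is left untreated (the default decision).
#'
#' @param pi Predicted risks from the proposed model, in `[0, 1]`.
#' @param y Observed binary outcomes (0/1), same length as `pi`.
#' @param z Risk threshold(s) in `[0, 1)`.
#' @return Numeric vector, one net benefit per threshold.
#' @seealso [nb_empirical_all()], [nb_model_given_truth()]
#' @export
nb_empirical_model <- function(pi, y, z) {
  .check_risks(pi, "'pi'")
  .check_outcomes(y)
  if (length(pi) != length(y))
    stop("'pi' and 'y' must have the same length", call. = FALSE)
  .nb_over_z(z, function(zz) mean((pi > zz) * .nb_terms(y, zz)))
}

#' Empirical net benefit of treating everyone
#'
#' Treat-all assumes every patient is test positive:
#' \deqn{\hat{NB}_{all}(z) = \frac{1}{n}\sum_i [Y_i - (1-Y_i)\,z/(1-z)].}
#' At `z = 0` this equals the event rate.
#'
#' @inheritParams nb_empirical_model
#' @return Numeric vector, one net benefit per threshold.
#' @export
nb_empirical_all <- function(y, z) {
  .check_outcomes(y)
  .nb_over_z(z, function(zz) mean(.nb_terms(y, zz)))
}

#' Net benefit of a model when the correct risks are known
#'
#' Replaces the observed outcome with the correct (strongly calibrated) risk
#' `p` for each patient:
#' \deqn{NB_{Model}(z;\theta) = \frac{1}{n}\sum_i I(\pi_i > z)\,
#'   [p_i - (1-p_i)\,z/(1-z)].}
#' With degenerate risks `p` in `{0, 1}` this reproduces
#' [nb_empirical_model()] exactly.
#'
#' @param pi Predicted risks from the proposed model.
#' @param p Correct risks (e.g. one posterior draw), same length as `pi`.
#' @param z Risk threshold(s) in `[0, 1)`.
#' @return Numeric vector, one net benefit per threshold.
#' @export
nb_model_given_truth <- function(pi, p, z) {
  .check_risks(pi, "'pi'")
  .check_risks(p, "'p'")
  if (length(pi) != length(p))
    stop("'pi' and 'p' must have the same length", call. = FALSE)
  .nb_over_z(z, function(zz) mean((pi > zz) * .nb_terms(p, zz)))
}

#' Net benefit of treating everyone when the correct risks are known
#'
#' @inheritParams nb_model_given_truth
#' @return Numeric vector, one net benefit per threshold.  At `z = 0` this is
#'   `mean(p)`.
#' @export
nb_all_given_truth <- function(p, z) {
  .check_risks(p, "'p'")
  .nb_over_z(z, function(zz) mean(.nb_terms(p, zz)))
}

#' Net benefit of the optimal treatment rule under the correct risks
#'
#' If the correct risks were known, the best possible rule treats exactly the
#' patients whose correct risk exceeds the threshold:
#' \deqn{NB_{max}(z;\theta) = \frac{1}{n}\sum_i I(p_i > z)\,
#'   [p_i - (1-p_i)\,z/(1-z)].}
#' Each summand is included precisely when it is positive, so this dominates
#' the model-based and treat-all net benefits (and zero) for any `pi` sharing
#' the same `p`.
#'
#' @inheritParams nb_model_given_truth
#' @return Numeric vector, one net benefit per threshold.
#' @export
nb_max_given_truth <- function(p, z) {
  .check_risks(p, "'p'")
  .nb_over_z(z, function(zz) mean((p > zz) * .nb_terms(p, zz)))
}

#' Concordance (c-) statistic for binary outcomes
#'
#' Probability that a randomly chosen event case is assigned a higher risk
#' than a randomly chosen non-event case; ties count one half.  Computed from
#' midranks.
#'
#' @param pi Predicted risks (any monotone score works).
#' @param y Observed binary outcomes (0/1); at least one event and one
#'   non-event are required.
#' @return The c-statistic, a number in `[0, 1]`.
#' @export
c_statistic <- function(pi, y) {
  .check_outcomes(y)
  if (!is.numeric(pi) || anyNA(pi) || length(pi) != length(y))
    stop("'pi' must be numeric, non-missing, same length as 'y'", call. = FALSE)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("c-statistic is undefined without both events and non-events",
         call. = FALSE)
  r <- rank(pi)                      # midranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default threshold grid
#'
#' Thresholds 0 to 0.99 in steps of 0.01 (z = 1 is excluded from the domain),
#' optionally augmented with user-specified clinically motivated thresholds
#' such as 0.02.
#'
#' @param extra Additional thresholds to merge into the grid.
#' @return Sorted unique numeric vector of thresholds.
#' @export
default_threshold_grid <- function(extra = NULL) {
  z <- seq(0, 0.99, by = 0.01)
  if (!is.null(extra)) {
    .check_threshold(extra)
    z <- sort(unique(c(z, extra)))
  }
  z
}
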