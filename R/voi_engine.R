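# Monte Carlo EVPI over a threshold grid.  Per draw and threshold we keep
# paired quantities:
#   nb_model, nb_all, nb_max — the three NB estimators under the drawn
#     correct risks, and
#   d_model = nb_max - nb_model, d_all = nb_max - nb_all — computed directly
#     as sums of sign-definite addends (clamped at zero, where they can only
#     differ from the exact value by rounding noise).
# EVPI is then min(mean nb_max, mean d_model, mean d_all), which equals the
# defining expression nb_max_bar - max(0, nb_model_bar, nb_all_bar) in exact
# arithmetic and is nonnegative by construction in floating point as well.

# per-draw NB components for a correct-risk vector p over a threshold grid
nb_draw_components <- function(p, ind_pi, z, r) {
  n <- length(p)
  Tm <- matrix(p, n, length(z)) - (1 - p) %o% r
  ind_p <- outer(p, z, ">")
  pos <- pmax(Tm, 0)
  neg <- pmax(-Tm, 0)
  list(
    nb_model = colMeans(ind_pi * Tm),
    nb_all   = colMeans(Tm),
    nb_max   = colMeans(ind_p * pos),
    d_model  = colMeans((ind_p & !ind_pi) * pos + (ind_pi & !ind_p) * neg),
    d_all    = colMeans((!ind_p) * neg)
  )
}

#' Expected value of perfect information from posterior-mean net benefits
#'
#' \deqn{EVPI(z) = \bar{NB}_{max}(z) - \max\{0, \bar{NB}_{Model}(z),
#'   \bar{NB}_{all}(z)\}.}
#' The arithmetic identity on already-computed posterior means; [compute_voi()]
#' evaluates the same quantity from paired draws.
#'
#' @param nb_model_bar Posterior-mean net benefit of the proposed model.
#' @param nb_all_bar Posterior-mean net benefit of treating everyone.
#' @param nb_max_bar Posterior-mean net benefit under perfect information.
#' @return EVPI, vectorized over thresholds.
#' @examples
#' evpi(0.0484, 0.0478, 0.0489)  # 0.0005
#' @export
evpi <- function(nb_model_bar, nb_all_bar, nb_max_bar) {
  nb_max_bar - pmax(0, nb_model_bar, nb_all_bar)
}

#' Relative EVPI
#'
#' The ratio of the expected incremental net benefit (over the no-model
#' baseline, `max(0, nb_all_bar)`) under perfect versus current information.
#' Where defined it is at least 1; it is `+Inf` when the current-information
#' increment is zero but the perfect-information increment is positive, and
#' undefined (returned as `NA`) when the perfect-information increment is
#' itself zero — then neither the correct nor the proposed model adds net
#' benefit over the default decisions.
#'
#' @inheritParams evpi
#' @return Extended-real vector: finite values `>= 1`, `Inf`, or `NA` for the
#'   undefined case.
#' @export
relative_evpi <- function(nb_model_bar, nb_all_bar, nb_max_bar) {
  num <- nb_max_bar - pmax(0, nb_all_bar)
  den <- pmax(0, nb_model_bar, nb_all_bar) - pmax(0, nb_all_bar)
  ifelse(num == 0, NA_real_, ifelse(den == 0, Inf, num / den))
}

#' Monte Carlo value-of-information analysis for a risk model in development
#'
#' Implements the bootstrap-based EVPI algorithm: for each of `n_draws`
#' iterations, draw a correct-risk vector from the posterior (by refitting
#' the developer on a bootstrap-weighted sample, or by MVN coefficient
#' sampling), evaluate the model/treat-all/perfect-information net benefits
#' on the original sample at every threshold, and average.  EVPI and relative
#' EVPI are computed from the paired draws, which makes `evpi >= 0` exact,
#' not merely in expectation.
#'
#' @param sample A [development_sample()].
#' @param developer A [model_developer()]; re-run inside every draw.
#' @param proposed_risks Predicted risks of the proposed model on `sample`.
#'   Default `NULL` fits `developer` once on the full, unweighted sample.
#' @param thresholds Threshold grid in `[0, 1)`; default
#'   [default_threshold_grid()].
#' @param n_draws Number of posterior draws (>= 2). Default 1000.
#' @param scheme Posterior sampling scheme; see [draw_correct_risks()].
#' @param seed Master seed; per-draw substreams are derived from it.
#' @param min_events,max_redraws Degenerate-resample guard passed to the
#'   sampler.
#' @param mc_se_warn Warn when the Monte Carlo SE of EVPI exceeds this
#'   fraction of EVPI at any threshold where EVPI > 0. Default 0.1.
#' @return An object of class `voi_result`: a list with `curves` (data frame
#'   with one row per threshold: posterior-mean NBs, `delta_current`,
#'   `delta_perfect`, `evpi`, `evpi_r`, best current strategy and Monte Carlo
#'   standard errors), draw diagnostics, and the inputs' metadata.
#' @references The algorithm loops: bootstrap the development data, redo
#'   model development, apply the refitted model to the original sample, and
#'   accumulate the three NB estimators; see the package vignette.
#' @export
compute_voi <- function(sample, developer, proposed_risks = NULL,
                        thresholds = default_threshold_grid(),
                        n_draws = 1000,
                        scheme = SAMPLING_SCHEMES,
                        seed = 1L, min_events = 1L, max_redraws = 100L,
                        mc_se_warn = 0.1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(sample, "development_sample"),
            inherits(developer, "model_developer"))
  .check_threshold(thresholds)
  if (n_draws < 2) stop("'n_draws' must be at least 2", call. = FALSE)

  if (is.null(proposed_risks)) {
    proposed_risks <- fit_proposed(developer, sample)$risks
  }
  .check_risks(proposed_risks, "'proposed_risks'")
  if (length(proposed_risks) != sample$n)
    stop("'proposed_risks' must align with the sample rows", call. = FALSE)

  z <- as.numeric(thresholds)
  r <- z / (1 - z)
  m <- length(z)
  ind_pi <- outer(proposed_risks, z, ">")

  mvn <- if (scheme == "likelihood_mvn") mvn_posterior(sample) else NULL
  seeds <- derive_seeds(seed, n_draws)

  mats <- lapply(1:5, function(i) matrix(NA_real_, n_draws, m))
  names(mats) <- c("nb_model", "nb_all", "nb_max", "d_model", "d_all")
  ok <- logical(n_draws)
  for (d in seq_len(n_draws)) {
    set.seed(seeds[d])
    dr <- draw_correct_risks(sample, developer, scheme,
                             min_events = min_events,
                             max_redraws = max_redraws, mvn = mvn)
    ok[d] <- isTRUE(dr$ok)
    if (!ok[d]) next
    comp <- nb_draw_components(dr$risks, ind_pi, z, r)
    for (nm in names(mats)) mats[[nm]][d, ] <- comp[[nm]]
  }

  finalize_voi(mats, ok, z, scheme = scheme, seed = seed, n = sample$n,
               proposed_risks = proposed_risks, mc_se_warn = mc_se_warn)
}

# assemble a voi_result from per-draw component matrices (shared with
# joint_loop)
finalize_voi <- function(mats, ok, z, scheme, seed, n, proposed_risks,
                         mc_se_warn) {
  m <- length(z)
  n_draws <- length(ok)
  used <- sum(ok)
  failed <- n_draws - used
  if (used == 0L)
    stop("all posterior draws failed (degenerate resamples or fit errors)",
         call. = FALSE)
  if (failed > 0L)
    warning(failed, " of ", n_draws, " posterior draws failed and were ",
            "excluded from the posterior means", call. = FALSE)

  mu <- lapply(mats, function(x) colMeans(x[ok, , drop = FALSE]))
  sdv <- lapply(mats, function(x) apply(x[ok, , drop = FALSE], 2, stats::sd))

  ev <- pmin(mu$nb_max, mu$d_model, mu$d_all)
  delta_perfect <- pmin(mu$nb_max, mu$d_all)
  delta_current <- delta_perfect - ev
  evpi_r <- ifelse(delta_perfect == 0, NA_real_,
                   ifelse(delta_current == 0, Inf,
                          delta_perfect / delta_current))

  # best strategy under current information; ties favour the simpler
  # strategy (none > all > model)
  strat <- c("none", "all", "model")
  best_ix <- apply(rbind(0, mu$nb_all, mu$nb_model), 2, which.max)
  best <- strat[best_ix]
  # EVPI's MC SE: draw-level sd of the paired difference against the chosen
  # current-information comparator
  sd_evpi <- vapply(seq_len(m), function(j) {
    switch(best[j], none = sdv$nb_max[j], all = sdv$d_all[j],
           model = sdv$d_model[j])
  }, numeric(1))

  curves <- data.frame(
    threshold = z,
    nb_model_bar = mu$nb_model,
    nb_all_bar = mu$nb_all,
    nb_max_bar = mu$nb_max,
    delta_current = delta_current,
    delta_perfect = delta_perfect,
    evpi = ev,
    evpi_r = evpi_r,
    best_current = best,
    mc_se_model = sdv$nb_model / sqrt(used),
    mc_se_all = sdv$nb_all / sqrt(used),
    mc_se_max = sdv$nb_max / sqrt(used),
    mc_se_evpi = sd_evpi / sqrt(used),
    row.names = NULL
  )

  noisy <- curves$evpi > 0 & curves$mc_se_evpi > mc_se_warn * curves$evpi
  if (any(noisy))
    warning("Monte Carlo SE exceeds ", round(100 * mc_se_warn),
            "% of EVPI at ", sum(noisy), " threshold(s); ",
            "consider increasing 'n_draws'", call. = FALSE)

  structure(list(curves = curves, n_draws_used = used,
                 n_draws_failed = failed, scheme = scheme, seed = seed,
                 n = n, proposed_risks = proposed_risks,
                 mc_se_flagged = sum(noisy)),
            class = "voi_result")
}

#' @export
print.voi_result <- function(x, digits = 4, ...) {
  cat("Value-of-information analysis (", x$scheme, ")\n", sep = "")
  cat("  n =", x$n, "| draws used =", x$n_draws_used,
      "| failed =", x$n_draws_failed, "\n")
  show_z <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)
  rows <- x$curves[x$curves$threshold %in% show_z,
                   c("threshold", "nb_model_bar", "nb_all_bar", "nb_max_bar",
                     "evpi", "evpi_r", "best_current")]
  if (nrow(rows)) print(format(rows, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Incremental net-benefit curves under current and perfect information
#'
#' Extracts, per threshold, the expected incremental net benefit of risk
#' stratification over the no-model baseline `max(0, nb_all_bar)` under
#' current information (`delta_current`) and under perfect information
#' (`delta_perfect`), with `delta_perfect - delta_current = evpi` and
#' `delta_perfect >= delta_current >= 0` everywhere.
#'
#' @param result A [compute_voi()] result.
#' @return Data frame with columns `threshold`, `delta_current`,
#'   `delta_perfect`, `evpi`.
#' @export
decision_curves_bayes <- function(result) {
  stopifnot(inherits(result, "voi_result"))
  result$curves[c("threshold", "delta_current", "delta_perfect", "evpi")]
}

#' EVPI as a function of development sample size
#'
#' Repeatedly draws development datasets of each requested size — either
#' subsampling a parent sample without replacement or generating fresh data
#' from a synthetic truth — runs [compute_voi()] on each, and summarizes
#' EVPI by the mean and relative EVPI by the median across replicates.
#' Datasets with fewer than `min_events_data` events are redrawn (small
#' resamples of a rare outcome do not support reliable model development).
#' `Inf` relative EVPI propagates through the median; undefined (`NA`)
#' values are excluded and counted.
#'
#' @param sizes Ascending vector of development sample sizes.
#' @param developer A [model_developer()].
#' @param parent Optional parent [development_sample()] to subsample without
#'   replacement.
#' @param dgp Optional [logistic_dgp()] generating fresh datasets.  Exactly
#'   one of `parent`/`dgp` must be given.
#' @param replicates Independent datasets per size. Default 10.
#' @param thresholds Thresholds at which to evaluate. Default
#'   `c(0.01, 0.02, 0.05, 0.1)`.
#' @param n_draws Posterior draws per dataset. Default 200.
#' @param scheme Posterior sampling scheme.
#' @param seed Master seed.
#' @param min_events_data Minimum events for a dataset to be analysed
#'   (redraw otherwise). Default 8.
#' @param ... Passed on to [compute_voi()].
#' @return Data frame with one row per (size, threshold): `evpi_mean`,
#'   `evpi_r_median`, `n_undefined`, `n_replicates`.
#' @export
sample_size_sweep <- function(sizes, developer, parent = NULL, dgp = NULL,
                              replicates = 10,
                              thresholds = c(0.01, 0.02, 0.05, 0.1),
                              n_draws = 200,
                              scheme = SAMPLING_SCHEMES,
                              seed = 1L, min_events_data = 8L, ...) {
  scheme <- match.arg(scheme)
  if (is.null(parent) == is.null(dgp))
    stop("give exactly one of 'parent' or 'dgp'", call. = FALSE)
  if (is.unsorted(sizes, strictly = TRUE))
    stop("'sizes' must be strictly ascending", call. = FALSE)
  if (!is.null(parent) && max(sizes) > parent$n)
    stop("requested size exceeds the parent sample (n = ", parent$n, ")",
         call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  .check_threshold(thresholds)

  seeds <- matrix(derive_seeds(seed, length(sizes) * replicates),
                  nrow = length(sizes))
  rows <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    ev_mat <- matrix(NA_real_, replicates, length(thresholds))
    er_mat <- matrix(NA_real_, replicates, length(thresholds))
    for (rep_i in seq_len(replicates)) {
      sub_seed <- seeds[si, rep_i]
      set.seed(sub_seed)
      ds <- NULL
      for (attempt in 1:100) {
        cand <- if (!is.null(parent)) {
          keep <- sample.int(parent$n, size, replace = FALSE)
          development_sample(
            cbind(parent$covariates[keep, , drop = FALSE],
                  outcome = parent$outcomes[keep]))
        } else {
          generate_sample(dgp, size)$sample
        }
        ev <- n_events(cand)
        if (ev >= min_events_data && ev <= cand$n - 1L) { ds <- cand; break }
      }
      if (is.null(ds))
        stop("could not draw a dataset of size ", size, " with at least ",
             min_events_data, " events", call. = FALSE)
      res <- compute_voi(ds, developer, thresholds = thresholds,
                         n_draws = n_draws, scheme = scheme,
                         seed = sub_seed, ...)
      ev_mat[rep_i, ] <- res$curves$evpi
      er_mat[rep_i, ] <- res$curves$evpi_r
    }
    for (zi in seq_along(thresholds)) {
      er <- er_mat[, zi]
      rows[[length(rows) + 1L]] <- data.frame(
        size = size,
        threshold = thresholds[zi],
        evpi_mean = mean(ev_mat[, zi]),
        evpi_r_median = if (all(is.na(er))) NA_real_ else
          stats::median(er[!is.na(er)]),
        n_undefined = sum(is.na(er)),
        n_replicates = replicates
      )
    }
  }
  do.call(rbind, rows)
}
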