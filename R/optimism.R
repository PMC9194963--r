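# Harrell's bootstrap optimism correction: refit the developer on each
# bootstrap resample, evaluate the refitted model both on the resample and on
# the original sample, and average the differences.  The same ordinary-
# bootstrap iteration drives the EVPI draws, so both can share one loop.

#' Harrell bootstrap optimism correction
#'
#' For each bootstrap replicate a new model is developed on the resample, and
#' the optimism contribution is its performance on the resample minus its
#' performance on the original sample.  The corrected value is the apparent
#' (full-sample) performance minus the average optimism.  Supported metrics:
#' the decision-curve net benefit of the model at each threshold (corrected
#' pointwise, no smoothing across thresholds) and the c-statistic.
#'
#' Replicates whose resample has fewer than `min_events` events (or no
#' non-events), or whose refit fails, are redrawn under the same guard policy
#' as the posterior sampler and reported in the result.
#'
#' @param sample A [development_sample()].
#' @param developer A [model_developer()]; must fit on resampled rows.
#' @param thresholds Threshold grid for the net-benefit metric.
#' @param metrics Subset of `c("nb", "c_statistic")`.
#' @param n_boot Number of bootstrap replicates (>= 1). Default 1000.
#' @param seed Master seed (per-replicate substreams).
#' @param min_events,max_redraws Resample guard.
#' @return An object of class `optimism_report` with elements `nb` (data
#'   frame: threshold, apparent, optimism, corrected), `cstat` (same triple
#'   for the c-statistic), `n_boot_used`, `n_boot_failed`.
#' @export
harrell_correct <- function(sample, developer,
                            thresholds = default_threshold_grid(),
                            metrics = c("nb", "c_statistic"),
                            n_boot = 1000, seed = 1L,
                            min_events = 1L, max_redraws = 100L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(inherits(sample, "development_sample"),
            inherits(developer, "model_developer"))
  if (n_boot < 1) stop("'n_boot' must be >= 1", call. = FALSE)
  .check_threshold(thresholds)

  prop <- fit_proposed(developer, sample)
  acc <- optimism_accumulator(sample, prop$risks, thresholds, metrics)
  seeds <- derive_seeds(seed, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    it <- ordinary_iteration(sample, developer, min_events, max_redraws)
    acc$add(it)
  }
  acc$report(scheme_note = "harrell")
}

# closure collecting per-replicate optimism contributions; shared between
# harrell_correct() and joint_loop()
optimism_accumulator <- function(sample, proposed_risks, thresholds,
                                 metrics) {
  y <- sample$outcomes
  z <- as.numeric(thresholds)
  apparent_nb <- if ("nb" %in% metrics)
    nb_empirical_model(proposed_risks, y, z) else NULL
  apparent_c <- if ("c_statistic" %in% metrics)
    c_statistic(proposed_risks, y) else NULL
  opt_nb <- list()
  opt_c <- numeric(0)
  used <- 0L
  failed <- 0L

  add <- function(it) {
    if (!isTRUE(it$ok)) { failed <<- failed + 1L; return(invisible(NULL)) }
    idx <- it$indices
    p_orig <- it$risks
    # the refitted model on its own bootstrap rows: rowwise prediction makes
    # this the original-sample predictions subset at the resampled indices
    p_boot <- p_orig[idx]
    if ("nb" %in% metrics) {
      opt_nb[[length(opt_nb) + 1L]] <<-
        nb_empirical_model(p_boot, y[idx], z) -
        nb_empirical_model(p_orig, y, z)
    }
    if ("c_statistic" %in% metrics) {
      cb <- tryCatch(c_statistic(p_boot, y[idx]), error = function(e) NA_real_)
      co <- c_statistic(p_orig, y)
      opt_c[length(opt_c) + 1L] <<- cb - co
    }
    used <<- used + 1L
    invisible(NULL)
  }

  report <- function(scheme_note = "harrell") {
    if (used == 0L)
      stop("all bootstrap replicates failed", call. = FALSE)
    if (failed > 0L)
      warning(failed, " bootstrap replicate(s) failed and were excluded",
              call. = FALSE)
    nb_df <- NULL
    if ("nb" %in% metrics) {
      opt <- colMeans(do.call(rbind, opt_nb))
      nb_df <- data.frame(threshold = z, apparent = apparent_nb,
                          optimism = opt, corrected = apparent_nb - opt,
                          row.names = NULL)
    }
    cs <- NULL
    if ("c_statistic" %in% metrics) {
      oc <- mean(opt_c, na.rm = TRUE)
      cs <- list(apparent = apparent_c, optimism = oc,
                 corrected = apparent_c - oc)
    }
    structure(list(nb = nb_df, cstat = cs, n_boot_used = used,
                   n_boot_failed = failed),
              class = "optimism_report")
  }

  list(add = add, report = report)
}

#' @export
print.optimism_report <- function(x, digits = 4, ...) {
  cat("Harrell bootstrap optimism correction (", x$n_boot_used,
      " replicates used, ", x$n_boot_failed, " failed)\n", sep = "")
  if (!is.null(x$cstat))
    cat(sprintf("  c-statistic: apparent %.4f, optimism %.4f, corrected %.4f\n",
                x$cstat$apparent, x$cstat$optimism, x$cstat$corrected))
  if (!is.null(x$nb)) {
    show_z <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)
    rows <- x$nb[x$nb$threshold %in% show_z, ]
    if (nrow(rows)) print(format(rows, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Joint EVPI and optimism-correction loop
#'
#' One ordinary-bootstrap resampling pass yields both the EVPI posterior
#' draws (refitted-model predictions on the original sample) and the Harrell
#' optimism contributions (refitted-model metric on the resample minus on the
#' original sample).  With a shared seed the result is identical to running
#' [compute_voi()] (with `scheme = "ordinary_bootstrap"`) and
#' [harrell_correct()] separately.
#'
#' @inheritParams compute_voi
#' @param n_iter Number of shared bootstrap iterations.
#' @param metrics Optimism metrics; see [harrell_correct()].
#' @return List with elements `voi` (a `voi_result`) and `optimism` (an
#'   `optimism_report`).
#' @export
joint_loop <- function(sample, developer, proposed_risks = NULL,
                       thresholds = default_threshold_grid(),
                       n_iter = 1000, seed = 1L,
                       metrics = c("nb", "c_statistic"),
                       min_events = 1L, max_redraws = 100L,
                       mc_se_warn = 0.1) {
  stopifnot(inherits(sample, "development_sample"),
            inherits(developer, "model_developer"))
  .check_threshold(thresholds)
  if (n_iter < 2) stop("'n_iter' must be at least 2", call. = FALSE)
  metrics <- match.arg(metrics, several.ok = TRUE)

  if (is.null(proposed_risks)) {
    proposed_risks <- fit_proposed(developer, sample)$risks
  }
  .check_risks(proposed_risks, "'proposed_risks'")

  z <- as.numeric(thresholds)
  r <- z / (1 - z)
  m <- length(z)
  ind_pi <- outer(proposed_risks, z, ">")
  acc <- optimism_accumulator(sample, proposed_risks, thresholds, metrics)

  seeds <- derive_seeds(seed, n_iter)
  mats <- lapply(1:5, function(i) matrix(NA_real_, n_iter, m))
  names(mats) <- c("nb_model", "nb_all", "nb_max", "d_model", "d_all")
  ok <- logical(n_iter)
  for (d in seq_len(n_iter)) {
    set.seed(seeds[d])
    it <- ordinary_iteration(sample, developer, min_events, max_redraws)
    acc$add(it)
    ok[d] <- isTRUE(it$ok)
    if (!ok[d]) next
    comp <- nb_draw_components(it$risks, ind_pi, z, r)
    for (nm in names(mats)) mats[[nm]][d, ] <- comp[[nm]]
  }
  voi <- finalize_voi(mats, ok, z, scheme = "ordinary_bootstrap",
                      seed = seed, n = sample$n,
                      proposed_risks = proposed_risks,
                      mc_se_warn = mc_se_warn)
  list(voi = voi, optimism = acc$report())
}
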