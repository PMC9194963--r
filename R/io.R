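# CSV input with encoding, run configuration, and the command-style
# orchestration used by the shell interface.  Output schema:
#   voi_results.csv  — one row per threshold; +Inf relative EVPI serialized
#                      as "Inf", the undefined case as an empty field;
#   diagnostics.json — seeds, draw counts, config echo.

#' Read a development sample from CSV
#'
#' Reads a headered CSV, validates the outcome coding, one-hot encodes
#' character/factor predictors against a recorded reference level (the first
#' level alphabetically), and preserves row order.  Missing values are an
#' error: no imputation is performed.
#'
#' @param path CSV file path.
#' @param outcome Outcome column name; values must be 0/1, TRUE/FALSE or
#'   yes/no.
#' @param predictors Optional character vector of predictor columns; default
#'   all non-outcome columns.
#' @return A [development_sample()]; the encoding reference levels are kept
#'   in `attr(, "reference_levels")`.
#' @export
read_sample <- function(path, outcome = "outcome", predictors = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!outcome %in% names(df))
    stop("outcome column '", outcome, "' not found in ", path, call. = FALSE)
  if (is.null(predictors)) predictors <- setdiff(names(df), outcome)
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols))
    stop("predictor column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  y_raw <- df[[outcome]]
  y <- map_outcome(y_raw)
  bad <- which(is.na(y))
  if (length(bad))
    stop("outcome column '", outcome, "' has non-binary value(s), e.g. '",
         y_raw[bad[1]], "' at row ", bad[1], call. = FALSE)

  sub <- df[predictors]
  na_cols <- names(sub)[vapply(sub, anyNA, logical(1))]
  if (length(na_cols))
    stop("missing values in column(s): ", paste(na_cols, collapse = ", "),
         " (no imputation is implemented)", call. = FALSE)

  refs <- list()
  enc <- list()
  for (nm in predictors) {
    x <- sub[[nm]]
    if (is.numeric(x)) {
      enc[[nm]] <- x
    } else if (is.logical(x)) {
      enc[[nm]] <- as.numeric(x)
    } else {
      f <- factor(x)
      if (nlevels(f) < 2L)
        stop("predictor '", nm, "' is constant and cannot be encoded",
             call. = FALSE)
      refs[[nm]] <- levels(f)[1]
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, "_", levels(f)[-1])
      for (cn in colnames(mm)) enc[[cn]] <- as.numeric(mm[, cn])
    }
  }
  out <- as.data.frame(enc, check.names = TRUE)
  out$outcome <- y
  s <- development_sample(out)
  attr(s, "reference_levels") <- refs
  s
}

map_outcome <- function(y) {
  if (is.numeric(y)) return(ifelse(y %in% c(0, 1), y, NA_real_))
  if (is.logical(y)) return(as.numeric(y))
  yl <- tolower(trimws(as.character(y)))
  out <- rep(NA_real_, length(yl))
  out[yl %in% c("1", "yes", "true", "y")] <- 1
  out[yl %in% c("0", "no", "false", "n")] <- 0
  out
}

#' Write a development sample to CSV
#'
#' Inverse of [read_sample()] for already-encoded samples: covariate columns
#' plus the outcome column, one row per observation.
#'
#' @param sample A [development_sample()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "development_sample"))
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the command-line workflow
#'
#' Validates and bundles everything a pipeline run needs.  Thresholds must
#' lie in `[0, 0.99]`; a threshold of 1 is rejected before any computation.
#'
#' @param input Input CSV path.
#' @param outcome Outcome column name.
#' @param predictors Optional predictor columns.
#' @param thresholds Threshold vector; default [default_threshold_grid()].
#' @param scheme Posterior sampling scheme.
#' @param n_draws Posterior draws for EVPI.
#' @param n_boot Bootstrap replicates for optimism correction.
#' @param seed Master seed.
#' @param min_events Resample guard.
#' @param developer `"lasso"`, `"logistic"`, or a [model_developer()].
#' @param output_dir Directory for result artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(input, outcome = "outcome", predictors = NULL,
                       thresholds = default_threshold_grid(),
                       scheme = SAMPLING_SCHEMES,
                       n_draws = 1000, n_boot = 1000, seed = 1L,
                       min_events = 1L, developer = "lasso",
                       output_dir = ".") {
  scheme <- match.arg(scheme)
  if (!is.numeric(thresholds) || anyNA(thresholds) ||
      any(thresholds < 0 | thresholds > 0.99))
    stop("thresholds must lie in [0, 0.99]", call. = FALSE)
  if (n_draws < 1 || n_boot < 1)
    stop("'n_draws' and 'n_boot' must be >= 1", call. = FALSE)
  dev <- if (inherits(developer, "model_developer")) developer
         else switch(match.arg(developer, c("lasso", "logistic")),
                     lasso = lasso_developer(),
                     logistic = logistic_developer())
  structure(list(input = input, outcome = outcome, predictors = predictors,
                 thresholds = sort(unique(thresholds)), scheme = scheme,
                 n_draws = n_draws, n_boot = n_boot, seed = as.integer(seed),
                 min_events = as.integer(min_events), developer = dev,
                 output_dir = output_dir),
            class = "run_config")
}

fmt6 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else if (is.infinite(v)) "Inf"
    else format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Write VoI results to CSV
#'
#' One row per threshold, numbers at 6 significant digits; `Inf` relative
#' EVPI written as `"Inf"` and the undefined case as an empty field.  The
#' encoding round-trips through [read_voi_results()].
#'
#' @param result A `voi_result`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_voi_results <- function(result, path) {
  stopifnot(inherits(result, "voi_result"))
  cv <- result$curves
  num_cols <- setdiff(names(cv), "best_current")
  out <- data.frame(lapply(cv[num_cols], fmt6),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$best_current <- cv$best_current
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a VoI results CSV
#'
#' @param path CSV written by [write_voi_results()].
#' @return Data frame with numeric columns restored (`Inf` and the empty
#'   undefined flag included).
#' @export
read_voi_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), "best_current")) {
    x <- df[[nm]]
    if (is.character(x)) {
      x[x == ""] <- NA
      df[[nm]] <- as.numeric(ifelse(x == "Inf", Inf, x))
    }
  }
  df
}

#' Run the full EVPI pipeline on a CSV input
#'
#' Reads the sample, develops the proposed model on the full data, runs the
#' Monte Carlo EVPI analysis, and writes `voi_results.csv` plus
#' `diagnostics.json` (and optionally a decision-curve plot) into the output
#' directory.  Identical configuration and seed give byte-identical CSV
#' output.
#'
#' @param config A [run_config()].
#' @param plot If `TRUE`, also write `decision_curves.pdf`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `voi_result` and output paths.
#' @export
run_evpi_command <- function(config, plot = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  say("[voidev] reading sample from ", config$input)
  sample <- read_sample(config$input, config$outcome, config$predictors)
  say("[voidev] n = ", sample$n, ", events = ", n_events(sample))
  say("[voidev] developing proposed model (", config$developer$label, ")")
  set.seed(config$seed)
  pi_hat <- fit_proposed(config$developer, sample)$risks
  say("[voidev] computing EVPI over ", length(config$thresholds),
      " thresholds, ", config$n_draws, " draws (", config$scheme, ")")
  result <- compute_voi(sample, config$developer, proposed_risks = pi_hat,
                        thresholds = config$thresholds,
                        n_draws = config$n_draws, scheme = config$scheme,
                        seed = config$seed, min_events = config$min_events)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(config$output_dir, "voi_results.csv")
  json_path <- file.path(config$output_dir, "diagnostics.json")
  write_voi_results(result, csv_path)
  diag <- list(
    input = config$input, outcome = config$outcome,
    scheme = config$scheme, seed = config$seed,
    n = result$n, n_draws = config$n_draws,
    n_draws_used = result$n_draws_used,
    n_draws_failed = result$n_draws_failed,
    mc_se_flagged = result$mc_se_flagged,
    developer = config$developer$label,
    thresholds = config$thresholds
  )
  jsonlite::write_json(diag, json_path, auto_unbox = TRUE, digits = NA)
  paths <- list(voi_results = csv_path, diagnostics = json_path)
  if (plot) {
    pdf_path <- file.path(config$output_dir, "decision_curves.pdf")
    plot_voi(result, file = pdf_path)
    paths$plot <- pdf_path
  }
  say("[voidev] wrote ", csv_path)
  invisible(list(result = result, paths = paths))
}

#' Run the optimism-correction pipeline on a CSV input
#'
#' @param config A [run_config()]; `n_boot` controls the replicates.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `optimism_report` and output paths.
#' @export
run_optimism_command <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  say("[voidev] reading sample from ", config$input)
  sample <- read_sample(config$input, config$outcome, config$predictors)
  say("[voidev] Harrell correction, ", config$n_boot, " bootstraps")
  rep <- harrell_correct(sample, config$developer,
                         thresholds = config$thresholds,
                         n_boot = config$n_boot, seed = config$seed,
                         min_events = config$min_events)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(config$output_dir, "optimism_results.csv")
  nb <- rep$nb
  rows <- rbind(
    data.frame(metric = "nb_model", threshold = nb$threshold,
               apparent = nb$apparent, optimism = nb$optimism,
               corrected = nb$corrected),
    data.frame(metric = "c_statistic", threshold = NA_real_,
               apparent = rep$cstat$apparent, optimism = rep$cstat$optimism,
               corrected = rep$cstat$corrected)
  )
  rows$apparent <- fmt6(rows$apparent)
  rows$optimism <- fmt6(rows$optimism)
  rows$corrected <- fmt6(rows$corrected)
  utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE,
                   na = "")
  say("[voidev] wrote ", csv_path)
  invisible(list(report = rep, paths = list(optimism_results = csv_path)))
}

#' Simulate a development sample to CSV
#'
#' Generates a sample from a preset or supplied DGP and writes it in the same
#' CSV dialect [read_sample()] reads.
#'
#' @param n Sample size.
#' @param path Output CSV path.
#' @param dgp A [logistic_dgp()]; default [gusto_like_dgp()].
#' @param seed Seed.
#' @return Invisibly, the generated list from [generate_sample()].
#' @export
run_simulate_command <- function(n, path, dgp = gusto_like_dgp(),
                                 seed = 1L) {
  gen <- generate_sample(dgp, n, seed = seed)
  write_sample(gen$sample, path)
  invisible(gen)
}
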