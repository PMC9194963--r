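test_that("EVPI and relative EVPI arithmetic handle all cases", {
  expect_equal(evpi(0.0484, 0.0478, 0.0489), 0.0005)
  expect_equal(evpi(0.3, 0.1, 0.3), 0)
  # treat-none best under current information
  expect_equal(evpi(-0.1, -0.2, 0.0), 0)
  # quotient of rounded printed increments
  expect_equal(relative_evpi(0.0484, 0.0478, 0.0489), 0.0011 / 0.0006,
               tolerance = 1e-6)
  # +Inf sentinel: no current-information gain, positive perfect gain
  expect_identical(relative_evpi(0.05, 0.05, 0.051), Inf)
  # undefined flag: no gain even with perfect information
  expect_identical(relative_evpi(0.05, 0.05, 0.05), NA_real_)
  # vectorized
  expect_length(evpi(c(0.1, 0.2), c(0, 0.1), c(0.15, 0.25)), 2)
})

test_that("compute_voi validates its inputs", {
  gen <- generate_sample(quick_dgp(), 60, seed = 21)
  dev <- logistic_developer()
  expect_error(compute_voi(gen$sample, dev, n_draws = 1), "at least 2")
  expect_error(compute_voi(gen$sample, dev, thresholds = c(0.1, 1)),
               "0 <= z < 1")
  expect_error(compute_voi(gen$sample, dev,
                           proposed_risks = runif(10), n_draws = 5),
               "align")
})

test_that("an oracle developer returning the true risks has zero EVPI", {
  gen <- generate_sample(quick_dgp(), 150, seed = 22)
  res <- compute_voi(gen$sample, oracle_developer(gen$true_risks),
                     n_draws = 20, scheme = "bayesian_bootstrap", seed = 5)
  expect_true(all(res$curves$evpi == 0))
})

test_that("incremental curves satisfy their algebraic identities", {
  gen <- generate_sample(quick_dgp(), 200, seed = 23)
  dev <- logistic_developer()
  res <- suppressWarnings(
    compute_voi(gen$sample, dev, n_draws = 60,
                scheme = "ordinary_bootstrap", seed = 9))
  dc <- decision_curves_bayes(res)
  expect_identical(nrow(dc), nrow(res$curves))
  expect_true(all(dc$delta_perfect >= dc$delta_current))
  expect_true(all(dc$delta_current >= 0))
  expect_equal(dc$delta_perfect - dc$delta_current, dc$evpi,
               tolerance = 1e-15)
  # relative EVPI is >= 1 wherever defined and finite
  er <- res$curves$evpi_r
  expect_true(all(er[!is.na(er) & is.finite(er)] >= 1))
  # posterior-mean NBs respect the scale bounds
  r <- exchange_rate(res$curves$threshold)
  for (col in c("nb_model_bar", "nb_all_bar", "nb_max_bar")) {
    expect_true(all(res$curves[[col]] >= -r - 1e-12))
    expect_true(all(res$curves[[col]] <= 1 + 1e-12))
  }
})

test_that("results are deterministic given the seed", {
  gen <- generate_sample(quick_dgp(), 100, seed = 24)
  dev <- logistic_developer()
  r1 <- suppressWarnings(compute_voi(gen$sample, dev, n_draws = 30, seed = 77,
                                     scheme = "bayesian_bootstrap"))
  r2 <- suppressWarnings(compute_voi(gen$sample, dev, n_draws = 30, seed = 77,
                                     scheme = "bayesian_bootstrap"))
  expect_identical(r1$curves, r2$curves)
})

test_that("partial and total draw failure are surfaced", {
  gen <- generate_sample(quick_dgp(), 80, seed = 25)
  expect_warning(
    res <- compute_voi(gen$sample, flaky_developer(), n_draws = 30,
                       scheme = "ordinary_bootstrap", seed = 31,
                       max_redraws = 1, mc_se_warn = Inf),
    "failed"
  )
  expect_identical(res$n_draws_used + res$n_draws_failed, 30L)
  expect_gt(res$n_draws_failed, 0)
  always_fails <- model_developer(
    fit = function(sample, weights = NULL, indices = NULL) stop("no"),
    predict = function(fitted, covariates) stop("no")
  )
  expect_error(
    suppressWarnings(compute_voi(gen$sample, always_fails,
                                 proposed_risks = rep(0.5, gen$sample$n),
                                 n_draws = 3, max_redraws = 2)),
    "all posterior draws failed")
})

test_that("the sample-size sweep aggregates replicates per size and threshold", {
  dgp <- quick_dgp()
  dev <- logistic_developer()
  sw <- suppressWarnings(
    sample_size_sweep(c(80, 160), dev, dgp = dgp, replicates = 2,
                      thresholds = c(0.1, 0.2), n_draws = 25,
                      scheme = "ordinary_bootstrap", seed = 42,
                      min_events_data = 8))
  expect_identical(nrow(sw), 4L)
  expect_true(all(sw$evpi_mean >= 0))
  expect_true(all(sw$n_undefined >= 0 & sw$n_undefined <= sw$n_replicates))
  # medians tolerate the +Inf sentinel
  expect_true(all(is.na(sw$evpi_r_median) | sw$evpi_r_median >= 1))
  # guard rails
  gen <- generate_sample(dgp, 50, seed = 1)
  expect_error(sample_size_sweep(c(100), dev, parent = gen$sample),
               "exceeds the parent")
  expect_error(sample_size_sweep(c(100, 50), dev, dgp = dgp), "ascending")
  expect_error(sample_size_sweep(c(50), dev), "exactly one")
})

test_that("subsampling a parent without replacement reuses its rows", {
  gen <- generate_sample(quick_dgp(), 300, seed = 26)
  dev <- intercept_developer()
  sw <- suppressWarnings(
    sample_size_sweep(c(60), dev, parent = gen$sample, replicates = 1,
                      thresholds = c(0.2), n_draws = 25,
                      scheme = "bayesian_bootstrap", seed = 5,
                      min_events_data = 5))
  expect_identical(nrow(sw), 1L)
  expect_gte(sw$evpi_mean, 0)
})
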