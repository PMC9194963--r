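test_that("exchange rate encodes the harm-benefit trade-off", {
  expect_equal(exchange_rate(0.02), 1 / 49)
  expect_equal(1 / exchange_rate(0.02), 49)
  expect_identical(exchange_rate(0), 0)
  expect_equal(exchange_rate(0.5), 1)
  expect_error(exchange_rate(1), "0 <= z < 1")
  expect_error(exchange_rate(-0.1), "0 <= z < 1")
})

test_that("empirical net benefit of the model matches hand computation", {
  # term by term: 1, (untreated), 0.6 - 0.4*0.25 ... with strict indicator
  expect_equal(nb_empirical_model(c(0.3, 0.1, 0.6), c(1, 1, 0), 0.2), 0.25)
  # empty treated set
  expect_equal(nb_empirical_model(c(0.1, 0.2), c(1, 0), 0.2), 0)
  # all treated, all events
  expect_equal(nb_empirical_model(c(0.9, 0.9), c(1, 1), 0.2), 1)
  # a patient exactly at the threshold is untreated
  expect_equal(nb_empirical_model(c(0.2), c(1), 0.2), 0)
  expect_error(nb_empirical_model(c(0.5, 0.5), c(1), 0.2), "same length")
})

test_that("treat-all net benefit matches hand computation", {
  expect_equal(nb_empirical_all(c(0, 0, 0), 0.2), -0.25)
  expect_equal(nb_empirical_all(c(1, 1), 0.7), 1)
  expect_equal(nb_empirical_all(c(1, 0, 0, 0), 0.2), 0.0625)
  # at z = 0 it is the event rate
  expect_equal(nb_empirical_all(c(1, 0, 0, 0), 0), 0.25)
})

test_that("counterfactual net benefits match hand computation", {
  expect_equal(nb_model_given_truth(0.9, 0.5, 0.2), 0.5 - 0.5 * 0.25)
  expect_equal(nb_model_given_truth(c(0.1, 0.15), c(0.1, 0.15), 0.2), 0)
  expect_equal(nb_all_given_truth(c(0.1, 0.3), 0), 0.2)
  expect_equal(nb_all_given_truth(c(0.5, 0.5), 0.5), 0)
  expect_equal(nb_all_given_truth(c(0.1, 0.3), 0.2), 0)
  expect_equal(nb_max_given_truth(c(0.1, 0.3), 0.2), (0.3 - 0.7 * 0.25) / 2)
  expect_equal(nb_max_given_truth(c(0.05, 0.1), 0.2), 0)
})

test_that("net-benefit estimators are vectorized over the threshold grid", {
  z <- default_threshold_grid()
  y <- rep(c(0, 1), 10)
  expect_length(nb_empirical_all(y, z), length(z))
  expect_length(default_threshold_grid(extra = 0.025), length(z) + 1)
  expect_error(default_threshold_grid(extra = 1), "0 <= z < 1")
})

test_that("perfect-information NB dominates model, treat-all and zero", {
  set.seed(401)
  for (i in 1:200) {
    cs <- random_case()
    nbm <- nb_model_given_truth(cs$pi, cs$p, cs$z)
    nba <- nb_all_given_truth(cs$p, cs$z)
    nbx <- nb_max_given_truth(cs$p, cs$z)
    expect_gte(nbx, nbm)
    expect_gte(nbx, nba)
    expect_gte(nbx, 0)
    # scale: NB lies in [-z/(1-z), 1]
    r <- exchange_rate(cs$z)
    expect_true(all(c(nbm, nba, nbx) >= -r - 1e-12))
    expect_true(all(c(nbm, nba, nbx) <= 1 + 1e-12))
  }
})

test_that("degenerate correct risks reproduce the empirical estimators", {
  set.seed(402)
  for (i in 1:100) {
    cs <- random_case()
    expect_identical(nb_model_given_truth(cs$pi, cs$y, cs$z),
                     nb_empirical_model(cs$pi, cs$y, cs$z))
    expect_identical(nb_all_given_truth(cs$y, cs$z),
                     nb_empirical_all(cs$y, cs$z))
  }
})

test_that("treat-all net benefit is non-increasing in the threshold", {
  set.seed(403)
  z <- default_threshold_grid()
  for (i in 1:20) {
    y <- rbinom(30, 1, runif(1, 0.1, 0.9))
    nba <- nb_empirical_all(y, z)
    expect_true(all(diff(nba) <= 1e-12))
  }
})

test_that("c-statistic handles ties, separation and degenerate input", {
  expect_equal(c_statistic(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)
  expect_equal(c_statistic(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(c_statistic(rep(0.3, 10), rbinom(10, 1, 0.5) * 0 + c(rep(0, 5), rep(1, 5))), 0.5)
  expect_error(c_statistic(c(0.1, 0.2), c(1, 1)), "undefined")
  # agrees with the Wilcoxon/pair-counting definition on random data
  set.seed(404)
  for (i in 1:20) {
    pi <- round(runif(25), 1)            # force some ties
    y <- rbinom(25, 1, 0.4)
    if (sum(y) %in% c(0, 25)) next
    pairs <- outer(pi[y == 1], pi[y == 0], "-")
    expect_equal(c_statistic(pi, y),
                 mean((pairs > 0) + 0.5 * (pairs == 0)))
  }
})
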