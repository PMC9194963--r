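test_that("bootstrap weight vectors are valid simplex points", {
  set.seed(501)
  expect_identical(bayesian_bootstrap_weights(1), 1)
  expect_identical(ordinary_bootstrap_weights(1), 1)
  expect_error(bayesian_bootstrap_weights(0), "positive")
  expect_error(ordinary_bootstrap_weights(0), "positive")
  for (n in c(2, 5, 37)) {
    wb <- bayesian_bootstrap_weights(n)
    wo <- ordinary_bootstrap_weights(n)
    expect_length(wb, n)
    expect_true(all(wb >= 0) && abs(sum(wb) - 1) < 1e-12)
    expect_true(all(wo >= 0) && abs(sum(wo) - 1) < 1e-12)
    # multinomial weights are multiples of 1/n
    expect_true(all(abs(wo * n - round(wo * n)) < 1e-12))
  }
})

test_that("both weight schemes have per-coordinate mean 1/n", {
  set.seed(502)
  n <- 3
  wo <- t(replicate(5000, ordinary_bootstrap_weights(n)))
  se <- apply(wo, 2, sd) / sqrt(nrow(wo))
  expect_true(all(abs(colMeans(wo) - 1 / n) < 3 * se))
  wb <- t(replicate(5000, bayesian_bootstrap_weights(n)))
  seb <- apply(wb, 2, sd) / sqrt(nrow(wb))
  expect_true(all(abs(colMeans(wb) - 1 / n) < 3 * seb))
})

test_that("the draw stream is reproducible from a fixed seed", {
  gen <- generate_sample(quick_dgp(), 80, seed = 11)
  dev <- logistic_developer()
  draws <- function() {
    seeds <- voidev:::derive_seeds(99, 5)
    lapply(seeds, function(s) {
      set.seed(s)
      draw_correct_risks(gen$sample, dev, "bayesian_bootstrap")$risks
    })
  }
  expect_identical(draws(), draws())
})

test_that("ordinary-bootstrap draws equal resample-rows-then-fit exactly", {
  gen <- generate_sample(quick_dgp(), 100, seed = 12)
  s <- gen$sample
  dev <- logistic_developer()
  set.seed(321)
  d1 <- draw_correct_risks(s, dev, "ordinary_bootstrap")$risks
  # manual path: same RNG consumption order
  set.seed(321)
  idx <- sample.int(s$n, s$n, replace = TRUE)
  df <- cbind(s$covariates[idx, , drop = FALSE], .y = s$outcomes[idx])
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = df))
  d2 <- as.numeric(predict(fit, newdata = s$covariates, type = "response"))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("a point-mass posterior returns the proposed model every draw", {
  gen <- generate_sample(quick_dgp(), 60, seed = 13)
  dev <- point_mass_developer(logistic_developer())
  pi_hat <- voidev:::fit_proposed(dev, gen$sample)$risks
  set.seed(7)
  for (i in 1:5) {
    d <- draw_correct_risks(gen$sample, dev, "bayesian_bootstrap")
    expect_true(d$ok)
    expect_equal(d$risks, pi_hat, tolerance = 1e-15)
    expect_true(all(d$risks >= 0 & d$risks <= 1))
    expect_length(d$risks, gen$sample$n)
  }
})

test_that("intercept-only Bayesian-bootstrap draws are centred on the event rate", {
  gen <- generate_sample(quick_dgp(), 50, seed = 14)
  s <- gen$sample
  dev <- intercept_developer()
  set.seed(77)
  draws <- replicate(2000, draw_correct_risks(s, dev, "bayesian_bootstrap")$risks[1])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean(s$outcomes)), 3 * se)
})

test_that("MVN coefficient posterior matches the logistic MLE and its SEs", {
  gen <- generate_sample(quick_dgp(), 400, seed = 15)
  post <- mvn_posterior(gen$sample)
  # zero-covariance limit collapses on the MLE
  expect_equal(drop(draw_coefficients(post, 1, scale = 0)), post$coef,
               tolerance = 1e-12)
  set.seed(16)
  draws <- draw_coefficients(post, 5000)
  se_mean <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - post$coef) < 3 * se_mean))
  # marginal draw SDs track the reported coefficient SEs within 5%
  expect_true(all(abs(apply(draws, 2, sd) / sqrt(diag(post$vcov)) - 1) < 0.05))
  # risks from a draw are valid
  set.seed(17)
  d <- draw_correct_risks(gen$sample, logistic_developer(),
                          "likelihood_mvn", mvn = post)
  expect_true(all(d$risks >= 0 & d$risks <= 1))
  expect_length(d$risks, gen$sample$n)
})

test_that("a singular design is an explicit MVN-posterior error", {
  gen <- generate_sample(quick_dgp(), 80, seed = 18)
  df <- as.data.frame(gen$sample)
  df$x3 <- df$x1                       # aliased column
  expect_error(mvn_posterior(development_sample(df)),
               "aliased|positive definite")
})

test_that("degenerate resamples are redrawn and failures are reported", {
  # one event in a tiny sample: ordinary bootstrap often omits it
  df <- data.frame(x = c(rnorm(7), 3), outcome = c(rep(0, 7), 1))
  s <- development_sample(df)
  set.seed(19)
  d <- draw_correct_risks(s, intercept_developer(), "ordinary_bootstrap",
                          min_events = 1, max_redraws = 100)
  expect_true(d$ok)
  expect_gte(d$attempts, 1)
  # an unattainable guard fails explicitly, never silently
  d2 <- draw_correct_risks(s, intercept_developer(), "ordinary_bootstrap",
                           min_events = 5, max_redraws = 3)
  expect_false(d2$ok)
  expect_null(d2$risks)
})
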