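# shared fixtures: small synthetic truths and quick developers

# two-predictor logistic truth with moderate signal
quick_dgp <- function(b1 = 0.8, b2 = -0.6, intercept = -1.5) {
  logistic_dgp(
    intercept = intercept,
    predictors = list(
      x1 = list(dist = list(kind = "normal", mean = 0, sd = 1), coef = b1),
      x2 = list(dist = list(kind = "normal", mean = 0, sd = 1), coef = b2)
    )
  )
}

# random small (pi, p, y, z) case for property loops
random_case <- function(n_max = 30) {
  n <- sample.int(n_max, 1)
  list(
    n = n,
    pi = runif(n),
    p = runif(n),
    y = rbinom(n, 1, 0.5),
    z = runif(1, 0, 0.95)
  )
}

# developer whose fit fails whenever the resample/weight draw gives an odd
# number of (weighted > 1/n) rows — used to exercise partial-failure paths
flaky_developer <- function() {
  base <- logistic_developer()
  model_developer(
    fit = function(sample, weights = NULL, indices = NULL) {
      key <- if (!is.null(indices)) sum(indices) else
        sum(weights > 1 / length(weights))
      if (key %% 2 == 1) stop("flaky fit")
      base$fit(sample, weights, indices)
    },
    predict = base$predict,
    label = "flaky logistic"
  )
}
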