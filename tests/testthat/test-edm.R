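test_that("delay embedding follows the lagged-coordinate convention", {
  m <- delay_embed(1:6, E = 2, l = 1)
  expect_equal(nrow(m), 5)
  expect_equal(unname(m[1, ]), c(2, 1))
  expect_equal(unname(delay_embed(1:5, E = 1)), matrix(1:5, ncol = 1),
               ignore_attr = TRUE)
  m2 <- delay_embed(1:10, E = 3, l = 2)
  expect_equal(nrow(m2), 6)
  expect_equal(unname(m2[6, ]), c(10, 8, 6))
  # un-embedding (first coordinate) reproduces the tail of x
  x <- rnorm(50)
  expect_equal(delay_embed(x, 4, 3)[, 1], x[10:50], ignore_attr = TRUE)
  expect_error(delay_embed(1:5, E = 3, l = 3), "too short")
})

test_that("simplex projection matches an exhaustive nearest-neighbour oracle", {
  set.seed(21)
  for (E in c(2, 4)) {
    lib <- rnorm(120)
    tgt <- rnorm(80)
    got <- simplex_forecast(lib, tgt, E = E, l = 1)
    want <- oracle_simplex(lib, tgt, E = E, l = 1)
    expect_equal(got$predictions, want$predictions, tolerance = 1e-10)
    expect_equal(got$observed, want$observed)
  }
})

test_that("simplex skill separates deterministic from random dynamics", {
  s <- simulate_four_species(800, seed = 1)
  x <- s$Y1
  f <- simplex_forecast(x[1:500], x[501:600], E = 2, l = 1)
  expect_gt(f$skill, 0.99)  # noiseless logistic map is 1-step predictable
  # predictions lie within the range of neighbour futures, hence of the data
  expect_true(all(f$predictions >= min(x) & f$predictions <= max(x)))
  set.seed(9)
  skills <- replicate(5, simplex_forecast(rnorm(500), rnorm(200),
                                          E = 3, l = 1)$skill)
  expect_lt(stats::median(abs(skills)), 0.2)
})

test_that("a target state identical to a library state uses the zero-distance rule", {
  x <- rep(c(0.2, 0.8, 0.5, 0.9), 30)  # period-4 noiseless series
  f <- simplex_forecast(x, x[1:20], E = 2, l = 1)
  expect_equal(f$predictions, f$observed, tolerance = 1e-12)
})

test_that("embedding-dimension selection favours low dimensions for the logistic map", {
  s <- simulate_four_species(500, seed = 1)
  expect_lte(select_embedding_dimension(s$Y1[1:300], 1:10, l = 1), 3)
  # a short series truncates the candidate range without error
  expect_no_error(select_embedding_dimension(rnorm(40), 1:20, l = 1))
})

test_that("lag selection finds the first mutual-information minimum", {
  x <- sin(2 * pi * (1:400) / 40)
  lag <- select_lag(x)
  # the quarter-period minimum: verify against an independent MI oracle
  mio <- vapply(1:15, function(k) oracle_mi(x[1:(400 - k)], x[(k + 1):400]),
                numeric(1))
  expect_equal(which.min(mio), 10)
  expect_true(lag >= 5 && lag <= 13)
  # white noise sits at the MI floor immediately: small lag
  set.seed(3)
  lags <- replicate(5, select_lag(rnorm(400)))
  expect_lte(stats::median(lags), 4)
  # no usable minimum (series too short to scan): fall back to the default
  expect_equal(select_lag(rnorm(8)), 2)
})

test_that("the package MI estimator agrees with the oracle", {
  set.seed(14)
  x <- rnorm(300); y <- x + rnorm(300)
  expect_equal(ccmbn:::.mutual_information(x, y), oracle_mi(x, y),
               tolerance = 1e-10)
})

test_that("S-map theta = 0 reduces to a leave-one-out global linear forecast", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.6), 150))
  res <- smap_nonlinearity(x, theta_grid = c(0), E = 2, l = 1)
  # oracle: for each state, fit the global linear map on all other states
  X <- delay_embed(x, 2, 1)
  t_idx <- as.integer(rownames(X))
  keep <- t_idx + 1 <= length(x)
  X <- X[keep, , drop = FALSE]
  y <- x[t_idx[keep] + 1]
  pred <- vapply(seq_len(nrow(X)), function(i) {
    fit <- stats::lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
    sum(c(1, X[i, ]) * fit$coefficients)
  }, numeric(1))
  expect_equal(res$skill[1], stats::cor(pred, y), tolerance = 1e-6)
})

test_that("S-map flags nonlinearity of the logistic map but not of AR(1)", {
  s <- simulate_four_species(400, seed = 2)
  res_log <- smap_nonlinearity(s$Y1[1:300], E = 2, l = 1)
  expect_true(attr(res_log, "nonlinear"))
  set.seed(8)
  flags <- replicate(3, {
    ar <- as.numeric(arima.sim(list(ar = 0.7), 300))
    attr(smap_nonlinearity(ar, E = 2, l = 1), "nonlinear")
  })
  expect_lte(sum(flags), 1)  # theta = 0 optimal for a linear process
})
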