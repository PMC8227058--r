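test_that("regression metrics match hand arithmetic and a two-pass oracle", {
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect[c("mae", "rmse", "r")]),
               c(mae = 0, rmse = 0, r = 1))

  m <- regression_metrics(c(1, 2, 3), c(1, 3, 2))
  expect_equal(m$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$r, 0.5, tolerance = 1e-12)

  # textbook two-pass computation on random vectors
  set.seed(1)
  for (i in 1:5) {
    y <- rnorm(50, 100, 20)
    yhat <- y + rnorm(50, 0, 10)
    m <- regression_metrics(y, yhat)
    expect_equal(m$mae, sum(abs(y - yhat)) / 50, tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(sum((y - yhat)^2) / 50), tolerance = 1e-12)
    r_oracle <- sum((y - mean(y)) * (yhat - mean(yhat))) /
      sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
    expect_equal(m$r, r_oracle, tolerance = 1e-12)
  }
})

test_that("degenerate predictions flag r instead of silently zeroing it", {
  expect_warning(m <- regression_metrics(c(1, 2, 3), c(2, 2, 2)), "undefined")
  expect_true(is.na(m$r))
  expect_true(is.finite(m$mae) && is.finite(m$rmse))
  expect_error(regression_metrics(1:3, 1:4), "equal length")
})

test_that("mae never exceeds rmse", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    y <- rnorm(n)
    yhat <- rnorm(n)
    m <- suppressWarnings(regression_metrics(y, yhat))
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("fold aggregation reports mean and sample sd", {
  agg <- aggregate_folds(data.frame(mae = c(200, 300), rmse = c(250, 350)))
  expect_equal(agg$mean, c(250, 300))
  expect_equal(agg$sd, c(sd(c(200, 300)), sd(c(250, 350))))
  expect_equal(agg$sd[1], 70.71, tolerance = 1e-3)

  ten <- aggregate_folds(data.frame(mae = rep(123, 10)))
  expect_equal(ten$sd, 0)

  single <- aggregate_folds(data.frame(mae = 100))
  expect_true(is.na(single$sd))
  expect_error(aggregate_folds(data.frame()), "fold")
})

test_that("histogram intersection behaves at the extremes and is symmetric", {
  set.seed(7)
  y <- rnorm(400)
  expect_equal(histogram_intersection(y, y, 20), 1)
  expect_equal(histogram_intersection(runif(100), runif(100) + 10, 20), 0)
  yhat <- rnorm(300, 0.5)
  expect_equal(histogram_intersection(y, yhat, 20),
               histogram_intersection(yhat, y, 20))
  # joint affine rescaling leaves the intersection unchanged
  expect_equal(histogram_intersection(3 * y - 2, 3 * yhat - 2, 20),
               histogram_intersection(y, yhat, 20))
})

test_that("unit-shifted normal intersection matches the analytic overlap", {
  # total-variation overlap of N(0,1) vs N(1,1) is 2*pnorm(-1/2) = 0.617
  set.seed(123)
  vals <- replicate(20, {
    y <- rnorm(1000)
    histogram_intersection(y, y + 1, 20)
  })
  expect_lt(abs(mean(vals) - 2 * pnorm(-0.5)), 0.03)
})

test_that("elbow rule is stable, caps, and handles constants", {
  set.seed(9)
  y <- runif(10000)
  k1 <- elbow_bins(y, 5:40)
  k2 <- elbow_bins(y, 5:60)
  expect_equal(k1, k2)
  expect_gte(k1, 5)

  expect_equal(elbow_bins(rep(3, 100)), 1L)
  expect_warning(k <- elbow_bins(c(1, 2, 3), candidates = 5:40), "Capping")
  expect_lte(k, 3)
})
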