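test_that("selection intensity matches the truncated-normal closed form", {
  expect_equal(selection_intensity(0.10), 1.755, tolerance = 1e-3)
  expect_equal(selection_intensity(0.05), 2.063, tolerance = 1e-3)
  expect_equal(selection_intensity(0.50), 0.7979, tolerance = 1e-4)
  expect_equal(printed_intensity(c(0.10, 0.05, 0.01)), c(1.76, 2.06, 2.67))
  expect_error(selection_intensity(0), "\\(0, 1\\)")
  expect_error(selection_intensity(1), "\\(0, 1\\)")
})

test_that("selection intensity is strictly decreasing and matches Monte Carlo", {
  p <- c(0.01, 0.05, 0.1, 0.5, 0.9)
  i <- selection_intensity(p)
  expect_true(all(diff(i) < 0))
  # mean of the selected upper tail of 10^7 standard normal draws
  set.seed(77)
  z <- rnorm(1e7)
  for (pp in c(0.01, 0.05, 0.1, 0.5)) {
    mc <- mean(z[z > quantile(z, 1 - pp)])
    expect_lt(abs(selection_intensity(pp) - mc), 0.002)
  }
})

test_that("direct and correlated responses follow their closed forms", {
  expect_equal(round(direct_response(1.76, 0.41, 44258)), 237)
  expect_equal(round(direct_response(1.76, 0.48, 87562)), 361)
  expect_equal(direct_response(0, 0.5, 1000), 0)
  expect_error(direct_response(1.76, -0.1, 1000), "negative heritability")

  expect_equal(round(correlated_response(1.76, 0.45, 0.84, 44258)), 209)
  expect_equal(round(correlated_response(2.67, 0.51, 0.83, 87562)), 468)
  # with r = 1 and equal heritability, CR collapses to DR
  expect_equal(correlated_response(2, 0.4, 1, 5000),
               direct_response(2, 0.4, 5000))
  expect_error(correlated_response(1.76, 0.45, 1.2, 44258), "-1, 1")
})

test_that("the scenario table reproduces published-style arithmetic", {
  ldmy <- scenario_table(real = list(H = 0.41, Vg = 44258),
                         htp = list(H = 0.45, r = 0.84))
  expect_equal(ldmy$i, c(1.76, 2.06, 2.67))
  expect_equal(round(ldmy$DR), rep(237, 3))
  expect_equal(round(ldmy$CR), c(209, 244, 317))
  expect_equal(round(ldmy$CR_DR, 2), c(0.88, 1.03, 1.34))

  tdmy <- scenario_table(real = list(H = 0.48, Vg = 87562),
                         htp = list(H = 0.51, r = 0.83))
  expect_equal(round(tdmy$DR), rep(361, 3))
  expect_equal(round(tdmy$CR), c(309, 361, 468))
  expect_equal(round(tdmy$CR_DR, 2), c(0.86, 1.00, 1.30))

  # identical real and HTP parameters with r = 1: baseline ratio is exactly 1
  same <- scenario_table(real = list(H = 0.41, Vg = 44258),
                         htp = list(H = 0.41, r = 1))
  expect_equal(same$CR_DR[1], 1)
  expect_error(scenario_table(real = list(H = 0.41), htp = list(H = 0.4, r = 1)),
               "Vg")
})

test_that("CR/DR is invariant to the real genetic variance", {
  set.seed(5)
  for (i in 1:20) {
    H_r <- runif(1, 0.1, 0.9)
    H_h <- runif(1, 0.1, 0.9)
    r <- runif(1, -1, 1)
    tab1 <- scenario_table(real = list(H = H_r, Vg = 1000),
                           htp = list(H = H_h, r = r))
    tab2 <- scenario_table(real = list(H = H_r, Vg = 987654),
                           htp = list(H = H_h, r = r))
    expect_equal(tab1$CR_DR, tab2$CR_DR, tolerance = 1e-12)
    # symbolic form: (i_CR / i_DR) * sqrt(H_htp / H_real) * r
    expect_equal(tab1$CR_DR,
                 (tab1$i / tab1$i[1]) * sqrt(H_h / H_r) * r,
                 tolerance = 1e-12)
  }
})
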