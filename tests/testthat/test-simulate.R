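test_that("degenerate variances give exactly mu + rep effect on family plots", {
  lay <- small_layout(seed = 1)
  gp <- genetic_params(mu = 1500, Vg = 0, Vb = 0, Ve = 0,
                       rho_row = 0, rho_col = 0,
                       check_effects = 0, rep_effects = c(0, 50))
  truth <- simulate_trial(lay, gp, seed = 2)
  fam <- dplyr::filter(truth, genotype_class == "family")
  expect_equal(fam$true_tdmy, 1500 + c(0, 50)[fam$rep], tolerance = 1e-12)
})

test_that("component additivity is exact and yields are non-negative", {
  lay <- make_layout(seed = 2)
  truth <- simulate_trial(lay, genetic_params(), seed = 5)
  expect_equal(truth$true_tdmy,
               truth$true_ldmy + truth$true_ssdmy + truth$true_dmdmy)
  expect_true(all(truth$true_tdmy >= 0))
  expect_true(all(truth$true_green_matter >= 0))
})

test_that("simulation is deterministic under a fixed seed", {
  lay <- small_layout(seed = 1)
  a <- simulate_trial(lay, genetic_params(), seed = 9)
  b <- simulate_trial(lay, genetic_params(), seed = 9)
  c <- simulate_trial(lay, genetic_params(), seed = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("variance components are targeted across replicate simulations", {
  lay <- make_layout(seed = 3)
  gp <- genetic_params(Vg = 44258, Vb = 20000, Ve = 100000,
                       rho_row = 0.3, rho_col = 0.3)
  n_rep <- 200
  fam_var <- block_var <- res_var <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    truth <- simulate_trial(lay, gp, seed = 5000 + s)
    fam <- dplyr::filter(truth, genotype_class == "family")
    fam_var[s] <- var(fam$family_effect[!duplicated(fam$genotype_id)])
    blocks <- dplyr::distinct(truth, rep, block, block_effect)
    block_var[s] <- var(blocks$block_effect)
    res_var[s] <- var(truth$residual)
  }
  expect_gt(mean(fam_var) / gp$Vg, 0.9)
  expect_lt(mean(fam_var) / gp$Vg, 1.1)
  expect_gt(mean(block_var) / gp$Vb, 0.9)
  expect_lt(mean(block_var) / gp$Vb, 1.1)
  expect_gt(mean(res_var) / gp$Ve, 0.9)
  expect_lt(mean(res_var) / gp$Ve, 1.1)
})

test_that("residual field recovers the planted AR1 lag-1 correlations", {
  lay <- make_layout(seed = 4)
  gp <- genetic_params(rho_row = 0.3, rho_col = 0.3)
  n_rep <- 100
  acc <- matrix(0, n_rep, 2)
  grid <- matrix(NA_integer_, attr(lay, "n_rows"), attr(lay, "n_cols"))
  grid[cbind(lay$field_row, lay$field_col)] <- seq_len(nrow(lay))
  down <- cbind(as.vector(grid[-nrow(grid), ]), as.vector(grid[-1, ]))
  right <- cbind(as.vector(grid[, -ncol(grid)]), as.vector(grid[, -1]))
  down <- down[stats::complete.cases(down), ]
  right <- right[stats::complete.cases(right), ]
  for (s in seq_len(n_rep)) {
    truth <- simulate_trial(lay, gp, seed = 7000 + s)
    e <- truth$residual
    acc[s, ] <- c(cor(e[down[, 1]], e[down[, 2]]),
                  cor(e[right[, 1]], e[right[, 2]]))
  }
  expect_lt(abs(mean(acc[, 1]) - 0.3), 0.05) # row direction
  expect_lt(abs(mean(acc[, 2]) - 0.3), 0.05) # column direction

  # independence case: adjacent-plot correlation near zero
  gp0 <- genetic_params(rho_row = 0, rho_col = 0)
  acc0 <- sapply(1:20, function(s) {
    e <- simulate_trial(lay, gp0, seed = 8000 + s)$residual
    cor(e[down[, 1]], e[down[, 2]])
  })
  expect_lt(abs(mean(acc0)), 0.1)
})

test_that("invalid AR1 correlations are rejected", {
  expect_error(genetic_params(rho_row = 1), "rho_row")
  expect_error(ar1_kron_ar1(1.2, 0.3, 1:4, 1:4), "rho_row")
})
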