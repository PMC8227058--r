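test_that("AR1 and separable correlation matrices have the right entries", {
  expect_equal(ar1_cor(0, 4), diag(4))
  A <- ar1_cor(0.5, 3)
  expect_equal(A[1, ], c(1, 0.5, 0.25))
  expect_true(isSymmetric(A))

  R <- ar1_kron_ar1(0.5, 0.4, rows = c(1, 1, 2), cols = c(1, 2, 2))
  expect_equal(diag(R), rep(1, 3))
  expect_equal(R[1, 2], 0.4)   # same row, adjacent columns
  expect_equal(R[2, 3], 0.5)   # same column, adjacent rows
  expect_equal(R[1, 3], 0.2)   # diagonal neighbour: 0.5 * 0.4
  expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("design matrices have the documented shapes", {
  lay <- make_layout(seed = 1)
  truth <- simulate_trial(lay, genetic_params(), seed = 2)
  mme <- build_mme(truth, trait = "true_tdmy")
  expect_equal(ncol(mme$X), 1 + 2 + 24)
  expect_equal(ncol(mme$Z1), 33)
  expect_equal(ncol(mme$Z2), 86)
  # check plots have all-zero family incidence
  chk <- truth$genotype_class != "family"
  expect_true(all(rowSums(mme$Z2[chk, ]) == 0))
  expect_true(all(rowSums(mme$Z2[!chk, ]) == 1))

  single <- one_way_data()
  sm <- build_mme(single, "y", include_blocks = FALSE)
  expect_equal(colnames(sm$X), "(Intercept)")
  expect_null(sm$Z1)

  dup <- truth
  dup$plot_id[2] <- dup$plot_id[1]
  expect_error(build_mme(dup, "true_tdmy"), "Duplicated")
})

test_that("restricted log-likelihood matches dense brute force on small data", {
  lay <- small_layout(seed = 1)
  truth <- simulate_trial(lay, genetic_params(), seed = 2)
  spec <- build_mme(truth, "true_tdmy")
  expect_lte(spec$n, 60)
  thetas <- list(
    list(Vb = 15000, Vg = 30000, Ve = 90000, rho_row = 0.3, rho_col = 0.2),
    list(Vb = 1000, Vg = 80000, Ve = 50000, rho_row = -0.4, rho_col = 0.5),
    list(Vb = 20000, Vg = 44258, Ve = 100000, rho_row = 0, rho_col = 0)
  )
  for (th in thetas) {
    expect_equal(restricted_loglik(spec, th), brute_force_loglik(spec, th),
                 tolerance = 1e-8)
  }
})

test_that("REML likelihood is invariant to shifts and fixed-effect coding", {
  dat <- one_way_data(g = 6, n_per = 3, seed = 4)
  spec <- build_mme(dat, "y", include_blocks = FALSE)
  th <- list(Vg = 20, Ve = 10, rho_row = 0, rho_col = 0)
  ll <- restricted_loglik(spec, th)

  shifted <- dat
  shifted$y <- dat$y + 500
  expect_equal(restricted_loglik(build_mme(shifted, "y", include_blocks = FALSE), th),
               ll, tolerance = 1e-8)

  # reparameterize X: replace intercept-only by an equivalent full-rank basis
  spec2 <- spec
  spec2$X <- matrix(2, spec$n, 1, dimnames = list(NULL, "two"))
  expect_equal(restricted_loglik(spec2, th), ll, tolerance = 1e-8)
})

test_that("balanced one-way fit equals the ANOVA REML estimator and lme4", {
  dat <- one_way_data(g = 10, n_per = 5, Vg = 25, Ve = 9, seed = 11)
  fit <- reml_fit(dat, "y", include_blocks = FALSE, fix_rho = c(0, 0))
  oracle <- one_way_anova_reml(dat)
  expect_gt(oracle$Vg, 0) # interior solution for this draw
  expect_equal(fit$theta$Vg, oracle$Vg, tolerance = 1e-6)
  expect_equal(fit$theta$Ve, oracle$Ve, tolerance = 1e-6)

  skip_if_not_installed("lme4")
  lfit <- lme4::lmer(y ~ 1 + (1 | genotype_id), data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$theta$Vg, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$theta$Ve, vc$vcov[2], tolerance = 1e-4)
  # lme4 omits the theta-constant + log|X'X|/2 of Harville's restricted
  # likelihood; reconcile the conventions before comparing
  ld_xtx <- as.numeric(determinant(crossprod(fit$spec$X))$modulus)
  expect_equal(fit$loglik - 0.5 * ld_xtx, as.numeric(stats::logLik(lfit)),
               tolerance = 1e-4)
})

test_that("null genetic variance is flagged rather than inflated", {
  dat <- one_way_data(g = 12, n_per = 4, Vg = 0, Ve = 9, seed = 26)
  expect_warning(
    fit <- reml_fit(dat, "y", include_blocks = FALSE, fix_rho = c(0, 0)),
    "lower bound"
  )
  expect_true(fit$vg_floored)
  expect_true(is.na(fit$H))
})

test_that("BLUPs shrink and the likelihood trace is monotone", {
  lay <- make_layout(seed = 5)
  truth <- simulate_trial(lay, genetic_params(), seed = 6)
  fit <- reml_fit(truth, "true_tdmy")
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_lte(var(fit$blup_family), fit$theta$Vg)
  expect_lte(fit$H, 1)
  expect_equal(length(fit$blup_family), 86)
  expect_gte(fit$mean_pairwise_pev, 0)
  # BLUPs track the simulated family effects
  sim_eff <- dplyr::distinct(
    dplyr::filter(truth, genotype_class == "family"),
    genotype_id, family_effect
  )
  expect_gt(cor(fit$blup_family[sim_eff$genotype_id], sim_eff$family_effect),
            0.6)
})

test_that("Cullis heritability follows its defining arithmetic", {
  base <- list(theta = list(Vg = 100), mean_pairwise_pev = 0, vg_floored = FALSE)
  expect_equal(cullis_H(base), 1)
  base$mean_pairwise_pev <- 200
  expect_equal(cullis_H(base), 0)
  base$mean_pairwise_pev <- 300
  expect_equal(cullis_H(base), -0.5) # negative estimates are reported as-is
  base$theta$Vg <- 0
  expect_warning(h <- cullis_H(base), "not positive")
  expect_true(is.na(h))
})

test_that("genetic correlation of identical, flipped and planted-twin fits", {
  lay <- make_layout(seed = 7)
  # high-accuracy setting: the BLUP correlation estimates the planted
  # genetic correlation attenuated by the reliability, so keep noise low
  gp <- genetic_params(Vb = 1000, Ve = 3000)
  truth <- simulate_trial(lay, gp, seed = 8)
  fit <- reml_fit(truth, "true_tdmy")
  expect_equal(genetic_correlation(fit, fit), 1)
  flipped <- fit
  flipped$blup_family <- -fit$blup_family
  expect_equal(genetic_correlation(fit, flipped), -1)

  # twin traits sharing family effects, independent residuals: with high
  # heritability the BLUP correlation approaches the planted value 1
  n_rep <- 15
  rs <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    t1 <- simulate_trial(lay, gp, seed = 300 + 2 * s)
    t2 <- simulate_trial(lay, gp, seed = 301 + 2 * s)
    fam <- t1$genotype_class == "family"
    twin <- t2
    twin$true_tdmy <- t2$true_tdmy +
      ifelse(fam, t1$family_effect - t2$family_effect, 0)
    f1 <- reml_fit(t1, "true_tdmy")
    f2 <- reml_fit(twin, "true_tdmy")
    rs[s] <- genetic_correlation(f1, f2)
  }
  expect_lt(abs(mean(rs) - 1), 0.1)
})

test_that("tidy and glance return the documented shapes", {
  lay <- small_layout(seed = 3)
  truth <- simulate_trial(lay, genetic_params(), seed = 4)
  fit <- reml_fit(truth, "true_tdmy")
  td <- tidy(fit)
  expect_named(td, c("family", "blup", "pev"))
  expect_equal(nrow(td), 12)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("Vg", "Ve", "rho_row", "H", "loglik") %in% names(gl)))
})
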