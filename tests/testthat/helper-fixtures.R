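# Shared fixtures: all synthetic, generated in code at test time.

# A small complete trial: 12 families + 2+2 genitors + 2 checks = 18 entries,
# 2 reps x 2 blocks of 9, on a 6 x 6 grid.
small_layout <- function(seed = 1) {
  make_layout(
    n_families = 12, n_genitors_sexual = 2, n_genitors_apomictic = 2,
    n_checks = 2, n_reps = 2, blocks_per_rep = 2,
    n_rows = 6, n_cols = 6, seed = seed
  )
}

# Balanced one-way random-effects data (g families x n plots each, no
# blocks, no checks, independent residuals) as a plot table reml_fit accepts.
one_way_data <- function(g = 8, n_per = 4, mu = 100, Vg = 25, Ve = 9,
                         seed = 1) {
  set.seed(seed)
  fam <- sprintf("F%02d", seq_len(g))
  eff <- rnorm(g, 0, sqrt(Vg))
  tibble::tibble(
    plot_id = seq_len(g * n_per),
    field_row = rep(seq_len(g), each = n_per),
    field_col = rep(seq_len(n_per), times = g),
    rep = 1L,
    block = 1L,
    genotype_id = rep(fam, each = n_per),
    genotype_class = factor(rep("family", g * n_per),
                            levels = c("family", "cultivar_check")),
    y = mu + rep(eff, each = n_per) + rnorm(g * n_per, 0, sqrt(Ve))
  )
}

# Closed-form REML variance components for balanced one-way data
# (interior solution): Vg = (MSB - MSW) / n, Ve = MSW.
one_way_anova_reml <- function(data) {
  groups <- split(data$y, data$genotype_id)
  n_per <- length(groups[[1]])
  means <- vapply(groups, mean, numeric(1))
  msb <- n_per * var(means)
  msw <- mean(vapply(groups, var, numeric(1)))
  list(Vg = max((msb - msw) / n_per, 0), Ve = msw)
}

# Brute-force restricted log-likelihood by direct dense inversion of V
# (independent of the package's Cholesky-based implementation).
brute_force_loglik <- function(spec, theta) {
  n <- spec$n
  dr <- abs(outer(spec$rows, spec$rows, "-"))
  dc <- abs(outer(spec$cols, spec$cols, "-"))
  R <- theta$rho_row^dr * theta$rho_col^dc
  V <- theta$Ve * R + theta$Vg * tcrossprod(spec$Z2)
  if (!is.null(spec$Z1)) V <- V + theta$Vb * tcrossprod(spec$Z1)
  Vinv <- solve(V)
  X <- spec$X
  XtVX <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(XtVX) %*% t(X) %*% Vinv
  p <- ncol(X)
  as.numeric(
    -0.5 * (determinant(V, logarithm = TRUE)$modulus +
              determinant(XtVX, logarithm = TRUE)$modulus -
              determinant(crossprod(X), logarithm = TRUE)$modulus +
              drop(t(spec$y) %*% P %*% spec$y) +
              (n - p) * log(2 * pi))
  )
}

# Tiny image with a left-right asymmetric pattern
asymmetric_image <- function(px = 8) {
  img <- array(0.2, c(px, px, 3))
  img[, 1:(px / 2), 2] <- 0.9
  img
}
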