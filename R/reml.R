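#' AR1 correlation matrices for field-trial residuals
#'
#' `ar1_cor()` returns the order-`n` first-order autoregressive correlation
#' matrix with entry `rho^|i-j|`. `ar1_kron_ar1()` returns the separable
#' row-by-column residual correlation over the *occupied* plot coordinates:
#' entry `(i, j)` is `rho_row^|row_i - row_j| * rho_col^|col_i - col_j|`.
#' Missing grid cells need no special handling because entries depend only
#' on coordinate distances.
#'
#' @param rho,rho_row,rho_col AR1 correlation(s), each in (-1, 1).
#' @param n Matrix order.
#' @param rows,cols Integer field coordinates, one per plot.
#' @return A symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @examples
#' ar1_cor(0.5, 3)
#' ar1_kron_ar1(0.5, 0.4, rows = c(1, 1, 2), cols = c(1, 2, 2))
#' @export
ar1_cor <- function(rho, n) {
  check_scalar(rho, "rho", lower = -1, upper = 1, strict = TRUE)
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

#' @rdname ar1_cor
#' @export
ar1_kron_ar1 <- function(rho_row, rho_col, rows, cols) {
  check_scalar(rho_row, "rho_row", lower = -1, upper = 1, strict = TRUE)
  check_scalar(rho_col, "rho_col", lower = -1, upper = 1, strict = TRUE)
  stopifnot(length(rows) == length(cols))
  dr <- abs(outer(rows, rows, "-"))
  dc <- abs(outer(cols, cols, "-"))
  rho_row^dr * rho_col^dc
}

#' Assemble the mixed-model design for one trait
#'
#' Builds the observation vector and incidence matrices of the plot-level
#' linear mixed model `y = X B + Z1 b + Z2 g + e`: fixed effects are an
#' intercept, replication contrasts (treatment-coded) and one indicator per
#' check-class genotype (genitors and cultivar checks, deviations from the
#' family population mean); `Z1` carries blocks within replications
#' (`b ~ N(0, Vb)`); `Z2` carries full-sib families (`g ~ N(0, Vg)`); the
#' residual carries the separable AR1 x AR1 spatial correlation built from
#' the plot field coordinates.
#'
#' @param data A data frame with one row per plot: `plot_id`, `field_row`,
#'   `field_col`, `rep`, `block`, `genotype_id`, `genotype_class` and the
#'   trait column.
#' @param trait Name of the trait column in `data`.
#' @param include_blocks Include the block-within-rep random term (set
#'   `FALSE` for designs without incomplete blocks).
#' @return A list of class `htp_mme` with elements `y`, `X`, `Z1` (or NULL),
#'   `Z2`, `rows`, `cols`, `families`, `n`, `trait`.
#' @examples
#' lay <- make_layout(seed = 1)
#' truth <- simulate_trial(lay, genetic_params(), seed = 2)
#' mme <- build_mme(truth, trait = "true_tdmy")
#' dim(mme$X) # 330 x 27
#' @export
build_mme <- function(data, trait, include_blocks = TRUE) {
  need <- c("plot_id", "field_row", "field_col", "rep", "block",
            "genotype_id", "genotype_class", trait)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(data$plot_id)) {
    abort("Duplicated plot_id in `data`.")
  }
  y <- data[[trait]]
  keep <- !is.na(y)
  if (any(!keep)) {
    warn(sprintf("Dropping %d plot(s) with missing %s.", sum(!keep), trait))
    data <- data[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(data)

  reps <- factor(data$rep)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (nlevels(reps) > 1L) {
    Xr <- stats::model.matrix(~reps)[, -1, drop = FALSE]
    colnames(Xr) <- paste0("rep", levels(reps)[-1])
    X <- cbind(X, Xr)
  }
  is_check <- data$genotype_class != "family"
  check_ids <- sort(unique(data$genotype_id[is_check]))
  if (length(check_ids)) {
    Xc <- vapply(check_ids, function(id) as.numeric(data$genotype_id == id),
                 numeric(n))
    colnames(Xc) <- check_ids
    X <- cbind(X, Xc)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Fixed-effects design is rank deficient; aliased column(s): ",
                 paste(aliased, collapse = ", ")))
  }

  Z1 <- NULL
  if (include_blocks) {
    bl <- factor(paste(data$rep, data$block, sep = ":"))
    if (nlevels(bl) > 1L) {
      Z1 <- stats::model.matrix(~ 0 + bl)
      colnames(Z1) <- levels(bl)
    }
  }

  families <- sort(unique(data$genotype_id[!is_check]))
  if (!length(families)) abort("No family-class genotypes in `data`.")
  Z2 <- vapply(families, function(id) as.numeric(data$genotype_id == id),
               numeric(n))
  colnames(Z2) <- families

  structure(
    list(
      y = y, X = X, Z1 = Z1, Z2 = Z2,
      rows = data$field_row, cols = data$field_col,
      families = families, n = n, trait = trait,
      plot_id = data$plot_id
    ),
    class = "htp_mme"
  )
}

# Build V and derived quantities at theta. Returns NULL on numerical failure.
.mme_core <- function(spec, theta) {
  n <- spec$n
  R <- ar1_kron_ar1(theta$rho_row, theta$rho_col, spec$rows, spec$cols)
  V <- theta$Ve * R
  if (!is.null(spec$Z1)) V <- V + theta$Vb * tcrossprod(spec$Z1)
  V <- V + theta$Vg * tcrossprod(spec$Z2)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  XtVinv <- crossprod(spec$X, Vinv)
  XtVinvX <- XtVinv %*% spec$X
  chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  XtVinvX_inv <- chol2inv(chx)
  P <- Vinv - t(XtVinv) %*% XtVinvX_inv %*% XtVinv
  Py <- drop(P %*% spec$y)
  p <- ncol(spec$X)
  # Harville's restricted likelihood: the + log|X'X|/2 term makes ll
  # invariant to the fixed-effect parameterization (it is constant in theta)
  ldXtX <- 2 * sum(log(diag(chol(crossprod(spec$X)))))
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) - ldXtX +
                  sum(spec$y * Py) + (n - p) * log(2 * pi))
  list(R = R, P = P, Py = Py, ll = ll,
       Vinv = Vinv, XtVinvX_inv = XtVinvX_inv, XtVinv = XtVinv)
}

#' Restricted log-likelihood of the spatial mixed model
#'
#' Evaluates the REML log-likelihood
#' `-1/2 [log|V| + log|X'V^-1 X| + y'Py] - (n - p)/2 log(2*pi)` with
#' `V = Vb Z1 Z1' + Vg Z2 Z2' + Ve R` and
#' `R = AR1(rho_row) (x) AR1(rho_col)` over the occupied plots. Invariant to
#' the fixed-effect parameterization and to constant shifts of `y`.
#'
#' @param spec An [build_mme()] object.
#' @param theta A list with `Vb`, `Vg`, `Ve`, `rho_row`, `rho_col` (`Vb`
#'   ignored when the model has no block term).
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(spec, theta) {
  stopifnot(inherits(spec, "htp_mme"))
  theta <- .complete_theta(theta)
  core <- .mme_core(spec, theta)
  if (is.null(core)) abort("V is numerically singular at this theta.")
  core$ll
}

.complete_theta <- function(theta) {
  defaults <- list(Vb = 0, Vg = 0, Ve = 1, rho_row = 0, rho_col = 0)
  theta <- modifyList(defaults, theta[!vapply(theta, is.null, logical(1))])
  for (v in c("Vb", "Vg", "Ve")) check_scalar(theta[[v]], v, lower = 0)
  check_scalar(theta$rho_row, "rho_row", -1, 1, strict = TRUE)
  check_scalar(theta$rho_col, "rho_col", -1, 1, strict = TRUE)
  theta
}

# pack/unpack the free parameter vector
.theta_names <- function(spec, fix_rho) {
  nm <- c(if (!is.null(spec$Z1)) "Vb", "Vg", "Ve")
  if (is.null(fix_rho)) nm <- c(nm, "rho_row", "rho_col")
  nm
}

#' Fit the spatial mixed model by Average-Information REML
#'
#' Maximizes the restricted log-likelihood over the variance components
#' `(Vb, Vg, Ve)` and the residual AR1 correlations `(rho_row, rho_col)`
#' using Average-Information (AI) updates with step halving, box
#' constraints (variances floored at `1e-8 * var(y)`, `|rho| <= 0.99`) and a
#' derivative-free Nelder-Mead fallback on the transformed scale
#' (log-variances, atanh-correlations) whenever an AI step cannot improve
#' the likelihood. At the optimum, fixed effects, family BLUPs and their
#' prediction-error (co)variance are obtained from the mixed-model
#' equations, and the Cullis broad-sense heritability
#' `H = 1 - mean pairwise PEV / (2 Vg)` is reported (possibly negative).
#'
#' @param data Either an [build_mme()] object or a per-plot data frame (in
#'   which case `trait` is required).
#' @param trait Trait column name (when `data` is a data frame).
#' @param init Optional named list of starting values; defaults to
#'   `Vb = Vg = Ve = var(y)/3`, `rho = 0`.
#' @param fix_rho Optional length-2 numeric `c(rho_row, rho_col)` to hold the
#'   correlations fixed instead of estimating them.
#' @param include_blocks Passed to [build_mme()] when building the design.
#' @param max_iter Maximum AI iterations.
#' @param tol_loglik,tol_param Convergence tolerances on the log-likelihood
#'   change and the relative parameter change.
#' @param pev `"pairwise"` (default; mean variance of BLUP differences, the
#'   Cullis form) or `"diagonal"` (mean diagonal PEV) for the heritability
#'   denominator's numerator.
#' @return An object of class `htp_reml`: a list with `theta` (the variance
#'   components and correlations), `beta`, `blup_block`, `blup_family`,
#'   `PEV_g`, `mean_pairwise_pev`, `H`, `loglik`, `converged`, `iterations`,
#'   `trace`, plus the design `spec`.
#' @seealso [cullis_H()], [genetic_correlation()], [tidy.htp_reml()],
#'   [glance.htp_reml()]
#' @examples
#' lay <- make_layout(seed = 1)
#' truth <- simulate_trial(lay, genetic_params(), seed = 2)
#' fit <- reml_fit(truth, trait = "true_tdmy")
#' glance(fit)
#' @export
reml_fit <- function(data, trait = NULL, init = NULL, fix_rho = NULL,
                     include_blocks = TRUE, max_iter = 100L,
                     tol_loglik = 1e-6, tol_param = 1e-4,
                     pev = c("pairwise", "diagonal")) {
  pev <- match.arg(pev)
  spec <- if (inherits(data, "htp_mme")) {
    data
  } else {
    if (is.null(trait)) abort("`trait` is required when `data` is a data frame.")
    build_mme(data, trait, include_blocks = include_blocks)
  }
  if (!is.null(fix_rho)) {
    stopifnot(length(fix_rho) == 2L, all(abs(fix_rho) < 1))
  }
  vy <- var(spec$y)
  if (!is.finite(vy) || vy <= 0) abort("Trait has no variance; nothing to fit.")
  floor_v <- 1e-8 * vy
  has_b <- !is.null(spec$Z1)

  theta <- list(
    Vb = if (has_b) vy / 3 else 0,
    Vg = vy / 3, Ve = vy / 3,
    rho_row = if (is.null(fix_rho)) 0 else fix_rho[1],
    rho_col = if (is.null(fix_rho)) 0 else fix_rho[2]
  )
  if (!is.null(init)) theta <- modifyList(theta, init)
  est_rho <- is.null(fix_rho)
  free <- .theta_names(spec, fix_rho)

  clamp <- function(th) {
    for (v in intersect(c("Vb", "Vg", "Ve"), free)) {
      th[[v]] <- max(th[[v]], floor_v)
    }
    th$rho_row <- max(min(th$rho_row, 0.99), -0.99)
    th$rho_col <- max(min(th$rho_col, 0.99), -0.99)
    th
  }
  theta <- clamp(theta)

  dR_mats <- function(th) {
    dr <- abs(outer(spec$rows, spec$rows, "-"))
    dc <- abs(outer(spec$cols, spec$cols, "-"))
    list(
      drow = ifelse(dr == 0, 0, dr * th$rho_row^(dr - 1)) * th$rho_col^dc,
      dcol = th$rho_row^dr * ifelse(dc == 0, 0, dc * th$rho_col^(dc - 1))
    )
  }
  Z1Z1 <- if (has_b) tcrossprod(spec$Z1) else NULL
  Z2Z2 <- tcrossprod(spec$Z2)

  core <- .mme_core(spec, theta)
  if (is.null(core)) abort("Likelihood undefined at the starting values.")
  trace <- core$ll
  converged <- FALSE
  used_fallback <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    # derivative matrices of V w.r.t. each free parameter
    Vdots <- list()
    if (has_b) Vdots$Vb <- Z1Z1
    Vdots$Vg <- Z2Z2
    Vdots$Ve <- core$R
    if (est_rho) {
      dR <- dR_mats(theta)
      Vdots$rho_row <- theta$Ve * dR$drow
      Vdots$rho_col <- theta$Ve * dR$dcol
    }
    Vdots <- Vdots[free]

    u <- lapply(Vdots, function(D) drop(D %*% core$Py))
    w <- lapply(u, function(ui) drop(core$P %*% ui))
    score <- vapply(seq_along(free), function(i) {
      -0.5 * (sum(core$P * Vdots[[i]]) - sum(core$Py * u[[i]]))
    }, numeric(1))
    AI <- matrix(0, length(free), length(free))
    for (i in seq_along(free)) {
      for (j in i:length(free)) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(u[[i]] * w[[j]])
      }
    }

    # solve the AI system after symmetric diagonal scaling: variance and
    # correlation parameters live on wildly different scales
    delta <- tryCatch({
      d <- sqrt(pmax(diag(AI), .Machine$double.xmin))
      As <- AI / tcrossprod(d)
      diag(As) <- diag(As) + 1e-10
      solve(As, score / d) / d
    }, error = function(e) NULL)
    improved <- FALSE
    if (!is.null(delta) && all(is.finite(delta))) {
      step <- 1
      for (h in 1:12) {
        cand <- theta
        for (i in seq_along(free)) {
          cand[[free[i]]] <- cand[[free[i]]] + step * delta[i]
        }
        cand <- clamp(cand)
        cand_core <- .mme_core(spec, cand)
        if (!is.null(cand_core) && is.finite(cand_core$ll) &&
            cand_core$ll >= core$ll - 1e-10) {
          dll <- cand_core$ll - core$ll
          rel <- max(abs(
            unlist(cand[free]) - unlist(theta[free])
          ) / pmax(abs(unlist(theta[free])), 1e-8))
          theta <- cand
          core <- cand_core
          trace <- c(trace, core$ll)
          improved <- TRUE
          if (dll < tol_loglik && rel < tol_param) converged <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (converged) break
    if (!improved) {
      # AI step cannot improve: finish with a derivative-free search
      used_fallback <- TRUE
      nm <- .reml_nm(spec, theta, free, floor_v, est_rho)
      if (nm$ll > core$ll + 1e-10) {
        theta <- nm$theta
        core <- .mme_core(spec, theta)
        trace <- c(trace, core$ll)
      }
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("REML did not converge within `max_iter` iterations.")
  }

  # solutions at the optimum
  beta <- drop(core$XtVinvX_inv %*% (core$XtVinv %*% spec$y))
  names(beta) <- colnames(spec$X)
  blup_block <- if (has_b) {
    stats::setNames(theta$Vb * drop(crossprod(spec$Z1, core$Py)),
                    colnames(spec$Z1))
  } else NULL
  g_hat <- stats::setNames(theta$Vg * drop(crossprod(spec$Z2, core$Py)),
                           spec$families)
  PZ2 <- core$P %*% spec$Z2
  PEV_g <- theta$Vg * diag(length(spec$families)) -
    theta$Vg^2 * crossprod(spec$Z2, PZ2)
  dimnames(PEV_g) <- list(spec$families, spec$families)

  m <- length(spec$families)
  mpev <- if (pev == "pairwise") {
    2 * (m * sum(diag(PEV_g)) - sum(PEV_g)) / (m * (m - 1))
  } else {
    mean(diag(PEV_g))
  }
  # a Vg this close to its floor is a boundary solution: no usable
  # genetic variance was found
  vg_floored <- theta$Vg <= 100 * floor_v
  H <- if (vg_floored) NA_real_ else 1 - mpev / (2 * theta$Vg)
  if (vg_floored) {
    warn("Vg is at its lower bound; heritability is undefined.")
  }

  structure(
    list(
      theta = theta[c(if (has_b) "Vb", "Vg", "Ve", "rho_row", "rho_col")],
      beta = beta, blup_block = blup_block, blup_family = g_hat,
      PEV_g = PEV_g, mean_pairwise_pev = mpev, pev_form = pev,
      H = H, vg_floored = vg_floored,
      loglik = core$ll, converged = converged, iterations = iter,
      used_fallback = used_fallback, trace = trace,
      spec = spec, fix_rho = fix_rho
    ),
    class = "htp_reml"
  )
}

# Nelder-Mead on transformed scale: log variances, atanh(rho/0.99)
.reml_nm <- function(spec, theta, free, floor_v, est_rho) {
  to_par <- function(th) {
    p <- numeric(0)
    for (v in intersect(c("Vb", "Vg", "Ve"), free)) p <- c(p, log(max(th[[v]], floor_v)))
    if (est_rho) p <- c(p, atanh(th$rho_row / 0.99), atanh(th$rho_col / 0.99))
    p
  }
  from_par <- function(p, th) {
    k <- 0
    for (v in intersect(c("Vb", "Vg", "Ve"), free)) {
      k <- k + 1
      th[[v]] <- exp(p[k])
    }
    if (est_rho) {
      th$rho_row <- 0.99 * tanh(p[k + 1])
      th$rho_col <- 0.99 * tanh(p[k + 2])
    }
    th
  }
  obj <- function(p) {
    th <- from_par(p, theta)
    core <- .mme_core(spec, th)
    if (is.null(core) || !is.finite(core$ll)) return(1e10)
    -core$ll
  }
  opt <- optim(to_par(theta), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(theta = from_par(opt$par, theta), ll = -opt$value)
}

#' Cullis broad-sense heritability from a fitted model
#'
#' `H = 1 - PEV / (2 Vg)` where `PEV` is the mean variance of the difference
#' between pairs of family BLUPs. `H` can be negative when the prediction
#' error dominates the genetic variance; negative values are reported, not
#' clamped.
#'
#' @param fit An [reml_fit()] object, or a list with `mean_pairwise_pev` and
#'   `theta$Vg`.
#' @return The heritability (scalar, possibly negative; `NA` when `Vg` is at
#'   its lower bound).
#' @export
cullis_H <- function(fit) {
  vg <- fit$theta$Vg
  if (is.null(vg) || !is.finite(vg) || vg <= 0 || isTRUE(fit$vg_floored)) {
    warn("Vg is not positive; heritability undefined.")
    return(NA_real_)
  }
  1 - fit$mean_pairwise_pev / (2 * vg)
}

#' Approximate genetic correlation between two fitted traits
#'
#' The Pearson correlation between the family BLUP vectors of two
#' single-trait fits on the same families (e.g. a field-measured trait and
#' its image-predicted HTP counterpart).
#'
#' @param fit_real,fit_htp [reml_fit()] objects sharing the same family set.
#' @return Correlation in `[-1, 1]`.
#' @export
genetic_correlation <- function(fit_real, fit_htp) {
  g1 <- fit_real$blup_family
  g2 <- fit_htp$blup_family
  if (!identical(names(g1), names(g2))) {
    common <- intersect(names(g1), names(g2))
    if (length(common) != length(g1) || length(common) != length(g2)) {
      abort("The two fits do not share the same family set.")
    }
    g2 <- g2[names(g1)]
  }
  if (sd(g1) == 0 || sd(g2) == 0) {
    abort("A BLUP vector has zero variance; the correlation is undefined.")
  }
  cor(g1, g2)
}

#' @export
print.htp_reml <- function(x, ...) {
  cat("<htp_reml>", x$spec$trait, "\n")
  cat("  components:",
      paste(sprintf("%s=%.4g", names(x$theta), unlist(x$theta)), collapse = ", "),
      "\n")
  cat(sprintf("  H = %.3f   logLik = %.3f   converged = %s (%d iter%s)\n",
              x$H, x$loglik, x$converged, x$iterations,
              if (x$used_fallback) ", fallback" else ""))
  invisible(x)
}

#' Tidy family BLUPs from a REML fit
#'
#' @param x An [reml_fit()] object.
#' @param ... Unused.
#' @return A tibble with `family`, `blup`, `pev` (diagonal prediction error
#'   variance).
#' @export
tidy.htp_reml <- function(x, ...) {
  tibble(
    family = names(x$blup_family),
    blup = unname(x$blup_family),
    pev = unname(diag(x$PEV_g))
  )
}

#' One-row summary of a REML fit
#'
#' @param x An [reml_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble with the variance components, correlations,
#'   heritability and fit diagnostics.
#' @export
glance.htp_reml <- function(x, ...) {
  tibble(
    trait = x$spec$trait,
    Vb = x$theta$Vb %||% NA_real_,
    Vg = x$theta$Vg,
    Ve = x$theta$Ve,
    rho_row = x$theta$rho_row,
    rho_col = x$theta$rho_col,
    mean_pairwise_pev = x$mean_pairwise_pev,
    H = x$H,
    loglik = x$loglik,
    converged = x$converged,
    iterations = x$iterations,
    n = x$spec$n
  )
}

#' Turn a fitted object into a tidy tibble
#'
#' Generic for per-component summaries of fitted objects (family BLUPs,
#' out-of-fold predictions); see the class-specific methods.
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' Generic for whole-fit summaries (variance components, heritability,
#' out-of-fold accuracy); see the class-specific methods.
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")
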