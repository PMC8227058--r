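#' Regression evaluation metrics
#'
#' Mean absolute error, root mean squared error (both in the units of the
#' trait) and the Pearson correlation between observed and predicted
#' values. The correlation uses the standard product-moment form with the
#' square root over the denominator product; when either vector has zero
#' variance `r` is undefined and returned as `NA` with a warning.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return A one-row tibble with `n`, `mae`, `rmse`, `r`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 3, 2))
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("`y` and `yhat` must have equal length.")
  if (length(y) < 1L) abort("Empty input.")
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    abort("Inputs must be finite.")
  }
  err <- y - yhat
  r <- if (length(y) >= 2L && sd(y) > 0 && sd(yhat) > 0) {
    cor(y, yhat)
  } else {
    warn("Zero variance in `y` or `yhat`; Pearson r undefined.")
    NA_real_
  }
  tibble(
    n = length(y),
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    r = r
  )
}

#' Aggregate per-fold metrics into mean and spread
#'
#' Unweighted mean and sample standard deviation (denominator `n - 1`)
#' across cross-validation folds, mirroring the conventional
#' `mean +/- sd` reporting of per-fold results. With a single fold the sd is
#' undefined and reported `NA`.
#'
#' @param sets A data frame of per-fold metrics (e.g. rows of
#'   [regression_metrics()] output, one per fold).
#' @param metrics Columns to aggregate; defaults to all numeric columns
#'   except `n` and `fold`.
#' @return A tibble with `metric`, `mean`, `sd`, `folds`.
#' @examples
#' aggregate_folds(data.frame(mae = c(200, 300), rmse = c(250, 350)))
#' @export
aggregate_folds <- function(sets, metrics = NULL) {
  if (is.null(sets) || nrow(sets) < 1L) abort("Need at least one fold.")
  if (is.null(metrics)) {
    metrics <- setdiff(
      names(sets)[vapply(sets, is.numeric, logical(1))],
      c("n", "fold")
    )
  }
  purrr::map_dfr(metrics, function(m) {
    x <- sets[[m]]
    tibble(
      metric = m,
      mean = mean(x),
      sd = if (length(x) >= 2L) sd(x) else NA_real_,
      folds = length(x)
    )
  })
}

#' Histogram intersection between observed and predicted distributions
#'
#' Bins both vectors on shared equal-width bin edges and returns
#' `sum_k min(p_k, q_k)` where `p` and `q` are the per-bin proportions of
#' the two samples (each summing to 1); 1 means identical binned
#' distributions, 0 disjoint supports. By default the edges span the union
#' range of both vectors, which makes the measure symmetric; `edges =
#' "real_only"` spans only the range of `y` (values outside fall into no
#' bin).
#'
#' @param y Observed values.
#' @param yhat Predicted values (length may differ from `y`).
#' @param n_bins Number of bins (>= 1), conventionally 20.
#' @param edges `"union"` (default) or `"real_only"`.
#' @return Intersection proportion in `[0, 1]`.
#' @examples
#' histogram_intersection(rnorm(500), rnorm(500), n_bins = 20)
#' @export
histogram_intersection <- function(y, yhat, n_bins = 20,
                                   edges = c("union", "real_only")) {
  edges <- match.arg(edges)
  if (!length(y) || !length(yhat)) abort("Inputs must be non-empty.")
  if (n_bins < 1L) abort("`n_bins` must be >= 1.")
  rng <- if (edges == "union") range(c(y, yhat)) else range(y)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin_props <- function(x) {
    idx <- findInterval(x, brk, rightmost.closed = TRUE)
    idx <- idx[idx >= 1L & idx <= n_bins]
    tabulate(idx, nbins = n_bins) / length(x)
  }
  sum(pmin(bin_props(y), bin_props(yhat)))
}

#' Choose a histogram bin count by the elbow rule
#'
#' Scores each candidate bin count by the within-bin sum of squares of `y`
#' around its bin means (equal-width bins): more bins always represent the
#' distribution better, but with diminishing returns. The elbow is the
#' first candidate whose relative improvement to the next candidate falls
#' below `tol`; past the elbow, additional bins no longer add meaningful
#' representativeness. Scanning low-to-high makes the choice stable when
#' the candidate range is extended upwards.
#'
#' @param y Data vector.
#' @param candidates Increasing integer candidates (default `5:40`).
#' @param tol Relative-improvement threshold (default 0.1).
#' @return The selected bin count. A constant vector returns 1; candidates
#'   above the number of distinct values are capped with a warning.
#' @examples
#' elbow_bins(runif(5000))
#' @export
elbow_bins <- function(y, candidates = 5:40, tol = 0.1) {
  if (!length(candidates)) abort("`candidates` must be non-empty.")
  candidates <- sort(unique(as.integer(candidates)))
  n_distinct <- length(unique(y))
  if (n_distinct <= 1L) return(1L)
  if (max(candidates) > n_distinct) {
    warn("Capping candidate bin counts at the number of distinct values.")
    candidates <- candidates[candidates <= n_distinct]
    if (!length(candidates)) return(n_distinct)
  }
  wss <- function(k) {
    brk <- seq(min(y), max(y), length.out = k + 1L)
    idx <- findInterval(y, brk, rightmost.closed = TRUE)
    means <- tapply(y, idx, mean)
    sum((y - means[as.character(idx)])^2)
  }
  scores <- vapply(candidates, wss, numeric(1))
  if (length(candidates) == 1L) return(candidates)
  for (k in seq_len(length(candidates) - 1L)) {
    if (scores[k] <= 0) return(candidates[k])
    rel <- (scores[k] - scores[k + 1L]) / scores[k]
    if (rel < tol) return(candidates[k])
  }
  candidates[length(candidates)]
}
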