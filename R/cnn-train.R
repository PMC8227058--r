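#' Training configuration for convolutional regression
#'
#' Adam with a fixed learning rate and mean-squared-error loss, matching
#' the conventional settings for small image-regression networks:
#' `learning_rate = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`,
#' `adam_eps = 1e-8`, up to 500 epochs with early stopping evaluated every
#' `early_stop_interval` epochs on a held-out slice of the training data.
#' Targets are standardized internally during optimization and predictions
#' are returned on the original scale.
#'
#' @param learning_rate Adam step size (> 0 allowed to be 0 for a null
#'   step).
#' @param beta1,beta2,adam_eps Adam moment constants.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (>= 1).
#' @param early_stop_interval Epochs between early-stopping evaluations.
#' @param val_fraction Fraction of the training items held out for early
#'   stopping (grouped by plot so augmented copies stay together).
#' @param seed Seed for shuffling, dropout and initialization at training
#'   time.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         epochs = 500, batch_size = 256,
                         early_stop_interval = 100,
                         val_fraction = 0.1,
                         seed = 1L) {
  check_scalar(learning_rate, "learning_rate", lower = 0)
  check_scalar(batch_size, "batch_size", lower = 1)
  check_scalar(epochs, "epochs", lower = 1)
  check_scalar(early_stop_interval, "early_stop_interval", lower = 1)
  check_scalar(val_fraction, "val_fraction", lower = 0, upper = 0.5)
  structure(
    list(
      learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
      adam_eps = adam_eps, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      early_stop_interval = as.integer(early_stop_interval),
      val_fraction = val_fraction, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Axis-flip augmentation of a plot image
#'
#' Returns the four axis-flip variants of an image (identity, left-right,
#' up-down, both). Flips permute pixels, so per-channel histograms are
#' unchanged; applying the same flip twice recovers the original.
#'
#' @param img An `H x W x 3` array.
#' @return A list of four arrays.
#' @examples
#' length(augment_flips(array(runif(48), c(4, 4, 3))))
#' @export
augment_flips <- function(img) {
  stopifnot(length(dim(img)) == 3L)
  h <- dim(img)[1]
  w <- dim(img)[2]
  list(
    img,
    img[, w:1, , drop = FALSE],
    img[h:1, , , drop = FALSE],
    img[h:1, w:1, , drop = FALSE]
  )
}

# stack a list of H x W x C images into an H x W x C x N array
.stack_images <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

# ---- Adam --------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- switch(l$type, conv = , fc = c("W", "b"), bn = c("gamma", "beta"), NULL)
    if (is.null(nm)) return(NULL)
    st <- list()
    for (p in nm) {
      st[[p]] <- list(m = numeric(length(l[[p]])), v = numeric(length(l[[p]])))
    }
    st
  })
}

.adam_update <- function(layers, grads, state, cfg, t) {
  lr <- cfg$learning_rate
  b1 <- cfg$beta1
  b2 <- cfg$beta2
  eps <- cfg$adam_eps
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    if (l$type == "bn") {
      # running statistics (not Adam-updated)
      l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * g$batch_mean
      l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * g$batch_var
      pars <- c("gamma", "beta")
    } else {
      pars <- c("W", "b")
    }
    for (p in pars) {
      gp <- g[[p]]
      if (is.null(gp)) next
      gv <- as.vector(gp)
      st <- state[[i]][[p]]
      st$m <- b1 * st$m + (1 - b1) * gv
      st$v <- b2 * st$v + (1 - b2) * gv^2
      l[[p]] <- l[[p]] - lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
      state[[i]][[p]] <- st
    }
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}

# ---- training ----------------------------------------------------------

#' Train a regressor on one set of images
#'
#' Minimizes the mean squared error with Adam. A grouped slice of the
#' training items (`val_fraction`) is held out; every
#' `early_stop_interval` epochs its MSE is evaluated and training stops —
#' restoring the best weights — once it deteriorates. Targets are
#' standardized internally; the fitted centering is stored in the model so
#' predictions come back in trait units.
#'
#' @param model An [build_regressor()] object.
#' @param images List of `H x W x 3` arrays.
#' @param targets Numeric targets, one per image.
#' @param cfg A [train_config()].
#' @param groups Optional grouping vector (same length as `images`):
#'   augmented copies of one plot share a group so the early-stopping slice
#'   never splits a plot.
#' @return The trained model, with attributes `loss_trace` (per-epoch
#'   training MSE, trait units squared) and `val_trace`.
#' @export
train_fold <- function(model, images, targets, cfg = train_config(),
                       groups = NULL) {
  stopifnot(inherits(model, "htp_regressor"), length(images) == length(targets))
  if (any(!is.finite(targets))) abort("Targets must be finite.")
  n <- length(images)
  if (n < 2L) abort("Need at least two training images.")
  set.seed(cfg$seed)
  groups <- groups %||% seq_len(n)

  ctr <- mean(targets)
  scl <- sd(targets)
  if (!is.finite(scl) || scl == 0) scl <- 1
  model$target_center <- ctr
  model$target_scale <- scl
  z <- (targets - ctr) / scl

  # grouped validation slice for early stopping
  ug <- unique(groups)
  n_val_g <- floor(cfg$val_fraction * length(ug))
  val_idx <- integer(0)
  if (n_val_g >= 1L && cfg$epochs > cfg$early_stop_interval) {
    val_g <- sample(ug, n_val_g)
    val_idx <- which(groups %in% val_g)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  x_all <- .stack_images(images)
  states <- lapply(model$streams, .adam_init)
  head_state <- .adam_init(model$head)

  best <- list(val = Inf, model = NULL)
  trace <- numeric(0)
  val_trace <- numeric(0)
  t <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    ep_n <- 0L
    for (bi in batches) {
      xb <- x_all[, , , bi, drop = FALSE]
      zb <- z[bi]
      fw <- .model_forward(model, xb, training = TRUE)
      pred <- fw$out
      if (any(!is.finite(pred))) {
        abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch))
      }
      err <- pred - zb
      ep_loss <- ep_loss + sum(err^2)
      ep_n <- ep_n + length(bi)
      dpred <- matrix(2 * err / length(bi), nrow = 1)

      hb <- .stack_backward(model$head, fw$head_caches, dpred)
      t <- t + 1L
      upd <- .adam_update(model$head, hb$grads, head_state, cfg, t)
      model$head <- upd$layers
      head_state <- upd$state

      dfeat <- hb$dx
      off <- 0L
      for (s in seq_along(model$streams)) {
        rows <- fw$stream_rows[s]
        ds <- dfeat[(off + 1L):(off + rows), , drop = FALSE]
        off <- off + rows
        sb <- .stack_backward(model$streams[[s]], fw$stream_caches[[s]], ds,
                              need_input_grad = FALSE)
        upd <- .adam_update(model$streams[[s]], sb$grads, states[[s]], cfg, t)
        model$streams[[s]] <- upd$layers
        states[[s]] <- upd$state
      }
    }
    trace <- c(trace, scl^2 * ep_loss / ep_n)

    if (length(val_idx) && epoch %% cfg$early_stop_interval == 0L) {
      vp <- .predict_array(model, x_all[, , , val_idx, drop = FALSE])
      vmse <- mean((vp - z[val_idx])^2)
      val_trace <- c(val_trace, scl^2 * vmse)
      if (vmse < best$val) {
        best$val <- vmse
        best$model <- model
      } else {
        model <- best$model
        break
      }
    }
  }
  attr(model, "loss_trace") <- trace
  attr(model, "val_trace") <- val_trace
  model
}

# predictions on the standardized scale from a stacked array
.predict_array <- function(model, x) {
  .model_forward(model, x, training = FALSE)$out
}

#' Predict from a trained regressor
#'
#' @param object A trained [build_regressor()] model.
#' @param images List of `H x W x 3` arrays (or a data frame with an
#'   `image` list-column).
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Numeric predictions in trait units.
#' @export
predict.htp_regressor <- function(object, images, batch_size = 64, ...) {
  if (is.data.frame(images)) images <- images$image
  n <- length(images)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- .stack_images(images[idx])
    out[idx] <- .predict_array(object, x)
  }
  out * object$target_scale + object$target_center
}

#' Out-of-fold HTP trait by k-fold cross-validated image regression
#'
#' Randomly partitions the plots into `k` near-equal folds; for each fold a
#' fresh network is trained on the remaining folds (with axis-flip
#' augmentation of the training images only) and predicts the held-out
#' plots. The concatenated out-of-fold predictions form the HTP trait used
#' downstream in the genetic model. Augmented copies of a plot never enter
#' the fold in which that plot is tested, because augmentation is applied
#' after the split, to training data only.
#'
#' @param data A tibble with `plot_id`, list-column `image`, and the target
#'   column.
#' @param target Name of the target column (e.g. `"tdmy_ha"`).
#' @param spec An [arch_spec()].
#' @param cfg A [train_config()].
#' @param k Number of folds (default 10; must not exceed the plot count).
#' @param seed Seed controlling the fold partition and per-fold training.
#' @param augment Apply flip augmentation to training folds.
#' @return An object of class `htp_cv`: list with `predictions`
#'   (tibble `plot_id`, `fold`, `y`, `yhat`), `fold_metrics`, `summary`
#'   (mean +/- sd across folds), `arch`, `target`.
#' @export
crossval_predict <- function(data, target, spec = arch_spec("macnn"),
                             cfg = train_config(), k = 10, seed = 1L,
                             augment = TRUE) {
  stopifnot(is.data.frame(data), "image" %in% names(data),
            target %in% names(data))
  n <- nrow(data)
  if (k > n) abort(sprintf("k = %d folds exceed the %d available plots.", k, n))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))

  preds <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (augment) {
      tr_imgs <- purrr::flatten(purrr::map(data$image[tr], augment_flips))
      tr_targets <- rep(data[[target]][tr], each = 4L)
      tr_groups <- rep(tr, each = 4L)
    } else {
      tr_imgs <- data$image[tr]
      tr_targets <- data[[target]][tr]
      tr_groups <- tr
    }
    model <- build_regressor(spec, input_px = dim(data$image[[1]])[1],
                             in_channels = dim(data$image[[1]])[3],
                             seed = seed + f)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- train_fold(model, tr_imgs, tr_targets, fold_cfg,
                        groups = tr_groups)
    yhat <- predict(model, data$image[te])
    preds[[f]] <- tibble(
      plot_id = data$plot_id[te], fold = f,
      y = data[[target]][te], yhat = yhat
    )
    fold_metrics[[f]] <- dplyr::mutate(
      regression_metrics(data[[target]][te], yhat),
      fold = f, .before = 1
    )
  }
  predictions <- dplyr::arrange(dplyr::bind_rows(preds), .data$plot_id)
  fold_metrics <- dplyr::bind_rows(fold_metrics)
  structure(
    list(
      predictions = predictions,
      fold_metrics = fold_metrics,
      summary = aggregate_folds(fold_metrics),
      arch = spec$name, target = target, k = k, seed = seed
    ),
    class = "htp_cv"
  )
}

#' @export
print.htp_cv <- function(x, ...) {
  cat(sprintf("<htp_cv> %s on %s, %d folds, %d plots\n",
              x$arch, x$target, x$k, nrow(x$predictions)))
  ov <- regression_metrics(x$predictions$y, x$predictions$yhat)
  cat(sprintf("  out-of-fold: mae %.1f, rmse %.1f, r %.3f\n",
              ov$mae, ov$rmse, ov$r))
  invisible(x)
}

#' Tidy out-of-fold predictions
#'
#' @param x An [crossval_predict()] result.
#' @param ... Unused.
#' @return The predictions tibble (`plot_id`, `fold`, `y`, `yhat`).
#' @export
tidy.htp_cv <- function(x, ...) x$predictions

#' One-row out-of-fold performance summary
#'
#' @param x An [crossval_predict()] result.
#' @param ... Unused.
#' @return A one-row tibble with overall out-of-fold `mae`, `rmse`, `r` and
#'   the across-fold mean and sd of each.
#' @export
glance.htp_cv <- function(x, ...) {
  ov <- regression_metrics(x$predictions$y, x$predictions$yhat)
  s <- x$summary
  wide <- stats::setNames(
    as.list(c(s$mean, s$sd)),
    c(paste0(s$metric, "_fold_mean"), paste0(s$metric, "_fold_sd"))
  )
  dplyr::bind_cols(
    tibble(arch = x$arch, target = x$target, k = x$k,
           n = ov$n, mae = ov$mae, rmse = ov$rmse, r = ov$r),
    as_tibble(wide)
  )
}
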