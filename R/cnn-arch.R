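#' Architecture specification for a convolutional regressor
#'
#' Describes a small image-regression network as a stack of convolution
#' blocks (3x3 filters unless stated, 'same' padding, optional batch
#' normalization, ReLU, optional average/max pooling) followed by fully
#' connected layers with dropout and a single linear output unit.
#'
#' Built-in presets:
#' * `"macnn"` — four convolution blocks with batch normalization and
#'   average pooling, one fully connected layer with dropout. Default
#'   widths (8/16/32/64 filters) keep the network CPU-friendly; widen
#'   `conv_blocks`/`fc_sizes` to reach the million-parameter regime of its
#'   published namesake.
#' * `"lfcnn"` — a late-fusion multi-stream network: `n_streams`
#'   independent streams of one 8-filter convolution, global max pooling, a
#'   16-unit ReLU layer and a single ReLU neuron; the stream outputs are
#'   concatenated and fed to two final fully connected layers.
#' * `"alexnet"` — the classic five-convolution / three-FC stack adapted to
#'   single-output regression (build-only here; far too heavy to train
#'   routinely on a CPU).
#' * `"custom"` — exactly what you pass in `conv_blocks` / `fc_sizes`.
#'
#' @param name Preset name.
#' @param conv_blocks A list of blocks, each a list with `filters`, and
#'   optionally `kernel` (default 3), `stride` (1), `pad` (`kernel %/% 2`),
#'   `pool` (pooling size, 0 = none), `pool_type` (`"avg"`/`"max"`),
#'   `batch_norm` (logical). Overrides the preset.
#' @param fc_sizes Integer vector of hidden fully connected widths.
#' @param dropout_rate Dropout probability applied before each hidden FC
#'   layer.
#' @param n_streams Stream count (`"lfcnn"` only).
#' @return A list of class `arch_spec`.
#' @examples
#' arch_spec("macnn")
#' @export
arch_spec <- function(name = c("macnn", "lfcnn", "alexnet", "custom"),
                      conv_blocks = NULL, fc_sizes = NULL,
                      dropout_rate = NULL, n_streams = 5) {
  name <- match.arg(name)
  block <- function(filters, kernel = 3, stride = 1, pad = kernel %/% 2,
                    pool = 0, pool_type = "avg", batch_norm = FALSE) {
    list(filters = filters, kernel = kernel, stride = stride, pad = pad,
         pool = pool, pool_type = pool_type, batch_norm = batch_norm)
  }
  preset <- switch(name,
    macnn = list(
      conv_blocks = list(
        block(8, pool = 4, batch_norm = TRUE),
        block(16, pool = 2, batch_norm = TRUE),
        block(32, pool = 2, batch_norm = TRUE),
        block(64, pool = 2, batch_norm = TRUE)
      ),
      fc_sizes = 64, dropout_rate = 0.5
    ),
    lfcnn = list(
      conv_blocks = list(block(8, pool = -1, pool_type = "max")), # -1: global
      fc_sizes = 8, dropout_rate = 0
    ),
    alexnet = list(
      conv_blocks = list(
        block(96, kernel = 11, stride = 4, pad = 2, pool = 3, pool_type = "max"),
        block(256, kernel = 5, pool = 3, pool_type = "max"),
        block(384),
        block(384),
        block(256, pool = 3, pool_type = "max")
      ),
      fc_sizes = c(4096, 4096), dropout_rate = 0.5
    ),
    custom = list(conv_blocks = NULL, fc_sizes = integer(0), dropout_rate = 0)
  )
  spec <- list(
    name = name,
    conv_blocks = conv_blocks %||% preset$conv_blocks,
    fc_sizes = fc_sizes %||% preset$fc_sizes,
    dropout_rate = dropout_rate %||% preset$dropout_rate,
    n_streams = if (name == "lfcnn") n_streams else 1L
  )
  if (is.null(spec$conv_blocks) || length(spec$conv_blocks) < 1L) {
    abort("An architecture needs at least one convolution block.")
  }
  spec$conv_blocks <- lapply(spec$conv_blocks, function(b) do.call(block, b))
  check_scalar(spec$dropout_rate, "dropout_rate", lower = 0, upper = 1)
  structure(spec, class = "arch_spec")
}

# ---- layer construction ------------------------------------------------

.he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# Build one conv stack (list of layer objects) and return it with the
# output shape. shape: c(H, W, C) for arrays, single integer for vectors.
.build_stream <- function(blocks, fc_after, dropout_rate, input_px, in_channels,
                          final_relu = FALSE) {
  layers <- list()
  shape <- c(input_px, input_px, in_channels)
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  for (b in blocks) {
    Ho <- (shape[1] + 2 * b$pad - b$kernel) %/% b$stride + 1
    Wo <- (shape[2] + 2 * b$pad - b$kernel) %/% b$stride + 1
    if (Ho < 1 || Wo < 1) {
      abort(sprintf("Input %dx%d too small for a %dx%d convolution.",
                    shape[1], shape[2], b$kernel, b$kernel))
    }
    fan_in <- b$kernel^2 * shape[3]
    add(list(
      type = "conv", k = b$kernel, stride = b$stride, pad = b$pad,
      in_shape = shape,
      W = .he_init(b$filters, fan_in, fan_in), b = numeric(b$filters)
    ))
    shape <- c(Ho, Wo, b$filters)
    if (b$batch_norm) {
      add(list(
        type = "bn", shape = shape,
        gamma = rep(1, b$filters), beta = numeric(b$filters),
        rmean = numeric(b$filters), rvar = rep(1, b$filters),
        momentum = 0.9, eps = 1e-5
      ))
    }
    add(list(type = "relu"))
    pool <- if (b$pool == -1) min(shape[1], shape[2]) else b$pool
    if (pool > 1) {
      Hp <- shape[1] %/% pool
      Wp <- shape[2] %/% pool
      if (Hp < 1 || Wp < 1) {
        abort(sprintf("Feature map %dx%d too small for pool size %d.",
                      shape[1], shape[2], pool))
      }
      add(list(type = "pool", size = pool,
               ptype = if (b$pool_type == "max") 1L else 0L,
               in_shape = shape))
      shape <- c(Hp, Wp, shape[3])
    }
  }
  add(list(type = "flatten", in_shape = shape))
  feat <- prod(shape)
  for (w in fc_after) {
    if (dropout_rate > 0) add(list(type = "dropout", rate = dropout_rate))
    add(list(type = "fc", W = .he_init(w, feat, feat), b = numeric(w)))
    add(list(type = "relu"))
    feat <- w
  }
  if (final_relu) {
    add(list(type = "fc", W = .he_init(1, feat, feat), b = numeric(1)))
    add(list(type = "relu"))
    feat <- 1L
  }
  list(layers = layers, out = feat)
}

#' Build a convolutional regressor
#'
#' Instantiates the network described by an [arch_spec()] for a given input
#' resolution, with He-initialized weights (deterministic per seed) and a
#' single linear output unit.
#'
#' @param spec An [arch_spec()].
#' @param input_px Input image side length in pixels.
#' @param in_channels Input channels (3 for RGB).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `htp_regressor` with elements `streams`
#'   (conv stacks), `head` (fully connected stack ending in the output
#'   unit), `param_count`, `arch`, `input_px`.
#' @examples
#' model <- build_regressor(arch_spec("macnn"), input_px = 64, seed = 1)
#' model$param_count
#' @export
build_regressor <- function(spec, input_px = 64, in_channels = 3, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  set.seed(seed)
  multi <- spec$n_streams > 1L
  streams <- list()
  if (multi) {
    # lfcnn: each stream carries its own FC 16 -> ReLU -> 1 -> ReLU tail
    for (s in seq_len(spec$n_streams)) {
      streams[[s]] <- .build_stream(
        spec$conv_blocks, fc_after = 16, dropout_rate = 0,
        input_px = input_px, in_channels = in_channels, final_relu = TRUE
      )
    }
    feat <- spec$n_streams
    head_fc <- spec$fc_sizes
  } else {
    streams[[1]] <- .build_stream(
      spec$conv_blocks, fc_after = integer(0), dropout_rate = 0,
      input_px = input_px, in_channels = in_channels
    )
    feat <- streams[[1]]$out
    head_fc <- spec$fc_sizes
  }
  head <- list()
  for (w in head_fc) {
    if (spec$dropout_rate > 0) {
      head[[length(head) + 1L]] <- list(type = "dropout", rate = spec$dropout_rate)
    }
    head[[length(head) + 1L]] <- list(type = "fc", W = .he_init(w, feat, feat),
                                      b = numeric(w))
    head[[length(head) + 1L]] <- list(type = "relu")
    feat <- w
  }
  head[[length(head) + 1L]] <- list(type = "fc", W = .he_init(1, feat, feat),
                                    b = numeric(1))

  model <- structure(
    list(
      arch = spec, input_px = input_px, in_channels = in_channels,
      streams = lapply(streams, `[[`, "layers"), head = head,
      target_center = 0, target_scale = 1
    ),
    class = "htp_regressor"
  )
  model$param_count <- count_parameters(model)
  model
}

#' Trainable parameter count of a regressor
#'
#' @param model An [build_regressor()] object.
#' @return Total number of trainable parameters (weights, biases, batch
#'   norm scales and shifts).
#' @export
count_parameters <- function(model) {
  one <- function(layers) {
    sum(vapply(layers, function(l) {
      switch(l$type,
        conv = ,
        fc = length(l$W) + length(l$b),
        bn = length(l$gamma) + length(l$beta),
        0L
      )
    }, numeric(1)))
  }
  sum(vapply(model$streams, one, numeric(1))) + one(model$head)
}

#' @export
print.htp_regressor <- function(x, ...) {
  cat(sprintf(
    "<htp_regressor> %s, input %dpx, %s stream(s), %s parameters\n",
    x$arch$name, x$input_px, length(x$streams),
    format(x$param_count, big.mark = ",")
  ))
  invisible(x)
}

# ---- forward / backward ------------------------------------------------

# x: array H x W x C x N (for conv stacks) or matrix feat x N (FC stacks)
.stack_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      res <- conv_forward_cpp(x, dim(x), l$W, l$b, l$k, l$stride, l$pad)
      caches[[i]] <- list(xin = x, in_dims = dim(x))
      x <- res$out
    } else if (l$type == "bn") {
      if (training) {
        res <- bn_forward_cpp(x, dim(x), l$gamma, l$beta, l$eps)
        caches[[i]] <- list(xhat = res$xhat, invstd = res$invstd,
                            mean = res$mean, var = res$var, dims = dim(x))
        x <- res$out
      } else {
        x <- bn_infer_cpp(x, dim(x), l$gamma, l$beta, l$rmean, l$rvar, l$eps)
      }
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = x > 0)
      x <- x * caches[[i]]$mask
    } else if (l$type == "pool") {
      res <- pool_forward_cpp(x, dim(x), l$size, l$ptype)
      caches[[i]] <- list(idx = res$idx, in_dims = dim(x), out_dims = dim(res$out))
      x <- res$out
    } else if (l$type == "flatten") {
      caches[[i]] <- list(in_dims = dim(x))
      dim(x) <- c(prod(dim(x)[1:3]), dim(x)[4])
    } else if (l$type == "fc") {
      caches[[i]] <- list(xin = x)
      x <- l$W %*% x + l$b
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix(stats::rbinom(length(x), 1, 1 - l$rate) / (1 - l$rate),
                       nrow(x), ncol(x))
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      }
    }
  }
  list(out = x, caches = caches)
}

.stack_backward <- function(layers, caches, dout, need_input_grad = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "conv") {
      res <- conv_backward_cpp(dout, dim(dout), cc$xin, l$W,
                               cc$in_dims, l$k, l$stride, l$pad,
                               need_dx = need_input_grad || i > 1L)
      grads[[i]] <- list(W = res$dW, b = res$db)
      dout <- res$dx
    } else if (l$type == "bn") {
      res <- bn_backward_cpp(dout, cc$xhat, cc$dims, l$gamma, cc$invstd)
      grads[[i]] <- list(gamma = res$dgamma, beta = res$dbeta,
                         batch_mean = cc$mean, batch_var = cc$var)
      dout <- res$dx
    } else if (l$type == "relu") {
      dout <- dout * cc$mask
    } else if (l$type == "pool") {
      dout <- pool_backward_cpp(dout, cc$out_dims, cc$in_dims,
                                l$size, l$ptype, cc$idx)
    } else if (l$type == "flatten") {
      dim(dout) <- cc$in_dims
    } else if (l$type == "fc") {
      grads[[i]] <- list(W = dout %*% t(cc$xin), b = rowSums(dout))
      dout <- crossprod(l$W, dout)
    } else if (l$type == "dropout") {
      if (!is.null(cc)) dout <- dout * cc$mask
    }
  }
  list(grads = grads, dx = dout)
}

# Full model forward; returns predictions (standardized scale) and caches.
.model_forward <- function(model, x, training) {
  souts <- vector("list", length(model$streams))
  scaches <- vector("list", length(model$streams))
  feats <- vector("list", length(model$streams))
  for (s in seq_along(model$streams)) {
    res <- .stack_forward(model$streams[[s]], x, training)
    feats[[s]] <- res$out
    scaches[[s]] <- res$caches
  }
  feat <- if (length(feats) == 1L) feats[[1]] else do.call(rbind, feats)
  hres <- .stack_forward(model$head, feat, training)
  list(out = drop(hres$out), stream_caches = scaches, head_caches = hres$caches,
       stream_rows = vapply(feats, nrow, integer(1)))
}
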