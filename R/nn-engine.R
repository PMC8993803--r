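# Compact CPU network engine backing the CNN/wCNN and GAN builders.
# A model is an environment holding an ordered list of layers; batches are
# 4D arrays (H, W, C, N) until flattened, then (features, N) matrices.
# Convolution/pooling kernels live in src/ (im2col + BLAS gemm); dense,
# batch-norm, dropout, activations and optimizers are plain R. All
# randomness (init, shuffling, dropout, noise) goes through R's RNG so a
# set.seed() upstream makes runs bit-reproducible on CPU.

nn_model <- function(layers, meta = list()) {
  m <- new.env(parent = emptyenv())
  m$layers <- layers
  m$meta <- meta
  m$t <- 0L              # optimizer step counter
  m$opt_state <- NULL
  class(m) <- "nn_model"
  m
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %d layers, %d parameters\n",
              length(x$layers), nn_count_params(x)))
  for (ly in x$layers) cat(" -", ly$type, "\n")
  invisible(x)
}

ly_zeropad <- function(pad = 1L) list(type = "zeropad", pad = as.integer(pad))

# Per-sample standardization (x - mean)/sd over each sample's pixels; no
# trainable parameters. Backward applies the exact Jacobian (as in layer
# normalization).
ly_standardize <- function(eps = 1e-6) list(type = "standardize", eps = eps)

ly_conv <- function(k, cin, cout, stride = 1L, pad = NULL, l2 = 0,
                    init_sd = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L          # "same" for stride 1
  if (is.null(init_sd)) init_sd <- sqrt(2 / (k * k * cin))  # He fan-in
  list(type = "conv",
       W = array(rnorm(k * k * cin * cout, 0, init_sd), c(k, k, cin, cout)),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad),
       l2 = l2)
}

ly_convtr <- function(k, cin, cout, out_h, out_w, stride = 2L, pad = NULL,
                      init_sd = 0.02) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(type = "convtr",
       W = array(rnorm(k * k * cout * cin, 0, init_sd), c(k, k, cout, cin)),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad),
       out_h = as.integer(out_h), out_w = as.integer(out_w), l2 = 0)
}

ly_act <- function(fn) list(type = "act", fn = fn)

ly_pool <- function(kind = c("max", "avg")) {
  list(type = "pool", kind = match.arg(kind))
}

avgpool_fwd <- function(X) {
  d <- dim(X)
  o <- seq(1, 2 * (d[1] %/% 2), by = 2); p <- seq(1, 2 * (d[2] %/% 2), by = 2)
  (X[o, p, , , drop = FALSE] + X[o + 1, p, , , drop = FALSE] +
   X[o, p + 1, , , drop = FALSE] + X[o + 1, p + 1, , , drop = FALSE]) / 4
}

avgpool_bwd <- function(dY, H, W) {
  d <- dim(dY)
  dX <- array(0, c(H, W, d[3], d[4]))
  o <- seq(1, 2 * d[1], by = 2); p <- seq(1, 2 * d[2], by = 2)
  g <- dY / 4
  dX[o, p, , ] <- g; dX[o + 1, p, , ] <- g
  dX[o, p + 1, , ] <- g; dX[o + 1, p + 1, , ] <- g
  dX
}

ly_flatten <- function() list(type = "flatten")

ly_dropout <- function(rate) list(type = "dropout", rate = rate)

ly_dense <- function(n_in, n_out, l2 = 0, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / n_in)
  list(type = "dense", W = matrix(rnorm(n_in * n_out, 0, init_sd), n_out, n_in),
       b = numeric(n_out), l2 = l2)
}

ly_batchnorm <- function(channels, eps = 1e-5, momentum = 0.9) {
  list(type = "batchnorm", gamma = rep(1, channels), beta = numeric(channels),
       eps = eps, momentum = momentum,
       running_mean = numeric(channels), running_var = rep(1, channels))
}

ly_reshape <- function(shape3) list(type = "reshape", shape3 = as.integer(shape3))

leaky_relu_activation <- function(alpha = 0.2) {
  structure(list(name = "leaky_relu",
                 forward = function(x) ifelse(x > 0, x, alpha * x),
                 backward = function(x, up) up * ifelse(x > 0, 1, alpha)),
            class = "activation_fn")
}

tanh_activation <- function() {
  structure(list(name = "tanh",
                 forward = function(x) tanh(x),
                 backward = function(x, up) up * (1 - tanh(x)^2)),
            class = "activation_fn")
}

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    res <- switch(ly$type,
      zeropad = {
        d <- dim(X); p <- ly$pad
        Y <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
        Y[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- X
        list(out = Y, cache = d)
      },
      standardize = {
        d <- dim(X); m <- prod(d[1:3])
        Xm <- matrix(X, m, d[4])
        mu <- colMeans(Xm)
        sdv <- sqrt(colMeans(Xm^2) - mu^2 + ly$eps)
        xhat <- sweep(sweep(Xm, 2, mu), 2, sdv, `/`)
        list(out = array(xhat, d), cache = list(xhat = xhat, sdv = sdv, d = d))
      },
      conv = list(out = cpp_conv2d_fwd(X, ly$W, ly$b, ly$stride, ly$pad),
                  cache = X),
      convtr = list(out = cpp_convtr2d_fwd(X, ly$W, ly$b, ly$stride, ly$pad,
                                           ly$out_h, ly$out_w),
                    cache = X),
      act = list(out = ly$fn$forward(X), cache = X),
      pool = {
        if (identical(ly$kind, "avg")) {
          list(out = avgpool_fwd(X),
               cache = list(idx = NULL, H = dim(X)[1], W = dim(X)[2]))
        } else {
          r <- cpp_maxpool_fwd(X)
          list(out = r$Y, cache = list(idx = r$idx, H = dim(X)[1], W = dim(X)[2]))
        }
      },
      flatten = {
        d <- dim(X)
        list(out = matrix(X, prod(d[1:3]), d[4]), cache = d)
      },
      reshape = {
        n <- if (is.matrix(X)) ncol(X) else dim(X)[4]
        list(out = array(X, c(ly$shape3, n)), cache = dim(X))
      },
      dropout = {
        if (training && ly$rate > 0) {
          mask <- (runif(length(X)) >= ly$rate) / (1 - ly$rate)
          dim(mask) <- dim(X)
          list(out = X * mask, cache = mask)
        } else list(out = X, cache = NULL)
      },
      dense = list(out = ly$W %*% X + ly$b, cache = X),
      batchnorm = nn_bn_forward(ly, X, training, model, i),
      stop(sprintf("unknown layer type '%s'", ly$type)))
    caches[[i]] <- res$cache
    X <- res$out
  }
  list(out = X, caches = caches)
}

# Batch norm over channels: 4D input normalizes each channel across
# (H, W, N); 2D input normalizes each row (feature) across the batch.
nn_bn_forward <- function(ly, X, training, model, i) {
  fourd <- !is.matrix(X)
  if (fourd) {
    d <- dim(X)
    Xm <- matrix(aperm(X, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  } else {
    Xm <- t(X)
  }
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    ly$running_mean <- ly$momentum * ly$running_mean + (1 - ly$momentum) * mu
    ly$running_var <- ly$momentum * ly$running_var + (1 - ly$momentum) * v
    model$layers[[i]] <- ly
  } else {
    mu <- ly$running_mean
    v <- ly$running_var
  }
  inv_std <- 1 / sqrt(v + ly$eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, inv_std, `*`)
  Ym <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
  out <- if (fourd) {
    d <- dim(X)
    aperm(array(Ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else t(Ym)
  list(out = out, cache = list(xhat = xhat, inv_std = inv_std, fourd = fourd,
                               dims = dim(X), training = training))
}

nn_backward <- function(model, caches, dout) {
  n_layers <- length(model$layers)
  grads <- vector("list", n_layers)
  for (i in rev(seq_len(n_layers))) {
    ly <- model$layers[[i]]
    cache <- caches[[i]]
    if (ly$type == "standardize") {
      d <- cache$d; m <- prod(d[1:3])
      dYm <- matrix(dout, m, d[4])
      dXm <- dYm - matrix(colMeans(dYm), m, d[4], byrow = TRUE) -
        cache$xhat * matrix(colMeans(dYm * cache$xhat), m, d[4], byrow = TRUE)
      dout <- array(sweep(dXm, 2, cache$sdv, `/`), d)
    } else if (ly$type == "zeropad") {
      d <- cache; p <- ly$pad
      dout <- dout[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
    } else if (ly$type == "conv") {
      g <- cpp_conv2d_bwd(cache, ly$W, dout, ly$stride, ly$pad)
      if (ly$l2 > 0) g$dW <- g$dW + 2 * ly$l2 * ly$W
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dout <- g$dX
    } else if (ly$type == "convtr") {
      g <- cpp_convtr2d_bwd(cache, ly$W, dout, ly$stride, ly$pad)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dout <- g$dX
    } else if (ly$type == "act") {
      dout <- ly$fn$backward(cache, dout)
    } else if (ly$type == "pool") {
      dout <- if (is.null(cache$idx)) avgpool_bwd(dout, cache$H, cache$W)
              else cpp_maxpool_bwd(dout, cache$idx, cache$H, cache$W)
    } else if (ly$type == "flatten") {
      dout <- array(dout, cache)
    } else if (ly$type == "reshape") {
      dout <- if (length(cache) == 2) matrix(dout, cache[1], cache[2])
              else array(dout, cache)
    } else if (ly$type == "dropout") {
      if (!is.null(cache)) dout <- dout * cache
    } else if (ly$type == "dense") {
      dW <- dout %*% t(cache)
      if (ly$l2 > 0) dW <- dW + 2 * ly$l2 * ly$W
      grads[[i]] <- list(dW = dW, db = rowSums(dout))
      dout <- t(ly$W) %*% dout
    } else if (ly$type == "batchnorm") {
      if (!cache$training) stop("batch-norm backward requires training mode")
      dYm <- if (cache$fourd) {
        d <- cache$dims
        matrix(aperm(dout, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
      } else t(dout)
      m <- nrow(dYm)
      dgamma <- colSums(dYm * cache$xhat)
      dbeta <- colSums(dYm)
      dXm <- sweep(m * dYm, 2, dbeta) - sweep(cache$xhat, 2, dgamma, `*`)
      dXm <- sweep(dXm, 2, ly$gamma * cache$inv_std / m, `*`)
      grads[[i]] <- list(dgamma = dgamma, dbeta = dbeta)
      dout <- if (cache$fourd) {
        d <- cache$dims
        aperm(array(dXm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      } else t(dXm)
    }
  }
  attr(grads, "dX") <- dout    # gradient w.r.t. the model input
  grads
}

# ---- optimizers ------------------------------------------------------------

nn_param_names <- function(ly) {
  switch(ly$type,
         conv = , convtr = , dense = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         character(0))
}

grad_name <- function(p) paste0("d", sub("^W$", "W", p))

nn_update <- function(model, grads, cfg) {
  model$t <- model$t + 1L
  if (is.null(model$opt_state)) model$opt_state <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    ly <- model$layers[[i]]
    st <- model$opt_state[[i]]
    if (is.null(st)) st <- list()
    for (p in nn_param_names(ly)) {
      g <- grads[[i]][[grad_name(p)]]
      if (cfg$optimizer == "sgd") {
        ly[[p]] <- ly[[p]] - cfg$lr * g
      } else {                     # adam
        key_m <- paste0("m_", p); key_v <- paste0("v_", p)
        if (is.null(st[[key_m]])) { st[[key_m]] <- g * 0; st[[key_v]] <- g * 0 }
        st[[key_m]] <- cfg$beta1 * st[[key_m]] + (1 - cfg$beta1) * g
        st[[key_v]] <- cfg$beta2 * st[[key_v]] + (1 - cfg$beta2) * g^2
        mhat <- st[[key_m]] / (1 - cfg$beta1^model$t)
        vhat <- st[[key_v]] / (1 - cfg$beta2^model$t)
        ly[[p]] <- ly[[p]] - cfg$lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    model$layers[[i]] <- ly
    model$opt_state[[i]] <- st
  }
  invisible(model)
}

#' Number of trainable parameters of a model
#'
#' @param model An `nn_model` (from the CNN/wCNN or GAN builders).
#' @return Integer parameter count.
#' @export
nn_count_params <- function(model) {
  sum(vapply(model$layers, function(ly) {
    sum(vapply(nn_param_names(ly), function(p) length(ly[[p]]), 0))
  }, 0))
}

nn_l2_penalty <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (!is.null(ly$l2) && ly$l2 > 0 && !is.null(ly$W)) ly$l2 * sum(ly$W^2) else 0
  }, 0))
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), `/`)
}
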