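# Minimal neural-network engine: dense / 1-D convolution / max-pooling /
# batch-normalisation / nearest-neighbour upsampling layers trained by
# backpropagation with Adam. All trainable parameters of a network live in
# one flat vector (net$theta); an integer layout table drives the compiled
# forward/backward kernels in src/kernels.cpp. Activations sit between
# layers so every layer has a single algebraic rule.

# ---- layer constructors (pure descriptors) ----------------------------------

nn_dense <- function(units, activation = NULL) {
  list(kind = "dense", units = units, activation = activation)
}

nn_conv1d <- function(filters, kernel, stride = 1L, pad = 0L, activation = NULL) {
  list(kind = "conv", filters = filters, kernel = kernel,
       stride = stride, pad = pad, activation = activation)
}

nn_maxpool1d <- function(size, stride = size) {
  list(kind = "pool", size = size, stride = stride)
}

nn_batchnorm <- function() list(kind = "norm")

nn_activation <- function(name) list(kind = "activation", activation = name)

nn_flatten <- function() list(kind = "flatten")

nn_reshape <- function(channels) list(kind = "reshape", channels = channels)

nn_upsample1d <- function(factor) list(kind = "upsample", factor = factor)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- network construction ---------------------------------------------------

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

act_code <- function(name) {
  code <- match(name, c("relu", "lrelu", "tanh", "sigmoid", "linear")) - 1L
  if (is.na(code)) stop("unknown activation: ", name)
  code
}

kind_code <- function(kind) {
  match(kind, c("dense", "reshape", "flatten", "conv", "pool", "norm",
                "upsample", "activation"))
}

# Expand fused activations into standalone layers so the forward/backward
# walk is uniform.
nn_expand_defs <- function(defs) {
  out <- list()
  for (d in defs) {
    if (d$kind == "activation") {
      out[[length(out) + 1L]] <- d
      next
    }
    act <- d$activation
    d$activation <- NULL
    out[[length(out) + 1L]] <- d
    if (!is.null(act)) out[[length(out) + 1L]] <- nn_activation(act)
  }
  out
}

#' @noRd
# input_shape: integer d for dense domain, or c(L, C) for conv domain.
# Parameter initialisation (Glorot uniform) consumes the caller's RNG stream.
nn_build <- function(defs, input_shape) {
  defs <- nn_expand_defs(defs)
  nl <- length(defs)
  layout <- matrix(0L, nl, 14L)
  theta <- numeric(0)
  wmask <- numeric(0)
  rstats <- numeric(0)
  shape <- as.integer(input_shape)

  add_params <- function(w, b, regularized) {
    woff <- length(theta)
    theta <<- c(theta, w)
    wmask <<- c(wmask, rep(if (regularized) 1 else 0, length(w)))
    boff <- length(theta)
    theta <<- c(theta, b)
    wmask <<- c(wmask, numeric(length(b)))
    c(woff, length(w), boff, length(b))
  }

  for (i in seq_len(nl)) {
    d <- defs[[i]]
    row <- integer(14L)
    row[1L] <- kind_code(d$kind)
    if (d$kind == "dense") {
      stopifnot(length(shape) == 1L)
      w <- glorot_uniform(shape, d$units, shape * d$units)
      row[9:12] <- add_params(w, numeric(d$units), TRUE)
      row[3L] <- shape
      row[5L] <- d$units
      shape <- d$units
    } else if (d$kind == "reshape") {
      stopifnot(length(shape) == 1L, shape %% d$channels == 0L)
      shape <- c(shape %/% d$channels, d$channels)
      row[3L] <- shape[1L]
      row[4L] <- d$channels
    } else if (d$kind == "flatten") {
      stopifnot(length(shape) == 2L)
      row[3L] <- shape[1L]
      row[4L] <- shape[2L]
      shape <- prod(shape)
    } else if (d$kind == "conv") {
      stopifnot(length(shape) == 2L)
      L <- shape[1L]; C <- shape[2L]
      out_len <- (L + 2L * d$pad - d$kernel) %/% d$stride + 1L
      if (out_len < 1L) {
        stop("conv layer ", i, ": kernel ", d$kernel,
             " does not fit input length ", L)
      }
      w <- glorot_uniform(d$kernel * C, d$filters, d$kernel * C * d$filters)
      row[9:12] <- add_params(w, numeric(d$filters), TRUE)
      row[3L] <- L; row[4L] <- C; row[5L] <- d$filters
      row[6L] <- d$kernel; row[7L] <- d$stride; row[8L] <- d$pad
      row[14L] <- out_len
      shape <- c(out_len, d$filters)
    } else if (d$kind == "pool") {
      stopifnot(length(shape) == 2L)
      out_len <- (shape[1L] - d$size) %/% d$stride + 1L
      if (out_len < 1L) {
        stop("pool layer ", i, ": window does not fit input length ",
             shape[1L])
      }
      row[3L] <- shape[1L]; row[4L] <- shape[2L]
      row[6L] <- d$size; row[7L] <- d$stride
      row[14L] <- out_len
      shape <- c(out_len, shape[2L])
    } else if (d$kind == "norm") {
      nc <- if (length(shape) == 2L) shape[2L] else shape
      row[9:12] <- add_params(rep(1, nc), numeric(nc), FALSE)  # gamma, beta
      row[4L] <- nc
      row[13L] <- length(rstats)
      rstats <- c(rstats, numeric(nc), rep(1, nc))  # running mean, var
    } else if (d$kind == "upsample") {
      stopifnot(length(shape) == 2L)
      row[3L] <- shape[1L]; row[4L] <- shape[2L]
      row[6L] <- d$factor
      shape <- c(shape[1L] * d$factor, shape[2L])
    } else if (d$kind == "activation") {
      row[2L] <- act_code(d$activation)
    } else {
      stop("unknown layer kind: ", d$kind)
    }
    layout[i, ] <- row
    defs[[i]] <- d
  }
  structure(
    list(defs = defs, layout = layout, theta = theta, wmask = wmask,
         rstats = rstats, input_shape = as.integer(input_shape),
         output_shape = shape),
    class = "fp_network"
  )
}

nn_n_params <- function(net) length(net$theta)

# deterministic digest of all parameters (freeze-contract checks)
nn_checksum <- function(net) sum(net$theta * (seq_along(net$theta) %% 97))

# ---- forward / backward / optimiser wrappers ---------------------------------

# training: use batch statistics in norm layers; update_stats: refresh the
# running statistics (only when this network is the one being optimised).
nn_forward <- function(net, x, training = FALSE, update_stats = training,
                       want_caches = TRUE) {
  r <- .nn_fwd(net$theta, net$layout, net$rstats, as.matrix(x), training,
               update_stats, want_caches)
  if (update_stats) net$rstats <- drop(r$rstats)
  list(out = r$out, caches = r$caches, net = net)
}

# returns list(grad_in, gtheta): gradient wrt input and wrt net$theta
nn_backward <- function(net, caches, grad) {
  r <- .nn_bwd(net$theta, net$layout, caches, grad)
  list(grad_in = r$grad_in, gtheta = drop(r$gtheta))
}

nn_adam_init <- function(net) {
  list(t = 0L, m = numeric(length(net$theta)), v = numeric(length(net$theta)))
}

# L2 penalty applies to weight matrices only (kernel regularizer), not to
# biases or normalisation parameters (net$wmask).
nn_adam_step <- function(net, gtheta, state, lr, l2 = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  r <- .nn_adam(net$theta, gtheta, state$m, state$v, net$wmask, lr, l2,
                1 - beta1^state$t, 1 - beta2^state$t, beta1, beta2, eps)
  net$theta <- drop(r$theta)
  state$m <- drop(r$m)
  state$v <- drop(r$v)
  list(net = net, state = state)
}

# fused single-batch update (forward + backward + Adam) for a classifier or
# discriminator; y is a one-hot matrix
nn_train_batch <- function(net, state, x, y, lr, l2) {
  state$t <- state$t + 1L
  r <- .nn_train_step(net$theta, net$layout, net$rstats, state$m, state$v,
                      net$wmask, as.matrix(x), y, lr, l2,
                      1 - 0.9^state$t, 1 - 0.999^state$t)
  net$theta <- drop(r$theta)
  net$rstats <- drop(r$rstats)
  state$m <- drop(r$m)
  state$v <- drop(r$v)
  list(net = net, state = state, loss = r$loss, acc = r$acc)
}

# fused generator update through a frozen discriminator
nn_gen_batch <- function(g_net, g_state, d_net, z, cond, mask, lr, l2) {
  g_state$t <- g_state$t + 1L
  if (is.null(cond)) cond <- matrix(0, nrow(z), 0L)
  if (is.null(mask)) {
    mvec <- numeric(0)
    uvec <- numeric(0)
  } else {
    mvec <- mask$mask
    uvec <- mask$unmask
  }
  r <- .nn_gen_step(g_net$theta, g_net$layout, g_net$rstats, g_state$m,
                    g_state$v, g_net$wmask, d_net$theta, d_net$layout,
                    d_net$rstats, z, cond, mvec, uvec, lr, l2,
                    1 - 0.9^g_state$t, 1 - 0.999^g_state$t)
  g_net$theta <- drop(r$theta)
  g_net$rstats <- drop(r$rstats)
  g_state$m <- drop(r$m)
  g_state$v <- drop(r$v)
  list(net = g_net, state = g_state, loss = r$loss)
}

# ---- losses ------------------------------------------------------------------

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# 2-class softmax cross-entropy on one-hot labels; grad wrt logits.
softmax_ce <- function(logits, y) {
  p <- row_softmax(logits)
  loss <- -mean(rowSums(y * log(p + 1e-12)))
  list(loss = loss, grad = (p - y) / nrow(y), p = p)
}

onehot <- function(idx, n_classes) {
  y <- matrix(0, length(idx), n_classes)
  y[cbind(seq_along(idx), idx)] <- 1
  y
}
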