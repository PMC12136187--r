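# Model fitting: discriminator pretraining with stratified cross-validation,
# the two-step alternating GAN loop (unconditional and conditional), and
# fingerprint sampling.

#' Training configuration
#'
#' Defaults follow the reference training protocol: 100 epochs of
#' discriminator pretraining, 800 GAN epochs, mini-batches of 32, Adam with
#' learning rates 1e-6 (discriminator) and 1e-3 (generator) inside the
#' adversarial loop, and an L2 kernel penalty. `pretrain_learning_rate` is
#' the rate used when the discriminator is trained *independently* as a
#' classifier; the tiny 1e-6 discriminator rate is an adversarial-balance
#' setting tied to long GAN runs and is far too small for stand-alone
#' classification (see the package vignette).
#'
#' @param d_epochs discriminator pretraining epochs.
#' @param gan_epochs adversarial training epochs (one full pass over the
#'   real set per epoch).
#' @param batch_size mini-batch size.
#' @param d_learning_rate,g_learning_rate Adam learning rates inside the GAN
#'   loop.
#' @param pretrain_learning_rate Adam learning rate for stand-alone
#'   discriminator training.
#' @param l2_coeff L2 kernel-regularizer coefficient (weights only).
#' @param seed integer seed governing initialisation, shuffling and noise.
#' @return object of class `fp_training_config`.
#' @export
fp_training_config <- function(d_epochs = 100L, gan_epochs = 800L,
                               batch_size = 32L, d_learning_rate = 1e-6,
                               g_learning_rate = 1e-3,
                               pretrain_learning_rate = 1e-3,
                               l2_coeff = 1e-4, seed = 1L) {
  cfg <- list(d_epochs = as.integer(d_epochs),
              gan_epochs = as.integer(gan_epochs),
              batch_size = as.integer(batch_size),
              d_learning_rate = d_learning_rate,
              g_learning_rate = g_learning_rate,
              pretrain_learning_rate = pretrain_learning_rate,
              l2_coeff = l2_coeff, seed = as.integer(seed))
  stopifnot(cfg$d_epochs > 0L, cfg$gan_epochs > 0L, cfg$batch_size > 0L,
            cfg$d_learning_rate >= 0, cfg$g_learning_rate >= 0,
            cfg$pretrain_learning_rate >= 0, cfg$l2_coeff >= 0)
  structure(cfg, class = "fp_training_config")
}

as_bits_matrix <- function(x) {
  m <- if (inherits(x, "fp_set")) x$bits else as.matrix(x)
  storage.mode(m) <- "double"
  m
}

as_binary_labels <- function(labels, n) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    labels <- ifelse(labels == 1, "active", "inactive")
  }
  labels <- factor(as.character(labels), levels = c("active", "inactive"))
  if (anyNA(labels)) stop("labels must be 'active'/'inactive' (or 1/0)")
  stopifnot(length(labels) == n)
  labels
}

# one classifier fit: full passes over (X, y) with seeded shuffling
train_classifier <- function(net, X, y_idx, epochs, lr, l2, batch, seed) {
  n <- nrow(X)
  state <- nn_adam_init(net)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in seq_len(ceiling(n / batch))) {
      idx <- ord[(((b - 1L) * batch + 1L):min(b * batch, n))]
      r <- nn_train_batch(net, state, X[idx, , drop = FALSE],
                          onehot(y_idx[idx], 2L), lr, l2)
      if (!is.finite(r$loss)) {
        stop("non-finite classifier loss at epoch ", ep, ", batch ", b)
      }
      net <- r$net
      state <- r$state
    }
  }
  net
}

#' Train and cross-validate a fingerprint discriminator
#'
#' Trains one of the six DCNN variants as a stand-alone active/inactive
#' classifier under stratified k-fold cross-validation: for every fold the
#' network is trained from scratch on the other k-1 folds and evaluated on
#' the held-out fold (AUC, accuracy, F1, precision, recall, confusion
#' counts). A final model is then trained on all rows.
#'
#' @param x fingerprints: an [fp_set()], an `fp_labeled_set`, or a 0/1
#'   matrix.
#' @param labels class labels (`active`/`inactive` or 1/0); ignored when `x`
#'   is an `fp_labeled_set`.
#' @param architecture discriminator variant name (see
#'   [architecture_names()]).
#' @param folds an [stratified_kfold()] assignment, or `NULL` to create one.
#' @param k number of folds when `folds` is `NULL`.
#' @param config an [fp_training_config()].
#' @param epochs training epochs (default `config$d_epochs`).
#' @param learning_rate Adam rate (default `config$pretrain_learning_rate`).
#' @return object of class `fp_discriminator`: fields `model` (final network
#'   handle), `architecture`, `cv` (per-fold metric data.frame), `cv_means`,
#'   `folds`, `config`.
#' @seealso [predict.fp_discriminator()], [classifier_metrics()]
#' @export
fp_discriminator <- function(x, labels = NULL, architecture = "AlexNet",
                             folds = NULL, k = 10L,
                             config = fp_training_config(),
                             epochs = config$d_epochs,
                             learning_rate = config$pretrain_learning_rate) {
  if (inherits(x, "fp_labeled_set")) {
    labels <- x$labels
    x <- x$fps
  }
  X <- as_bits_matrix(x)
  labels <- as_binary_labels(labels, nrow(X))
  y_idx <- as.integer(labels)  # 1 = active (positive), 2 = inactive
  if (is.null(folds)) folds <- stratified_kfold(labels, k = k,
                                                seed = config$seed)
  stopifnot(inherits(folds, "fp_folds"), length(folds$fold) == nrow(X))

  cv <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- folds$fold == f
    handle <- build_discriminator(architecture, input_length = ncol(X),
                                  seed = config$seed + f)
    net <- train_classifier(handle$net, X[!test, , drop = FALSE],
                            y_idx[!test], epochs = epochs,
                            lr = learning_rate, l2 = config$l2_coeff,
                            batch = config$batch_size,
                            seed = config$seed + 1000L * f)
    p <- row_softmax(nn_forward(net, X[test, , drop = FALSE],
                            want_caches = FALSE)$out)
    m <- classifier_metrics(labels[test] == "active", p[, 1L])
    cv[[f]] <- data.frame(fold = f, auc = m$auc, accuracy = m$accuracy,
                          f1 = m$f1, precision = m$precision,
                          recall = m$recall, tp = m$confusion["tp"],
                          fp = m$confusion["fp"], tn = m$confusion["tn"],
                          fn = m$confusion["fn"], row.names = NULL)
  }
  cv <- do.call(rbind, cv)

  final <- build_discriminator(architecture, input_length = ncol(X),
                               seed = config$seed)
  final$net <- train_classifier(final$net, X, y_idx, epochs = epochs,
                                lr = learning_rate, l2 = config$l2_coeff,
                                batch = config$batch_size, seed = config$seed)
  structure(list(model = final, architecture = final$architecture, cv = cv,
                 cv_means = colMeans(cv[, -1L]), folds = folds,
                 config = config, levels = levels(labels)),
            class = "fp_discriminator")
}

#' @export
print.fp_discriminator <- function(x, ...) {
  cat("Fingerprint discriminator (", x$architecture, "), ",
      x$folds$k, "-fold cross-validation\n", sep = "")
  cat(sprintf("  mean AUC %.3f, accuracy %.3f, F1 %.3f\n",
              x$cv_means["auc"], x$cv_means["accuracy"], x$cv_means["f1"]))
  invisible(x)
}

#' @export
summary.fp_discriminator <- function(object, ...) {
  cat("Per-fold held-out metrics:\n")
  print(object$cv, row.names = FALSE, digits = 3)
  cat("\nMeans:\n")
  print(round(object$cv_means, 4))
  invisible(object$cv)
}

#' Predict from a trained discriminator
#'
#' @param object an [fp_discriminator()].
#' @param newdata fingerprints ([fp_set()] or 0/1 matrix).
#' @param type `"prob"` for the positive-class (active) probability,
#'   `"class"` for hard labels.
#' @param ... unused.
#' @return numeric vector of probabilities or factor of labels.
#' @export
predict.fp_discriminator <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_scores(object$model, as_bits_matrix(newdata))[, 1L]
  if (type == "prob") p
  else factor(ifelse(p >= 0.5, "active", "inactive"),
              levels = c("active", "inactive"))
}

# ---- GAN loops ---------------------------------------------------------------

# Shared two-step alternating loop. `cond` carries per-row condition indices
# (1-based) or NULL. Per-epoch randomness (shuffle + noise table) is derived
# from the seed alone, so the noise table is fixed across epochs: with zero
# learning rates the run is an exact identity, and runs are bit-reproducible.
gan_train_loop <- function(d_handle, g_handle, X, cond, cfg, epochs,
                           d_lr, g_lr, verbose = FALSE) {
  n <- nrow(X)
  batch <- min(cfg$batch_size, n)
  nz <- g_handle$generator_spec$noise_dim
  n_classes <- if (is.null(cond)) 0L else max(cond)
  d_state <- nn_adam_init(d_handle$net)
  g_state <- nn_adam_init(g_handle$net)
  mask <- g_handle$generator_spec$mask
  log <- matrix(NA_real_, epochs, 3L,
                dimnames = list(NULL, c("d_loss", "g_loss", "d_acc")))

  set.seed(cfg$seed)
  ord <- sample.int(n)
  Z <- matrix(stats::rnorm(n * nz), n, nz)      # fixed noise table
  Z2 <- matrix(stats::rnorm(n * nz), n, nz)     # generator-step noise table
  n_batches <- ceiling(n / batch)
  X <- as.matrix(X)
  storage.mode(X) <- "double"

  for (ep in seq_len(epochs)) {
    dl <- gl <- acc <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[(((b - 1L) * batch + 1L):min(b * batch, n))]
      nb <- length(idx)
      real <- X[idx, , drop = FALSE]
      cnd <- if (is.null(cond)) NULL else cond[idx]

      ## step 1: update D on a real batch (class 1) and a generated batch
      ## (class 2); G frozen.
      zin <- Z[idx, , drop = FALSE]
      if (!is.null(cond)) zin <- condition_join(zin, cnd, n_classes)
      fake <- nn_forward(g_handle$net, zin, training = TRUE,
                         update_stats = FALSE, want_caches = FALSE)$out
      if (!is.null(mask)) fake <- apply_mask(fake, mask)
      xd <- rbind(real, fake)
      if (!is.null(cond)) xd <- condition_join(xd, c(cnd, cnd), n_classes)
      y <- onehot(rep(c(1L, 2L), each = nb), 2L)
      rd <- nn_train_batch(d_handle$net, d_state, xd, y, d_lr, cfg$l2_coeff)
      if (!is.finite(rd$loss)) {
        stop("non-finite discriminator loss at epoch ", ep, ", step 1")
      }
      d_handle$net <- rd$net
      d_state <- rd$state

      ## step 2: update G through the frozen discriminator with positive
      ## (real) labels on generated samples.
      zin2 <- Z2[idx, , drop = FALSE]
      if (!is.null(cond)) zin2 <- condition_join(zin2, cnd, n_classes)
      cnd_block <- if (is.null(cond)) NULL else onehot(cnd, n_classes)
      rg <- nn_gen_batch(g_handle$net, g_state, d_handle$net, zin2,
                         cnd_block, mask, g_lr, cfg$l2_coeff)
      if (!is.finite(rg$loss)) {
        stop("non-finite generator loss at epoch ", ep, ", step 2")
      }
      g_handle$net <- rg$net
      g_state <- rg$state

      dl <- dl + rd$loss
      gl <- gl + rg$loss
      acc <- acc + rd$acc
    }
    log[ep, ] <- c(dl, gl, acc) / n_batches
    if (verbose && (ep %% 50L == 0L || ep == 1L)) {
      message(sprintf("epoch %4d  d_loss %.4f  g_loss %.4f  d_acc %.3f",
                      ep, log[ep, 1L], log[ep, 2L], log[ep, 3L]))
    }
  }
  list(d = d_handle, g = g_handle,
       log = data.frame(epoch = seq_len(epochs), as.data.frame(log)))
}

#' Train an unconditional fingerprint GAN
#'
#' Trains a deep convolutional GAN on real (active) fingerprints with the
#' two-step alternating protocol: per epoch and mini-batch, first the
#' discriminator is updated on a real batch (positive label) and a generated
#' batch (negative label) with the generator frozen, then the generator is
#' updated through the frozen discriminator with positive labels on its own
#' samples (non-saturating minimax objective, 2-class cross-entropy).
#'
#' @param x real fingerprints: an [fp_set()], 0/1 matrix, or an
#'   `fp_labeled_set` (its *active* rows are used).
#' @param architecture discriminator variant.
#' @param generator an [generator_spec()]; output length defaults to the
#'   fingerprint length.
#' @param mask optional [mcs_mask()] attached to the generator so every
#'   sample preserves the masked feature bits.
#' @param config an [fp_training_config()].
#' @param epochs adversarial epochs (default `config$gan_epochs`).
#' @param d_lr,g_lr Adam learning rates (default the config's GAN rates).
#' @param verbose print progress every 50 epochs.
#' @return object of class `fp_dcgan` with fields `generator`,
#'   `discriminator` (network handles), `log` (per-epoch losses and
#'   discriminator accuracy), `scheme`, `config`.
#' @seealso [simulate.fp_dcgan()], [sample_fingerprints()]
#' @export
fp_dcgan <- function(x, architecture = "AlexNet", generator = NULL,
                     mask = NULL, config = fp_training_config(),
                     epochs = config$gan_epochs,
                     d_lr = config$d_learning_rate,
                     g_lr = config$g_learning_rate, verbose = FALSE) {
  if (inherits(x, "fp_labeled_set")) x <- x$fps[x$labels == "active"]
  scheme <- if (inherits(x, "fp_set")) x$scheme else "MACCS"
  X <- as_bits_matrix(x)
  stopifnot(nrow(X) > 0L)
  if (is.null(generator)) generator <- generator_spec(output_length = ncol(X))
  if (!is.null(mask)) {
    generator$mask <- if (inherits(mask, "fp_mcs_mask")) mask
                      else mcs_mask(mask, length = ncol(X))
  }
  d <- build_discriminator(architecture, input_length = ncol(X),
                           seed = config$seed)
  g <- build_generator(generator, seed = config$seed + 1L)
  res <- gan_train_loop(d, g, X, cond = NULL, cfg = config, epochs = epochs,
                        d_lr = d_lr, g_lr = g_lr, verbose = verbose)
  structure(list(generator = res$g, discriminator = res$d, log = res$log,
                 scheme = scheme, n_real = nrow(X), config = config,
                 conditional = FALSE),
            class = "fp_dcgan")
}

#' Train a conditional fingerprint GAN
#'
#' Same alternating protocol as [fp_dcgan()], with a one-hot class label
#' appended to both the generator input (noise) and the discriminator input
#' (fingerprint). Training on active *and* inactive compounds with the label
#' as condition steers sampling: requesting the active label at generation
#' time yields fingerprints biased toward the active class.
#'
#' @param x fingerprints: an [fp_set()], 0/1 matrix, or `fp_labeled_set`.
#' @param labels class labels (`active`/`inactive`); ignored for an
#'   `fp_labeled_set`.
#' @inheritParams fp_dcgan
#' @return object of class `c("fp_cdcgan", "fp_dcgan")`; its generator
#'   accepts a class label at sampling time.
#' @export
fp_cdcgan <- function(x, labels = NULL, architecture = "AlexNet",
                      generator = NULL, mask = NULL,
                      config = fp_training_config(),
                      epochs = config$gan_epochs,
                      d_lr = config$d_learning_rate,
                      g_lr = config$g_learning_rate, verbose = FALSE) {
  if (inherits(x, "fp_labeled_set")) {
    labels <- x$labels
    x <- x$fps
  }
  scheme <- if (inherits(x, "fp_set")) x$scheme else "MACCS"
  X <- as_bits_matrix(x)
  labels <- as_binary_labels(labels, nrow(X))
  if (nlevels(droplevels(labels)) < 2L) {
    stop("conditional training needs both classes present")
  }
  n_classes <- 2L
  if (is.null(generator)) generator <- generator_spec(output_length = ncol(X))
  generator$condition_dim <- n_classes
  if (!is.null(mask)) {
    generator$mask <- if (inherits(mask, "fp_mcs_mask")) mask
                      else mcs_mask(mask, length = ncol(X))
  }
  d <- build_discriminator(architecture, input_length = ncol(X),
                           condition_dim = n_classes, seed = config$seed)
  g <- build_generator(generator, seed = config$seed + 1L)
  res <- gan_train_loop(d, g, X, cond = as.integer(labels), cfg = config,
                        epochs = epochs, d_lr = d_lr, g_lr = g_lr,
                        verbose = verbose)
  structure(list(generator = res$g, discriminator = res$d, log = res$log,
                 scheme = scheme, n_real = nrow(X), config = config,
                 conditional = TRUE, levels = levels(labels)),
            class = c("fp_cdcgan", "fp_dcgan"))
}

#' @export
print.fp_dcgan <- function(x, ...) {
  cat("Fingerprint ", if (x$conditional) "conditional " else "",
      "GAN (discriminator: ", x$discriminator$architecture, ")\n", sep = "")
  cat("  trained ", nrow(x$log), " epochs on ", x$n_real,
      " real fingerprints\n", sep = "")
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final d_loss %.4f, g_loss %.4f, d_acc %.3f\n",
              last$d_loss, last$g_loss, last$d_acc))
  if (!is.null(x$generator$generator_spec$mask)) {
    cat("  mask attached: ", sum(x$generator$generator_spec$mask$mask),
        " pinned bits\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.fp_dcgan <- function(object, ...) {
  print(object)
  cat("\nLoss trajectory (every 10% of epochs):\n")
  idx <- unique(round(seq(1L, nrow(object$log), length.out = 11L)))
  print(object$log[idx, ], row.names = FALSE, digits = 4)
  invisible(object$log)
}

#' Plot GAN training losses
#'
#' @param x an `fp_dcgan`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fp_dcgan <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$d_loss, x$log$g_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("discriminator", "generator"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
}

# ---- sampling ----------------------------------------------------------------

#' Sample binary fingerprints from a trained (or fresh) generator
#'
#' Draws standard-normal noise, runs the generator, and binarizes the
#' continuous output at the threshold. For a masked generator every sample
#' contains all mask bits (the mask layer pins them to exactly 1, above any
#' threshold < 1). Reproducible for a given seed.
#'
#' @param object an `fp_dcgan`/`fp_cdcgan` fit or a generator network handle
#'   from [build_generator()].
#' @param n number of fingerprints.
#' @param seed integer seed.
#' @param label condition class for a conditional generator (`"active"`,
#'   `"inactive"`, or an integer index); must be `NULL` for an unconditional
#'   one.
#' @param threshold binarization threshold in (0, 1).
#' @return an [fp_set()] of `n` fingerprints.
#' @export
sample_fingerprints <- function(object, n, seed = 1L, label = NULL,
                                threshold = 0.5) {
  stopifnot(n >= 1L, threshold > 0, threshold < 1)
  if (inherits(object, "fp_dcgan")) {
    g <- object$generator
    scheme <- object$scheme
    lvls <- object$levels
  } else if (inherits(object, "fp_network_handle") &&
             !is.null(object$generator_spec)) {
    g <- object
    scheme <- "MACCS"
    lvls <- c("active", "inactive")
  } else {
    stop("object is not a generator or GAN fit")
  }
  spec <- g$generator_spec
  cond_dim <- spec$condition_dim
  if (is.null(cond_dim) && !is.null(label)) {
    stop("label supplied, but the generator is unconditional")
  }
  if (!is.null(cond_dim) && is.null(label)) {
    stop("a conditional generator needs a sampling label")
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(n * spec$noise_dim), n, spec$noise_dim)
  if (!is.null(cond_dim)) {
    if (is.character(label)) label <- match(label, lvls)
    label <- as.integer(label)
    if (is.na(label) || label < 1L || label > cond_dim) {
      stop("condition label out of range 1..", cond_dim)
    }
    z <- condition_join(z, label, cond_dim)
  }
  # chunk the forward pass so very large draws stay memory-bounded
  chunk <- 2048L
  bits <- matrix(0L, n, spec$output_length)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    bits[s:e, ] <- (generator_forward(g, z[s:e, , drop = FALSE]) >=
                      threshold) * 1L
  }
  fp_set(bits, scheme = if (scheme %in% names(fp_scheme_lengths)) scheme
                        else "MACCS",
         ids = sprintf("gen%05d", seq_len(n)))
}

#' @rdname sample_fingerprints
#' @param nsim number of fingerprints (alias of `n` for the [simulate()]
#'   generic).
#' @param ... passed on to [sample_fingerprints()] (`label`, `threshold`).
#' @export
simulate.fp_dcgan <- function(object, nsim = 1L, seed = 1L, ...) {
  sample_fingerprints(object, n = nsim, seed = seed, ...)
}

# ---- persistence ---------------------------------------------------------------

#' Save and load fitted models
#'
#' Checkpoints a fitted GAN or discriminator in R's native serialization
#' format, next to a small JSON sidecar (`<path>.json`) recording the
#' architecture name, fingerprint scheme, seed and package version for
#' audit without deserializing the weights.
#'
#' @param object an `fp_dcgan`, `fp_cdcgan` or `fp_discriminator` fit.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `write_fpgan_model()` returns `path` invisibly;
#'   `read_fpgan_model()` returns the fitted object.
#' @export
write_fpgan_model <- function(object, path) {
  stopifnot(inherits(object, c("fp_dcgan", "fp_discriminator")))
  saveRDS(object, path)
  arch <- if (inherits(object, "fp_discriminator")) object$architecture
          else object$discriminator$architecture
  sidecar <- list(
    class = class(object)[1L],
    architecture = arch,
    scheme = object$scheme %||% "MACCS",
    seed = object$config$seed,
    conditional = isTRUE(object$conditional),
    package_version = as.character(utils::packageVersion("fpgan"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fpgan_model
#' @export
read_fpgan_model <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, c("fp_dcgan", "fp_discriminator"))) {
    stop("file does not contain an fpgan model: ", path)
  }
  object
}
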