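# Discriminator and generator construction: the six named DCNN variants
# (declared in inst/extdata/architectures.yaml), the reversed-convolution
# generator, the one-hot condition join, and the substructure-preserving
# mask layer.

.arch_env <- new.env(parent = emptyenv())

#' Architecture specifications
#'
#' The discriminator variants are declared in a versioned YAML table shipped
#' with the package (`system.file("extdata", "architectures.yaml", package =
#' "fpgan")`). Each variant maps a fingerprint (a 1-D binary signal) through
#' a dense input projection, a stack of 1-D convolution / pooling /
#' normalisation layers translated from the canonical image architectures,
#' and a dense head emitting two class scores. `VGGNet13` and `VGGNet11` are
#' derived from `VGGNet16` by removing the layer groups tagged `asterisk`
#' and `asterisk`+`pound` respectively.
#'
#' @param name one of `"LeNet5"`, `"AlexNet"`, `"ZFNet"`, `"VGGNet11"`,
#'   `"VGGNet13"`, `"VGGNet16"`.
#' @return an object of class `fp_architecture`: a list with elements `name`,
#'   `input_projection` and `layers` (ordered layer descriptors).
#' @examples
#' spec <- architecture_spec("LeNet5")
#' length(spec$layers)
#' @export
architecture_spec <- function(name) {
  tab <- arch_table()
  name <- match.arg(name, architecture_names())
  base <- if (startsWith(name, "VGGNet")) "VGGNet16" else name
  layers <- tab$architectures[[base]]
  if (name == "VGGNet13") {
    layers <- Filter(function(l) is.null(l$group) || l$group != "asterisk", layers)
  } else if (name == "VGGNet11") {
    layers <- Filter(function(l) is.null(l$group), layers)
  }
  structure(list(name = name, input_projection = tab$input_projection,
                 layers = layers, version = tab$version),
            class = "fp_architecture")
}

#' @rdname architecture_spec
#' @export
architecture_names <- function() {
  c("LeNet5", "AlexNet", "ZFNet", "VGGNet11", "VGGNet13", "VGGNet16")
}

arch_table <- function() {
  if (is.null(.arch_env$table)) {
    path <- system.file("extdata", "architectures.yaml", package = "fpgan")
    .arch_env$table <- yaml::read_yaml(path)
  }
  .arch_env$table
}

arch_layer_defs <- function(spec) {
  to_def <- function(l) {
    switch(l$kind,
      dense = nn_dense(l$units, l$activation),
      conv = nn_conv1d(l$filters, l$kernel, l$stride %||% 1L, l$pad %||% 0L,
                       l$activation),
      pool = nn_maxpool1d(l$size, l$stride %||% l$size),
      norm = nn_batchnorm(),
      flatten = nn_flatten(),
      stop("unknown layer kind in architecture table: ", l$kind)
    )
  }
  c(list(to_def(spec$input_projection), nn_reshape(1L)),
    lapply(spec$layers, to_def))
}

#' Build a discriminator network
#'
#' Instantiates one of the six named DCNN variants as a trainable network
#' mapping a fingerprint (optionally concatenated with a one-hot condition
#' vector, see [condition_join()]) to two class scores. Parameters are
#' initialised by the Glorot uniform scheme from the supplied seed.
#'
#' @param architecture architecture name (see [architecture_names()]) or an
#'   `fp_architecture` object.
#' @param input_length fingerprint length in bits.
#' @param condition_dim number of condition classes appended one-hot to the
#'   input, or `NULL` for an unconditional discriminator.
#' @param seed integer seed for parameter initialisation.
#' @return an object of class `fp_network_handle` wrapping the network, with
#'   fields `net`, `architecture`, `input_length`, `condition_dim`, `seed`.
#' @examples
#' d <- build_discriminator("AlexNet", 168, seed = 1)
#' p <- predict_scores(d, matrix(rbinom(32 * 168, 1, 0.3), 32))
#' dim(p)  # 32 x 2 row-stochastic
#' @export
build_discriminator <- function(architecture, input_length = 168L,
                                condition_dim = NULL, seed = 1L) {
  spec <- if (inherits(architecture, "fp_architecture")) architecture
          else architecture_spec(architecture)
  in_dim <- as.integer(input_length) + (if (is.null(condition_dim)) 0L else as.integer(condition_dim))
  defs <- arch_layer_defs(spec)
  set.seed(seed)
  net <- nn_build(defs, in_dim)
  structure(list(net = net, architecture = spec$name,
                 input_length = as.integer(input_length),
                 condition_dim = condition_dim, seed = as.integer(seed)),
            class = "fp_network_handle")
}

#' @export
print.fp_network_handle <- function(x, ...) {
  role <- if (!is.null(x$generator_spec)) "generator" else "discriminator"
  cat("<fpgan ", role, " network: ", x$architecture, ">\n", sep = "")
  cat("  input length: ", x$input_length,
      if (!is.null(x$condition_dim)) paste0(" (+", x$condition_dim, " condition)"),
      "\n", sep = "")
  cat("  trainable parameters: ", nn_n_params(x$net), "\n", sep = "")
  invisible(x)
}

# row-stochastic class scores from a discriminator handle
#' Forward pass of a discriminator
#'
#' @param handle a discriminator built by [build_discriminator()].
#' @param x matrix of fingerprints (rows), already condition-joined if the
#'   discriminator is conditional.
#' @return matrix of row-stochastic 2-class probabilities.
#' @export
predict_scores <- function(handle, x) {
  stopifnot(inherits(handle, "fp_network_handle"))
  row_softmax(nn_forward(handle$net, as.matrix(x), training = FALSE,
                         want_caches = FALSE)$out)
}

#' Generator specification
#'
#' The generator reverses the discriminator's convolutional path: a dense
#' projection of the noise vector to a short multi-channel signal, followed
#' by four convolutional blocks (1-D convolution, batch normalisation, leaky
#' ReLU), nearest-neighbour upsampling between the first three blocks to
#' reach the fingerprint length, and a final 1-channel convolution with a
#' sigmoid output so every position lies in \[0, 1\]. An optional mask (see
#' [mcs_mask()]) pins designated feature bits to exactly 1 in every output.
#'
#' @param noise_dim dimension of the standard-normal noise prior.
#' @param output_length fingerprint length; must be divisible by 8 (three
#'   2x upsampling stages).
#' @param channels channel widths of the four convolutional blocks.
#' @param kernel kernel extent of the convolutional blocks.
#' @param condition_dim number of condition classes appended one-hot to the
#'   noise vector, or `NULL`.
#' @param mask an `fp_mcs_mask`, or `NULL`.
#' @return an object of class `fp_generator_spec`.
#' @export
generator_spec <- function(noise_dim = 100L, output_length = 168L,
                           channels = c(8L, 8L, 8L, 8L), kernel = 3L,
                           condition_dim = NULL, mask = NULL) {
  stopifnot(noise_dim >= 1L, length(channels) == 4L)
  if (output_length %% 8L != 0L) {
    stop("output_length must be divisible by 8 (three 2x upsampling stages)")
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "fp_mcs_mask"))
    if (length(mask$mask) != output_length) {
      stop("mask length ", length(mask$mask),
           " does not match output_length ", output_length)
    }
  }
  structure(list(noise_dim = as.integer(noise_dim),
                 output_length = as.integer(output_length),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 condition_dim = condition_dim, mask = mask),
            class = "fp_generator_spec")
}

generator_layer_defs <- function(spec) {
  L0 <- spec$output_length %/% 8L
  k <- spec$kernel
  p <- k %/% 2L
  ch <- spec$channels
  list(
    nn_dense(L0 * ch[1L], "lrelu"),
    nn_reshape(ch[1L]),
    nn_conv1d(ch[1L], k, pad = p), nn_batchnorm(), nn_activation("lrelu"),
    nn_upsample1d(2L),
    nn_conv1d(ch[2L], k, pad = p), nn_batchnorm(), nn_activation("lrelu"),
    nn_upsample1d(2L),
    nn_conv1d(ch[3L], k, pad = p), nn_batchnorm(), nn_activation("lrelu"),
    nn_upsample1d(2L),
    nn_conv1d(ch[4L], k, pad = p), nn_batchnorm(), nn_activation("lrelu"),
    nn_conv1d(1L, k, pad = p, activation = "sigmoid"),
    nn_flatten()
  )
}

#' Build a generator network
#'
#' @param spec an [generator_spec()] object.
#' @param seed integer seed for parameter initialisation.
#' @return an object of class `fp_network_handle` with `generator_spec`
#'   attached.
#' @examples
#' g <- build_generator(generator_spec(output_length = 168L), seed = 1)
#' x <- generator_forward(g, matrix(rnorm(5 * 100), 5))
#' range(x)  # within [0, 1]
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "fp_generator_spec"))
  in_dim <- spec$noise_dim +
    (if (is.null(spec$condition_dim)) 0L else as.integer(spec$condition_dim))
  set.seed(seed)
  net <- nn_build(generator_layer_defs(spec), in_dim)
  stopifnot(net$output_shape == spec$output_length)
  structure(list(net = net, architecture = "generator",
                 input_length = in_dim, condition_dim = spec$condition_dim,
                 generator_spec = spec, seed = as.integer(seed)),
            class = "fp_network_handle")
}

#' Run a generator forward
#'
#' Maps noise rows (already condition-joined if conditional) to continuous
#' fingerprint activations in \[0, 1\], applying the generator's mask if one
#' is attached.
#'
#' @param handle a generator built by [build_generator()].
#' @param z matrix of noise vectors (rows).
#' @return matrix of continuous activations in \[0, 1\], one fingerprint per
#'   row.
#' @export
generator_forward <- function(handle, z) {
  stopifnot(inherits(handle, "fp_network_handle"),
            !is.null(handle$generator_spec))
  out <- nn_forward(handle$net, as.matrix(z), training = FALSE,
                    want_caches = FALSE)$out
  m <- handle$generator_spec$mask
  if (!is.null(m)) out <- apply_mask(out, m)
  out
}

#' Substructure-preserving mask
#'
#' Encodes the fingerprint feature bits of a common substructure as a binary
#' `mask` vector (1 at substructure feature positions) plus its complement
#' `unmask`. Attached to a generator, the mask layer computes
#' `x * unmask + mask`, so masked positions are pinned to exactly 1 in every
#' generated fingerprint while all other positions pass through unchanged.
#'
#' @param positions 1-based positions of the substructure feature bits, or a
#'   logical/0-1 vector of full fingerprint length.
#' @param length fingerprint length (ignored when `positions` is already a
#'   full-length vector).
#' @return an object of class `fp_mcs_mask` with fields `mask` and `unmask`.
#' @examples
#' m <- mcs_mask(c(3, 7), length = 16)
#' sum(m$mask)          # 2
#' all(m$unmask == 1 - m$mask)
#' @export
mcs_mask <- function(positions, length = 168L) {
  if (length(positions) == length && all(positions %in% c(0, 1))) {
    mask <- as.numeric(positions)
  } else {
    positions <- as.integer(positions)
    stopifnot(all(positions >= 1L), all(positions <= length))
    mask <- numeric(length)
    mask[positions] <- 1
  }
  structure(list(mask = mask, unmask = 1 - mask), class = "fp_mcs_mask")
}

#' Mask from a substructure pattern
#'
#' Convenience wrapper that encodes a substructure (SMILES/SMARTS written as
#' SMILES) with [fp_encode()] and uses its set bits as the mask positions, so
#' generated fingerprints always contain the substructure's feature keys.
#'
#' @param smiles substructure as a SMILES string.
#' @param scheme fingerprint scheme (default MACCS).
#' @param length fingerprint length.
#' @return an `fp_mcs_mask`.
#' @export
mcs_mask_from_smiles <- function(smiles, scheme = "MACCS", length = 168L) {
  fp <- fp_encode(c(mcs = smiles), scheme = scheme, length = length)
  mcs_mask(as.numeric(fp$bits[1L, ]), length = length)
}

#' Apply a substructure mask to generator output
#'
#' Computes `x * unmask + mask` element-wise along each row: positions with
#' `mask = 1` become exactly 1, positions with `mask = 0` are unchanged. The
#' operation is idempotent.
#'
#' @param x matrix (rows are samples) or vector of continuous activations in
#'   \[0, 1\].
#' @param mask an `fp_mcs_mask`.
#' @return object of the same shape as `x`.
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(mask, "fp_mcs_mask"))
  if (is.matrix(x)) {
    if (ncol(x) != length(mask$mask)) stop("mask length does not match input")
    x * rep(mask$unmask, each = nrow(x)) + rep(mask$mask, each = nrow(x))
  } else {
    if (length(x) != length(mask$mask)) stop("mask length does not match input")
    x * mask$unmask + mask$mask
  }
}

#' Append a one-hot condition block
#'
#' Concatenates a one-hot encoding of a class label to each row of the
#' primary input (noise for the generator, fingerprint for the
#' discriminator).
#'
#' @param primary matrix (rows are samples) or single vector.
#' @param label integer class index in `1..n_classes` (scalar or one per
#'   row).
#' @param n_classes number of classes.
#' @return matrix with `n_classes` extra columns.
#' @examples
#' condition_join(matrix(0, 1, 3), 1, 2)  # appends [1, 0]
#' @export
condition_join <- function(primary, label, n_classes) {
  if (!is.matrix(primary)) primary <- matrix(primary, nrow = 1L)
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep(label, nrow(primary))
  stopifnot(length(label) == nrow(primary))
  if (any(label < 1L | label > n_classes)) {
    stop("condition label out of range 1..", n_classes)
  }
  cbind(primary, onehot(label, n_classes))
}
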