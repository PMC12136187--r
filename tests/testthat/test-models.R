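# Network engine correctness (gradients), architecture contracts, the mask
# layer and condition joining.

test_that("backpropagation matches finite differences on a mixed-layer net", {
  ns <- asNamespace("fpgan")
  set.seed(42)
  defs <- list(
    ns$nn_dense(24, "tanh"), ns$nn_reshape(2L),
    ns$nn_conv1d(3L, 3L, stride = 1L, pad = 1L, activation = "tanh"),
    ns$nn_batchnorm(), ns$nn_maxpool1d(2L), ns$nn_upsample1d(2L),
    ns$nn_conv1d(2L, 3L, stride = 2L, activation = "sigmoid"),
    ns$nn_flatten(), ns$nn_dense(2L)
  )
  net <- ns$nn_build(defs, 7L)
  x <- matrix(rnorm(5 * 7), 5)
  y <- ns$onehot(sample(1:2, 5, TRUE), 2L)
  loss_of <- function(net, xx) {
    fw <- ns$nn_forward(net, xx, training = TRUE, update_stats = FALSE)
    ns$softmax_ce(fw$out, y)$loss
  }
  fw <- ns$nn_forward(net, x, training = TRUE, update_stats = FALSE)
  bw <- ns$nn_backward(net, fw$caches, ns$softmax_ce(fw$out, y)$grad)
  eps <- 1e-6
  for (k in sample(seq_along(net$theta), 60)) {
    np <- net
    np$theta[k] <- np$theta[k] + eps
    lp <- loss_of(np, x)
    np$theta[k] <- np$theta[k] - 2 * eps
    lm <- loss_of(np, x)
    gnum <- (lp - lm) / (2 * eps)
    expect_lt(abs(gnum - bw$gtheta[k]),
              1e-4 * max(1, abs(gnum)))
  }
  for (k in sample(seq_along(x), 10)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    gnum <- (loss_of(net, xp) - loss_of(net, xm)) / (2 * eps)
    expect_lt(abs(gnum - bw$grad_in[k]), 1e-4 * max(1, abs(gnum)))
  }
})

test_that("all six discriminator variants share the input/output contract", {
  set.seed(1)
  x <- matrix(rbinom(32 * 168, 1, 0.3), 32)
  counts <- numeric(0)
  for (a in architecture_names()) {
    d <- build_discriminator(a, 168, seed = 1)
    p <- predict_scores(d, x)
    expect_equal(dim(p), c(32L, 2L))
    expect_equal(rowSums(p), rep(1, 32), tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
    counts[a] <- fpgan:::nn_n_params(d$net)
  }
  expect_lt(counts["VGGNet11"], counts["VGGNet13"])
  expect_lt(counts["VGGNet13"], counts["VGGNet16"])
  expect_error(build_discriminator("ResNet", 168), "arg")
})

test_that("an untrained discriminator scores at chance level", {
  dat <- make_synthetic_fpset(n_active = 400, n_inactive = 400, seed = 2)
  aucs <- vapply(1:10, function(s) {
    d <- build_discriminator("AlexNet", 168, seed = s)
    p <- predict_scores(d, dat$fps$bits)[, 1]
    classifier_metrics(dat$labels == "active", p)$auc
  }, numeric(1))
  # chance level: unbiased across seeds, no seed systematically separates
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
  expect_true(all(aucs > 0.25 & aucs < 0.75))
})

test_that("the generator is deterministic with outputs in [0, 1]", {
  g <- build_generator(generator_spec(output_length = 64L, noise_dim = 16L),
                       seed = 4)
  set.seed(9)
  z <- matrix(rnorm(10 * 16), 10)
  o1 <- generator_forward(g, z)
  o2 <- generator_forward(g, z)
  expect_identical(o1, o2)
  expect_true(all(o1 >= 0 & o1 <= 1))
  expect_equal(ncol(o1), 64L)
})

test_that("the mask layer pins substructure bits to exactly one", {
  m <- mcs_mask(c(3, 7, 10), length = 16)
  expect_identical(m$unmask, 1 - m$mask)
  x <- matrix(runif(5 * 16), 5)
  out <- apply_mask(x, m)
  expect_true(all(out[, c(3, 7, 10)] == 1))
  expect_identical(out[, -c(3, 7, 10)], x[, -c(3, 7, 10)])
  # formula edge cases and the element-wise oracle
  expect_identical(apply_mask(numeric(16), m), m$mask)
  zero_mask <- mcs_mask(integer(0), length = 16)
  expect_identical(apply_mask(x, zero_mask), x)
  oracle <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    oracle[i, j] <- x[i, j] * m$unmask[j] + m$mask[j]
  }
  expect_identical(out, oracle)
  # idempotence
  expect_identical(apply_mask(out, m), out)
  expect_error(apply_mask(matrix(0, 2, 8), m), "length")
})

test_that("masked generator output contains the mask at every threshold", {
  m <- mcs_mask(c(1, 5, 20, 40), length = 64)
  g <- build_generator(generator_spec(output_length = 64L, noise_dim = 8L,
                                      mask = m), seed = 2)
  set.seed(3)
  cont <- generator_forward(g, matrix(rnorm(20 * 8), 20))
  expect_true(all(cont[, c(1, 5, 20, 40)] == 1))
  for (thr in c(0.1, 0.5, 0.9)) {
    bits <- (cont >= thr) * 1
    for (i in 1:20) expect_true(bit_containment(m$mask, bits[i, ]))
  }
  # binarization is monotone in the threshold
  b_lo <- (cont >= 0.3) * 1
  b_hi <- (cont >= 0.7) * 1
  expect_true(all(b_hi <= b_lo))
})

test_that("condition_join appends exactly a one-hot block", {
  out <- condition_join(matrix(0, 1, 3), 1, 2)
  expect_identical(drop(out), c(0, 0, 0, 1, 0))
  x <- matrix(rnorm(6), 2, 3)
  j1 <- condition_join(x, c(1, 2), 4)
  expect_equal(ncol(j1), 7L)
  j2 <- condition_join(x, c(2, 1), 4)
  expect_identical(j1[, 1:3], j2[, 1:3])
  expect_false(identical(j1[, 4:7], j2[, 4:7]))
  expect_error(condition_join(x, 5, 4), "range")
})
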