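# Discriminator pretraining, the alternating GAN loop (freezing, null
# training), and fingerprint sampling.

test_that("training config validates its inputs", {
  expect_error(fp_training_config(batch_size = 0))
  expect_error(fp_training_config(d_learning_rate = -1))
  cfg <- fp_training_config(gan_epochs = 10)
  expect_s3_class(cfg, "fp_training_config")
  expect_identical(cfg$gan_epochs, 10L)
})

test_that("pretraining separates a perfectly separable fixture", {
  dat <- make_synthetic_fpset(n_active = 300, n_inactive = 300,
                              p_on_active = 1, p_on_inactive = 0,
                              background_p = 0.3, seed = 5)
  fit <- fp_discriminator(dat, architecture = "AlexNet", k = 2L,
                          epochs = 3L, config = tiny_config())
  expect_gte(fit$cv_means[["auc"]], 0.99)
  expect_equal(nrow(fit$cv), 2L)
  # prediction interface
  p <- predict(fit, dat$fps)
  expect_length(p, 600)
  expect_gt(mean(p[dat$labels == "active"]), mean(p[dat$labels == "inactive"]))
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  dat <- make_synthetic_fpset(n_active = 300, n_inactive = 300, seed = 6)
  set.seed(7)
  shuffled <- sample(dat$labels)
  fit <- fp_discriminator(dat$fps, shuffled, architecture = "LeNet5",
                          k = 2L, epochs = 2L, config = tiny_config())
  expect_gt(fit$cv_means[["auc"]], 0.4)
  expect_lt(fit$cv_means[["auc"]], 0.6)
})

test_that("the alternating loop freezes the network that is not training", {
  dat <- make_synthetic_fpset(n_active = 96, n_inactive = 0, length = 64,
                              signature_bits = 1:8, seed = 8)
  ns <- asNamespace("fpgan")
  gspec <- generator_spec(output_length = 64L, noise_dim = 8L)
  cfg <- fp_training_config(seed = 3)

  # zero generator rate: G parameters stay at initialisation, D moves
  fit_g0 <- fp_dcgan(dat, generator = gspec, config = cfg, epochs = 2L,
                     d_lr = 1e-3, g_lr = 0)
  g_init <- build_generator(gspec, seed = cfg$seed + 1L)
  d_init <- build_discriminator("AlexNet", 64L, seed = cfg$seed)
  expect_identical(fit_g0$generator$net$theta, g_init$net$theta)
  expect_false(identical(fit_g0$discriminator$net$theta, d_init$net$theta))

  # zero discriminator rate: D parameters stay, G moves
  fit_d0 <- fp_dcgan(dat, generator = gspec, config = cfg, epochs = 2L,
                     d_lr = 0, g_lr = 1e-3)
  expect_identical(fit_d0$discriminator$net$theta, d_init$net$theta)
  expect_false(identical(fit_d0$generator$net$theta, g_init$net$theta))
})

test_that("with both learning rates zero all losses are constant", {
  dat <- make_synthetic_fpset(n_active = 96, n_inactive = 0, length = 64,
                              seed = 9)
  fit <- fp_dcgan(dat, generator = generator_spec(output_length = 64L,
                                                  noise_dim = 8L),
                  config = fp_training_config(seed = 4), epochs = 4L,
                  d_lr = 0, g_lr = 0)
  expect_equal(diff(range(fit$log$d_loss)), 0)
  expect_equal(diff(range(fit$log$g_loss)), 0)
})

test_that("sampling is reproducible and respects the conditioning contract", {
  dat <- make_synthetic_fpset(n_active = 96, n_inactive = 0, length = 64,
                              seed = 10)
  fit <- fp_dcgan(dat, generator = generator_spec(output_length = 64L,
                                                  noise_dim = 8L),
                  config = tiny_config(4), epochs = 2L)
  s1 <- sample_fingerprints(fit, 25, seed = 42)
  s2 <- sample_fingerprints(fit, 25, seed = 42)
  expect_identical(s1$bits, s2$bits)
  expect_error(sample_fingerprints(fit, 5, seed = 1, label = "active"),
               "unconditional")

  # simulate() is the S3 route to the same draw
  s3 <- simulate(fit, nsim = 25, seed = 42)
  expect_identical(s3$bits, s1$bits)

  two <- two_signature_fixture(n_per_class = 96, length = 64)
  cfit <- fp_cdcgan(two, generator = generator_spec(output_length = 64L,
                                                    noise_dim = 8L),
                    config = tiny_config(5), epochs = 2L)
  expect_error(sample_fingerprints(cfit, 5, seed = 1), "label")
  expect_error(sample_fingerprints(cfit, 5, seed = 1, label = 7), "range")
  sc <- sample_fingerprints(cfit, 10, seed = 1, label = "active")
  expect_equal(nrow(sc$bits), 10L)
})

test_that("conditional training requires both classes", {
  dat <- make_synthetic_fpset(n_active = 50, n_inactive = 0, length = 64,
                              seed = 11)
  expect_error(fp_cdcgan(dat$fps, rep("active", 50),
                         config = tiny_config()),
               "both classes")
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  dat <- make_synthetic_fpset(n_active = 96, n_inactive = 0, length = 64,
                              seed = 13)
  fit <- fp_dcgan(dat, generator = generator_spec(output_length = 64L,
                                                  noise_dim = 8L),
                  config = tiny_config(7), epochs = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  write_fpgan_model(fit, path)
  back <- read_fpgan_model(path)
  expect_identical(sample_fingerprints(back, 10, seed = 2)$bits,
                   sample_fingerprints(fit, 10, seed = 2)$bits)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(sidecar$architecture, "AlexNet")
  expect_false(sidecar$conditional)
})

test_that("masked GAN samples always contain the mask bits", {
  dat <- make_synthetic_fpset(n_active = 96, n_inactive = 0, length = 64,
                              seed = 12)
  m <- mcs_mask(c(2, 17, 33), length = 64)
  fit <- fp_dcgan(dat, generator = generator_spec(output_length = 64L,
                                                  noise_dim = 8L),
                  mask = m, config = tiny_config(6), epochs = 2L)
  s <- sample_fingerprints(fit, 200, seed = 3)
  expect_true(all(s$bits[, c(2, 17, 33)] == 1))
})
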