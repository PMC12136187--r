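# Decoy matching, stratified folds and the synthetic fixture generators.

bimodal_pool <- function(seed = 1L, n_act = 300L, n_pool = 2000L) {
  set.seed(seed)
  list(
    act = data.frame(molecule_id = paste0("a", seq_len(n_act)),
                     MW = rnorm(n_act, 300, 15), logP = rnorm(n_act, 3, 0.4)),
    pool = data.frame(
      molecule_id = paste0("p", seq_len(n_pool)),
      MW = c(rnorm(n_pool / 2, 150, 15), rnorm(n_pool / 2, 300, 15)),
      logP = c(rnorm(n_pool / 2, 1, 0.4), rnorm(n_pool / 2, 3, 0.4)))
  )
}

test_that("decoy matching prefers the property mode occupied by the actives", {
  d <- bimodal_pool()
  sel <- match_decoys(d$act, d$pool, 300, seed = 5)
  expect_length(sel, 300)
  expect_false(anyDuplicated(sel) > 0)
  frac_matching_mode <- mean(as.integer(sub("p", "", sel)) > 1000)
  expect_gte(frac_matching_mode, 0.8)
})

test_that("decoy matching handles edge cases and is deterministic", {
  d <- bimodal_pool()
  expect_error(match_decoys(d$act, d$pool, 5000, seed = 1), "exceeds")
  degenerate <- d$act
  degenerate$MW <- 300
  expect_error(match_decoys(degenerate,
                            transform(d$pool, MW = 300), 10, seed = 1),
               "zero-variance")
  all_of_it <- match_decoys(d$act, d$pool, nrow(d$pool), seed = 2)
  expect_setequal(all_of_it, d$pool$molecule_id)
  expect_identical(match_decoys(d$act, d$pool, 50, seed = 7),
                   match_decoys(d$act, d$pool, 50, seed = 7))
})

test_that("stratified folds are exact partitions with balanced classes", {
  labels <- rep(c("active", "inactive"), c(10, 10))
  f <- stratified_kfold(labels, k = 10, seed = 1)
  per_fold <- table(f$fold, labels)
  expect_true(all(per_fold == 1))

  # the reference screening-set shape: 7002 actives + 9998 decoys
  labels2 <- rep(c("active", "inactive"), c(7002, 9998))
  f2 <- stratified_kfold(labels2, k = 10, seed = 3)
  sizes <- tabulate(f2$fold, 10)
  expect_true(all(sizes == 1700))
  act_per_fold <- tabulate(f2$fold[labels2 == "active"], 10)
  expect_true(all(act_per_fold %in% c(700, 701)))
  expect_identical(sort(unique(f2$fold)), 1:10)
  expect_length(f2$fold, 17000)

  expect_identical(stratified_kfold(labels2, k = 10, seed = 3)$fold, f2$fold)
  expect_error(stratified_kfold(rep(c("a", "b"), c(5, 100)), k = 10),
               "fewer than k")
})

test_that("synthetic fingerprint sets plant the configured signature", {
  sep <- make_synthetic_fpset(n_active = 200, n_inactive = 200,
                              signature_bits = 1:10, p_on_active = 1,
                              p_on_inactive = 0, background_p = 0, seed = 2)
  pop <- rowSums(sep$fps$bits[, 1:10])
  expect_true(all(pop[sep$labels == "active"] == 10))
  expect_true(all(pop[sep$labels == "inactive"] == 0))

  # equal on-rates leave no class signal
  flat <- make_synthetic_fpset(n_active = 1500, n_inactive = 1500,
                               p_on_active = 0.4, p_on_inactive = 0.4,
                               background_p = 0.4, seed = 4)
  dif <- abs(colMeans(flat$fps$bits[flat$labels == "active", ]) -
               colMeans(flat$fps$bits[flat$labels == "inactive", ]))
  expect_lt(mean(dif), 0.03)

  expect_identical(make_synthetic_fpset(seed = 9)$fps$bits,
                   make_synthetic_fpset(seed = 9)$fps$bits)
})

test_that("a one-bit decision stump separates the default fixture", {
  dat <- make_synthetic_fpset(seed = 6)
  # stump on the best signature bit; expected accuracy (0.9 + 0.9) / 2
  acc <- max(vapply(dat$signature_bits, function(b) {
    mean((dat$fps$bits[, b] == 1) == (dat$labels == "active"))
  }, numeric(1)))
  expect_gte(acc, 0.85)
})

test_that("the synthetic library records exact core ground truth", {
  all_core <- make_synthetic_library(n = 40, fraction_with_core = 1, seed = 1)
  expect_true(all(confirm_substructure(default_core_smarts(), all_core)))
  none <- make_synthetic_library(n = 40, fraction_with_core = 0, seed = 1)
  expect_false(any(confirm_substructure(default_core_smarts(), none)))

  lib <- make_synthetic_library(n = 150, fraction_with_core = 0.3, seed = 8)
  expect_equal(sum(lib$has_core), 45)
  expect_identical(unname(confirm_substructure(default_core_smarts(), lib)),
                   lib$has_core)
  expect_identical(make_synthetic_library(n = 50, seed = 3)$smiles,
                   make_synthetic_library(n = 50, seed = 3)$smiles)
  expect_error(make_synthetic_library(n = 10, planted_core_smarts = "c1cc"),
               "SMARTS")
})
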