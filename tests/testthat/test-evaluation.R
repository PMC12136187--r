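# Generation metrics, classifier metrics and drug-likeness properties.

test_that("uniqueness and novelty follow their set definitions", {
  A <- c(1, 0, 1)
  B <- c(0, 1, 1)
  C <- c(1, 1, 1)
  expect_equal(uniqueness(rbind(A, A, B)), 2 / 3)
  expect_equal(uniqueness(rbind(A, B, C)), 1)
  expect_equal(uniqueness(rbind(A, A, A, A)), 1 / 4)
  expect_error(uniqueness(matrix(0, 0, 3)), "empty")

  expect_equal(novelty(rbind(A, B), rbind(A, B, C)), 0)
  expect_equal(novelty(rbind(A, B), rbind(C)), 1)
  expect_equal(novelty(rbind(A, B, B, C), rbind(C)), 2 / 3)
})

test_that("diversity and similarity match the quadratic loop oracles", {
  one <- rbind(c(1, 1, 0), c(1, 1, 0))
  expect_equal(as.numeric(diversity(one)), 0)
  disjoint <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  expect_equal(as.numeric(diversity(disjoint)), 1)

  m <- random_fp_matrix(100, len = 48, seed = 13)
  acc <- 0; np <- 0
  for (i in 1:99) for (j in (i + 1):100) {
    acc <- acc + naive_tanimoto(m[i, ], m[j, ]); np <- np + 1
  }
  expect_equal(as.numeric(diversity(m)), 1 - acc / np, tolerance = 1e-12)
  expect_false(attr(diversity(m), "subsampled"))
  expect_true(attr(diversity(m, max_pairs = 100, seed = 1), "subsampled"))

  a <- random_fp_matrix(50, len = 48, seed = 14)
  b <- random_fp_matrix(50, len = 48, seed = 15)
  acc <- 0
  for (i in 1:50) for (j in 1:50) acc <- acc + naive_tanimoto(a[i, ], b[j, ])
  expect_equal(as.numeric(similarity_to_reference(a, b)), acc / 2500,
               tolerance = 1e-12)
  expect_equal(as.numeric(similarity_to_reference(rbind(c(1, 1)), rbind(c(1, 1)))), 1)
  expect_equal(as.numeric(similarity_to_reference(rbind(c(1, 0)), rbind(c(0, 1)))), 0)
})

test_that("subsampled pair metrics stay close to the exhaustive value", {
  m <- random_fp_matrix(400, len = 64, seed = 16)
  exact <- as.numeric(diversity(m))
  sub <- as.numeric(diversity(m, max_pairs = 2e4, seed = 2))
  expect_lt(abs(exact - sub), 0.02)
})

test_that("classifier metrics use midrank AUC consistent with pair counting", {
  expect_equal(classifier_metrics(c(TRUE, TRUE, FALSE), c(.9, .8, .1))$auc, 1)
  expect_equal(classifier_metrics(c(TRUE, FALSE), c(0, 1))$auc, 0)
  expect_error(classifier_metrics(c(TRUE, TRUE), c(.1, .2)), "both classes")

  set.seed(17)
  y <- runif(200) < 0.4
  s <- round(runif(200), 2)  # ties on purpose
  m <- classifier_metrics(y, s)
  # oracle: all-pairs concordance with half-credit ties
  pos <- s[y]; neg <- s[!y]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  expect_equal(m$auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)

  cf <- m$confusion
  expect_equal(m$accuracy, (cf["tp"] + cf["tn"]) / 200, ignore_attr = TRUE)
  expect_equal(m$precision, cf["tp"] / (cf["tp"] + cf["fp"]),
               ignore_attr = TRUE)
  expect_equal(m$recall, cf["tp"] / (cf["tp"] + cf["fn"]), ignore_attr = TRUE)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(sum(cf), 200)
})

test_that("drug-likeness properties are chemically sensible", {
  prof <- druglike_profile(c(benzene = "c1ccccc1", ethanol = "CCO",
                             aspirin = drug_smiles[["aspirin"]]))
  expect_equal(prof$MW[1], 78.11, tolerance = 1e-3)
  expect_equal(prof$TPSA[2], 20.23, tolerance = 1e-6)
  expect_true(prof$lipinski_pass[3])
  expect_true(all(prof$QED >= 0 & prof$QED <= 1))
  expect_equal(prof$HBD[2], 1)
  expect_equal(prof$AROM, c(1, 0, 1))
})

test_that("report generation is pure", {
  gen <- random_fp_matrix(60, len = 32, seed = 18)
  trn <- random_fp_matrix(40, len = 32, seed = 19)
  r1 <- generation_report(gen, trn)
  r2 <- generation_report(gen, trn)
  expect_identical(r1, r2)
  expect_true(all(unlist(r1[1, 1:4]) >= 0 & unlist(r1[1, 1:4]) <= 1))
  expect_equal(r1$n_samples, 60)
})
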