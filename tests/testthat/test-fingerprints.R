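# Fingerprint encoding, Tanimoto similarity, containment, substructure
# confirmation and serialization.

test_that("MACCS encoding matches the toolkit keys, padded to 168 bits", {
  fp <- fp_encode(drug_smiles, scheme = "MACCS")
  expect_s3_class(fp, "fp_set")
  expect_equal(dim(fp$bits), c(length(drug_smiles), 168L))
  expect_true(all(fp$bits %in% 0:1))

  # oracle: the toolkit's raw MACCS bit matrix, zero-padded above key 166
  mols <- ChemmineOB::forEachMol(
    "SMILES", paste(drug_smiles, names(drug_smiles), sep = "\t",
                    collapse = "\n"), identity)
  raw <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  expect_true(all(raw[, 169:ncol(raw)] == 0))
  expect_equal(unname(fp$bits), unname(raw[, 1:168]), ignore_attr = TRUE)

  # positions above the native key range are constant padding
  expect_true(all(fp$bits[, 167:168] == 0))
})

test_that("encoding is canonical and methane is a near-empty fingerprint", {
  fp <- fp_encode(c(e1 = "CCO", e2 = "OCC", methane = "C"))
  expect_identical(fp$bits[1, ], fp$bits[2, ])
  expect_lte(sum(fp$bits[3, ]), 3)
  expect_gte(sum(fp$bits[1, ]), 5)
})

test_that("FP2 encoding is 1024-bit, deterministic, and near-empty for methane", {
  fp <- fp_encode(c(m = "C", tol = "Cc1ccccc1", tol2 = "Cc1ccccc1"),
                  scheme = "FP2")
  expect_equal(ncol(fp$bits), 1024L)
  expect_equal(sum(fp$bits[1, ]), 0)
  expect_identical(fp$bits[2, ], fp$bits[3, ])
})

test_that("unparsable SMILES raise an error naming the offender", {
  expect_error(fp_encode(c(ok = "CCO", bad = "C1CC")), "bad")
  expect_error(fp_encode(c(x = "")), "empty")
})

test_that("tanimoto follows the set definition with an all-zero convention", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  a <- c(1, 0, 1, 1)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  f1 <- fp_set(matrix(c(1L, 1L), 1), "MACCS")
  f2 <- fp_set(matrix(c(1L, 1L), 1), "FP2")
  expect_error(tanimoto(f1, f2), "comparable")
})

test_that("tanimoto agrees exactly with the per-bit loop oracle", {
  m <- random_fp_matrix(60, len = 40, seed = 5)
  for (r in 1:200) {
    i <- sample(60, 1); j <- sample(60, 1)
    expect_identical(tanimoto(m[i, ], m[j, ]), naive_tanimoto(m[i, ], m[j, ]))
  }
  # symmetry and range on the full matrix
  ts <- fpgan:::tanimoto_matrix(m)
  expect_true(all(abs(ts - t(ts)) < 1e-15))
  expect_true(all(ts >= 0 & ts <= 1))
})

test_that("bit containment is the no-false-negative substructure screen", {
  expect_true(bit_containment(c(0, 0, 0), c(1, 0, 1)))
  expect_true(bit_containment(c(1, 0, 1), c(1, 0, 1)))
  expect_false(bit_containment(c(1, 1, 0), c(1, 0, 1)))

  # screening with substitution-stable core keys has no false negatives:
  # every molecule that truly contains the core passes the bit screen
  exemplars <- make_synthetic_library(n = 12, fraction_with_core = 1,
                                      seed = 99)
  screen <- mcs_screen_bits(default_core_smarts(), exemplars)
  expect_gte(sum(screen), 20)
  lib <- make_synthetic_library(n = 60, fraction_with_core = 0.5, seed = 3)
  lib_fp <- fp_encode(lib)
  for (i in which(lib$has_core)) {
    expect_true(bit_containment(screen, lib_fp$bits[i, ]))
  }
  # the raw pattern bits are a superset of the stable screen
  core_fp <- fp_encode(c(core = default_core_smarts()))
  expect_true(bit_containment(screen, core_fp$bits[1, ]))
})

test_that("substructure confirmation is exact subgraph matching", {
  res <- confirm_substructure("c1ccccc1",
                              c(toluene = "Cc1ccccc1", chx = "C1CCCCC1"))
  expect_identical(unname(res), c(TRUE, FALSE))
  expect_error(confirm_substructure("c1cc", c(a = "CCO")), "SMARTS")

  lib <- make_synthetic_library(n = 80, fraction_with_core = 0.35, seed = 9)
  conf <- confirm_substructure(default_core_smarts(), lib)
  expect_identical(unname(conf), lib$has_core)
})

test_that("fingerprint CSV serialization round-trips", {
  fp <- fp_encode(drug_smiles[1:5])
  path <- withr::local_tempfile(fileext = ".csv")
  write_fingerprints(fp, path)
  back <- read_fingerprints(path)
  expect_identical(back$bits, fp$bits)
  expect_identical(back$scheme, fp$scheme)
  # unseparated 0/1 strings, first position written first
  row1 <- utils::read.csv(path, colClasses = "character")$bitstring[1]
  expect_equal(nchar(row1), 168L)
  expect_identical(substr(row1, 1, 8),
                   paste0(fp$bits[1, 1:8], collapse = ""))
})
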