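# Banded similarity search, two-round substructure confirmation and
# candidate ranking.

small_search_fixture <- function(seed = 21L) {
  lib <- make_synthetic_library(n = 150, fraction_with_core = 0.4,
                                seed = seed)
  lib_fp <- fp_encode(lib)
  queries <- lib_fp[seq(1, 150, by = 15)]  # 10 library members as queries
  list(lib = lib, lib_fp = lib_fp, queries = queries)
}

test_that("an exact library match scores 1.0 in the top band", {
  fx <- small_search_fixture()
  res <- search_library(fx$queries, fx$lib,
                        thresholds = c(0.70, 0.75, 0.80, 0.85))
  expect_s3_class(res, "fp_search_result")
  top <- res$hits[res$hits$ts == 1, ]
  expect_gte(nrow(top), length(fx$queries))
  expect_true(all(top$band == 0.85))
})

test_that("band counts are nested and equal the brute-force double loop", {
  fx <- small_search_fixture()
  thresholds <- c(0.5, 0.6, 0.7, 0.8)
  res <- search_library(fx$queries, fx$lib, thresholds = thresholds)
  expect_true(all(diff(res$band_counts$count) <= 0))

  qb <- fx$queries$bits
  max_ts <- vapply(seq_len(nrow(fx$lib_fp$bits)), function(i) {
    max(vapply(seq_len(nrow(qb)), function(j) {
      naive_tanimoto(fx$lib_fp$bits[i, ], qb[j, ])
    }, numeric(1)))
  }, numeric(1))
  oracle_counts <- vapply(thresholds, function(t) sum(max_ts >= t), 0L)
  expect_identical(res$band_counts$count, oracle_counts)

  # hit sets nested across thresholds
  for (k in 2:length(thresholds)) {
    hi <- res$hits$molecule_id[res$hits$ts >= thresholds[k]]
    lo <- res$hits$molecule_id[res$hits$ts >= thresholds[k - 1]]
    expect_true(all(hi %in% lo))
  }
  # every hit satisfies ts >= band
  expect_true(all(res$hits$ts >= res$hits$band))
})

test_that("a permissive single threshold returns the whole library once", {
  fx <- small_search_fixture()
  res <- search_library(fx$queries[1], fx$lib, thresholds = 1e-9)
  expect_equal(sort(res$hits$molecule_id), sort(fx$lib$molecule_id))
  expect_false(anyDuplicated(res$hits$molecule_id) > 0)
})

test_that("unparsable library molecules are skipped and counted", {
  fx <- small_search_fixture()
  lib <- rbind(fx$lib[1:20, c("molecule_id", "smiles", "source")],
               data.frame(molecule_id = "broken", smiles = "C1CC",
                          source = "x"))
  res <- search_library(fx$queries, lib, thresholds = c(0.5, 0.8))
  expect_equal(res$n_skipped, 1L)
  expect_equal(res$n_library, 20L)
  expect_error(search_library(fx$queries, fx$lib, thresholds = c(0.8, 0.5)),
               "ascending")
})

test_that("two-round confirmation recovers exactly the planted-core subset", {
  fx <- small_search_fixture()
  res <- search_library(fx$queries, fx$lib, thresholds = c(0.3, 0.5, 0.7))
  res <- mcs_confirm_hits(res, fx$lib, default_core_smarts())
  truth <- fx$lib$has_core[match(res$hits$molecule_id, fx$lib$molecule_id)]
  expect_identical(res$hits$mcs_confirmed, truth)
  # confirmation filters, never adds
  expect_lte(sum(res$hits$mcs_confirmed), nrow(res$hits))
  # a pattern absent from every molecule confirms nothing
  res2 <- mcs_confirm_hits(res, fx$lib, "c1ccc2c(c1)ccc1ccccc12")  # anthracene
  expect_false(any(res2$hits$mcs_confirmed))
})

test_that("candidates rank by similarity, then QED, then id", {
  hits <- data.frame(query_id = "q", molecule_id = c("m1", "m2", "m3", "m4"),
                     ts = c(0.9, 0.9, 0.95, 0.9),
                     band = 0.85, stringsAsFactors = FALSE)
  res <- structure(list(hits = hits, band_counts = data.frame(),
                        n_library = 4L, n_skipped = 0L),
                   class = "fp_search_result")
  profiles <- data.frame(molecule_id = c("m1", "m2", "m3", "m4"),
                         QED = c(0.5, 0.8, 0.1, 0.5))
  ranked <- rank_candidates(res, profiles, top_n = 10)
  expect_identical(ranked$molecule_id, c("m3", "m2", "m1", "m4"))
  expect_equal(nrow(rank_candidates(res, profiles, top_n = 2)), 2L)

  # reference: naive order() on the same keys
  o <- order(-hits$ts, -profiles$QED[match(hits$molecule_id,
                                           profiles$molecule_id)],
             hits$molecule_id)
  expect_identical(ranked$molecule_id, hits$molecule_id[o])
  expect_error(rank_candidates(res, profiles[1:2, ], top_n = 2), "missing")
})
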