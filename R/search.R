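# Similarity search of generated fingerprints against a compound library at
# banded Tanimoto thresholds, two-round substructure confirmation, and
# candidate ranking.

#' Tanimoto similarity search against a compound library
#'
#' Encodes the library with the queries' fingerprint scheme, computes each
#' library molecule's maximum Tanimoto similarity over all queries, and
#' reports every molecule clearing the lowest threshold together with the
#' highest threshold band it clears. Band counts are counts of *distinct*
#' library molecules, so they are non-increasing as the threshold rises and
#' the hit sets are nested.
#'
#' @param queries generated fingerprints (an [fp_set()]).
#' @param library a [molecule_records()] table (or any data.frame with
#'   `molecule_id`, `smiles`), or an [fp_set()] of pre-encoded fingerprints.
#' @param thresholds ascending similarity thresholds in (0, 1\].
#' @param mw_range optional `c(low, high)` molecular-weight window applied
#'   before counting (requires a SMILES library).
#' @return list of class `fp_search_result`: `hits` (data.frame `query_id`,
#'   `molecule_id`, `ts`, `band`), `band_counts` (data.frame `threshold`,
#'   `count`), `n_library`, `n_skipped`.
#' @export
search_library <- function(queries, library,
                           thresholds = c(0.70, 0.75, 0.80, 0.85),
                           mw_range = NULL) {
  stopifnot(inherits(queries, "fp_set"), length(queries) > 0L)
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must be strictly ascending and in (0, 1]")
  }

  n_skipped <- 0L
  if (inherits(library, "fp_set")) {
    lib_fp <- library
    lib_ids <- library$ids
    if (!is.null(mw_range)) {
      stop("mw_range filtering needs a SMILES library, not pre-encoded fingerprints")
    }
  } else {
    stopifnot(is.data.frame(library), nrow(library) > 0L)
    # batch parse first; fall back to per-molecule screening only on failure
    batch_ok <- !inherits(
      tryCatch(ob_parse(library$smiles, library$molecule_id),
               error = identity), "error")
    parseable <- if (batch_ok) rep(TRUE, nrow(library)) else {
      vapply(seq_len(nrow(library)), function(i) {
        !inherits(tryCatch(ob_parse(library$smiles[i], library$molecule_id[i]),
                           error = identity), "error")
      }, TRUE)
    }
    n_skipped <- sum(!parseable)
    lib <- library[parseable, , drop = FALSE]
    if (nrow(lib) == 0L) stop("no parseable molecules in the library")
    if (!is.null(mw_range)) {
      props <- property_table(lib)
      keep <- props$MW >= mw_range[1L] & props$MW <= mw_range[2L]
      lib <- lib[keep, , drop = FALSE]
      if (nrow(lib) == 0L) stop("no library molecules inside mw_range")
    }
    lib_fp <- fp_encode(lib, scheme = queries$scheme,
                        length = ncol(queries$bits))
    lib_ids <- lib$molecule_id
  }
  fp_check_comparable(queries, lib_fp)

  ts <- tanimoto_matrix(lib_fp$bits, queries$bits)  # n_lib x n_query
  max_ts <- apply(ts, 1L, max)
  best_q <- queries$ids[max.col(ts, ties.method = "first")]

  band_counts <- data.frame(
    threshold = thresholds,
    count = vapply(thresholds, function(t) sum(max_ts >= t), 0L)
  )
  sel <- max_ts >= thresholds[1L]
  band <- vapply(max_ts[sel], function(s) max(thresholds[thresholds <= s]),
                 numeric(1L))
  hits <- data.frame(query_id = best_q[sel], molecule_id = lib_ids[sel],
                     ts = max_ts[sel], band = band,
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$ts, hits$molecule_id), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, band_counts = band_counts,
                 n_library = length(max_ts), n_skipped = n_skipped,
                 thresholds = thresholds),
            class = "fp_search_result")
}

#' @export
print.fp_search_result <- function(x, ...) {
  cat("<fp_search_result: ", nrow(x$hits), " hits over ", x$n_library,
      " library molecules", if (x$n_skipped > 0L)
        paste0(" (", x$n_skipped, " unparsable, skipped)"), ">\n", sep = "")
  print(x$band_counts, row.names = FALSE)
  invisible(x)
}

#' Two-round substructure confirmation of search hits
#'
#' Flags every hit with whether its molecule truly contains the common
#' substructure: a fast FP2 bit-containment screen (no false negatives)
#' followed by exact subgraph matching on the molecules passing the screen.
#'
#' @param result an [search_library()] result.
#' @param library the molecule table the search ran against (lookup by
#'   `molecule_id`).
#' @param mcs_smarts substructure pattern (SMARTS, or SMILES used as
#'   SMARTS).
#' @return the search result with a logical `mcs_confirmed` column added to
#'   `hits`, plus `n_screened` (hits passing the FP2 screen).
#' @export
mcs_confirm_hits <- function(result, library, mcs_smarts) {
  stopifnot(inherits(result, "fp_search_result"))
  hits <- result$hits
  idx <- match(hits$molecule_id, library$molecule_id)
  if (anyNA(idx)) {
    stop("missing molecule records for hits: ",
         paste(utils::head(hits$molecule_id[is.na(idx)], 3L), collapse = ", "))
  }
  confirmed <- logical(nrow(hits))
  screened <- logical(nrow(hits))
  if (nrow(hits) > 0L) {
    mols <- library[idx, , drop = FALSE]
    pat_fp <- fp_encode(c(mcs = mcs_smarts), scheme = "FP2")
    mol_fp <- fp_encode(mols, scheme = "FP2")
    qbits <- which(pat_fp$bits[1L, ] == 1L)
    screened <- rowSums(mol_fp$bits[, qbits, drop = FALSE]) == length(qbits)
    if (any(screened)) {
      confirmed[screened] <-
        unname(confirm_substructure(mcs_smarts, mols[screened, , drop = FALSE]))
    }
  }
  result$hits$mcs_confirmed <- confirmed
  result$n_screened <- sum(screened)
  result
}

#' Rank retrieved candidates
#'
#' Sorts hits by Tanimoto similarity, breaking ties by drug-likeness (QED)
#' and then by molecule id for determinism, and returns the top rows.
#'
#' @param result an [search_library()] result (optionally after
#'   [mcs_confirm_hits()]; confirmed-only filtering via `confirmed_only`).
#' @param profiles a [druglike_profile()] table covering all hit molecules.
#' @param top_n number of candidates to return.
#' @param confirmed_only keep only substructure-confirmed hits.
#' @return data.frame of the top candidates with `ts` and `QED` columns.
#' @export
rank_candidates <- function(result, profiles, top_n = 10L,
                            confirmed_only = FALSE) {
  stopifnot(inherits(result, "fp_search_result"), top_n > 0L)
  hits <- result$hits
  if (confirmed_only) {
    if (is.null(hits$mcs_confirmed)) {
      stop("run mcs_confirm_hits() before confirmed_only ranking")
    }
    hits <- hits[hits$mcs_confirmed, , drop = FALSE]
  }
  idx <- match(hits$molecule_id, profiles$molecule_id)
  if (anyNA(idx)) {
    stop("druglike profiles missing for some hit molecules")
  }
  hits$QED <- profiles$QED[idx]
  hits <- hits[order(-hits$ts, -hits$QED, hits$molecule_id), , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, top_n)
}
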