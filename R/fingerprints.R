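# Binary molecular fingerprints: encoding through Open Babel (ChemmineOB),
# Tanimoto similarity, bit containment, and exact substructure confirmation.

fp_scheme_lengths <- c(MACCS = 168L, FP2 = 1024L)

#' Fingerprint set
#'
#' A set of fixed-length binary fingerprints sharing one scheme. `bits` is an
#' integer 0/1 matrix with one fingerprint per row; `ids` names the rows.
#' MACCS fingerprints are 168 bits long by convention here: Open Babel emits
#' the 166 canonical MACCS keys (key k at position k) and the remaining
#' positions are constant-zero padding, so the full key dictionary is always
#' contained in the declared length.
#'
#' @param bits 0/1 matrix, one fingerprint per row.
#' @param scheme `"MACCS"` or `"FP2"`.
#' @param ids character vector of molecule ids (defaults to rownames or
#'   `fp<i>`).
#' @return an object of class `fp_set`.
#' @export
fp_set <- function(bits, scheme = c("MACCS", "FP2"), ids = NULL) {
  scheme <- match.arg(scheme)
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0L, 1L))) stop("fingerprint bits must be 0 or 1")
  storage.mode(bits) <- "integer"
  if (is.null(ids)) ids <- rownames(bits) %||% paste0("fp", seq_len(nrow(bits)))
  stopifnot(length(ids) == nrow(bits))
  rownames(bits) <- ids
  structure(list(bits = bits, scheme = scheme, ids = as.character(ids)),
            class = "fp_set")
}

#' @export
print.fp_set <- function(x, ...) {
  cat("<fp_set: ", nrow(x$bits), " x ", ncol(x$bits), " bits, scheme ",
      x$scheme, ">\n", sep = "")
  cat("  mean popcount: ", round(mean(rowSums(x$bits)), 1), "\n", sep = "")
  invisible(x)
}

#' @export
`[.fp_set` <- function(x, i, ...) {
  fp_set(x$bits[i, , drop = FALSE], scheme = x$scheme, ids = x$ids[i])
}

#' @export
as.matrix.fp_set <- function(x, ...) x$bits

#' @export
length.fp_set <- function(x) nrow(x$bits)

fp_check_comparable <- function(a, b) {
  if (inherits(a, "fp_set") && inherits(b, "fp_set") && a$scheme != b$scheme) {
    stop("fingerprints are not comparable: schemes ", a$scheme, " and ",
         b$scheme, " differ")
  }
  dim_of <- function(x) {
    if (inherits(x, "fp_set")) ncol(x$bits)
    else if (is.matrix(x)) ncol(x)
    else length(x)
  }
  la <- dim_of(a)
  lb <- dim_of(b)
  if (la != lb) stop("fingerprints are not comparable: lengths ", la,
                     " and ", lb, " differ")
  invisible(TRUE)
}

# ---- molecule parsing --------------------------------------------------------

# Builds Open Babel molecule handles from SMILES. On a batch parse failure,
# re-parses one-by-one to name the offending input.
ob_parse <- function(smiles, ids = names(smiles)) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  bad <- is.na(smiles) | !nzchar(trimws(smiles))
  if (any(bad)) {
    stop("unparsable SMILES for ", paste(ids[bad], collapse = ", "),
         ": empty or missing string")
  }
  txt <- paste(smiles, ids, sep = "\t", collapse = "\n")
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", txt, identity),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) != length(smiles)) {
    for (i in seq_along(smiles)) {
      one <- tryCatch(
        ChemmineOB::forEachMol("SMILES", paste(smiles[i], ids[i], sep = "\t"),
                               identity),
        error = function(e) NULL
      )
      if (is.null(one)) {
        stop("unparsable SMILES for molecule '", ids[i], "': ", smiles[i])
      }
    }
    stop("SMILES parsing failed for an undetermined input")
  }
  names(mols) <- ids
  mols
}

as_molecule_input <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("molecule_id", "smiles") %in% names(x)))
    list(smiles = as.character(x$smiles), ids = as.character(x$molecule_id))
  } else {
    ids <- names(x) %||% paste0("mol", seq_along(x))
    list(smiles = as.character(x), ids = ids)
  }
}

# ---- encoding ----------------------------------------------------------------

#' Encode molecules as binary fingerprints
#'
#' Computes MACCS-key (default, 168 bits with the 166 canonical keys at
#' positions 1-166 and constant-zero padding above) or path-based FP2
#' (1024 bits) fingerprints through Open Babel. Encoding is deterministic for
#' a given structure: different SMILES spellings of the same molecule give
#' identical fingerprints.
#'
#' @param x character vector of SMILES (optionally named with molecule ids)
#'   or a molecule table (data.frame with columns `molecule_id`, `smiles`,
#'   e.g. from [read_molecules()] or [make_synthetic_library()]).
#' @param scheme `"MACCS"` or `"FP2"`.
#' @param length fingerprint length; defaults to the scheme length (168 for
#'   MACCS, 1024 for FP2). For MACCS any length at or above the native key
#'   count is accepted and zero-padded.
#' @return an [fp_set()].
#' @examples
#' \donttest{
#' fp <- fp_encode(c(ethanol = "CCO", toluene = "Cc1ccccc1"))
#' rowSums(as.matrix(fp))
#' }
#' @export
fp_encode <- function(x, scheme = c("MACCS", "FP2"), length = NULL) {
  scheme <- match.arg(scheme)
  inp <- as_molecule_input(x)
  mols <- ob_parse(inp$smiles, inp$ids)
  m <- ChemmineOB::fingerprint_OB(mols, scheme)
  if (is.vector(m)) m <- matrix(m, nrow = 1L)
  if (scheme == "MACCS") {
    length <- as.integer(length %||% fp_scheme_lengths[["MACCS"]])
    used <- which(colSums(m) > 0)
    native <- if (base::length(used)) max(used) else 0L
    if (length < native) {
      stop("requested MACCS length ", length, " is below the highest native ",
           "key position ", native)
    }
    out <- matrix(0L, nrow(m), length)
    out[, seq_len(min(ncol(m), length))] <-
      m[, seq_len(min(ncol(m), length)), drop = FALSE]
  } else {
    length <- as.integer(length %||% fp_scheme_lengths[["FP2"]])
    if (length != ncol(m)) {
      stop("FP2 fingerprints are ", ncol(m), " bits; length ", length,
           " is not supported")
    }
    out <- m
    storage.mode(out) <- "integer"
  }
  fp_set(out, scheme = scheme, ids = inp$ids)
}

# ---- similarity --------------------------------------------------------------

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over set bits. Symmetric, in \[0, 1\], and defined
#' as 0 when both fingerprints are all-zero (so empty generated fingerprints
#' never rank as perfect hits). Fingerprints must share scheme and length.
#'
#' @param a,b 0/1 vectors, or single-fingerprint [fp_set()] objects.
#' @return similarity score in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0), c(1, 0, 1))  # 1/3
#' @export
tanimoto <- function(a, b) {
  fp_check_comparable(a, b)
  if (inherits(a, "fp_set")) a <- as.numeric(a$bits[1L, ])
  if (inherits(b, "fp_set")) b <- as.numeric(b$bits[1L, ])
  inter <- sum(a * b)
  union <- sum(a) + sum(b) - inter
  if (union == 0) 0 else inter / union
}

# All-pairs Tanimoto between the rows of A and the rows of B (or of A with
# itself when B is NULL). Zero-union pairs score 0.
tanimoto_matrix <- function(a, b = NULL) {
  A <- if (inherits(a, "fp_set")) a$bits else as.matrix(a)
  storage.mode(A) <- "double"
  if (is.null(b)) {
    inter <- tcrossprod(A)
    pc <- rowSums(A)
    union <- outer(pc, pc, "+") - inter
  } else {
    if (!is.null(b)) fp_check_comparable(a, b)
    B <- if (inherits(b, "fp_set")) b$bits else as.matrix(b)
    storage.mode(B) <- "double"
    inter <- tcrossprod(A, B)
    union <- outer(rowSums(A), rowSums(B), "+") - inter
  }
  ts <- inter / union
  ts[union == 0] <- 0
  ts
}

#' Bit containment of one fingerprint in another
#'
#' `TRUE` iff every set bit of `query` is also set in `candidate` - the
#' fingerprint-level necessary condition for substructure containment, used
#' as a fast screen before exact subgraph confirmation
#' ([confirm_substructure()]).
#'
#' @param query,candidate 0/1 vectors or single-fingerprint [fp_set()]
#'   objects sharing one scheme.
#' @return logical.
#' @export
bit_containment <- function(query, candidate) {
  fp_check_comparable(query, candidate)
  if (inherits(query, "fp_set")) query <- as.numeric(query$bits[1L, ])
  if (inherits(candidate, "fp_set")) candidate <- as.numeric(candidate$bits[1L, ])
  all(candidate[query == 1] == 1)
}

# ---- substructure confirmation ----------------------------------------------

#' Exact substructure confirmation
#'
#' Tests whether candidate molecules contain a substructure pattern by exact
#' subgraph matching (Open Babel SMARTS engine). This is the authoritative
#' second-round check run after fingerprint screening: folded-fingerprint
#' containment can collide, subgraph isomorphism cannot.
#'
#' @param pattern substructure as a SMARTS (or SMILES) string.
#' @param candidates character vector of SMILES (optionally named) or a
#'   molecule table with columns `molecule_id`, `smiles`.
#' @return named logical vector, one element per candidate.
#' @examples
#' \donttest{
#' confirm_substructure("c1ccccc1", c(toluene = "Cc1ccccc1", chx = "C1CCCCC1"))
#' }
#' @export
confirm_substructure <- function(pattern, candidates) {
  stopifnot(is.character(pattern), base::length(pattern) == 1L, nzchar(pattern))
  inp <- as_molecule_input(candidates)
  mols <- ob_parse(inp$smiles, inp$ids)
  n <- tryCatch(
    ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE),
    error = function(e) stop("unparsable SMARTS pattern: ", pattern)
  )
  stats::setNames(n >= 1, inp$ids)
}

#' Substitution-stable screening keys for a substructure pattern
#'
#' Key-based fingerprints of a bare substructure (encoded as a molecule) can
#' contain hydrogen-count keys that vanish once the attachment points are
#' substituted - e.g. a primary-amide key set for `O=C(N)c1cc[nH]n1` is
#' absent from every N-substituted analogue, so screening with the raw
#' pattern bits would produce false negatives. This helper intersects the
#' pattern's bits with the bits of exemplar molecules known to contain the
#' pattern, keeping only the substitution-stable keys; [bit_containment()]
#' screening with these keys has no false negatives on the exemplified
#' substitution contexts.
#'
#' @param pattern substructure as SMILES.
#' @param exemplars SMILES vector or molecule table of molecules containing
#'   the pattern.
#' @param scheme,length fingerprint scheme and length (see [fp_encode()]).
#' @return 0/1 vector of screening keys.
#' @export
mcs_screen_bits <- function(pattern, exemplars, scheme = "MACCS",
                            length = NULL) {
  bits <- fp_encode(c(pattern = pattern), scheme = scheme,
                    length = length)$bits[1L, ]
  ex <- fp_encode(exemplars, scheme = scheme, length = length)$bits
  stable <- bits == 1L & colSums(ex) == nrow(ex)
  as.integer(stable)
}

# ---- serialization -----------------------------------------------------------

#' Read and write fingerprint sets as CSV
#'
#' Fingerprints are serialized as CSV with columns `id`, `scheme`,
#' `bitstring`, where `bitstring` is an unseparated 0/1 string with the
#' most significant position (bit 1) written first.
#'
#' @param fps an [fp_set()].
#' @param path file path.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns an [fp_set()].
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(inherits(fps, "fp_set"))
  bitstring <- apply(fps$bits, 1L, paste0, collapse = "")
  utils::write.csv(
    data.frame(id = fps$ids, scheme = fps$scheme, bitstring = bitstring,
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bitstring = "character"))
  scheme <- unique(df$scheme)
  if (base::length(scheme) != 1L) stop("mixed fingerprint schemes in ", path)
  bits <- do.call(rbind, lapply(strsplit(df$bitstring, ""), as.integer))
  fp_set(bits, scheme = scheme, ids = df$id)
}
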