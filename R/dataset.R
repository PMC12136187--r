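# Training-set construction: property-matched decoy selection, stratified
# k-fold assignment, and the synthetic fixture generators (labeled
# fingerprint sets and toy SMILES libraries with planted substructures).

#' Property-matched decoy selection
#'
#' Selects decoys from a candidate pool so that their joint molecular-weight
#' / logP distribution matches the actives'. MW and logP are z-scored jointly
#' over actives and pool (the two properties are on incommensurate scales),
#' projected onto the first principal component of the active set, and pool
#' members are drawn without replacement with probability proportional to a
#' Gaussian kernel density estimate (Scott's bandwidth) of the active scores
#' evaluated at each pool member's score.
#'
#' @param active_props,pool_props property tables (data.frames with columns
#'   `molecule_id`, `MW`, `logP`, e.g. from [property_table()]).
#' @param n_select number of decoys to draw (at most the pool size).
#' @param seed integer seed; all randomness in the draw flows through it.
#' @return character vector of `n_select` selected pool `molecule_id`s.
#' @export
match_decoys <- function(active_props, pool_props, n_select, seed = 1L) {
  stopifnot(nrow(active_props) > 0L, nrow(pool_props) > 0L)
  n_select <- as.integer(n_select)
  if (n_select > nrow(pool_props)) {
    stop("n_select (", n_select, ") exceeds the pool size (",
         nrow(pool_props), ")")
  }
  X <- rbind(as.matrix(active_props[, c("MW", "logP")]),
             as.matrix(pool_props[, c("MW", "logP")]))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (zero-variance) property column: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  na <- nrow(active_props)
  Za <- Z[seq_len(na), , drop = FALSE]
  pc <- stats::prcomp(Za, center = TRUE, scale. = FALSE)
  score <- function(z) {
    sweep(z, 2L, pc$center) %*% pc$rotation[, 1L]
  }
  s_act <- drop(score(Za))
  s_pool <- drop(score(Z[-seq_len(na), , drop = FALSE]))
  h <- stats::bw.nrd(s_act)  # Scott's rule-of-thumb bandwidth
  # exact Gaussian KDE of the active scores, evaluated at the pool scores
  w <- vapply(s_pool, function(s) mean(stats::dnorm((s - s_act) / h)) / h,
              numeric(1L))
  w <- w + 1e-12  # keep far-out pool members drawable when all weights vanish
  set.seed(seed)
  sel <- sample.int(length(s_pool), n_select, replace = FALSE, prob = w)
  as.character(pool_props$molecule_id[sel])
}

#' Stratified k-fold assignment
#'
#' Partitions rows into `k` folds preserving class proportions: per-fold
#' class counts differ from exact proportionality by at most one, and the
#' per-class remainders are distributed cyclically across classes so total
#' fold sizes are as equal as possible (e.g. a 7002/9998 two-class vector
#' under `k = 10` gives ten folds of exactly 1700 rows with 700 or 701
#' members of the first class).
#'
#' @param labels class vector (factor, character or integer).
#' @param k number of folds (`k >= 2`; every class needs at least `k`
#'   members).
#' @param seed integer seed for the within-class shuffle.
#' @return an object of class `fp_folds`: list with `fold` (integer vector in
#'   `1..k`, one per row) and `k`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ", k,
         " members")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L  # rotates each class's larger folds so totals balance
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    base <- n %/% k
    rem <- n %% k
    sizes <- rep(base, k)
    if (rem > 0L) {
      big <- ((offset + seq_len(rem) - 1L) %% k) + 1L
      sizes[big] <- sizes[big] + 1L
      offset <- (offset + rem) %% k
    }
    fold[idx] <- rep.int(seq_len(k), sizes)
  }
  structure(list(fold = fold, k = k), class = "fp_folds")
}

#' @export
print.fp_folds <- function(x, ...) {
  cat("<fp_folds: ", x$k, " folds over ", length(x$fold), " rows>\n", sep = "")
  print(table(fold = x$fold))
  invisible(x)
}

#' Write a fold assignment as CSV
#'
#' @param folds an `fp_folds` object.
#' @param ids row ids.
#' @param path output file (columns `id`, `fold`).
#' @export
write_folds <- function(folds, ids, path) {
  stopifnot(inherits(folds, "fp_folds"), length(ids) == length(folds$fold))
  utils::write.csv(data.frame(id = ids, fold = folds$fold), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic labeled fingerprint set
#'
#' Generates a two-class fingerprint dataset with a planted signature:
#' actives set each signature bit with probability `p_on_active`, inactives
#' with `p_on_inactive`, and every other bit is Bernoulli(`background_p`) in
#' both classes. The defaults emulate an easily separable active/decoy
#' screening set: 2000 + 2000 molecules, 168 bits, a 20-bit signature at 0.9
#' vs 0.1, background rate 0.3 (drug-like MACCS fingerprints typically have
#' 40-60 of 166 keys set). Bit-reproducible for a given seed.
#'
#' @param n_active,n_inactive class sizes.
#' @param length fingerprint length.
#' @param signature_bits 1-based positions of the signature bits.
#' @param p_on_active,p_on_inactive signature-bit on-probability per class.
#' @param background_p on-probability of all non-signature bits.
#' @param seed integer seed.
#' @return list of class `fp_labeled_set`: `fps` (an [fp_set()]), `labels`
#'   (factor with levels `active`, `inactive`), `signature_bits`.
#' @export
make_synthetic_fpset <- function(n_active = 2000L, n_inactive = 2000L,
                                 length = 168L, signature_bits = 1:20,
                                 p_on_active = 0.9, p_on_inactive = 0.1,
                                 background_p = 0.3, seed = 1L) {
  stopifnot(all(signature_bits >= 1L), all(signature_bits <= length),
            all(c(p_on_active, p_on_inactive, background_p) >= 0),
            all(c(p_on_active, p_on_inactive, background_p) <= 1))
  set.seed(seed)
  n <- n_active + n_inactive
  bits <- matrix(stats::rbinom(n * length, 1L, background_p), n, length)
  sig <- as.integer(signature_bits)
  bits[seq_len(n_active), sig] <-
    stats::rbinom(n_active * base::length(sig), 1L, p_on_active)
  if (n_inactive > 0L) {
    bits[n_active + seq_len(n_inactive), sig] <-
      stats::rbinom(n_inactive * base::length(sig), 1L, p_on_inactive)
  }
  ids <- c(sprintf("act%05d", seq_len(n_active)),
           sprintf("dec%05d", seq_len(n_inactive)))
  labels <- factor(rep(c("active", "inactive"), c(n_active, n_inactive)),
                   levels = c("active", "inactive"))
  structure(list(fps = fp_set(bits, scheme = "MACCS", ids = ids),
                 labels = labels, signature_bits = sig),
            class = "fp_labeled_set")
}

#' @export
print.fp_labeled_set <- function(x, ...) {
  cat("<fp_labeled_set: ", length(x$fps), " fingerprints x ",
      ncol(x$fps$bits), " bits>\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

# Substituents and scaffolds for the toy SMILES library. The planted core is
# a synthetic stand-in for a lead-series maximum common substructure: an
# N-phenyl pyrazole-3-carboxamide. Core-free scaffolds contain no pyrazole
# ring, so ground-truth containment is decided by construction.
.lib_substituents <- c("C", "CC", "CCC", "C(C)C", "CO", "CCO", "N", "OC",
                       "F", "Cl", "Br", "C(F)(F)F", "OCC", "CC(C)C")
.lib_core_templates <- c(
  "O=C(Nc1ccc(%s)cc1)c1cc(%s)[nH]n1",
  "O=C(Nc1ccccc1%s)c1cc(%s)[nH]n1",
  "O=C(NCc1ccc(%s)cc1)c1cc(%s)[nH]n1"
)
.lib_plain_templates <- c(
  "O=C(Nc1ccc(%s)cc1)c1ccc(%s)cc1",   # benzanilide
  "Cc1ccc(%s)cc1S(=O)(=O)N%s",        # tosyl sulfonamide
  "O=C(O%s)c1ccc(%s)cn1",             # pyridine ester
  "c1ccc(-c2ccc(%s)cc2%s)cc1",        # biphenyl
  "O=C(%s)N1CCN(%s)CC1"               # piperazine amide
)

#' Default planted-core pattern of the synthetic library
#'
#' SMARTS (written as SMILES) of the synthetic stand-in lead-series core
#' planted by [make_synthetic_library()]: a pyrazole-3-carboxamide.
#'
#' @return character scalar.
#' @export
default_core_smarts <- function() "O=C(N)c1cc[nH]n1"

#' Synthetic SMILES library with a planted core
#'
#' Generates a toy compound library by decorating scaffold templates with
#' small substituents. A fraction of the molecules is built on templates
#' containing a planted core substructure (by default the pyrazole
#' carboxamide of [default_core_smarts()]); the remainder uses core-free
#' scaffolds. The ground-truth containment flag is recorded per molecule in
#' the `has_core` column. Reproducible for a given seed.
#'
#' @param n library size.
#' @param planted_core_smarts core pattern; only the default core is
#'   guaranteed to be present/absent by construction, a custom pattern is
#'   validated against the generated molecules by exact matching.
#' @param fraction_with_core fraction of molecules built on core templates.
#' @param seed integer seed.
#' @return a [molecule_records()] table with an extra logical column
#'   `has_core`.
#' @export
make_synthetic_library <- function(n = 1000L,
                                   planted_core_smarts = default_core_smarts(),
                                   fraction_with_core = 0.3, seed = 1L) {
  stopifnot(fraction_with_core >= 0, fraction_with_core <= 1)
  # fail early on an invalid pattern
  invisible(confirm_substructure(planted_core_smarts, c(probe = "CCO")))
  set.seed(seed)
  n <- as.integer(n)
  n_core <- round(n * fraction_with_core)
  pick <- function(templates, m) {
    if (m == 0L) return(character(0L))
    tpl <- sample(templates, m, replace = TRUE)
    r1 <- sample(.lib_substituents, m, replace = TRUE)
    r2 <- sample(.lib_substituents, m, replace = TRUE)
    sprintf(tpl, r1, r2)
  }
  smiles <- c(pick(.lib_core_templates, n_core),
              pick(.lib_plain_templates, n - n_core))
  has_core <- rep(c(TRUE, FALSE), c(n_core, n - n_core))
  ord <- sample.int(n)
  rec <- molecule_records(smiles[ord], sprintf("lib%05d", seq_len(n)),
                          source = "synthetic_library")
  rec$has_core <- has_core[ord]
  if (!identical(planted_core_smarts, default_core_smarts())) {
    rec$has_core <- unname(confirm_substructure(planted_core_smarts, rec))
  }
  rec
}
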