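# Generation-quality metrics (uniqueness, novelty, diversity, similarity),
# classifier performance metrics, and report assembly.

fp_keys <- function(x) {
  m <- if (inherits(x, "fp_set")) x$bits else as.matrix(x)
  do.call(paste0, as.data.frame(m))
}

#' Uniqueness of a generated fingerprint set
#'
#' Ratio of distinct bit-vectors to the total number of fingerprints. Every
#' generated bit-vector counts as a valid fingerprint, so the denominator is
#' the sample size.
#'
#' @param fps an [fp_set()] or 0/1 matrix.
#' @return ratio in \[0, 1\].
#' @examples
#' uniqueness(rbind(c(1, 0), c(1, 0), c(0, 1)))  # 2/3
#' @export
uniqueness <- function(fps) {
  keys <- fp_keys(fps)
  if (length(keys) == 0L) stop("empty fingerprint set")
  length(unique(keys)) / length(keys)
}

#' Novelty of a generated set relative to a training set
#'
#' Fraction of *unique* generated fingerprints that do not occur in the
#' training set.
#'
#' @param fps generated fingerprints.
#' @param training training fingerprints (same scheme/length).
#' @return ratio in \[0, 1\].
#' @examples
#' novelty(rbind(c(1, 0), c(0, 1), c(0, 1), c(1, 1)), rbind(c(1, 1)))  # 2/3
#' @export
novelty <- function(fps, training) {
  u <- unique(fp_keys(fps))
  if (length(u) == 0L) stop("empty fingerprint set")
  tr <- unique(fp_keys(training))
  sum(!u %in% tr) / length(u)
}

#' Internal diversity of a fingerprint set
#'
#' One minus the mean pairwise Tanimoto similarity over all unordered pairs.
#' When the pair count exceeds `max_pairs` a seeded uniform subsample of
#' pairs is used instead (flagged by the `subsampled` attribute).
#'
#' @param fps an [fp_set()] or 0/1 matrix with at least 2 rows.
#' @param max_pairs exhaustive-computation cap (default exhaustive up to
#'   2000 fingerprints).
#' @param seed seed for the pair subsample.
#' @return diversity score in \[0, 1\]; attribute `subsampled` records
#'   whether pairs were subsampled.
#' @export
diversity <- function(fps, max_pairs = 2e6, seed = 1L) {
  m <- if (inherits(fps, "fp_set")) fps$bits else as.matrix(fps)
  n <- nrow(m)
  if (n < 2L) stop("diversity needs at least 2 fingerprints")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    ts <- tanimoto_matrix(m)
    out <- 1 - mean(ts[upper.tri(ts)])
    attr(out, "subsampled") <- FALSE
  } else {
    set.seed(seed)
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n - 1L, max_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # uniform off-diagonal pairs
    s <- pair_tanimoto(m, i, j)
    out <- 1 - mean(s)
    attr(out, "subsampled") <- TRUE
  }
  out
}

# Tanimoto for aligned row pairs (i[k], j[k]) without forming the full
# similarity matrix; evaluated in fixed-size chunks to bound memory
pair_tanimoto <- function(m, i, j, chunk = 1e5L) {
  storage.mode(m) <- "double"
  pc <- rowSums(m)
  out <- numeric(length(i))
  for (s in seq.int(1L, length(i), by = chunk)) {
    e <- min(s + chunk - 1L, length(i))
    ii <- i[s:e]; jj <- j[s:e]
    inter <- rowSums(m[ii, , drop = FALSE] * m[jj, , drop = FALSE])
    union <- pc[ii] + pc[jj] - inter
    out[s:e] <- ifelse(union == 0, 0, inter / union)
  }
  out
}

#' Mean similarity of a generated set to a reference set
#'
#' Mean Tanimoto similarity over the full generated x reference cross
#' product (subsampled above `max_pairs`, as in [diversity()]).
#'
#' @param fps generated fingerprints.
#' @param reference reference (training) fingerprints, same scheme/length.
#' @param max_pairs exhaustive-computation cap.
#' @param seed seed for the pair subsample.
#' @return mean similarity in \[0, 1\].
#' @export
similarity_to_reference <- function(fps, reference, max_pairs = 4e6,
                                    seed = 1L) {
  a <- if (inherits(fps, "fp_set")) fps$bits else as.matrix(fps)
  b <- if (inherits(reference, "fp_set")) reference$bits else as.matrix(reference)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty fingerprint set")
  n_pairs <- as.double(nrow(a)) * nrow(b)
  if (n_pairs <= max_pairs) {
    out <- mean(tanimoto_matrix(a, b))
    attr(out, "subsampled") <- FALSE
  } else {
    set.seed(seed)
    k <- as.integer(max_pairs)
    i <- sample.int(nrow(a), k, replace = TRUE)
    j <- sample.int(nrow(b), k, replace = TRUE)
    # stacked so one pair_tanimoto chunk loop serves the cross product
    out <- mean(pair_tanimoto(rbind(a, b), i, nrow(a) + j))
    attr(out, "subsampled") <- TRUE
  }
  out
}

#' Generation-quality report
#'
#' Bundles the four generation metrics for a sample of generated
#' fingerprints against the training set.
#'
#' @param fps generated fingerprints.
#' @param training training fingerprints.
#' @inheritParams diversity
#' @return data.frame of class `fp_generation_report` with columns
#'   `uniqueness`, `novelty`, `diversity`, `similarity`, `n_samples`.
#' @export
generation_report <- function(fps, training, max_pairs = 2e6, seed = 1L) {
  n <- if (inherits(fps, "fp_set")) length(fps) else nrow(fps)
  structure(
    data.frame(uniqueness = uniqueness(fps),
               novelty = novelty(fps, training),
               diversity = as.numeric(diversity(fps, max_pairs, seed)),
               similarity = as.numeric(
                 similarity_to_reference(fps, training, 2 * max_pairs, seed)),
               n_samples = n),
    class = c("fp_generation_report", "data.frame")
  )
}

#' Classifier performance metrics
#'
#' AUC by the Mann-Whitney rank statistic (midranks for ties), plus
#' accuracy, F1, precision, recall and the confusion counts at a 0.5 score
#' threshold. Accuracy, precision, recall and F1 are consistent with the
#' returned confusion counts by construction.
#'
#' @param y_true logical (or 0/1) vector: positive-class indicator.
#' @param scores positive-class score per sample.
#' @return list with `auc`, `accuracy`, `f1`, `precision`, `recall`, and
#'   `confusion` (named vector `tp`, `fp`, `tn`, `fn`).
#' @export
classifier_metrics <- function(y_true, scores) {
  y <- as.logical(y_true)
  stopifnot(length(y) == length(scores))
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both classes present in y_true")
  }
  r <- rank(scores)  # midranks
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- scores >= 0.5
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(auc = auc, accuracy = (tp + tn) / length(y), f1 = f1,
       precision = precision, recall = recall,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}
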