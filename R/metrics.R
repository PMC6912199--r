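#' Fuse the two model scores
#'
#' Convex combination `s = lambda * s1 + (1 - lambda) * s2` of the
#' similarity-feature model score (s1) and the topology-feature model score
#' (s2). `lambda = 0.5` is the method's operating point.
#'
#' @param s1,s2 numeric score vectors of equal length.
#' @param lambda mixing weight in \[0, 1\].
#' @return numeric vector of fused scores.
#' @export
fuse_scores <- function(s1, s2, lambda = 0.5) {
  if (length(s1) != length(s2)) stop2("s1 and s2 have different lengths")
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop2("lambda must lie in [0, 1], got ", lambda)
  lambda * s1 + (1 - lambda) * s2
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance: the probability that a random
#' positive outranks a random negative, ties counted 1/2. Identical to the
#' area under the ROC curve traced over all distinct score thresholds.
#'
#' @param labels binary vector (1/TRUE = positive); both classes required.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores)) stop2("labels and scores differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop2("AUC requires both classes; got ", n1, " positives and ", n0, " negatives")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank candidate miRNAs for one disease
#'
#' Sorts the disease's candidates by fused score, descending; ties are broken
#' lexicographically by miRNA ID so rankings are reproducible.
#'
#' @param table data frame with columns `disease`, `mirna`, `s` (and
#'   typically `s1`, `s2`).
#' @param disease disease ID present in the table.
#' @return character vector of miRNA IDs, best first.
#' @export
rank_candidates <- function(table, disease) {
  rows <- table[table$disease == disease, , drop = FALSE]
  if (!nrow(rows)) stop2("unknown disease ID: ", disease)
  rows$mirna[order(-rows$s, rows$mirna)]
}

#' Precision and recall over the top-k ranked candidates
#'
#' `pre = |top-k intersect held_out| / k`;
#' `rec = |top-k intersect held_out| / |held_out|`.
#'
#' @param ranked character vector of candidate miRNA IDs, best first.
#' @param held_out non-empty set of true (held-out) positive miRNA IDs.
#' @param k cutoff, `k >= 1`.
#' @return named numeric vector `c(pre = , rec = )`.
#' @export
precision_recall_at_k <- function(ranked, held_out, k) {
  if (!length(held_out)) stop2("held_out positives must be non-empty")
  if (k < 1) stop2("k must be >= 1")
  hits <- length(intersect(utils::head(ranked, k), held_out))
  c(pre = hits / k, rec = hits / length(held_out))
}
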