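#' Positive-unlabeled sample space and cross-validation folds
#'
#' Only positive disease-miRNA associations are observed; every other pair is
#' unlabeled. `enumerate_unlabeled()` lists the complement of the edge set,
#' `sample_negatives()` draws pseudo-negatives uniformly from it (the
#' unlabeled pool is ~29x larger than the positive set at the reference
#' scale, so potential true associations are diluted), and
#' `make_disease_folds()` partitions one disease's positives into five folds
#' for per-disease cross-validation.
#'
#' @param net an [association_network()].
#' @return `enumerate_unlabeled()`: data frame with columns `disease`,
#'   `mirna` covering all `m*h - |edges|` non-associated pairs, in
#'   disease-major lexicographic order.
#' @export
enumerate_unlabeled <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  all_pairs <- expand.grid(mirna = net$mirnas, disease = net$diseases,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[, c("disease", "mirna")]
  keep <- !(pair_keys(all_pairs$disease, all_pairs$mirna) %in%
              pair_keys(net$edges$disease, net$edges$mirna))
  out <- all_pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname enumerate_unlabeled
#' @param unlabeled data frame of unlabeled pairs.
#' @param k number of negatives to draw (`k =` number of positives gives the
#'   1:1 training ratio).
#' @param seed integer seed; draws are uniform without replacement and
#'   reproducible.
#' @return `sample_negatives()`: data frame of `k` pairs.
#' @export
sample_negatives <- function(unlabeled, k, seed = 1L) {
  if (k > nrow(unlabeled))
    stop2("requested ", k, " negatives from only ", nrow(unlabeled),
          " unlabeled pairs")
  set.seed(seed)
  out <- unlabeled[sample.int(nrow(unlabeled), k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname enumerate_unlabeled
#' @param disease disease ID whose positives are partitioned.
#' @param n_folds number of folds (5 for the standard protocol).
#' @return `make_disease_folds()`: list with `disease`, `folds` (list of
#'   `n_folds` disjoint miRNA-ID vectors whose union is the disease's
#'   positives, sizes differing by at most 1) and `seed`.
#' @export
make_disease_folds <- function(net, disease, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(net, "assoc_network"))
  if (!disease %in% net$diseases) stop2("unknown disease ID: ", disease)
  pos <- net$edges$mirna[net$edges$disease == disease]
  if (length(pos) < n_folds)
    warning("disease ", disease, " has only ", length(pos),
            " positives for ", n_folds, "-fold CV; some folds will be empty",
            call. = FALSE)
  set.seed(seed)
  shuffled <- if (length(pos)) sample(pos) else character()
  assignment <- rep_len(seq_len(n_folds), length(shuffled))
  folds <- lapply(seq_len(n_folds), function(f) shuffled[assignment == f])
  list(disease = disease, folds = folds, seed = as.integer(seed))
}

#' Fold assignment table for per-disease cross-validation
#'
#' Assigns every positive of every eligible disease (those with at least
#' `min_positives` associations) to one of `n_folds` folds via
#' [make_disease_folds()] (seeded shuffle + round-robin), using a
#' disease-specific seed offset so assignments are independent across
#' diseases but reproducible.
#'
#' @inheritParams enumerate_unlabeled
#' @param n_folds number of folds.
#' @param seed base seed.
#' @param min_positives minimum positive count for a disease to be evaluated.
#' @return data frame with columns `disease`, `mirna`, `fold`; attribute
#'   `eligible` lists the evaluated diseases.
#' @export
cv_fold_assignments <- function(net, n_folds = 5L, seed = 1L,
                                min_positives = n_folds) {
  stopifnot(inherits(net, "assoc_network"))
  counts <- table(net$edges$disease)
  eligible <- sort(names(counts)[counts >= min_positives])
  rows <- lapply(seq_along(eligible), function(i) {
    fp <- make_disease_folds(net, eligible[i], n_folds,
                             seed = seed + i)
    data.frame(disease = eligible[i],
               mirna = unlist(fp$folds, use.names = FALSE),
               fold = rep(seq_len(n_folds), lengths(fp$folds)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease = character(), mirna = character(), fold = integer())
  attr(out, "eligible") <- eligible
  out
}
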