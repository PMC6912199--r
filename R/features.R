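#' Disease-miRNA pair feature vectors
#'
#' Two feature families describe a (disease, miRNA) pair:
#' \itemize{
#'   \item similarity-based: the disease's row of the DS matrix concatenated
#'     with the miRNA's row of the RS matrix (length m + h, e.g.
#'     336 + 577 = 913), later compressed by the autoencoder;
#'   \item topology-based: the DeepWalk embedding of the disease concatenated
#'     with that of the miRNA (length 2n, e.g. 128 + 128 = 256).
#' }
#' Both constructions are pure lookups; batch versions order rows exactly as
#' the supplied pair table.
#'
#' @param d disease ID.
#' @param r miRNA ID.
#' @param ds,rs similarity matrices with entity IDs as dimnames.
#' @return `similarity_pair_vector()`: numeric vector of length
#'   `ncol(ds) + ncol(rs)`.
#' @examples
#' ds <- diag(2); dimnames(ds) <- list(c("d1", "d2"), c("d1", "d2"))
#' rs <- diag(3); dimnames(rs) <- list(paste0("r", 1:3), paste0("r", 1:3))
#' similarity_pair_vector("d1", "r2", ds, rs)
#' @export
similarity_pair_vector <- function(d, r, ds, rs) {
  if (!d %in% rownames(ds)) stop2("unknown disease ID: ", d)
  if (!r %in% rownames(rs)) stop2("unknown miRNA ID: ", r)
  c(ds[d, ], rs[r, ])
}

#' @rdname similarity_pair_vector
#' @param pairs data frame with columns `disease`, `mirna`.
#' @return `similarity_pair_matrix()`: matrix with one row per pair.
#' @export
similarity_pair_matrix <- function(pairs, ds, rs) {
  bad_d <- setdiff(unique(pairs$disease), rownames(ds))
  bad_r <- setdiff(unique(pairs$mirna), rownames(rs))
  if (length(bad_d)) stop2("unknown disease ID: ", bad_d[1L])
  if (length(bad_r)) stop2("unknown miRNA ID: ", bad_r[1L])
  out <- cbind(ds[as.character(pairs$disease), , drop = FALSE],
               rs[as.character(pairs$mirna), , drop = FALSE])
  rownames(out) <- pair_keys(pairs$disease, pairs$mirna)
  out
}

#' @rdname similarity_pair_vector
#' @param phi embedding matrix with node IDs as rownames.
#' @return `embedding_pair_vector()`: numeric vector of length `2 * ncol(phi)`.
#' @export
embedding_pair_vector <- function(d, r, phi) {
  if (!d %in% rownames(phi)) stop2("unknown disease ID: ", d)
  if (!r %in% rownames(phi)) stop2("unknown miRNA ID: ", r)
  c(phi[d, ], phi[r, ])
}

#' @rdname similarity_pair_vector
#' @return `embedding_pair_matrix()`: matrix with one row per pair.
#' @export
embedding_pair_matrix <- function(pairs, phi) {
  bad <- setdiff(unique(c(as.character(pairs$disease), as.character(pairs$mirna))),
                 rownames(phi))
  if (length(bad)) stop2("node absent from the embedding: ", bad[1L])
  out <- cbind(phi[as.character(pairs$disease), , drop = FALSE],
               phi[as.character(pairs$mirna), , drop = FALSE])
  rownames(out) <- pair_keys(pairs$disease, pairs$mirna)
  out
}
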