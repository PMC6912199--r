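#' Functional gene network with log-likelihood edge scores
#'
#' Undirected weighted gene-gene network in the HumanNet style: each edge
#' carries a non-negative log-likelihood score (LLS) quantifying confidence
#' that the two genes are functionally linked. Self-edges are rejected,
#' duplicate undirected records collapse to the first occurrence.
#'
#' @param edges data frame with columns `gene1`, `gene2` (character) and
#'   `lls` (non-negative numeric).
#' @return An object of class `"gene_network"`.
#' @export
gene_network <- function(edges) {
  if (!is.data.frame(edges) || !all(c("gene1", "gene2", "lls") %in% names(edges)))
    stop2("`edges` must have columns 'gene1', 'gene2', 'lls'")
  edges <- data.frame(gene1 = as.character(edges$gene1),
                      gene2 = as.character(edges$gene2),
                      lls   = as.numeric(edges$lls),
                      stringsAsFactors = FALSE)
  if (any(edges$gene1 == edges$gene2))
    stop2("gene network contains self-edges")
  if (any(!is.finite(edges$lls)) || any(edges$lls < 0))
    stop2("LLS scores must be finite and non-negative")
  # canonical undirected key, first record wins
  key <- ifelse(edges$gene1 < edges$gene2,
                paste(edges$gene1, edges$gene2, sep = "\t"),
                paste(edges$gene2, edges$gene1, sep = "\t"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 genes = sort(unique(c(edges$gene1, edges$gene2)))),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene functional network: %d genes, %d LLS edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

# Internal: symmetric sparse LLS matrix over a fixed gene universe.
lls_sparse_matrix <- function(net, genes) {
  i <- match(net$edges$gene1, genes)
  j <- match(net$edges$gene2, genes)
  keep <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                       x = rep(net$edges$lls[keep], 2L),
                       dims = c(length(genes), length(genes)),
                       dimnames = list(genes, genes))
}

#' Log-likelihood score between a gene and a gene set
#'
#' Aggregates the LLS edge weights from gene `g` into the members of `S` that
#' are present in the network. The default aggregation is the sum over edges
#' (matching the additive outer sums of the disease-similarity score); `"max"`
#' takes the strongest single link instead. Returns 0 when `g` has no edge
#' into `S` (including empty `S` or `g` absent from the network).
#'
#' @param g gene ID.
#' @param S character vector of gene IDs (the set).
#' @param net a [gene_network()].
#' @param method `"sum"` (default) or `"max"`.
#' @return Non-negative scalar.
#' @examples
#' net <- gene_network(data.frame(gene1 = "g", gene2 = c("x", "y", "z"),
#'                                lls = c(1.5, 2.5, 9)))
#' lls_gene_to_set("g", c("x", "y"), net)  # 4
#' @export
lls_gene_to_set <- function(g, S, net, method = c("sum", "max")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "gene_network"))
  e <- net$edges
  hit <- (e$gene1 == g & e$gene2 %in% S) | (e$gene2 == g & e$gene1 %in% S)
  w <- e$lls[hit]
  if (!length(w)) return(0)
  if (method == "sum") sum(w) else max(w)
}

check_similarity_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop2("similarity matrix must be square")
  if (any(!is.finite(m)))
    stop2("similarity matrix has non-finite entries")
  if (max(abs(m - t(m))) >= tol)
    stop2("similarity matrix is not symmetric within 1e-9")
  invisible(m)
}

#' Disease similarity from shared gene-set functional linkage
#'
#' Scores a disease pair by the total log-likelihood linkage between their
#' gene sets, normalised by the combined set size:
#' \deqn{DS(d_i,d_j) = \frac{\sum_{g_1 \in S(d_i)} LLS(g_1, S(d_j)) +
#'   \sum_{g_2 \in S(d_j)} LLS(g_2, S(d_i))}{|S(d_i)| + |S(d_j)|}}
#' and 0 when both gene sets are empty. The diagonal is computed by the same
#' formula. With the default `"sum"` aggregation the numerator is evaluated
#' as a sparse quadratic form (indicator matrix times LLS matrix), which is
#' algebraically identical to the double loop over genes.
#'
#' @param disease_genes named list: disease ID -> character vector of genes.
#' @param net a [gene_network()].
#' @param diseases character vector of disease IDs defining row/column order.
#' @param method aggregation for [lls_gene_to_set()]; `"max"` falls back to a
#'   per-pair loop.
#' @return m x m symmetric similarity matrix with `diseases` as dimnames.
#' @export
ds_matrix <- function(disease_genes, net, diseases, method = c("sum", "max")) {
  method <- match.arg(method)
  if (!length(diseases)) stop2("`diseases` must be non-empty")
  diseases <- as.character(diseases)
  unknown <- setdiff(names(disease_genes), diseases)
  if (length(unknown))
    stop2("disease-gene map names unknown disease ID(s): ",
          paste(utils::head(unknown, 5), collapse = ", "))
  sets <- lapply(setNames(diseases, diseases),
                 function(d) unique(as.character(disease_genes[[d]] %||% character())))
  sizes <- lengths(sets)
  denom <- outer(sizes, sizes, `+`)

  if (method == "sum") {
    genes <- sort(unique(c(unlist(sets, use.names = FALSE), net$genes)))
    if (!length(genes)) {
      num <- matrix(0, length(diseases), length(diseases))
    } else {
      W <- lls_sparse_matrix(net, genes)
      Mi <- Matrix::sparseMatrix(
        i = rep(seq_along(sets), sizes),
        j = match(unlist(sets, use.names = FALSE), genes),
        x = 1, dims = c(length(sets), length(genes)))
      # sum_{g1 in Si} LLS(g1, Sj) = (M W M^T)_{ij}; W symmetric, so the two
      # outer sums are (MWM')_{ij} + (MWM')_{ji}
      A <- as.matrix(Mi %*% W %*% Matrix::t(Mi))
      num <- A + t(A)
    }
  } else {
    m <- length(diseases)
    num <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(i)) {
      v <- sum(vapply(sets[[i]], lls_gene_to_set, 0, S = sets[[j]],
                      net = net, method = method)) +
           sum(vapply(sets[[j]], lls_gene_to_set, 0, S = sets[[i]],
                      net = net, method = method))
      num[i, j] <- num[j, i] <- v
    }
  }
  ds <- ifelse(denom > 0, num / denom, 0)
  dimnames(ds) <- list(diseases, diseases)
  ds <- (ds + t(ds)) / 2  # remove floating-point asymmetry
  check_similarity_matrix(ds)
}

#' miRNA similarity from shared validated targets
#'
#' Off-diagonal entry (i, j) is the number of targets shared by the two
#' miRNAs; with `normalize = TRUE` (default) counts are divided by the
#' global maximum off-diagonal count so entries lie in \[0, 1\] and are
#' commensurate with the binary family/cluster components. The diagonal is
#' forced to 0. miRNAs absent from the map have an empty target set.
#'
#' @param targets named list: miRNA ID -> character vector of target IDs.
#' @param mirnas character vector of miRNA IDs defining the matrix order.
#' @param normalize divide by the maximum off-diagonal count (no-op when all
#'   counts are zero).
#' @return h x h symmetric matrix.
#' @export
shared_target_similarity <- function(targets, mirnas, normalize = TRUE) {
  if (!length(mirnas)) stop2("`mirnas` must be non-empty")
  mirnas <- as.character(mirnas)
  sets <- lapply(setNames(mirnas, mirnas),
                 function(r) unique(as.character(targets[[r]] %||% character())))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(universe)) {
    cnt <- matrix(0, length(mirnas), length(mirnas))
  } else {
    Tm <- Matrix::sparseMatrix(
      i = rep(seq_along(sets), lengths(sets)),
      j = match(unlist(sets, use.names = FALSE), universe),
      x = 1, dims = c(length(sets), length(universe)))
    cnt <- as.matrix(Matrix::tcrossprod(Tm))
  }
  diag(cnt) <- 0
  if (normalize && max(cnt) > 0) cnt <- cnt / max(cnt)
  dimnames(cnt) <- list(mirnas, mirnas)
  check_similarity_matrix(cnt)
}

#' Binary group-membership similarity (miRNA family or cluster)
#'
#' Entry (i, j) is 1 when the two miRNAs share at least one group (family or
#' genomic cluster) and 0 otherwise. The diagonal is 1 for annotated miRNAs
#' and 0 for miRNAs with no group.
#'
#' @param groups named list: miRNA ID -> character vector of group IDs.
#' @param mirnas character vector of miRNA IDs defining the matrix order.
#' @return h x h binary symmetric matrix.
#' @export
membership_similarity <- function(groups, mirnas) {
  mirnas <- as.character(mirnas)
  sets <- lapply(setNames(mirnas, mirnas),
                 function(r) unique(as.character(groups[[r]] %||% character())))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(universe)) {
    sim <- matrix(0, length(mirnas), length(mirnas))
  } else {
    G <- Matrix::sparseMatrix(
      i = rep(seq_along(sets), lengths(sets)),
      j = match(unlist(sets, use.names = FALSE), universe),
      x = 1, dims = c(length(sets), length(universe)))
    sim <- as.matrix(Matrix::tcrossprod(G) > 0) * 1
  }
  dimnames(sim) <- list(mirnas, mirnas)
  check_similarity_matrix(sim)
}

#' Weights of the four miRNA-similarity components
#'
#' Non-negative weights for the target-sharing (RST), family (RSF), cluster
#' (RSC) and disease-derived (RSD) components of the combined miRNA
#' similarity. Defaults (0.2, 0.1, 0.2, 0.5) are the best-performing setting
#' of the method.
#'
#' @param alpha,beta,gamma,delta non-negative weights for RST, RSF, RSC, RSD.
#' @return An object of class `"similarity_weights"`.
#' @export
similarity_weights <- function(alpha = 0.2, beta = 0.1, gamma = 0.2, delta = 0.5) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(!is.finite(w)) || any(w < 0))
    stop2("similarity weights must be finite and non-negative")
  structure(as.list(w), class = "similarity_weights")
}

#' Combine the four miRNA-similarity components
#'
#' Elementwise weighted sum
#' `RS = alpha*RST + beta*RSF + gamma*RSC + delta*RSD`. All four matrices
#' must share the same miRNA ordering (dimnames).
#'
#' @param rst,rsf,rsc,rsd similarity matrices with identical dimnames.
#' @param weights a [similarity_weights()].
#' @return Combined symmetric similarity matrix.
#' @export
combine_similarity <- function(rst, rsf, rsc, rsd,
                               weights = similarity_weights()) {
  stopifnot(inherits(weights, "similarity_weights"))
  mats <- list(rst, rsf, rsc, rsd)
  ids <- rownames(rst)
  ok <- vapply(mats, function(m)
    identical(rownames(m), ids) && identical(colnames(m), ids), TRUE)
  if (is.null(ids) || !all(ok))
    stop2("the four component matrices must share one miRNA ID ordering")
  rs <- weights$alpha * rst + weights$beta * rsf +
        weights$gamma * rsc + weights$delta * rsd
  check_similarity_matrix(rs)
}

#' Build both similarity matrices of the bilayer network
#'
#' Convenience wrapper: computes the disease similarity (DS) matrix from the
#' disease-gene map and gene network, the three computed miRNA components
#' (targets, family, cluster), and combines them with the supplied
#' disease-derived matrix into the final RS matrix.
#'
#' @param net an [association_network()] fixing the ID orders.
#' @param disease_genes,gene_net,mirna_targets,mirna_family,mirna_cluster raw
#'   inputs; see the individual builders.
#' @param rsd precomputed disease-derived miRNA similarity matrix (entries in
#'   \[0, 1\], dimnames = miRNA IDs in any order containing `net$mirnas`).
#' @param weights a [similarity_weights()].
#' @param lls_method aggregation passed to [ds_matrix()].
#' @return list with elements `ds` and `rs`.
#' @export
build_similarities <- function(net, disease_genes, gene_net, mirna_targets,
                               mirna_family, mirna_cluster, rsd,
                               weights = similarity_weights(),
                               lls_method = "sum") {
  stopifnot(inherits(net, "assoc_network"))
  ds <- ds_matrix(disease_genes, gene_net, net$diseases, method = lls_method)
  rst <- shared_target_similarity(mirna_targets, net$mirnas)
  rsf <- membership_similarity(mirna_family, net$mirnas)
  rsc <- membership_similarity(mirna_cluster, net$mirnas)
  missing <- setdiff(net$mirnas, rownames(rsd))
  if (length(missing))
    stop2("RSD matrix is missing miRNA ID(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  rsd <- rsd[net$mirnas, net$mirnas]
  rs <- combine_similarity(rst, rsf, rsc, rsd, weights)
  list(ds = ds, rs = rs)
}
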