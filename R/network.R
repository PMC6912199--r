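#' Bipartite disease-miRNA association network
#'
#' Container for the known association edges between a fixed set of diseases
#' and a fixed set of miRNAs. Duplicate records are dropped; disease and miRNA
#' identifier lists are kept in deterministic (lexicographic) order so that
#' every downstream matrix has a reproducible layout.
#'
#' @param edges data frame with columns `disease` and `mirna` (character).
#' @param diseases optional character vector of disease IDs; defaults to the
#'   IDs observed in `edges`. Extra IDs are allowed (isolated diseases).
#' @param mirnas optional character vector of miRNA IDs, as for `diseases`.
#' @return An object of class `"assoc_network"`: a list with elements
#'   `diseases`, `mirnas` (sorted character vectors) and `edges`
#'   (deduplicated data frame).
#' @examples
#' net <- association_network(data.frame(disease = "d1", mirna = "r1"))
#' n_pairs(net)
#' @export
association_network <- function(edges, diseases = NULL, mirnas = NULL) {
  if (!is.data.frame(edges) || !all(c("disease", "mirna") %in% names(edges)))
    stop2("`edges` must be a data frame with columns 'disease' and 'mirna'")
  edges <- data.frame(disease = as.character(edges$disease),
                      mirna   = as.character(edges$mirna),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  diseases <- sort(unique(c(as.character(diseases %||% character()), edges$disease)))
  mirnas   <- sort(unique(c(as.character(mirnas %||% character()), edges$mirna)))
  if (length(intersect(diseases, mirnas)))
    stop2("disease and miRNA identifier sets overlap: ",
          paste(utils::head(intersect(diseases, mirnas), 3), collapse = ", "))
  edges <- edges[order(edges$disease, edges$mirna), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(diseases = diseases, mirnas = mirnas, edges = edges),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("Disease-miRNA association network\n")
  cat(sprintf("  %d diseases x %d miRNAs, %d known associations (%.4f density)\n",
              length(x$diseases), length(x$mirnas), nrow(x$edges),
              nrow(x$edges) / max(1, n_pairs(x))))
  invisible(x)
}

#' Total number of disease-miRNA pairs in the sample space
#'
#' @param net an `assoc_network`.
#' @return `m * h`, the number of ordered (disease, miRNA) pairs.
#' @export
n_pairs <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  length(net$diseases) * length(net$mirnas)
}

# Internal: "disease\tmirna" keys for fast set operations on pair sets.
pair_keys <- function(disease, mirna) paste(disease, mirna, sep = "\t")

#' Remove a set of association edges from a network
#'
#' Used by the cross-validation driver to hide held-out positives: the
#' returned network keeps the full node lists (so matrix layouts are stable)
#' but drops the given edges.
#'
#' @param net an `assoc_network`.
#' @param drop data frame with columns `disease`, `mirna` of edges to remove.
#' @return A new `assoc_network` without the dropped edges.
#' @export
drop_edges <- function(net, drop) {
  stopifnot(inherits(net, "assoc_network"))
  keep <- !(pair_keys(net$edges$disease, net$edges$mirna) %in%
              pair_keys(as.character(drop$disease), as.character(drop$mirna)))
  association_network(net$edges[keep, , drop = FALSE],
                      diseases = net$diseases, mirnas = net$mirnas)
}

# Internal: adjacency list over the undirected bipartite graph, keyed by node
# ID; values are character vectors of neighbours.
bipartite_adjacency <- function(net) {
  adj <- c(
    split(net$edges$mirna, factor(net$edges$disease, levels = net$diseases)),
    split(net$edges$disease, factor(net$edges$mirna, levels = net$mirnas))
  )
  lapply(adj, as.character)
}
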