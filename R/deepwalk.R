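#' DeepWalk configuration
#'
#' Settings for random-walk generation and SkipGram training on the bipartite
#' association network. The window size (`window = 5`) and embedding
#' dimension (`dim = 128`) are the method's operating point; walk
#' count and length follow conventional DeepWalk settings.
#'
#' @param walks_per_node walks started at every node (gamma).
#' @param walk_length nodes per walk (t).
#' @param window SkipGram context radius (w).
#' @param dim embedding dimension (n).
#' @param epochs SkipGram passes over the walk corpus.
#' @param learning_rate initial SGD step size; decays linearly to
#'   `min_learning_rate` over training.
#' @param min_learning_rate floor of the learning-rate schedule.
#' @param seed integer seed controlling walks and initialisation.
#' @return An object of class `"walk_config"`.
#' @export
walk_config <- function(walks_per_node = 10, walk_length = 40, window = 5,
                        dim = 128, epochs = 5, learning_rate = 0.025,
                        min_learning_rate = 1e-4, seed = 1L) {
  stopifnot(walks_per_node >= 1, walk_length >= 1, window >= 1, dim >= 1,
            epochs >= 0, learning_rate > 0, min_learning_rate > 0)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window), dim = as.integer(dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 min_learning_rate = min_learning_rate,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Truncated uniform random walks on the association network
#'
#' Starts `walks_per_node` walks at every node of the (undirected, unweighted)
#' bipartite disease-miRNA network; each step moves to a uniformly random
#' neighbour. A walk from an isolated node is the single start node.
#'
#' @param net an [association_network()].
#' @param cfg a [walk_config()].
#' @return List of character vectors (node-ID sequences), one per walk,
#'   with attribute `nodes` giving the full node ordering.
#' @export
generate_walks <- function(net, cfg = walk_config()) {
  stopifnot(inherits(net, "assoc_network"), inherits(cfg, "walk_config"))
  nodes <- c(net$diseases, net$mirnas)
  if (!length(nodes)) stop2("association network has no nodes")
  adj <- bipartite_adjacency(net)
  set.seed(cfg$seed)
  walks <- vector("list", length(nodes) * cfg$walks_per_node)
  k <- 0L
  for (start in nodes) {
    for (g in seq_len(cfg$walks_per_node)) {
      walk <- character(cfg$walk_length)
      walk[1L] <- cur <- start
      len <- 1L
      while (len < cfg$walk_length) {
        nb <- adj[[cur]]
        if (!length(nb)) break  # isolated node: truncate
        cur <- nb[sample.int(length(nb), 1L)]
        len <- len + 1L
        walk[len] <- cur
      }
      k <- k + 1L
      walks[[k]] <- walk[seq_len(len)]
    }
  }
  attr(walks, "nodes") <- nodes
  walks
}

#' Huffman tree for the hierarchical softmax
#'
#' Builds a binary Huffman code over node frequencies observed in the walk
#' corpus, so frequent nodes sit close to the root and every leaf path has
#' length O(log |V|). Ties in frequency are broken lexicographically by the
#' smallest node ID under each subtree, making the tree deterministic. The
#' internal-node parameter matrix Psi is initialised to zeros.
#'
#' @param corpus list of walks (character vectors) from [generate_walks()].
#' @param dim embedding dimension (width of Psi).
#' @return An object of class `"hs_tree"`: list with `ids` (leaf ordering),
#'   `paths`/`codes` (per leaf, internal-node index sequence from the root and
#'   0/1 branch directions), `psi` ((|V|-1) x dim matrix) and `freq`.
#' @export
build_hs_tree <- function(corpus, dim) {
  counts <- table(unlist(corpus, use.names = FALSE))
  if (length(counts) < 1L) stop2("walk corpus covers no node")
  ids <- sort(names(counts))
  freq <- as.numeric(counts[ids])
  V <- length(ids)

  if (V == 1L) {
    # degenerate single-leaf tree: empty path, probability 1
    return(structure(list(ids = ids, paths = list(integer()),
                          codes = list(integer()),
                          psi = matrix(0, 0, dim), freq = freq),
                     class = "hs_tree"))
  }

  # active forest: each entry a subtree with total freq, tie-break key
  # (lexicographically smallest leaf), children (negative = leaf index)
  n_internal <- V - 1L
  node_freq <- c(freq, rep(NA_real_, n_internal))
  node_key  <- c(ids, rep(NA_character_, n_internal))
  left <- integer(n_internal); right <- integer(n_internal)
  active <- seq_len(V)
  nxt <- V
  for (step in seq_len(n_internal)) {
    ord <- active[order(node_freq[active], node_key[active])]
    a <- ord[1L]; b <- ord[2L]
    nxt <- nxt + 1L
    internal_idx <- nxt - V           # 1..V-1, row into psi
    left[internal_idx] <- a; right[internal_idx] <- b
    node_freq[nxt] <- node_freq[a] + node_freq[b]
    node_key[nxt] <- min(node_key[a], node_key[b])
    active <- c(setdiff(active, c(a, b)), nxt)
  }
  root <- active[1L]

  paths <- vector("list", V); codes <- vector("list", V)
  walk_down <- function(node, path, code) {
    if (node <= V) {
      paths[[node]] <<- path; codes[[node]] <<- code
    } else {
      idx <- node - V
      walk_down(left[idx],  c(path, idx), c(code, 0L))
      walk_down(right[idx], c(path, idx), c(code, 1L))
    }
  }
  walk_down(root, integer(), integer())

  structure(list(ids = ids, paths = paths, codes = codes,
                 psi = matrix(0, n_internal, dim), freq = freq),
            class = "hs_tree")
}

#' @export
print.hs_tree <- function(x, ...) {
  cat(sprintf("Hierarchical-softmax Huffman tree: %d leaves, depth %d-%d\n",
              length(x$ids), min(lengths(x$paths)), max(lengths(x$paths))))
  invisible(x)
}

#' Hierarchical-softmax probability of one leaf given a context embedding
#'
#' Probability assigned to node `v` by the binary-tree factorised softmax:
#' the product over the internal nodes on `v`'s root path of
#' `sigmoid(+/- phi(context) . psi(b))`, the sign set by the branch taken.
#' Over all leaves these probabilities sum to exactly 1.
#'
#' @param v target node ID (a leaf).
#' @param context conditioning node ID (its embedding row is used).
#' @param tree an [build_hs_tree()] result (its `psi` holds the trained
#'   internal parameters).
#' @param phi embedding matrix with node IDs as rownames.
#' @return Probability in (0, 1\].
#' @export
leaf_probability <- function(v, context, tree, phi) {
  stopifnot(inherits(tree, "hs_tree"))
  iv <- match(v, tree$ids)
  if (is.na(iv)) stop2("unknown leaf: ", v)
  if (!context %in% rownames(phi)) stop2("unknown context node: ", context)
  path <- tree$paths[[iv]]; code <- tree$codes[[iv]]
  if (!length(path)) return(1)
  x <- as.numeric(tree$psi[path, , drop = FALSE] %*% phi[context, ])
  prod(1 / (1 + exp(-ifelse(code == 0L, x, -x))))
}

# Internal: walks as 1-based integer vectors over tree$ids.
index_walks <- function(corpus, ids) {
  lapply(corpus, function(w) {
    idx <- match(w, ids)
    if (anyNA(idx)) stop2("walk contains node absent from the tree")
    idx
  })
}

#' Train SkipGram embeddings on a walk corpus
#'
#' Maximises the co-occurrence likelihood of nodes within a window `w` along
#' each walk, using the hierarchical-softmax factorisation: for each centre
#' node the context-node root paths are descended and both the centre
#' embedding and the internal-node parameters are updated by stochastic
#' gradient ascent. Deterministic under a fixed seed (single-threaded,
#' fixed update order, seeded initialisation).
#'
#' @param corpus walk list from [generate_walks()].
#' @param cfg a [walk_config()].
#' @param tree optional prebuilt [build_hs_tree()]; built from the corpus
#'   when `NULL`.
#' @param phi optional initial embedding matrix (rows = `tree$ids`); defaults
#'   to seeded uniform values in `[-0.5/dim, 0.5/dim]`.
#' @return list with `phi` (|V| x dim embedding matrix, node IDs as
#'   rownames) and `tree` (with trained `psi`).
#' @export
train_skipgram <- function(corpus, cfg = walk_config(), tree = NULL, phi = NULL) {
  stopifnot(inherits(cfg, "walk_config"))
  if (cfg$dim <= 0) stop2("embedding dimension must be positive")
  if (!length(corpus)) stop2("walk corpus is empty")
  if (is.null(tree)) tree <- build_hs_tree(corpus, cfg$dim)
  V <- length(tree$ids)
  if (is.null(phi)) {
    set.seed(cfg$seed + 1L)
    phi <- matrix(runif(V * cfg$dim, -0.5 / cfg$dim, 0.5 / cfg$dim),
                  V, cfg$dim, dimnames = list(tree$ids, NULL))
  } else {
    stopifnot(identical(rownames(phi), tree$ids), ncol(phi) == cfg$dim)
  }
  if (cfg$epochs == 0L || V == 1L)
    return(list(phi = phi, tree = tree))
  iw <- index_walks(corpus, tree$ids)
  out <- skipgram_train_cpp(iw, tree$paths, tree$codes, phi, tree$psi,
                            cfg$window, cfg$epochs,
                            cfg$learning_rate, cfg$min_learning_rate)
  rownames(out$phi) <- tree$ids
  tree$psi <- out$psi
  list(phi = out$phi, tree = tree)
}

#' Mean negative log-likelihood of a corpus under current parameters
#'
#' Average over all in-window (centre, context) pairs of
#' `-log Pr(context | phi(centre))` computed through the hierarchical
#' softmax. Used to monitor that training makes progress.
#'
#' @inheritParams train_skipgram
#' @param tree,phi parameters as returned by [train_skipgram()].
#' @param window context radius.
#' @return Scalar mean negative log-likelihood (`NA` for an empty pair set).
#' @export
skipgram_loss <- function(corpus, tree, phi, window = 5L) {
  iw <- index_walks(corpus, tree$ids)
  skipgram_loss_cpp(iw, tree$paths, tree$codes,
                    phi[tree$ids, , drop = FALSE], tree$psi, as.integer(window))
}

#' Learn DeepWalk node embeddings for an association network
#'
#' Convenience wrapper: generates walks, builds the Huffman tree and trains
#' SkipGram. Every node of the network gets one embedding row (isolated
#' nodes keep their initialisation, reached only through their own walks).
#'
#' @param net an [association_network()].
#' @param cfg a [walk_config()].
#' @return |V| x dim embedding matrix, node IDs as rownames, with the walk
#'   corpus attached as attribute `"corpus"`.
#' @export
deepwalk <- function(net, cfg = walk_config()) {
  corpus <- generate_walks(net, cfg)
  fit <- train_skipgram(corpus, cfg)
  # rows ordered as the network's node list
  emb <- fit$phi[match(attr(corpus, "nodes"), rownames(fit$phi)), , drop = FALSE]
  attr(emb, "corpus") <- corpus
  emb
}
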