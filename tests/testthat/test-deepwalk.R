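test_that("walk generation starts gamma walks of length t at every node", {
  net <- complete_net(c("d1", "d2"), c("r1", "r2", "r3"))  # 5 nodes
  cfg <- walk_config(walks_per_node = 2, walk_length = 4, dim = 4, seed = 5)
  walks <- generate_walks(net, cfg)
  expect_length(walks, 10L)
  expect_true(all(lengths(walks) == 4L))
  starts <- vapply(walks, `[`, "", 1L)
  expect_equal(sort(table(starts)), sort(table(rep(c(net$diseases, net$mirnas), 2))),
               ignore_attr = TRUE)
})

test_that("walks stay on the graph and isolated nodes yield singleton walks", {
  net <- association_network(
    data.frame(disease = c("d1", "d1"), mirna = c("r1", "r2")),
    mirnas = c("r1", "r2", "r9"))  # r9 isolated
  cfg <- walk_config(walks_per_node = 3, walk_length = 6, dim = 4, seed = 2)
  walks <- generate_walks(net, cfg)
  nodes <- c(net$diseases, net$mirnas)
  adj <- list(d1 = c("r1", "r2"), r1 = "d1", r2 = "d1", r9 = character())
  for (w in walks) {
    expect_true(all(w %in% nodes))
    if (length(w) > 1)
      for (i in seq_len(length(w) - 1L))
        expect_true(w[i + 1L] %in% adj[[w[i]]])
  }
  r9_walks <- walks[vapply(walks, `[`, "", 1L) == "r9"]
  expect_true(all(lengths(r9_walks) == 1L))
})

test_that("steps from a star centre are uniform over its neighbours", {
  net <- complete_net("d1", c("r1", "r2", "r3"))
  cfg <- walk_config(walks_per_node = 700, walk_length = 10, dim = 4, seed = 8)
  walks <- generate_walks(net, cfg)
  nxt <- unlist(lapply(walks, function(w) {
    from_centre <- which(w[-length(w)] == "d1")
    w[from_centre + 1L]
  }))
  expect_gt(length(nxt), 10000)
  expect_gt(stats::chisq.test(table(nxt))$p.value, 0.01)
})

test_that("Huffman tree has logarithmic, deterministic structure", {
  # 2 nodes: both paths are just the root
  t2 <- build_hs_tree(list(c("a", "b"), c("a", "b")), dim = 4)
  expect_true(all(lengths(t2$paths) == 1L))
  # 4 equal-frequency nodes: perfectly balanced, all depths 2
  t4 <- build_hs_tree(list(c("a", "b", "c", "d"), c("a", "b", "c", "d")), dim = 4)
  expect_true(all(lengths(t4$paths) == 2L))
  expect_equal(nrow(t4$psi), 3L)
  expect_true(all(t4$psi == 0))
  expect_error(build_hs_tree(list(), dim = 4), "no node")
})

test_that("leaf probabilities sum to one for any parameters", {
  set.seed(11)
  for (V in c(2, 7, 19, 32)) {
    # skewed frequencies to force an unbalanced tree
    corpus <- lapply(seq_len(V), function(i)
      rep(sprintf("n%02d", i), sample.int(9, 1)))
    tree <- build_hs_tree(corpus, dim = 6)
    tree$psi <- matrix(rnorm(length(tree$psi)), nrow(tree$psi))
    phi <- matrix(rnorm(V * 6), V, 6, dimnames = list(tree$ids, NULL))
    total <- sum(vapply(tree$ids, leaf_probability, 0,
                        context = tree$ids[1L], tree = tree, phi = phi))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("zero parameters give 0.5 per branch, hence 0.5^depth per leaf", {
  corpus <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  tree <- build_hs_tree(corpus, dim = 3)
  phi <- matrix(rnorm(12), 4, 3, dimnames = list(tree$ids, NULL))
  for (v in tree$ids)
    expect_equal(leaf_probability(v, "a", tree, phi), 0.25)
})

test_that("SkipGram training is shaped, seeded and stationary at 0 epochs", {
  net <- complete_net(c("d1", "d2", "d3"), c("r1", "r2", "r3", "r4"))
  cfg <- walk_config(walks_per_node = 4, walk_length = 10, dim = 12,
                     epochs = 2, seed = 21)
  emb1 <- deepwalk(net, cfg)
  expect_equal(dim(emb1), c(7L, 12L))
  expect_true(all(is.finite(emb1)))
  emb2 <- deepwalk(net, cfg)
  expect_identical(unclass(emb1)[, ], unclass(emb2)[, ])

  cfg0 <- walk_config(walks_per_node = 4, walk_length = 10, dim = 12,
                      epochs = 0, seed = 21)
  corpus <- generate_walks(net, cfg0)
  init <- train_skipgram(corpus, cfg0)
  trained <- train_skipgram(corpus, cfg)
  expect_false(identical(init$phi, trained$phi))
  expect_identical(init$phi, train_skipgram(corpus, cfg0)$phi)
})

test_that("training loss is non-increasing over epochs", {
  net <- complete_net(c("d1", "d2"), c("r1", "r2", "r3"))
  cfg1 <- walk_config(walks_per_node = 6, walk_length = 12, dim = 8,
                      epochs = 1, learning_rate = 0.01,
                      min_learning_rate = 0.0099, seed = 4)
  corpus <- generate_walks(net, cfg1)
  state <- train_skipgram(corpus, walk_config(walks_per_node = 6,
                                              walk_length = 12, dim = 8,
                                              epochs = 0, seed = 4))
  losses <- skipgram_loss(corpus, state$tree, state$phi, cfg1$window)
  for (ep in 1:5) {
    state <- train_skipgram(corpus, cfg1, tree = state$tree, phi = state$phi)
    losses <- c(losses, skipgram_loss(corpus, state$tree, state$phi, cfg1$window))
  }
  expect_true(all(diff(losses) <= abs(losses[-length(losses)]) * 1e-3))
  expect_lt(losses[length(losses)], losses[1L])
})

test_that("embeddings separate disconnected network components", {
  # two disjoint complete bipartite blocks
  edges <- rbind(expand.grid(disease = c("da1", "da2"),
                             mirna = c("ra1", "ra2", "ra3")),
                 expand.grid(disease = c("db1", "db2"),
                             mirna = c("rb1", "rb2", "rb3")))
  net <- association_network(edges)
  emb <- deepwalk(net, walk_config(walks_per_node = 10, walk_length = 20,
                                   dim = 16, epochs = 5, seed = 13))
  block <- substr(rownames(emb), 2, 2)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cos_pairs <- function(idx1, idx2) {
    v <- c()
    for (i in idx1) for (j in idx2)
      if (i != j) v <- c(v, cosine(emb[i, ], emb[j, ]))
    mean(v)
  }
  a <- which(block == "a"); b <- which(block == "b")
  within <- mean(c(cos_pairs(a, a), cos_pairs(b, b)))
  across <- cos_pairs(a, b)
  expect_gt(within, across)
})
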