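test_that("gene-to-set LLS aggregation sums edges into the set", {
  net <- gene_network(data.frame(gene1 = "g", gene2 = c("x", "y", "z"),
                                 lls = c(1.5, 2.5, 9)))
  expect_equal(lls_gene_to_set("g", c("x", "y"), net), 4)
  expect_equal(lls_gene_to_set("g", character(), net), 0)
  expect_equal(lls_gene_to_set("absent", c("x", "y"), net), 0)
  expect_equal(lls_gene_to_set("g", c("x", "y"), net, method = "max"), 2.5)
})

test_that("gene network validates and deduplicates undirected records", {
  expect_error(gene_network(data.frame(gene1 = "a", gene2 = "a", lls = 1)),
               "self-edges")
  expect_error(gene_network(data.frame(gene1 = "a", gene2 = "b", lls = -1)),
               "non-negative")
  net <- gene_network(data.frame(gene1 = c("a", "b"), gene2 = c("b", "a"),
                                 lls = c(2, 7)))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(lls_gene_to_set("a", "b", net), 2)
})

test_that("disease similarity matches hand-evaluated cases", {
  net <- gene_network(data.frame(gene1 = "g1", gene2 = "g2", lls = 2))
  map <- list(d1 = "g1", d2 = "g2", d3 = character())
  ds <- ds_matrix(map, net, c("d1", "d2", "d3"))
  expect_equal(ds["d1", "d2"], 2)          # (2 + 2) / (1 + 1)
  expect_equal(ds["d3", "d3"], 0)          # empty-set branch
  expect_equal(ds["d1", "d3"], 0)
  expect_equal(ds, t(ds))
  expect_error(ds_matrix(list(dX = "g1"), net, c("d1", "d2")), "unknown")
})

# independent double-loop oracle over Eq-style outer sums
ds_oracle <- function(map, net, diseases) {
  m <- length(diseases)
  out <- matrix(0, m, m, dimnames = list(diseases, diseases))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    Si <- map[[diseases[i]]] %||% character()
    Sj <- map[[diseases[j]]] %||% character()
    den <- length(Si) + length(Sj)
    if (den == 0) next
    num <- sum(vapply(Si, function(g) lls_gene_to_set(g, Sj, net), 0)) +
           sum(vapply(Sj, function(g) lls_gene_to_set(g, Si, net), 0))
    out[i, j] <- num / den
  }
  out
}

test_that("disease similarity agrees with the naive double-loop oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    genes <- paste0("g", 1:15)
    edges <- t(combn(genes, 2))
    keep <- runif(nrow(edges)) < 0.3
    net <- gene_network(data.frame(gene1 = edges[keep, 1],
                                   gene2 = edges[keep, 2],
                                   lls = runif(sum(keep), 0.1, 3)))
    diseases <- paste0("d", 1:8)
    map <- lapply(setNames(diseases, diseases),
                  function(d) sample(genes, sample(0:6, 1)))
    ds <- ds_matrix(map, net, diseases)
    expect_equal(ds, ds_oracle(map, net, diseases), tolerance = 1e-12)
  }
})

test_that("disease similarity is linear in the LLS scale", {
  set.seed(9)
  net1 <- gene_network(data.frame(gene1 = c("a", "a", "b"),
                                  gene2 = c("b", "c", "c"),
                                  lls = c(1, 2, 3)))
  net3 <- gene_network(within(net1$edges, lls <- lls * 3))
  map <- list(d1 = c("a", "b"), d2 = c("b", "c"), d3 = "c")
  expect_equal(ds_matrix(map, net3, names(map)),
               3 * ds_matrix(map, net1, names(map)))
})

test_that("shared-target similarity counts and normalises intersections", {
  targets <- list(r1 = c("t1", "t2", "t3", "t4"), r2 = c("t2", "t3", "t4"),
                  r3 = "t9")
  raw <- shared_target_similarity(targets, c("r1", "r2", "r3"),
                                  normalize = FALSE)
  expect_equal(raw["r1", "r2"], 3)
  expect_equal(raw["r1", "r3"], 0)
  expect_equal(diag(raw), c(r1 = 0, r2 = 0, r3 = 0))
  norm <- shared_target_similarity(targets, c("r1", "r2", "r3"))
  expect_equal(norm["r1", "r2"], 1)
  expect_true(all(norm >= 0 & norm <= 1))
  # all-zero counts: no division by zero
  zero <- shared_target_similarity(list(), c("r1", "r2"))
  expect_equal(zero, matrix(0, 2, 2, dimnames = list(c("r1", "r2"),
                                                     c("r1", "r2"))))
})

test_that("membership similarity is 1 iff a group is shared", {
  groups <- list(r1 = "f1", r2 = "f1", r3 = "f2")
  sim <- membership_similarity(groups, c("r1", "r2", "r3"))
  expect_equal(unname(sim), rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  # unannotated miRNA: zero row including its own diagonal
  sim2 <- membership_similarity(groups, c("r1", "r4"))
  expect_equal(unname(sim2["r4", ]), c(0, 0))
  expect_equal(sim2["r4", "r4"], 0)
})

test_that("similarity combination applies the component weights", {
  ids <- c("r1", "r2")
  mk <- function(v) matrix(v, 2, 2, dimnames = list(ids, ids))
  rst <- mk(1); rsf <- mk(1); rsc <- mk(0); rsd <- mk(0.4)
  rs <- combine_similarity(rst, rsf, rsc, rsd)
  expect_equal(rs["r1", "r2"], 0.2 + 0.1 + 0 + 0.2)  # default weights
  expect_equal(combine_similarity(rst, rsf, rsc, rsd,
                                  similarity_weights(1, 0, 0, 0)), rst)
  expect_equal(combine_similarity(mk(0), mk(0), mk(0), mk(0)), mk(0))
  bad <- mk(1); rownames(bad) <- c("rX", "r2")
  expect_error(combine_similarity(rst, rsf, rsc, bad), "ID ordering")
  expect_error(similarity_weights(alpha = -0.1), "non-negative")
})

test_that("bundle similarities are symmetric and finite", {
  b <- tiny_bundle()
  s <- build_similarities(b$net, b$disease_genes, b$gene_net,
                          b$mirna_targets, b$mirna_family, b$mirna_cluster,
                          b$rsd)
  for (m in s) {
    expect_true(all(is.finite(m)))
    expect_lt(max(abs(m - t(m))), 1e-9)
  }
})
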