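test_that("unlabeled enumeration is the exact complement of the edge set", {
  edges <- data.frame(disease = c("d1", "d1", "d2", "d3", "d3"),
                      mirna = c("r1", "r2", "r2", "r3", "r4"))
  net <- association_network(edges, diseases = paste0("d", 1:3),
                             mirnas = paste0("r", 1:4))
  u <- enumerate_unlabeled(net)
  expect_equal(nrow(u), 3 * 4 - 5)
  # brute-force oracle by nested loops
  expected <- list()
  for (d in net$diseases) for (r in net$mirnas)
    if (!any(edges$disease == d & edges$mirna == r))
      expected[[length(expected) + 1L]] <- c(d, r)
  got <- sort(paste(u$disease, u$mirna))
  expect_equal(got, sort(vapply(expected, paste, "", collapse = " ")))
  # disjointness and conservation
  expect_equal(nrow(u) + nrow(net$edges), n_pairs(net))

  empty <- association_network(edges[0, ], diseases = "d1",
                               mirnas = c("r1", "r2"))
  expect_equal(nrow(enumerate_unlabeled(empty)), 2L)
})

test_that("pair-space conservation holds on random networks", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- sample(3:8, 1); h <- sample(3:9, 1)
    all_p <- expand.grid(disease = paste0("d", 1:m), mirna = paste0("r", 1:h),
                         stringsAsFactors = FALSE)
    net <- association_network(all_p[runif(nrow(all_p)) < 0.3, ],
                               diseases = paste0("d", 1:m),
                               mirnas = paste0("r", 1:h))
    expect_equal(nrow(enumerate_unlabeled(net)) + nrow(net$edges), m * h)
  }
})

test_that("negative sampling is uniform, seeded, and size-checked", {
  net <- complete_net(paste0("d", 1:4), paste0("r", 1:6))
  net <- drop_edges(net, net$edges[1:20, ])
  u <- enumerate_unlabeled(net)  # 20 pairs
  expect_equal(nrow(sample_negatives(u, 0, seed = 1)), 0L)
  expect_error(sample_negatives(u, nrow(u) + 1, seed = 1), "only")
  expect_identical(sample_negatives(u, 5, seed = 9),
                   sample_negatives(u, 5, seed = 9))
  # inclusion frequency ~ Binomial(trials, k/n) per pair
  trials <- 400; k <- 5
  counts <- setNames(numeric(nrow(u)), paste(u$disease, u$mirna))
  for (t in seq_len(trials)) {
    s <- sample_negatives(u, k, seed = 1000 + t)
    key <- paste(s$disease, s$mirna)
    counts[key] <- counts[key] + 1
  }
  p <- k / nrow(u)
  bound <- 4 * sqrt(trials * p * (1 - p))
  expect_true(all(abs(counts - trials * p) <= bound))
})

test_that("per-disease folds partition positives round-robin", {
  edges <- data.frame(disease = "d1", mirna = sprintf("r%02d", 1:12))
  net <- association_network(edges)
  fp <- make_disease_folds(net, "d1", seed = 3)
  sizes <- lengths(fp$folds)
  expect_equal(sort(sizes, decreasing = TRUE), c(3, 3, 2, 2, 2))
  expect_setequal(unlist(fp$folds), edges$mirna)
  expect_equal(sum(duplicated(unlist(fp$folds))), 0L)

  edges10 <- data.frame(disease = "d1", mirna = sprintf("r%02d", 1:10))
  fp10 <- make_disease_folds(association_network(edges10), "d1", seed = 3)
  expect_true(all(lengths(fp10$folds) == 2L))

  expect_error(make_disease_folds(net, "dX"), "unknown disease")
  small <- association_network(data.frame(disease = "d1",
                                          mirna = c("r1", "r2")))
  expect_warning(make_disease_folds(small, "d1"), "only 2 positives")
})

test_that("fold assignment covers eligible diseases and is reproducible", {
  b <- tiny_bundle()
  f1 <- cv_fold_assignments(b$net, seed = 5)
  f2 <- cv_fold_assignments(b$net, seed = 5)
  expect_identical(f1, f2)
  counts <- table(b$net$edges$disease)
  expect_setequal(attr(f1, "eligible"), names(counts)[counts >= 5])
  # every positive of an eligible disease is assigned exactly once
  for (d in attr(f1, "eligible")) {
    expect_setequal(f1$mirna[f1$disease == d],
                    b$net$edges$mirna[b$net$edges$disease == d])
  }
  expect_true(all(f1$fold %in% 1:5))
})
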