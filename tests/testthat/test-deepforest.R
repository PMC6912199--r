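# planted-signal binary data: labels driven by two coordinates
make_toy <- function(n, p = 12L, seed = 1L, signal = 2) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 3] <- x[, 3] + signal * y
  x[, 7] <- x[, 7] - signal * y
  list(x = x, y = y)
}

test_that("sliding windows enumerate all stride-1 positions", {
  x <- matrix(seq_len(30), 3, 10)
  W <- sliding_windows(x, 4)
  expect_equal(attr(W, "positions"), 7L)
  expect_equal(nrow(W), 21L)
  # brute-force slicing oracle
  for (p in 1:7) for (i in 1:3)
    expect_equal(unname(W[(p - 1) * 3 + i, ]), x[i, p:(p + 3)])
  W1 <- sliding_windows(x, 10)
  expect_equal(attr(W1, "positions"), 1L)
  err <- tryCatch(sliding_windows(x, 11), error = conditionMessage)
  expect_match(err, "10")
  expect_match(err, "11")
  # the reference geometry: 256 features under a window of 100
  expect_equal(attr(sliding_windows(matrix(0, 1, 256), 100), "positions"), 157L)
})

test_that("deep forest separates separable data and is deterministic", {
  toy <- make_toy(60, seed = 5, signal = 4)
  cfg <- deep_forest_config(window = 5, trees_per_forest = 30, scan_trees = 10,
                            max_layers = 2, seed = 9)
  model <- deep_forest(toy$x, toy$y, cfg)
  p <- predict(model, toy$x)
  expect_gte(mean((p > 0.5) == (toy$y == 1)), 0.99)
  expect_true(all(p >= 0 & p <= 1))
  pm <- predict(model, toy$x, type = "matrix")
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
  expect_identical(p, predict(model, toy$x))
  model2 <- deep_forest(toy$x, toy$y, cfg)
  expect_identical(p, predict(model2, toy$x))
  # every cascade layer carries four forests
  for (l in model$layers) expect_length(l$forests, 4L)
})

test_that("input contracts are enforced", {
  toy <- make_toy(40)
  cfg <- deep_forest_config(window = 5, trees_per_forest = 10, scan_trees = 5)
  expect_error(deep_forest(toy$x, rep(1, 40), cfg), "single class")
  expect_error(deep_forest(toy$x[1:8, ], toy$y[1:8], cfg), "10 samples")
  expect_error(deep_forest(toy$x, toy$y,
                           deep_forest_config(window = 40)), "shorter")
  model <- deep_forest(toy$x, toy$y, cfg)
  expect_error(predict(model, toy$x[, 1:6]), "does not match")
})

test_that("a single-layer cascade is the plain average of its four forests", {
  toy <- make_toy(50, seed = 3)
  cfg <- deep_forest_config(window = 5, trees_per_forest = 20, scan_trees = 8,
                            max_layers = 1, seed = 77)
  model <- deep_forest(toy$x, toy$y, cfg)
  expect_equal(model$n_layers_used, 1L)
  newx <- make_toy(20, seed = 4)$x
  Z <- multi_grained_scan(model, newx)
  # independent ensemble: refit the four layer-1 forests directly with the
  # same derived seeds on the model's training representation
  y <- factor(toy$y, levels = c("0", "1"))
  types <- c("rf", "rf", "crf", "crf")
  probs <- vapply(1:4, function(f) {
    fit <- stim:::fit_forest(model$scan_train, y, types[f],
                             cfg$trees_per_forest,
                             stim:::df_forest_seed(cfg$seed, 1L, f))
    stim:::forest_prob(fit, Z)[, "1"]
  }, numeric(nrow(newx)))
  expect_equal(unname(predict(model, newx)), unname(rowMeans(probs)),
               tolerance = 1e-12)
})

test_that("held-out AUC on planted signal beats the permutation null", {
  train <- make_toy(80, seed = 11, signal = 2)
  test <- make_toy(60, seed = 12, signal = 2)
  cfg <- deep_forest_config(window = 5, trees_per_forest = 30, scan_trees = 10,
                            max_layers = 1, seed = 2)
  model <- deep_forest(train$x, train$y, cfg)
  s <- predict(model, test$x)
  auc <- roc_auc(test$y, s)
  set.seed(99)
  null_aucs <- replicate(200, roc_auc(sample(test$y), s))
  expect_gt(auc, 0.5 + 3 * stats::sd(null_aucs))
})
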