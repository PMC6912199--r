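test_that("similarity pair vectors are row-lookups of DS and RS", {
  ds <- toy_similarity(paste0("d", 1:3), seed = 1)
  rs <- toy_similarity(paste0("r", 1:4), seed = 2)
  v <- similarity_pair_vector("d2", "r3", ds, rs)
  expect_length(v, 7L)
  expect_equal(unname(v[1:3]), unname(ds["d2", ]))
  expect_equal(unname(v[4:7]), unname(rs["r3", ]))
  expect_error(similarity_pair_vector("dX", "r1", ds, rs), "unknown disease")
  expect_error(similarity_pair_vector("d1", "rX", ds, rs), "unknown miRNA")

  idds <- diag(3); dimnames(idds) <- dimnames(ds)
  idrs <- diag(4); dimnames(idrs) <- dimnames(rs)
  vi <- similarity_pair_vector("d1", "r4", idds, idrs)
  expect_equal(sum(vi == 1), 2L)
  expect_equal(which(vi == 1), c(1L, 7L), ignore_attr = TRUE)

  pairs <- expand.grid(disease = rownames(ds), mirna = rownames(rs),
                       stringsAsFactors = FALSE)
  M <- similarity_pair_matrix(pairs, ds, rs)
  for (k in seq_len(nrow(pairs)))
    expect_equal(unname(M[k, ]),
                 unname(similarity_pair_vector(pairs$disease[k],
                                               pairs$mirna[k], ds, rs)))
})

test_that("embedding pair vectors concatenate the two node rows", {
  phi <- matrix(seq_len(12), 4, 3,
                dimnames = list(c("d1", "d2", "r1", "r2"), NULL))
  v <- embedding_pair_vector("d2", "r1", phi)
  expect_equal(unname(v), c(phi["d2", ], phi["r1", ]))
  expect_length(v, 6L)
  expect_equal(unname(embedding_pair_vector("d1", "r2", phi * 0)), rep(0, 6))
  expect_error(embedding_pair_vector("dX", "r1", phi), "unknown disease")
  pairs <- data.frame(disease = c("d1", "d2"), mirna = c("r2", "r2"))
  M <- embedding_pair_matrix(pairs, phi)
  expect_equal(unname(M[2, ]), unname(v * 0 + c(phi["d2", ], phi["r2", ])))
})

test_that("autoencoder improves on its initialisation and compresses", {
  set.seed(31)
  X <- matrix(runif(120 * 30), 120, 30)
  spec <- autoencoder_spec(input_dim = 30, hidden_dim = 16, code_dim = 8,
                           epochs = 40, seed = 7)
  ae <- fit_autoencoder(X, spec)
  expect_lt(ae$history[length(ae$history)], ae$history[1L])
  codes <- encode(ae, X)
  expect_equal(dim(codes), c(120L, 8L))
  # deterministic refit and deterministic encoding
  ae2 <- fit_autoencoder(X, spec)
  expect_identical(ae$par, ae2$par)
  expect_identical(codes, encode(ae, X))
  # identical inputs encode identically
  Xdup <- X[c(1, 1), , drop = FALSE]
  cd <- encode(ae, Xdup)
  expect_identical(cd[1, ], cd[2, ])
  expect_error(fit_autoencoder(X[0, ], spec), "empty")
  expect_error(encode(ae, X[, 1:10]), "width")
})

test_that("constant inputs are reconstructed almost exactly", {
  X <- matrix(rep(c(3, 7, 1, 5, 2), each = 50), 50, 5)
  ae <- fit_autoencoder(X, autoencoder_spec(input_dim = 5, hidden_dim = 4,
                                            code_dim = 2, epochs = 60, seed = 1))
  expect_lt(ae$history[length(ae$history)], 1e-6)
})

test_that("low-rank structure is captured well below input variance", {
  set.seed(17)
  U <- matrix(rnorm(150 * 10), 150, 10)
  V <- matrix(rnorm(10 * 60), 10, 60)
  X <- U %*% V
  spec <- scaled_autoencoder_spec(60)  # keeps the 913-512-256 proportions
  expect_equal(c(spec$input_dim, spec$hidden_dim, spec$code_dim),
               c(60L, 34L, 17L))
  ae <- fit_autoencoder(X, spec)
  Xs <- (sweep(X, 2, apply(X, 2, min))) %*% diag(1 / (apply(X, 2, max) - apply(X, 2, min)))
  expect_lt(ae$history[length(ae$history)], 0.1 * mean(apply(Xs, 2, stats::var)))
})

test_that("reference autoencoder widths are preserved at the reference input", {
  spec <- scaled_autoencoder_spec(913)
  expect_equal(c(spec$input_dim, spec$hidden_dim, spec$code_dim),
               c(913L, 512L, 256L))
})
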