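#' Control parameters for fitting and evaluation
#'
#' Collects every tunable of the method with its reference operating point:
#' similarity weights (0.2, 0.1, 0.2, 0.5), DeepWalk window 5 and dimension
#' 128, autoencoder proportions 913-512-256, deep-forest scan window 100
#' with four forests per cascade layer, fusion weight `lambda = 0.5`, and
#' five cross-validation folds. When a pair-feature set is shorter than the
#' scan window (small networks), the window is clamped to the feature
#' length so scanning degenerates gracefully to a single position.
#'
#' @param lambda fusion weight in \[0, 1\] for the similarity-model score.
#' @param n_folds cross-validation folds (>= 2).
#' @param weights a [similarity_weights()].
#' @param walk a [walk_config()].
#' @param autoencoder an [autoencoder_spec()]; rescaled to the actual
#'   similarity-feature width via [scaled_autoencoder_spec()].
#' @param forest a [deep_forest_config()] applied identically to both
#'   feature sets.
#' @param seed base seed; all stage seeds derive from it.
#' @param verbose emit stage progress messages.
#' @return An object of class `"stim_control"`.
#' @export
stim_control <- function(lambda = 0.5, n_folds = 5L,
                         weights = similarity_weights(),
                         walk = walk_config(),
                         autoencoder = autoencoder_spec(),
                         forest = deep_forest_config(),
                         seed = 1L, verbose = FALSE) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop2("lambda must lie in [0, 1]")
  stopifnot(n_folds >= 2, inherits(weights, "similarity_weights"),
            inherits(walk, "walk_config"),
            inherits(autoencoder, "autoencoder_spec"),
            inherits(forest, "deep_forest_config"))
  structure(list(lambda = lambda, n_folds = as.integer(n_folds),
                 weights = weights, walk = walk, autoencoder = autoencoder,
                 forest = forest, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "stim_control")
}

say <- function(control, fmt, ...) {
  if (control$verbose) message(sprintf(fmt, ...))
}

clamp_window <- function(cfg, feature_len, seed) {
  cfg$window <- min(cfg$window, feature_len)
  cfg$seed <- as.integer(seed)
  cfg
}

# Internal: train every model stage on one (training) network.
# negative_pool is the unlabeled complement of the FULL network, so sampled
# negatives can never be held-out positives.
train_stage <- function(train_net, ds, rs, negative_pool, control, seed) {
  walk_cfg <- control$walk; walk_cfg$seed <- as.integer(seed)
  say(control, "  DeepWalk: %d nodes", length(train_net$diseases) + length(train_net$mirnas))
  phi <- deepwalk(train_net, walk_cfg)

  positives <- train_net$edges
  negatives <- sample_negatives(negative_pool, nrow(positives), seed = seed + 1L)
  pairs <- rbind(positives, negatives)
  y <- rep(c(1L, 0L), c(nrow(positives), nrow(negatives)))
  ord <- order(pairs$disease, pairs$mirna)  # disease-major deterministic order
  pairs <- pairs[ord, , drop = FALSE]; y <- y[ord]

  sim_raw <- similarity_pair_matrix(pairs, ds, rs)
  ae_spec <- scaled_autoencoder_spec(ncol(sim_raw), control$autoencoder)
  ae_spec$seed <- as.integer(seed + 2L)
  say(control, "  autoencoder: %d -> %d on %d pair vectors",
      ae_spec$input_dim, ae_spec$code_dim, nrow(sim_raw))
  ae <- fit_autoencoder(sim_raw, ae_spec)
  sim_X <- encode(ae, sim_raw)
  dw_X <- embedding_pair_matrix(pairs, phi)

  say(control, "  deep forest on similarity codes (%d-d)", ncol(sim_X))
  model_sim <- deep_forest(sim_X, y,
                           clamp_window(control$forest, ncol(sim_X), seed + 3L))
  say(control, "  deep forest on DeepWalk features (%d-d)", ncol(dw_X))
  model_dw <- deep_forest(dw_X, y,
                          clamp_window(control$forest, ncol(dw_X), seed + 4L))

  list(phi = phi, ae = ae, model_sim = model_sim, model_dw = model_dw,
       train_pairs = cbind(pairs, label = y))
}

score_stage <- function(stage, pairs, ds, rs, lambda) {
  s1 <- predict(stage$model_sim, encode(stage$ae, similarity_pair_matrix(pairs, ds, rs)))
  s2 <- predict(stage$model_dw, embedding_pair_matrix(pairs, stage$phi))
  data.frame(pairs, s1 = s1, s2 = s2, s = fuse_scores(s1, s2, lambda),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the similarity-plus-topology association model
#'
#' Trains the full predictor on a bilayer network: DeepWalk embeddings of
#' the association network, an autoencoder compressing the concatenated
#' DS/RS row-vector features of the training pairs, and two deep-forest
#' classifiers (one per feature family) whose scores are fused with weight
#' `lambda`. Training positives are all known associations; pseudo-negatives
#' are drawn 1:1 uniformly from the unlabeled pairs.
#'
#' @param net an [association_network()] of known associations.
#' @param ds disease similarity matrix over `net$diseases` (see
#'   [ds_matrix()]).
#' @param rs combined miRNA similarity matrix over `net$mirnas` (see
#'   [combine_similarity()]).
#' @param control a [stim_control()].
#' @return An object of class `"stim"` with `predict`, `print` and
#'   `summary` methods.
#' @seealso [stim_from_bundle()] to start from raw tables, [stim_cv()] for
#'   the cross-validated evaluation.
#' @export
stim <- function(net, ds, rs, control = stim_control()) {
  stopifnot(inherits(net, "assoc_network"), inherits(control, "stim_control"))
  if (!identical(rownames(ds), net$diseases))
    stop2("DS matrix rows must match the network's disease list")
  if (!identical(rownames(rs), net$mirnas))
    stop2("RS matrix rows must match the network's miRNA list")
  if (!nrow(net$edges)) stop2("association network has no edges to train on")
  pool <- enumerate_unlabeled(net)
  say(control, "training on full network (%d positives)", nrow(net$edges))
  stage <- train_stage(net, ds, rs, pool, control, seed = control$seed)
  structure(list(net = net, ds = ds, rs = rs, control = control,
                 stage = stage),
            class = "stim")
}

#' @rdname stim
#' @param bundle a [simulate_bilayer()] / [read_bundle()] bundle.
#' @export
stim_from_bundle <- function(bundle, control = stim_control()) {
  stopifnot(inherits(bundle, "stim_bundle"))
  sims <- build_similarities(bundle$net, bundle$disease_genes, bundle$gene_net,
                             bundle$mirna_targets, bundle$mirna_family,
                             bundle$mirna_cluster, bundle$rsd,
                             weights = control$weights)
  stim(bundle$net, sims$ds, sims$rs, control = control)
}

#' Predict candidate associations with a fitted model
#'
#' Scores, for each requested disease, every miRNA not already linked to it
#' in the training network, and ranks candidates by the fused score
#' (ties broken lexicographically).
#'
#' @param object a fitted [stim()] model.
#' @param diseases disease IDs to score (default: all with at least one
#'   training association).
#' @param top_k optional per-disease cutoff on the returned ranking.
#' @param ... unused.
#' @return data frame with columns `disease`, `mirna`, `s1`, `s2`, `s`,
#'   `rank` (1 = best per disease).
#' @export
predict.stim <- function(object, diseases = NULL, top_k = NULL, ...) {
  net <- object$net
  diseases <- diseases %||% sort(unique(net$edges$disease))
  unknown <- setdiff(diseases, net$diseases)
  if (length(unknown))
    stop2("unknown disease ID(s): ", paste(unknown, collapse = ", "),
          ". Available: ", paste(utils::head(net$diseases, 10), collapse = ", "),
          if (length(net$diseases) > 10) ", ..." else "")
  linked <- split(net$edges$mirna, net$edges$disease)
  cand <- do.call(rbind, lapply(diseases, function(d) {
    m <- setdiff(net$mirnas, linked[[d]])
    if (!length(m)) return(NULL)
    data.frame(disease = d, mirna = m, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || !nrow(cand))
    return(data.frame(disease = character(), mirna = character(),
                      s1 = numeric(), s2 = numeric(), s = numeric(),
                      rank = integer()))
  scored <- score_stage(object$stage, cand, object$ds, object$rs,
                        object$control$lambda)
  out <- do.call(rbind, lapply(split(scored, scored$disease), function(df) {
    df <- df[order(-df$s, df$mirna), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    if (!is.null(top_k)) df <- utils::head(df, top_k)
    df
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.stim <- function(x, ...) {
  cat("Similarity + topology disease-miRNA association model\n")
  print(x$net)
  cat(sprintf("  fusion lambda = %.2f; DeepWalk dim %d; encoded similarity dim %d\n",
              x$control$lambda, x$control$walk$dim,
              x$stage$ae$spec$code_dim))
  invisible(x)
}

#' @export
summary.stim <- function(object, ...) {
  cat("Model stages\n")
  print(object$stage$ae)
  cat("  similarity-feature forest: "); print(object$stage$model_sim)
  cat("  topology-feature forest:   "); print(object$stage$model_dw)
  cat(sprintf("  trained on %d positive and %d sampled negative pairs\n",
              sum(object$stage$train_pairs$label == 1L),
              sum(object$stage$train_pairs$label == 0L)))
  invisible(object)
}
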