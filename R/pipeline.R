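#' Run configuration for the end-to-end pipeline
#'
#' Builds the run configuration consumed by [run_stim_pipeline()], either
#' programmatically or from a YAML file whose keys mirror the arguments.
#' Input paths point at the plain-text tables described in [stim-io];
#' parameter blocks (`weights`, `walk`, `autoencoder`, `forest`) override
#' individual defaults of the corresponding constructors.
#'
#' @param associations,gene_network,disease_genes,mirna_targets,mirna_family,mirna_cluster,rsd
#'   input file paths.
#' @param output_dir directory for run artifacts.
#' @param lambda,n_folds,seed,verbose evaluation settings (see
#'   [stim_control()]).
#' @param weights,walk,autoencoder,forest named lists of overrides for
#'   [similarity_weights()], [walk_config()], [autoencoder_spec()],
#'   [deep_forest_config()].
#' @param evaluate run the cross-validated evaluation.
#' @param top_k rows kept per disease in the exported candidate ranking.
#' @return A named list of class `"stim_config"`.
#' @export
stim_config <- function(associations, gene_network, disease_genes,
                        mirna_targets, mirna_family, mirna_cluster, rsd,
                        output_dir = "stim_run", lambda = 0.5, n_folds = 5L,
                        seed = 1L, verbose = FALSE, weights = list(),
                        walk = list(), autoencoder = list(), forest = list(),
                        evaluate = TRUE, top_k = 30L) {
  cfg <- list(associations = associations, gene_network = gene_network,
              disease_genes = disease_genes, mirna_targets = mirna_targets,
              mirna_family = mirna_family, mirna_cluster = mirna_cluster,
              rsd = rsd, output_dir = output_dir, lambda = lambda,
              n_folds = as.integer(n_folds), seed = as.integer(seed),
              verbose = isTRUE(verbose), weights = weights, walk = walk,
              autoencoder = autoencoder, forest = forest,
              evaluate = isTRUE(evaluate), top_k = as.integer(top_k))
  class(cfg) <- "stim_config"
  cfg
}

#' @rdname stim_config
#' @param path YAML file with the same keys.
#' @export
read_stim_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  do.call(stim_config, yaml::read_yaml(path))
}

config_control <- function(cfg) {
  stim_control(
    lambda = cfg$lambda, n_folds = cfg$n_folds,
    weights = do.call(similarity_weights, cfg$weights),
    walk = do.call(walk_config, cfg$walk),
    autoencoder = do.call(autoencoder_spec, cfg$autoencoder),
    forest = do.call(deep_forest_config, cfg$forest),
    seed = cfg$seed, verbose = cfg$verbose)
}

#' Execute the full pipeline: network, features, models, evaluation
#'
#' Orchestrates the three stages end to end: (1) load the raw tables and
#' build the bilayer network's DS and RS matrices; (2) learn DeepWalk
#' embeddings and assemble both pair-feature families; (3) train the two
#' deep-forest models, fuse scores and (optionally) run the per-disease
#' five-fold evaluation. Artifacts written to `output_dir`:
#' `ds.tsv`, `rs.tsv`, `embeddings.txt` (word2vec text format),
#' `cv_scores.tsv`, `metrics.json`, `predictions.tsv` (top-k candidate
#' ranking per disease) and `manifest.json` (full configuration and seeds).
#' Two runs with identical configuration produce byte-identical artifacts.
#'
#' @param config a [stim_config()] or the path to its YAML form.
#' @return Invisibly, a list of class `"stim_run"` with elements `fit`
#'   (the [stim()] model), `cv` (the [stim_cv()] result or `NULL`),
#'   `similarities`, `config` and `paths`.
#' @export
run_stim_pipeline <- function(config) {
  if (is.character(config)) config <- read_stim_config(config)
  stopifnot(inherits(config, "stim_config"))
  inputs <- c("associations", "gene_network", "disease_genes",
              "mirna_targets", "mirna_family", "mirna_cluster", "rsd")
  for (f in inputs)
    if (!file.exists(config[[f]]))
      stop2("input file for '", f, "' not found: ", config[[f]])
  control <- config_control(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)

  say(control, "stage 1/3: building the bilayer network")
  net <- read_associations(config$associations)
  sims <- build_similarities(
    net,
    read_disease_gene_map(config$disease_genes),
    read_gene_network(config$gene_network),
    read_mirna_map(config$mirna_targets, "target"),
    read_mirna_map(config$mirna_family, "family"),
    read_mirna_map(config$mirna_cluster, "cluster"),
    read_similarity_matrix(config$rsd),
    weights = control$weights)
  write_similarity_matrix(sims$ds, out("ds.tsv"))
  write_similarity_matrix(sims$rs, out("rs.tsv"))

  cv <- NULL
  if (config$evaluate) {
    say(control, "stage 2/3: cross-validated evaluation")
    cv <- stim_cv(net, sims$ds, sims$rs, control = control)
    utils::write.table(cv$scores, out("cv_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mean_auc = cv$mean_auc,
           disease_metrics = cv$disease_metrics,
           k_values = cv$k_values, seed = cv$seed),
      out("metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  say(control, "stage 3/3: final model on the full network")
  fit <- stim(net, sims$ds, sims$rs, control = control)
  write_embeddings(fit$stage$phi, out("embeddings.txt"))
  preds <- predict(fit, top_k = config$top_k)
  utils::write.table(preds, out("predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- unclass(config)
  manifest$package_version <- as.character(utils::packageVersion("stim"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(structure(list(fit = fit, cv = cv, similarities = sims,
                           config = config,
                           paths = vapply(c("ds.tsv", "rs.tsv", "cv_scores.tsv",
                                            "metrics.json", "predictions.tsv",
                                            "embeddings.txt", "manifest.json"),
                                          out, "")),
                      class = "stim_run"))
}

#' Ranked candidate miRNAs for one disease
#'
#' Extracts the top-k candidate ranking (rank, miRNA, component scores and
#' fused score) for a named disease from a pipeline run or fitted model.
#'
#' @param run a `stim_run` (from [run_stim_pipeline()]) or a fitted
#'   [stim()] model.
#' @param disease disease ID.
#' @param top_k rows to return (0 gives an empty table with the header).
#' @return data frame with columns `rank`, `mirna`, `s1`, `s2`, `s`.
#' @export
predict_for_disease <- function(run, disease, top_k = 30L) {
  fit <- if (inherits(run, "stim_run")) run$fit else run
  stopifnot(inherits(fit, "stim"))
  ranked <- predict(fit, diseases = disease, top_k = max(0L, as.integer(top_k)))
  ranked[, c("rank", "mirna", "s1", "s2", "s")]
}
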