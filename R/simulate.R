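#' Specification of a synthetic bilayer-network fixture
#'
#' Planted-partition generator emulating the shape of the real inputs
#' (curated association lists, a functional gene network, target/family/
#' cluster annotation, a precomputed disease-derived miRNA similarity
#' matrix). Diseases and miRNAs are assigned to `n_blocks` latent
#' communities; a disease-miRNA association is drawn with probability
#' `within_block_edge_prob` inside a community and `cross_block_edge_prob`
#' across, so the premise of the method - similar diseases share miRNAs -
#' holds by construction and the signal strength is tunable. Setting the two
#' probabilities equal yields a null fixture with no recoverable signal.
#'
#' @param n_diseases,n_mirnas,n_genes entity counts.
#' @param n_blocks number of planted communities.
#' @param within_block_edge_prob,cross_block_edge_prob association
#'   probabilities inside/across blocks; within must be >= cross.
#' @param gene_overlap_strength probability that a disease carries each gene
#'   of its block's gene module (drives the DS signal).
#' @param target_pool_size number of distinct miRNA target IDs.
#' @param seed integer seed.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_diseases = 30L, n_mirnas = 50L, n_genes = 120L,
                         n_blocks = 3L, within_block_edge_prob = 0.5,
                         cross_block_edge_prob = 0.02,
                         gene_overlap_strength = 0.8,
                         target_pool_size = 120L, seed = 1L) {
  probs <- c(within_block_edge_prob, cross_block_edge_prob,
             gene_overlap_strength)
  if (any(probs < 0 | probs > 1)) stop2("probabilities must lie in [0, 1]")
  if (cross_block_edge_prob > within_block_edge_prob)
    stop2("cross_block_edge_prob (", cross_block_edge_prob,
          ") exceeds within_block_edge_prob (", within_block_edge_prob,
          "): no planted signal is possible")
  stopifnot(n_diseases >= n_blocks, n_mirnas >= n_blocks, n_genes >= n_blocks,
            n_blocks >= 1, target_pool_size >= n_blocks)
  structure(list(n_diseases = as.integer(n_diseases),
                 n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes), n_blocks = as.integer(n_blocks),
                 within_block_edge_prob = within_block_edge_prob,
                 cross_block_edge_prob = cross_block_edge_prob,
                 gene_overlap_strength = gene_overlap_strength,
                 target_pool_size = as.integer(target_pool_size),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a synthetic bilayer-network bundle
#'
#' Draws every input table of the pipeline under the planted-partition model
#' of a [fixture_spec()]: block-structured associations; per-block gene
#' modules shared by same-block diseases; an LLS gene network dense inside
#' modules; block-aligned miRNA target sets, families and genomic clusters;
#' and a noisy block-similarity matrix standing in for the disease-derived
#' miRNA similarity. Fully reproducible under the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return An object of class `"stim_bundle"`: list with `net`
#'   (association network), `disease_genes`, `gene_net`, `mirna_targets`,
#'   `mirna_family`, `mirna_cluster`, `rsd`, `blocks` (planted labels) and
#'   `spec`.
#' @export
simulate_bilayer <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  diseases <- pad_ids("disease", spec$n_diseases)
  mirnas <- pad_ids("mirna", spec$n_mirnas)
  genes <- pad_ids("gene", spec$n_genes)
  d_block <- setNames(rep_len(seq_len(spec$n_blocks), spec$n_diseases), diseases)
  r_block <- setNames(rep_len(seq_len(spec$n_blocks), spec$n_mirnas), mirnas)
  g_block <- setNames(rep_len(seq_len(spec$n_blocks), spec$n_genes), genes)

  # bipartite associations
  p <- ifelse(outer(d_block, r_block, `==`),
              spec$within_block_edge_prob, spec$cross_block_edge_prob)
  hit <- matrix(runif(length(p)) < p, nrow(p), ncol(p))
  idx <- which(hit, arr.ind = TRUE)
  net <- association_network(
    data.frame(disease = diseases[idx[, 1L]], mirna = mirnas[idx[, 2L]],
               stringsAsFactors = FALSE),
    diseases = diseases, mirnas = mirnas)

  # disease gene sets: block module + sparse background
  disease_genes <- lapply(diseases, function(d) {
    module <- genes[g_block == d_block[[d]]]
    background <- genes[g_block != d_block[[d]]]
    g <- c(module[runif(length(module)) < spec$gene_overlap_strength],
           background[runif(length(background)) < 0.05])
    if (!length(g)) g <- module[sample.int(length(module), 1L)]
    sort(g)
  })
  names(disease_genes) <- diseases

  # LLS network: strong within-module edges, weak sparse cross edges
  gp <- utils::combn(seq_len(spec$n_genes), 2L)
  same <- g_block[gp[1L, ]] == g_block[gp[2L, ]]
  keep <- runif(ncol(gp)) < ifelse(same, 0.3, 0.02)
  lls <- ifelse(same, runif(ncol(gp), 0.5, 2), runif(ncol(gp), 0.05, 0.3))
  gene_net <- gene_network(data.frame(
    gene1 = genes[gp[1L, keep]], gene2 = genes[gp[2L, keep]],
    lls = lls[keep], stringsAsFactors = FALSE))

  # target sets aligned with blocks
  targets <- pad_ids("target", spec$target_pool_size)
  t_block <- rep_len(seq_len(spec$n_blocks), spec$target_pool_size)
  mirna_targets <- lapply(mirnas, function(r) {
    own <- targets[t_block == r_block[[r]]]
    other <- targets[t_block != r_block[[r]]]
    sort(c(own[runif(length(own)) < 0.3], other[runif(length(other)) < 0.02]))
  })
  names(mirna_targets) <- mirnas

  # families (size ~4) and clusters (size ~3), nested inside blocks
  group_partition <- function(prefix, size) {
    out <- character(length(mirnas)); names(out) <- mirnas
    for (b in seq_len(spec$n_blocks)) {
      members <- sample(mirnas[r_block == b])
      grp <- ceiling(seq_along(members) / size)
      out[members] <- sprintf("%s_b%d_%d", prefix, b, grp)
    }
    lapply(as.list(out), identity)
  }
  mirna_family <- group_partition("fam", 4L)
  mirna_cluster <- group_partition("clu", 3L)

  # disease-derived miRNA similarity: block similarity plus noise, in [0, 1]
  base <- ifelse(outer(r_block, r_block, `==`), 0.55, 0.12)
  noise <- matrix(rnorm(length(base), 0, 0.08), nrow(base))
  noise <- (noise + t(noise)) / 2
  rsd <- pmin(pmax(base + noise, 0), 1)
  diag(rsd) <- 1
  dimnames(rsd) <- list(mirnas, mirnas)

  structure(list(net = net, disease_genes = disease_genes,
                 gene_net = gene_net, mirna_targets = mirna_targets,
                 mirna_family = mirna_family, mirna_cluster = mirna_cluster,
                 rsd = rsd,
                 blocks = list(disease = d_block, mirna = r_block,
                               gene = g_block),
                 spec = spec),
            class = "stim_bundle")
}

#' @export
print.stim_bundle <- function(x, ...) {
  cat(sprintf("Synthetic bilayer bundle: %d diseases x %d miRNAs (%d blocks), %d associations\n",
              length(x$net$diseases), length(x$net$mirnas),
              x$spec$n_blocks, nrow(x$net$edges)))
  invisible(x)
}

two_col_df <- function(map, col1, col2) {
  data.frame(setNames(list(rep(names(map), lengths(map)),
                           unlist(map, use.names = FALSE)), c(col1, col2)),
             stringsAsFactors = FALSE)
}

#' Write / read a fixture bundle as plain-text files
#'
#' Persists every table in the TSV dialects consumed by the loaders, plus a
#' `manifest.json` recording the generator spec, the full entity lists and
#' the planted block labels.
#'
#' @param bundle a [simulate_bilayer()] result.
#' @param dir output directory (created if needed).
#' @return `write_bundle()`: the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "stim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(bundle$net$edges, "associations.tsv")
  w(bundle$gene_net$edges, "gene_network.tsv")
  w(two_col_df(bundle$disease_genes, "disease", "gene"), "disease_genes.tsv")
  w(two_col_df(bundle$mirna_targets, "mirna", "target"), "mirna_targets.tsv")
  w(two_col_df(bundle$mirna_family, "mirna", "family"), "mirna_family.tsv")
  w(two_col_df(bundle$mirna_cluster, "mirna", "cluster"), "mirna_cluster.tsv")
  write_similarity_matrix(bundle$rsd, file.path(dir, "rsd.tsv"))
  jsonlite::write_json(
    list(spec = unclass(bundle$spec),
         diseases = bundle$net$diseases, mirnas = bundle$net$mirnas,
         blocks = lapply(bundle$blocks, as.list)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @return `read_bundle()`: a `stim_bundle` (block labels restored from the
#'   manifest).
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spec <- do.call(fixture_spec, as.list(manifest$spec))
  net <- read_associations(file.path(dir, "associations.tsv"),
                           diseases = manifest$diseases,
                           mirnas = manifest$mirnas)
  structure(list(
    net = net,
    disease_genes = read_disease_gene_map(file.path(dir, "disease_genes.tsv")),
    gene_net = read_gene_network(file.path(dir, "gene_network.tsv")),
    mirna_targets = read_mirna_map(file.path(dir, "mirna_targets.tsv"), "target"),
    mirna_family = read_mirna_map(file.path(dir, "mirna_family.tsv"), "family"),
    mirna_cluster = read_mirna_map(file.path(dir, "mirna_cluster.tsv"), "cluster"),
    rsd = read_similarity_matrix(file.path(dir, "rsd.tsv")),
    blocks = lapply(manifest$blocks, unlist),
    spec = spec), class = "stim_bundle")
}

#' Planted-signal recovery report
#'
#' Runs the full pipeline (similarity construction, DeepWalk, autoencoder,
#' two deep forests, score fusion) under per-disease five-fold
#' cross-validation on a synthetic bundle and reports how well the planted
#' associations are recovered.
#'
#' @param bundle a [simulate_bilayer()] result.
#' @param control a [stim_control()].
#' @param seed evaluation seed (folds, negative draws, model seeds).
#' @return An object of class `"stim_recovery"`: list with `mean_auc`,
#'   `mean_pre10`, `mean_rec10`, `per_disease` (data frame) and the
#'   underlying `cv` object.
#' @export
holdout_recovery_check <- function(bundle, control = stim_control(),
                                   seed = control$seed) {
  stopifnot(inherits(bundle, "stim_bundle"))
  sims <- build_similarities(bundle$net, bundle$disease_genes, bundle$gene_net,
                             bundle$mirna_targets, bundle$mirna_family,
                             bundle$mirna_cluster, bundle$rsd,
                             weights = control$weights)
  cv <- stim_cv(bundle$net, sims$ds, sims$rs, control = control, seed = seed)
  pd <- cv$disease_metrics
  structure(list(mean_auc = mean(pd$auc, na.rm = TRUE),
                 mean_pre10 = mean(pd$pre_at_10, na.rm = TRUE),
                 mean_rec10 = mean(pd$rec_at_10, na.rm = TRUE),
                 per_disease = pd, cv = cv, seed = seed),
            class = "stim_recovery")
}

#' @export
print.stim_recovery <- function(x, ...) {
  cat(sprintf("Planted-signal recovery over %d diseases: mean AUC %.3f, PRE@10 %.3f, REC@10 %.3f\n",
              nrow(x$per_disease), x$mean_auc, x$mean_pre10, x$mean_rec10))
  invisible(x)
}
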