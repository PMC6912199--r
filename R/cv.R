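#' Per-disease five-fold cross-validated evaluation
#'
#' Implements the evaluation protocol of the method: each eligible disease's
#' known miRNAs are randomly split into `n_folds` subsets; in turn one
#' subset is hidden and the remaining associations act as known information.
#' The held-out edges are removed from the association network before walk
#' generation, the autoencoder and both deep forests are refitted on the
#' fold's training pairs (pseudo-negatives are redrawn per fold from the
#' unlabeled complement of the full network, so a held-out positive can
#' never be sampled as a negative), and every miRNA not linked to a disease
#' in the training network is scored as a candidate. Per disease and fold,
#' AUC compares held-out positives against all remaining candidates;
#' precision/recall are computed over the top-k ranking at
#' k = 10, 20, ..., 100.
#'
#' @param net an [association_network()].
#' @param ds,rs similarity matrices (see [stim()]).
#' @param control a [stim_control()].
#' @param seed evaluation seed (defaults to `control$seed`).
#' @param k_values cutoffs for precision/recall at k.
#' @return An object of class `"stim_cv"`: list with
#'   \item{scores}{data frame `fold, disease, mirna, label, s1, s2, s` of
#'     every scored candidate pair}
#'   \item{fold_metrics}{per (disease, fold) AUC and top-k metrics}
#'   \item{disease_metrics}{per-disease means across folds}
#'   \item{mean_auc}{grand mean of the per-disease AUCs}
#' @export
stim_cv <- function(net, ds, rs, control = stim_control(),
                    seed = control$seed, k_values = seq(10L, 100L, 10L)) {
  stopifnot(inherits(net, "assoc_network"), inherits(control, "stim_control"))
  seed <- as.integer(seed)
  folds <- cv_fold_assignments(net, control$n_folds, seed = seed)
  eligible <- attr(folds, "eligible")
  if (!length(eligible))
    stop2("no disease has >= ", control$n_folds, " positives; nothing to evaluate")
  pool <- enumerate_unlabeled(net)
  linked_full <- split(net$edges$mirna, net$edges$disease)

  all_scores <- vector("list", control$n_folds)
  fold_rows <- list()
  for (k in seq_len(control$n_folds)) {
    say(control, "fold %d/%d", k, control$n_folds)
    held <- folds[folds$fold == k, , drop = FALSE]
    train_net <- drop_edges(net, held)
    stage <- train_stage(train_net, ds, rs, pool, control,
                         seed = seed + 100L * k)

    linked_train <- split(train_net$edges$mirna, train_net$edges$disease)
    held_by_disease <- split(held$mirna, held$disease)
    cand <- do.call(rbind, lapply(eligible, function(d) {
      m <- setdiff(net$mirnas, linked_train[[d]])
      if (!length(m)) return(NULL)
      data.frame(disease = d, mirna = m, stringsAsFactors = FALSE)
    }))
    scored <- score_stage(stage, cand, ds, rs, control$lambda)
    scored$label <- as.integer(pair_keys(scored$disease, scored$mirna) %in%
                                 pair_keys(held$disease, held$mirna))
    scored <- data.frame(fold = k, scored[, c("disease", "mirna", "label",
                                              "s1", "s2", "s")],
                         stringsAsFactors = FALSE)
    all_scores[[k]] <- scored

    for (d in eligible) {
      dd <- scored[scored$disease == d, , drop = FALSE]
      hpos <- held_by_disease[[d]] %||% character()
      if (!length(hpos) || !nrow(dd)) next
      auc <- if (any(dd$label == 1L) && any(dd$label == 0L))
        roc_auc(dd$label, dd$s) else NA_real_
      ranked <- rank_candidates(dd, d)
      pr <- vapply(k_values, function(kk)
        precision_recall_at_k(ranked, hpos, kk), c(pre = 0, rec = 0))
      row <- data.frame(disease = d, fold = k, n_held_out = length(hpos),
                        n_candidates = nrow(dd), auc = auc,
                        stringsAsFactors = FALSE)
      row[paste0("pre_at_", k_values)] <- pr["pre", ]
      row[paste0("rec_at_", k_values)] <- pr["rec", ]
      fold_rows[[length(fold_rows) + 1L]] <- row
    }
  }

  fold_metrics <- do.call(rbind, fold_rows)
  rownames(fold_metrics) <- NULL
  metric_cols <- setdiff(names(fold_metrics), c("disease", "fold"))
  disease_metrics <- do.call(rbind, lapply(split(fold_metrics, fold_metrics$disease),
    function(df) {
      out <- data.frame(disease = df$disease[1L], n_folds = nrow(df),
                        stringsAsFactors = FALSE)
      for (cc in metric_cols) out[[cc]] <- mean(df[[cc]], na.rm = TRUE)
      out
    }))
  rownames(disease_metrics) <- NULL

  scores <- do.call(rbind, all_scores)
  rownames(scores) <- NULL
  structure(list(scores = scores, fold_metrics = fold_metrics,
                 disease_metrics = disease_metrics,
                 mean_auc = mean(disease_metrics$auc, na.rm = TRUE),
                 eligible = eligible, k_values = k_values,
                 control = control, seed = seed),
            class = "stim_cv")
}

#' @export
print.stim_cv <- function(x, ...) {
  cat(sprintf("Five-fold per-disease evaluation: %d diseases, mean AUC %.3f\n",
              length(x$eligible), x$mean_auc))
  invisible(x)
}

#' @export
summary.stim_cv <- function(object, ...) {
  print(object)
  cat(sprintf("  mean PRE@10 %.3f, mean REC@10 %.3f over %d scored pairs\n",
              mean(object$disease_metrics$pre_at_10, na.rm = TRUE),
              mean(object$disease_metrics$rec_at_10, na.rm = TRUE),
              nrow(object$scores)))
  invisible(object$disease_metrics)
}
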