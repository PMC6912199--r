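#' Deep-forest configuration
#'
#' Settings for the two-stage deep forest: multi-grained scanning (a window
#' of `window` adjacent features slides with stride 1 over each pair vector;
#' every window instance is classified by small forests whose class
#' probabilities become the scanned representation) followed by a cascade in
#' which each layer holds four forests (two random forests and two
#' completely-random forests) whose class-probability outputs augment the
#' next layer's input. The reference operating point uses a window of 100
#' and 2 classes.
#'
#' @param window scan window width (must not exceed the feature length).
#' @param n_classes number of classes (binary association prediction: 2).
#' @param forests_per_layer forests in each cascade layer.
#' @param trees_per_forest trees per cascade forest.
#' @param scan_trees trees per scanning forest (smaller: they see every
#'   window instance).
#' @param max_layers cap on cascade depth.
#' @param early_stop_rounds stop growing after this many layers without
#'   improvement of the internal validation accuracy.
#' @param cv_folds folds of the fit-time cross-validation that produces
#'   leak-free augmentation features and the validation accuracy.
#' @param seed integer seed; all forest seeds derive from it.
#' @return An object of class `"deep_forest_config"`.
#' @export
deep_forest_config <- function(window = 100L, n_classes = 2L,
                               forests_per_layer = 4L, trees_per_forest = 100L,
                               scan_trees = 15L, max_layers = 3L,
                               early_stop_rounds = 1L, cv_folds = 3L,
                               seed = 1L) {
  stopifnot(window >= 1, n_classes == 2L, forests_per_layer == 4L,
            trees_per_forest >= 1, scan_trees >= 1, max_layers >= 1,
            early_stop_rounds >= 1, cv_folds >= 2)
  structure(list(window = as.integer(window), n_classes = 2L,
                 forests_per_layer = 4L,
                 trees_per_forest = as.integer(trees_per_forest),
                 scan_trees = as.integer(scan_trees),
                 max_layers = as.integer(max_layers),
                 early_stop_rounds = as.integer(early_stop_rounds),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "deep_forest_config")
}

#' Sliding-window view of a feature matrix
#'
#' Slices each row into all `L - window + 1` contiguous windows (stride 1).
#' Rows of the result are grouped by window position: rows
#' `(p-1)*n + (1..n)` hold window `p` of all `n` samples.
#'
#' @param x numeric matrix (samples x features).
#' @param window window width.
#' @return `(n * (L - window + 1)) x window` matrix with attribute
#'   `positions`.
#' @export
sliding_windows <- function(x, window) {
  x <- as.matrix(x)
  L <- ncol(x)
  if (L < window)
    stop2("feature length ", L, " is shorter than the scan window ", window)
  P <- L - window + 1L
  out <- do.call(rbind, lapply(seq_len(P), function(p)
    x[, p:(p + window - 1L), drop = FALSE]))
  dimnames(out) <- list(NULL, paste0("w", seq_len(window)))
  attr(out, "positions") <- P
  out
}

# Internal: one probability forest. type "rf" = random forest with default
# mtry; "crf" = completely-random forest (single random split candidate on a
# single random feature, the gcForest convention).
fit_forest <- function(x, y, type, trees, seed) {
  args <- list(x = as.data.frame(x), y = y, num.trees = trees,
               probability = TRUE, seed = seed, num.threads = 1L,
               verbose = FALSE)
  if (type == "crf") {
    args$splitrule <- "extratrees"
    args$num.random.splits <- 1L
    args$mtry <- 1L
  }
  do.call(ranger::ranger, args)
}

forest_prob <- function(fit, x) {
  p <- predict(fit, data = as.data.frame(x), num.threads = 1L,
               verbose = FALSE)$predictions
  p[, c("0", "1"), drop = FALSE]
}

# Internal: fill never-out-of-bag rows of an OOB probability matrix with the
# column means (class priors); normalise defensively.
clean_oob <- function(p) {
  bad <- !stats::complete.cases(p)
  if (any(bad)) {
    fill <- colMeans(p, na.rm = TRUE)
    p[bad, ] <- matrix(fill, sum(bad), ncol(p), byrow = TRUE)
  }
  p / pmax(rowSums(p), .Machine$double.eps)
}

# Internal: reassemble per-instance window probabilities into per-sample scan
# features, concatenated by forest then window position.
scan_features <- function(prob_list, n, P) {
  out <- do.call(cbind, lapply(seq_along(prob_list), function(f) {
    pm <- prob_list[[f]]
    do.call(cbind, lapply(seq_len(P), function(p)
      pm[(p - 1L) * n + seq_len(n), , drop = FALSE]))
  }))
  nf <- length(prob_list); nc <- ncol(prob_list[[1L]])
  colnames(out) <- paste0("s", rep(seq_len(nf), each = P * nc),
                          "_p", rep(rep(seq_len(P), each = nc), nf),
                          "_c", rep(seq_len(nc) - 1L, nf * P))
  out
}

# Internal: class-stratified fold assignment, seeded.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

df_forest_seed <- function(seed, layer, idx) seed + 1000L * layer + idx

#' Fit a deep-forest classifier
#'
#' Multi-grained scanning: every training vector is sliced into sliding
#' windows, window instances inherit their sample's label, and two scanning
#' forests (one random, one completely random) are fitted on all instances.
#' Out-of-bag class probabilities of the training instances form the scanned
#' representation, so no instance is described by trees that saw it.
#'
#' Cascade: layer k receives the scanned representation concatenated with
#' layer k-1's eight augmentation features (4 forests x 2 classes). Each
#' layer's augmentation features and validation accuracy come from a
#' fit-time stratified cross-validation; a forest refitted on the full layer
#' input is kept for prediction. Growth stops when validation accuracy fails
#' to improve for `early_stop_rounds` layers or `max_layers` is reached, and
#' prediction uses the best layer.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y binary labels (0/1, logical, or 2-level factor); both classes
#'   must be present and `nrow(x) >= 10`.
#' @param config a [deep_forest_config()].
#' @return An object of class `"deep_forest"`.
#' @export
deep_forest <- function(x, y, config = deep_forest_config()) {
  stopifnot(inherits(config, "deep_forest_config"))
  x <- as.matrix(x)
  if (is.logical(y)) y <- as.integer(y)
  y <- as.character(y)
  if (!all(y %in% c("0", "1")))
    stop2("labels must be binary 0/1 (or logical)")
  y <- factor(y, levels = c("0", "1"))
  if (nlevels(droplevels(y)) < 2L)
    stop2("labels contain a single class; both classes are required")
  if (nrow(x) < 10L) stop2("at least 10 samples are required")
  if (nrow(x) != length(y)) stop2("x and y sizes differ")

  n <- nrow(x)
  W <- sliding_windows(x, config$window)
  P <- attr(W, "positions")
  yw <- factor(rep(as.character(y), P), levels = c("0", "1"))

  scan_types <- c("rf", "crf")
  scan_fits <- lapply(seq_along(scan_types), function(f)
    fit_forest(W, yw, scan_types[f], config$scan_trees,
               df_forest_seed(config$seed, 0L, f)))
  oob <- lapply(scan_fits, function(fit)
    clean_oob(fit$predictions[, c("0", "1"), drop = FALSE]))
  Z <- scan_features(oob, n, P)

  types <- c("rf", "rf", "crf", "crf")
  layers <- list()
  aug <- NULL
  best_acc <- -Inf; best_layer <- 0L; stale <- 0L
  for (layer in seq_len(config$max_layers)) {
    input <- if (is.null(aug)) Z else cbind(Z, aug)
    fold <- stratified_folds(y, config$cv_folds, config$seed + layer)
    cv_probs <- vector("list", 4L)
    full_fits <- vector("list", 4L)
    for (f in 1:4) {
      fseed <- df_forest_seed(config$seed, layer, f)
      cv_p <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("0", "1")))
      for (k in seq_len(config$cv_folds)) {
        tr <- fold != k
        fit_k <- fit_forest(input[tr, , drop = FALSE], y[tr], types[f],
                            config$trees_per_forest, fseed + 10L * k)
        cv_p[!tr, ] <- forest_prob(fit_k, input[!tr, , drop = FALSE])
      }
      cv_probs[[f]] <- cv_p
      full_fits[[f]] <- fit_forest(input, y, types[f],
                                   config$trees_per_forest, fseed)
    }
    aug_new <- do.call(cbind, cv_probs)
    colnames(aug_new) <- paste0("a", rep(1:4, each = 2L), "_c", rep(0:1, 4L))
    pos <- rowMeans(do.call(cbind, lapply(cv_probs, function(p) p[, "1"])))
    acc <- mean((pos > 0.5) == (y == "1"))
    layers[[layer]] <- list(forests = full_fits, val_accuracy = acc)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc; best_layer <- layer; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$early_stop_rounds) break
    }
    aug <- aug_new
  }

  structure(list(config = config, scan_fits = scan_fits,
                 scan_positions = P, feature_len = ncol(x),
                 layers = layers, n_layers_used = best_layer,
                 val_accuracy = best_acc, scan_train = Z,
                 class_balance = table(y)),
            class = "deep_forest")
}

#' @export
print.deep_forest <- function(x, ...) {
  cat(sprintf(paste0("Deep forest: window %d over %d features (%d positions), ",
                     "%d cascade layer(s) used of %d grown; validation accuracy %.3f\n"),
              x$config$window, x$feature_len, x$scan_positions,
              x$n_layers_used, length(x$layers), x$val_accuracy))
  invisible(x)
}

#' Multi-grained scan transform of new samples
#'
#' Applies the fitted scanning forests to every sliding window of `x` and
#' concatenates the class-probability vectors: output width =
#' `positions x scan forests x classes`.
#'
#' @param object a fitted [deep_forest()].
#' @param x feature matrix with the training feature length.
#' @return scan-feature matrix.
#' @export
multi_grained_scan <- function(object, x) {
  stopifnot(inherits(object, "deep_forest"))
  x <- as.matrix(x)
  if (ncol(x) != object$feature_len)
    stop2("feature length ", ncol(x), " does not match the trained length ",
          object$feature_len)
  W <- sliding_windows(x, object$config$window)
  probs <- lapply(object$scan_fits, forest_prob, x = W)
  scan_features(probs, nrow(x), attr(W, "positions"))
}

#' Predict association probabilities with a deep forest
#'
#' Runs scanning, then the cascade up to the layer selected at fit time; the
#' positive-class probability is the mean over that layer's four forests.
#'
#' @param object a fitted [deep_forest()].
#' @param x feature matrix (same width as training).
#' @param type `"prob"` for the positive-class probability vector,
#'   `"matrix"` for the two-column class-probability matrix.
#' @param ... unused.
#' @return numeric vector (or matrix) of probabilities in \[0, 1\].
#' @export
predict.deep_forest <- function(object, x, type = c("prob", "matrix"), ...) {
  type <- match.arg(type)
  Z <- multi_grained_scan(object, x)
  aug <- NULL
  out <- NULL
  for (layer in seq_len(object$n_layers_used)) {
    input <- if (is.null(aug)) Z else cbind(Z, aug)
    probs <- lapply(object$layers[[layer]]$forests, forest_prob, x = input)
    aug <- do.call(cbind, probs)
    colnames(aug) <- paste0("a", rep(1:4, each = 2L), "_c", rep(0:1, 4L))
    if (layer == object$n_layers_used) {
      pm <- Reduce(`+`, probs) / length(probs)
      out <- if (type == "prob") pm[, "1"] else pm
    }
  }
  out
}
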