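#' Configuration for the patient-specific sleep stager
#'
#' Defaults follow the semi-automated protocol: 9 manually scored training
#' days at equidistant positions, an optimised subset of 8 of the 21
#' features chosen by sequential forward selection, and model selection over
#' K-nearest-neighbours (K = 3..50) and Gaussian naive Bayes, each tried on
#' normalized and unnormalized features.
#'
#' @param n_training_days number of training days (default 9).
#' @param n_selected_features features retained by selection (default 8).
#' @param classifier_families candidate families, subset of
#'   `c("knn", "naive_bayes")`.
#' @param knn_k_range candidate neighbour counts (within 3..50).
#' @param use_normalized `"auto"` (try both and keep the better), `TRUE` or
#'   `FALSE`.
#' @param cv_folds stratified cross-validation folds.
#' @param max_train_epochs cap on training epochs (stratified subsample) to
#'   keep KNN model selection tractable on long recordings.
#' @param sfs_classifier classifier used inside feature selection
#'   (`list(family=, k=)`).
#' @return object of class `stager_config`.
#' @export
stager_config <- function(n_training_days = 9,
                          n_selected_features = 8,
                          classifier_families = c("knn", "naive_bayes"),
                          knn_k_range = 3:50,
                          use_normalized = "auto",
                          cv_folds = 5,
                          max_train_epochs = 3000,
                          sfs_classifier = list(family = "knn", k = 5)) {
  if (n_selected_features > 21) stop("cannot select more than 21 features")
  if (min(knn_k_range) < 3 || max(knn_k_range) > 50)
    stop("knn_k_range must lie within 3..50")
  structure(list(n_training_days = n_training_days,
                 n_selected_features = n_selected_features,
                 classifier_families = match.arg(classifier_families,
                                                 c("knn", "naive_bayes"),
                                                 several.ok = TRUE),
                 knn_k_range = knn_k_range,
                 use_normalized = use_normalized,
                 cv_folds = cv_folds,
                 max_train_epochs = max_train_epochs,
                 sfs_classifier = sfs_classifier),
            class = "stager_config")
}

#' Pruning thresholds
#'
#' Epochs with more than half their samples missing (or flagged
#' artifactual) become UNKNOWN; days with more than 30% UNKNOWN epochs are
#' excluded from all analyses.
#'
#' @param epoch_missing_threshold fraction of missing samples above which an
#'   epoch is unusable (default 0.5).
#' @param day_unknown_threshold fraction of UNKNOWN epochs above which a day
#'   is excluded (default 0.3).
#' @return object of class `pruning_rules`.
#' @export
pruning_rules <- function(epoch_missing_threshold = 0.5,
                          day_unknown_threshold = 0.3) {
  stopifnot(epoch_missing_threshold > 0, epoch_missing_threshold < 1,
            day_unknown_threshold > 0, day_unknown_threshold < 1)
  structure(list(epoch_missing_threshold = epoch_missing_threshold,
                 day_unknown_threshold = day_unknown_threshold),
            class = "pruning_rules")
}

#' Pick training days at equidistant positions
#'
#' @param usable_days sorted vector of usable day identifiers.
#' @param n number of training days (default 9).
#' @return `n` distinct day identifiers, evenly spaced over the usable
#'   range.
#' @export
select_training_days <- function(usable_days, n = 9) {
  usable_days <- sort(usable_days)
  N <- length(usable_days)
  if (N < n) stop("need at least ", n, " usable days, have ", N)
  pos <- unique(round(seq(1, N, length.out = n)))
  usable_days[pos]
}

# Stratified fold assignment, deterministic given the seed.
make_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

classify <- function(train_x, train_y, test_x, spec) {
  if (spec$family == "knn") {
    class::knn(as.matrix(train_x), as.matrix(test_x), train_y,
               k = min(spec$k, nrow(train_x)))
  } else {
    fit <- e1071::naiveBayes(as.data.frame(train_x), train_y)
    stats::predict(fit, as.data.frame(test_x))
  }
}

macro_recall <- function(truth, pred) {
  cls <- unique(truth)
  mean(vapply(cls, function(cl) mean(pred[truth == cl] == cl), 0))
}

cv_score <- function(x, y, spec, fold) {
  preds <- factor(rep(NA, length(y)), levels = levels(y))
  for (f in sort(unique(fold))) {
    te <- fold == f
    preds[te] <- classify(x[!te, , drop = FALSE], y[!te],
                          x[te, , drop = FALSE], spec)
  }
  c(macro = macro_recall(as.character(y), as.character(preds)),
    accuracy = mean(preds == y))
}

#' Greedy sequential forward feature selection
#'
#' Adds, one at a time, the feature that maximizes cross-validated
#' macro-averaged recall of the working classifier; ties break toward the
#' lower canonical column index.
#'
#' @param x numeric matrix, epochs x features (named columns).
#' @param y stage labels (factor or character).
#' @param target_count number of features to select.
#' @param classifier `list(family = "knn"|"naive_bayes", k =)`.
#' @param cv_folds stratified folds.
#' @param seed fold-assignment seed.
#' @return character vector of selected feature names, in selection order,
#'   with per-step CV scores as the `scores` attribute.
#' @export
sequential_feature_selection <- function(x, y, target_count = 8,
                                         classifier = list(family = "knn", k = 5),
                                         cv_folds = 5, seed = NULL) {
  x <- as.matrix(x)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- factor(as.character(y)[keep])
  if (nlevels(y) < 2) stop("training data contains a single class")
  usable <- apply(x, 2, function(v) stats::sd(v) > 0)
  if (target_count > sum(usable))
    stop("fewer usable features than target_count")
  fold <- make_folds(y, cv_folds, seed)
  selected <- character(0)
  scores <- numeric(0)
  candidates <- colnames(x)[usable]
  while (length(selected) < target_count) {
    step <- vapply(candidates, function(f)
      cv_score(x[, c(selected, f), drop = FALSE], y, classifier, fold)["macro"],
      0)
    best <- which.max(step)  # first max: lower canonical index wins ties
    selected <- c(selected, candidates[best])
    scores <- c(scores, step[best])
    candidates <- candidates[-best]
  }
  attr(selected, "scores") <- unname(scores)
  selected
}

#' Train a patient-specific sleep stager
#'
#' Runs sequential feature selection, then model selection over the
#' KNN/naive-Bayes grid on normalized and/or unnormalized features by
#' stratified cross-validation. Ties prefer fewer effective parameters:
#' naive Bayes over KNN, then smaller K.
#'
#' @param features epochs x 21 matrix (unnormalized scale).
#' @param labels stage label per epoch (training days' manual scores or
#'   simulator ground truth).
#' @param config a [stager_config()].
#' @param seed controls fold assignment and subsampling.
#' @return object of class `sleep_stager`.
#' @export
train_stager <- function(features, labels, config = stager_config(),
                         seed = NULL) {
  x <- as.matrix(features)
  keep <- stats::complete.cases(x) &
    !is.na(labels) & as.character(labels) != "UNKNOWN"
  x <- x[keep, , drop = FALSE]
  y <- factor(as.character(labels)[keep])
  if (nlevels(y) < 2) stop("training data contains a single class")
  scarce <- levels(y)[table(y) < config$cv_folds]
  if (length(scarce))
    stop("class absent from some cross-validation folds: ",
         paste(scarce, collapse = ", "))

  if (nrow(x) > config$max_train_epochs) {
    idx <- with_seed(child_seed(seed, 1), {
      unlist(lapply(split(seq_along(y), y), function(i)
        sample(i, max(config$cv_folds,
                      round(length(i) / nrow(x) * config$max_train_epochs)))))
    })
    x <- x[idx, , drop = FALSE]; y <- droplevels(y[idx])
  }

  norm <- quantile_normalize(x)
  reps <- switch(as.character(config$use_normalized),
                 "auto" = c(FALSE, TRUE),
                 "TRUE" = TRUE, "FALSE" = FALSE)
  fold <- make_folds(y, config$cv_folds, child_seed(seed, 2))

  best <- NULL
  for (use_norm in reps) {
    xr <- if (use_norm) norm$x else x
    xr <- xr[, !apply(is.na(xr), 2, any), drop = FALSE]
    sel <- sequential_feature_selection(
      xr, y, config$n_selected_features, config$sfs_classifier,
      config$cv_folds, seed = child_seed(seed, 3))
    xs <- xr[, sel, drop = FALSE]
    grid <- list()
    if ("naive_bayes" %in% config$classifier_families)
      grid <- c(grid, list(list(family = "naive_bayes", k = NA)))
    if ("knn" %in% config$classifier_families)
      grid <- c(grid, lapply(config$knn_k_range, function(k)
        list(family = "knn", k = k)))
    for (spec in grid) {
      sc <- cv_score(xs, y, spec, fold)
      if (is.null(best) || sc["macro"] > best$cv_macro + 1e-12) {
        best <- list(selected_features = sel, family = spec$family,
                     k = spec$k, normalized = use_norm,
                     cv_macro = unname(sc["macro"]),
                     cv_accuracy = unname(sc["accuracy"]))
      }
    }
  }

  stager <- c(best, list(
    norm_params = norm$params,
    train_x = x[, , drop = FALSE],
    train_y = y,
    class_counts = table(y),
    feature_names = colnames(x),
    config = config, seed = seed))
  class(stager) <- "sleep_stager"
  stager
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat("Patient-specific sleep stager\n")
  cat("  classifier:", x$family,
      if (x$family == "knn") paste0("(k = ", x$k, ")") else "", "\n")
  cat("  features  :", paste(x$selected_features, collapse = ", "), "\n")
  cat("  scale     :", if (x$normalized) "quantile-normalized" else "raw", "\n")
  cat(sprintf("  CV macro recall %.3f, accuracy %.3f (n = %d epochs)\n",
              x$cv_macro, x$cv_accuracy, length(x$train_y)))
  invisible(x)
}

#' Score epochs with a trained stager
#'
#' Scores 24-h blocks at a time; epochs whose selected features are missing
#' are labelled UNKNOWN.
#'
#' @param stager a [train_stager()] result.
#' @param features epochs x features matrix with named columns
#'   (unnormalized scale; normalization is applied internally if the stager
#'   was selected on normalized features).
#' @param timestamp optional POSIXct per epoch; when given, a
#'   [hypnogram()] is returned, otherwise a factor of labels.
#' @return hypnogram or factor.
#' @export
score_epochs <- function(stager, features, timestamp = NULL) {
  x <- as.matrix(features)
  missing_cols <- setdiff(stager$feature_names, colnames(x))
  if (length(missing_cols))
    stop("feature schema mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "))
  x <- x[, stager$feature_names, drop = FALSE]
  xr <- if (stager$normalized) quantile_normalize(x, stager$norm_params)$x else x
  xs <- xr[, stager$selected_features, drop = FALSE]
  train <- if (stager$normalized) {
    quantile_normalize(stager$train_x, stager$norm_params)$x
  } else stager$train_x
  train <- train[, stager$selected_features, drop = FALSE]

  labels <- rep("UNKNOWN", nrow(xs))
  ok <- stats::complete.cases(xs)
  blocks <- split(which(ok), (which(ok) - 1) %/% EPOCHS_PER_DAY)
  for (b in blocks) {
    labels[b] <- as.character(classify(
      train, stager$train_y, xs[b, , drop = FALSE],
      list(family = stager$family, k = stager$k)))
  }
  if (is.null(timestamp)) factor(labels, levels = STAGE_LEVELS)
  else hypnogram(timestamp, labels)
}

#' Prune a hypnogram by artifact and missing-data rules
#'
#' Artifactual epochs, and epochs missing more than half their samples,
#' become UNKNOWN. Days (noon-to-noon) whose UNKNOWN fraction exceeds the
#' day threshold are listed as excluded. Pruning is idempotent and never
#' converts UNKNOWN back into a stage.
#'
#' @param h a [hypnogram()].
#' @param artifact logical per epoch (or NULL).
#' @param missing_frac numeric per epoch, fraction of missing samples (or
#'   NULL).
#' @param rules a [pruning_rules()].
#' @return list with `hypnogram` (pruned) and `excluded_days` (Date
#'   vector of day keys).
#' @export
prune <- function(h, artifact = NULL, missing_frac = NULL,
                  rules = pruning_rules()) {
  n <- nrow(h)
  if (!is.null(artifact) && length(artifact) != n)
    stop("artifact mask is not aligned with the hypnogram")
  if (!is.null(missing_frac) && length(missing_frac) != n)
    stop("missing mask is not aligned with the hypnogram")
  lab <- as.character(h$label)
  if (!is.null(artifact)) lab[artifact] <- "UNKNOWN"
  if (!is.null(missing_frac))
    lab[missing_frac > rules$epoch_missing_threshold] <- "UNKNOWN"
  key <- day_key(h$timestamp)
  unk <- tapply(lab == "UNKNOWN", key, mean)
  excluded <- as.Date(names(unk)[unk > rules$day_unknown_threshold])
  list(hypnogram = hypnogram(h$timestamp, lab), excluded_days = excluded)
}

#' Agreement between a predicted and a reference hypnogram
#'
#' UNKNOWN epochs on either side are excluded pairwise. Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with the chance agreement from the marginal
#' label distributions.
#'
#' @param predicted,truth hypnograms (or label vectors) of equal length.
#' @return list with `accuracy`, `kappa`, `confusion` (truth x predicted),
#'   `n` and per-class recall.
#' @export
evaluate_scoring <- function(predicted, truth) {
  p <- if (inherits(predicted, "hypnogram")) as.character(predicted$label)
       else as.character(predicted)
  t <- if (inherits(truth, "hypnogram")) as.character(truth$label)
       else as.character(truth)
  if (length(p) != length(t)) stop("sequences must be aligned")
  keep <- p != "UNKNOWN" & t != "UNKNOWN"
  if (!any(keep)) stop("no overlapping labelled epochs")
  p <- p[keep]; t <- t[keep]
  cls <- sort(unique(c(p, t)))
  cm <- table(factor(t, cls), factor(p, cls), dnn = c("truth", "predicted"))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  list(accuracy = po, kappa = kappa, confusion = cm, n = n,
       per_class_recall = recall)
}
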