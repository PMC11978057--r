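# Cross-validation benchmarking: stratified fold assignment, leak-free
# per-fold extractor fitting (eigenbasis/codebook from training indices
# only, recorded in an audit), per-class precision, and the extractor x
# classifier comparison grid.

#' Stratified fold assignment
#'
#' Deals each class's (seeded, shuffled) indices round-robin into `folds`
#' folds, so fold class proportions track the dataset.
#'
#' @param labels Character vector of identities.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..folds), one per sample.
#' @export
stratified_folds <- function(labels, folds, seed = 1) {
  labels <- as.character(labels)
  counts <- table(labels)
  short <- names(counts)[counts < folds]
  if (length(short) > 0)
    stopf("stratification error: class %s has %d samples for %d folds",
          short[1], counts[short[1]], folds)
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cls in names(counts)) {
      idx <- sample(which(labels == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Per-class precision from a confusion matrix
#'
#' Precision of class c is the diagonal count divided by the column sum
#' (true positives over all positive predictions).  Classes never predicted
#' have undefined precision and are absent from the result.
#'
#' @param confusion Square count matrix, rows = true, columns = predicted,
#'   with matching dimnames.
#' @return Named numeric vector over the predicted classes.
#' @export
per_class_precision <- function(confusion) {
  confusion <- as.matrix(confusion)
  cs <- colSums(confusion)
  predicted <- cs > 0
  stats::setNames(diag(confusion)[predicted] / cs[predicted],
                  colnames(confusion)[predicted])
}

# shared CV engine: one extractor, per-fold features cached, then one or
# more classifiers evaluated on identical folds.
#
# Fold hygiene with acceptable cost: per-image quantities with no fitted
# state (LBP histograms, keypoint descriptors) are computed once and sliced
# per fold; fitted state (eigenbasis, codebook) is fitted per fold on the
# training indices only.  The eigenbasis fit uses the snapshot identity on a
# precomputed linear Gram matrix — centering and eigenvectors are taken from
# the training sub-Gram only, which is algebraically identical to fitting
# PCA on the training images (asserted by a regression test against the
# direct path).
cv_features_per_fold <- function(dataset, scheme, assign, seed, extractor_opts) {
  folds <- max(assign)
  seeds <- derive_seeds(seed + 7L, folds)
  if (scheme == "ef") {
    p <- length(unclass(dataset$images[[1]]))
    X <- t(vapply(dataset$images, function(im) as.vector(unclass(im)), numeric(p)))
    G <- tcrossprod(X)
    vt <- extractor_opts$variance_target %||% 0.90
    return(lapply(seq_len(folds), function(f) {
      tr <- which(assign != f); te <- which(assign == f)
      Gtr <- G[tr, tr]
      rm <- rowMeans(Gtr); gm <- mean(Gtr)
      Gc <- Gtr - outer(rm, rep(1, length(tr))) - outer(rep(1, length(tr)), rm) + gm
      eg <- eigen(Gc, symmetric = TRUE)
      lam <- eg$values
      keep <- lam > max(lam[1], 0) * 1e-10
      if (!any(keep)) stopf("degenerate data: all training images identical")
      lam <- lam[keep]
      ratio <- lam / sum(lam)
      k <- which(cumsum(ratio) >= vt - 1e-12)[1]
      W <- sweep(eg$vectors[, seq_len(k), drop = FALSE], 2, sqrt(lam[seq_len(k)]), "/")
      # centered cross-Gram of every image against the training set
      A <- G[tr, , drop = FALSE]
      Ac <- sweep(A, 2, colMeans(A)) - rm + gm
      scores <- crossprod(Ac, W)             # n x k projections
      ex <- structure(list(scheme = "ef",
                           state = list(explained_ratio = ratio[seq_len(k)]),
                           opts = extractor_opts, n_fit = length(tr)),
                      class = "face_extractor")
      list(train_x = scores[tr, , drop = FALSE], test_x = scores[te, , drop = FALSE],
           train_idx = tr, test_idx = te, extractor = ex)
    }))
  }
  if (scheme == "lbph") {
    spec <- extractor_opts$lbp %||% lbp_spec()
    Fm <- do.call(rbind, lapply(dataset$images, lbp_histogram, spec = spec))
    Fm <- span_scores(Fm)
    return(lapply(seq_len(folds), function(f) {
      tr <- which(assign != f); te <- which(assign == f)
      ex <- structure(list(scheme = "lbph", state = spec, opts = extractor_opts,
                           n_fit = length(tr)),
                      class = "face_extractor")
      list(train_x = Fm[tr, , drop = FALSE], test_x = Fm[te, , drop = FALSE],
           train_idx = tr, test_idx = te, extractor = ex)
    }))
  }
  if (scheme %in% c("sift_bow", "surf_bow")) {
    method <- sub("_bow", "", scheme)
    k <- extractor_opts$vocabulary %||% 200L
    desc <- lapply(dataset$images, extract_keypoints, method = method,
                   top_k = extractor_opts$top_k)
    return(lapply(seq_len(folds), function(f) {
      tr <- which(assign != f); te <- which(assign == f)
      cb <- fit_codebook(desc[tr], k = k, seed = seeds[f])
      Fm <- do.call(rbind, lapply(desc, encode_bow, codebook = cb))
      ex <- structure(list(scheme = scheme, state = cb, opts = extractor_opts,
                           n_fit = length(tr)),
                      class = "face_extractor")
      list(train_x = Fm[tr, , drop = FALSE], test_x = Fm[te, , drop = FALSE],
           train_idx = tr, test_idx = te, extractor = ex)
    }))
  }
  # fallback: generic per-fold refit through the public extractor surface
  lapply(seq_len(folds), function(f) {
    tr <- which(assign != f); te <- which(assign == f)
    ex <- fit_extractor(scheme, dataset$images[tr], seed = seeds[f],
                        opts = extractor_opts)
    list(train_x = transform_features(ex, dataset$images[tr]),
         test_x = transform_features(ex, dataset$images[te]),
         train_idx = tr, test_idx = te, extractor = ex)
  })
}

# lossless re-expression of an n x p feature matrix (p > n) in the
# orthonormal basis of its row span: all inner products and Euclidean
# distances are preserved exactly, so every downstream classifier is
# unchanged while kernel and distance computations drop from p to <= n
# dimensions
span_scores <- function(Fm) {
  n <- nrow(Fm); p <- ncol(Fm)
  if (p <= n) return(Fm)
  G <- tcrossprod(Fm)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > max(eg$values[1], 0) * 1e-12
  sweep(eg$vectors[, keep, drop = FALSE], 2, sqrt(eg$values[keep]), "*")
}

cv_run_classifier <- function(dataset, fold_features, spec, seed, classes,
                              inner_folds = 5L) {
  folds <- length(fold_features)
  seeds <- derive_seeds(seed + 13L, folds)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(folds)
  predicted_all <- character(length(dataset$labels))
  for (f in seq_len(folds)) {
    ff <- fold_features[[f]]
    model <- train_classifier(ff$train_x, dataset$labels[ff$train_idx],
                              spec, seed = seeds[f], inner_folds = inner_folds)
    conf <- predict_confidence(model, ff$test_x)
    pred <- classes[max.col(conf, ties.method = "first")]
    truth <- dataset$labels[ff$test_idx]
    fold_acc[f] <- mean(pred == truth)
    predicted_all[ff$test_idx] <- pred
    for (i in seq_along(pred))
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  }
  list(fold_acc = fold_acc, confusion = confusion, predicted = predicted_all)
}

#' Cross-validate one extractor x classifier combination
#'
#' Stratified k-fold cross-validation with leak-free extractor fitting: for
#' every fold the eigenface basis or visual-word codebook is fitted on that
#' fold's training indices only (recorded in the returned audit), the
#' classifier is tuned and trained on the training portion, and the held-out
#' fold is scored.  Every sample is tested exactly once.
#'
#' @param dataset A `face_dataset` ([synth_dataset()], [load_dataset()]).
#' @param extractor Scheme name (see [extractor_schemes()]), or a pre-built
#'   classifier objective; normally a string.
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment, codebook fits and
#'   classifier tuning.
#' @param extractor_opts Options forwarded to [fit_extractor()].
#' @param classifier_override For testing: a function
#'   `(train_x, train_labels, test_x) -> predicted labels` substituted for
#'   the classifier (e.g. an oracle or constant classifier).
#' @param inner_folds Inner CV folds for the hyperparameter-tuning
#'   objective (runtime knob; 5 is the default, smaller trades tuning
#'   stability for speed).
#' @return A `cv_report`: `fold_accuracies`, `mean_accuracy` (mean of fold
#'   accuracies), `pooled_accuracy` (fraction correct pooled over folds),
#'   `per_class_precision`, `confusion`, `audit` (per-fold fitted-index
#'   record), `extractor`, `classifier`.
#' @export
cross_validate <- function(dataset, extractor = "ef", spec = classifier_spec(),
                           folds = 10L, seed = 1, extractor_opts = list(),
                           classifier_override = NULL, inner_folds = 5L) {
  stopifnot(inherits(dataset, "face_dataset"))
  classes <- sort(unique(dataset$labels))
  assign <- stratified_folds(dataset$labels, folds, seed = seed)
  fold_features <- cv_features_per_fold(dataset, extractor, assign, seed,
                                        extractor_opts)
  if (is.null(classifier_override)) {
    run <- cv_run_classifier(dataset, fold_features, spec, seed, classes,
                             inner_folds = inner_folds)
  } else {
    confusion <- matrix(0L, length(classes), length(classes),
                        dimnames = list(true = classes, predicted = classes))
    fold_acc <- numeric(folds)
    predicted_all <- character(length(dataset$labels))
    for (f in seq_len(folds)) {
      ff <- fold_features[[f]]
      pred <- classifier_override(ff$train_x, dataset$labels[ff$train_idx], ff$test_x)
      truth <- dataset$labels[ff$test_idx]
      fold_acc[f] <- mean(pred == truth)
      predicted_all[ff$test_idx] <- pred
      for (i in seq_along(pred))
        confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
    }
    run <- list(fold_acc = fold_acc, confusion = confusion, predicted = predicted_all)
  }
  audit <- lapply(fold_features, function(ff)
    list(fit_indices = ff$train_idx, test_indices = ff$test_idx,
         n_fit = ff$extractor$n_fit))
  structure(list(extractor = if (is.character(extractor)) extractor else "custom",
                 classifier = spec,
                 fold_accuracies = run$fold_acc,
                 mean_accuracy = mean(run$fold_acc),
                 pooled_accuracy = mean(run$predicted == dataset$labels),
                 per_class_precision = per_class_precision(run$confusion),
                 confusion = run$confusion,
                 fold_assignment = assign,
                 audit = audit, folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s x %s, %d-fold>\n", x$extractor,
              if (inherits(x$classifier, "classifier_spec")) spec_label(x$classifier)
              else "custom", x$folds))
  cat(sprintf("  mean accuracy:   %.4f\n", x$mean_accuracy))
  cat(sprintf("  pooled accuracy: %.4f\n", x$pooled_accuracy))
  cat(sprintf("  fold range:      [%.4f, %.4f]\n",
              min(x$fold_accuracies), max(x$fold_accuracies)))
  invisible(x)
}

#' Extractor x classifier comparison grid
#'
#' Evaluates the full cross-product of extractor schemes and classifier
#' specs under one shared fold assignment, reusing each extractor's per-fold
#' features across all classifiers.  A failing cell is recorded as `NA` and
#' the grid completes.
#'
#' @param dataset A `face_dataset`.
#' @param extractors Character vector of schemes.
#' @param classifiers List of [classifier_spec()] objects.
#' @param folds,seed,inner_folds As in [cross_validate()].
#' @param extractor_opts Shared extractor options.
#' @return A `cv_grid`: `accuracy` matrix (classifiers x extractors, pooled
#'   accuracy), `mean_accuracy` matrix, `reports` (nested list of
#'   `cv_report`s), `errors`.
#' @export
comparison_grid <- function(dataset, extractors = extractor_schemes(),
                            classifiers = default_classifier_suite(),
                            folds = 10L, seed = 1, extractor_opts = list(),
                            inner_folds = 5L) {
  stopifnot(inherits(dataset, "face_dataset"))
  classes <- sort(unique(dataset$labels))
  assign <- stratified_folds(dataset$labels, folds, seed = seed)
  cl_names <- vapply(classifiers, spec_label, "")
  acc <- matrix(NA_real_, length(classifiers), length(extractors),
                dimnames = list(cl_names, extractors))
  macc <- acc
  reports <- stats::setNames(vector("list", length(extractors)), extractors)
  errors <- list()
  for (ex in extractors) {
    fold_features <- tryCatch(
      cv_features_per_fold(dataset, ex, assign, seed, extractor_opts),
      error = function(e) e)
    if (inherits(fold_features, "error")) {
      errors[[ex]] <- conditionMessage(fold_features)
      next
    }
    reports[[ex]] <- stats::setNames(vector("list", length(classifiers)), cl_names)
    for (ci in seq_along(classifiers)) {
      run <- tryCatch(
        cv_run_classifier(dataset, fold_features, classifiers[[ci]], seed, classes,
                          inner_folds = inner_folds),
        error = function(e) e)
      if (inherits(run, "error")) {
        errors[[paste(ex, cl_names[ci], sep = ":")]] <- conditionMessage(run)
        next
      }
      acc[ci, ex] <- mean(run$predicted == dataset$labels)
      macc[ci, ex] <- mean(run$fold_acc)
      reports[[ex]][[ci]] <- structure(
        list(extractor = ex, classifier = classifiers[[ci]],
             fold_accuracies = run$fold_acc,
             mean_accuracy = mean(run$fold_acc),
             pooled_accuracy = acc[ci, ex],
             per_class_precision = per_class_precision(run$confusion),
             confusion = run$confusion, fold_assignment = assign,
             folds = folds, seed = seed),
        class = "cv_report")
    }
  }
  structure(list(accuracy = acc, mean_accuracy = macc, reports = reports,
                 errors = errors, folds = folds, seed = seed),
            class = "cv_grid")
}

#' The classifier suite of the benchmarking grid
#'
#' kNN, LDA and SVM with linear, polynomial (degree 2 and 3) and RBF
#' kernels.
#'
#' @param max_evals Tuning-evaluation cap applied to every tunable spec.
#' @return List of [classifier_spec()] objects.
#' @export
default_classifier_suite <- function(max_evals = 50L) {
  list(classifier_spec("knn", max_evals = max_evals),
       classifier_spec("lda"),
       classifier_spec("svm", "linear", max_evals = max_evals),
       classifier_spec("svm", "poly2", max_evals = max_evals),
       classifier_spec("svm", "poly3", max_evals = max_evals),
       classifier_spec("svm", "rbf", max_evals = max_evals))
}

#' @export
print.cv_grid <- function(x, ...) {
  cat(sprintf("<cv_grid: %d classifiers x %d extractors, %d-fold, accuracy %%>\n",
              nrow(x$accuracy), ncol(x$accuracy), x$folds))
  print(round(100 * x$accuracy, 2))
  if (length(x$errors)) cat(sprintf("  failed cells: %s\n",
                                    paste(names(x$errors), collapse = ", ")))
  invisible(x)
}

#' Write a comparison grid as CSV (percent, 2 decimals)
#'
#' @param grid A `cv_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  m <- round(100 * grid$accuracy, 2)
  df <- data.frame(model = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
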