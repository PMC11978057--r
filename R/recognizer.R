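# The fitted-model interface: one fitting function returning a classed
# object with the usual methods.  A face_recognizer couples fitted extractor
# state (eigenbasis, codebook, LBP spec) with a tuned classifier.

#' Fit a face recognizer
#'
#' Fits the chosen feature extractor on the training images and trains a
#' classifier (with Bayesian hyperparameter tuning) on the extracted
#' features.  This is the model object the cross-validation benchmark and
#' the realtime identification layer both build on.
#'
#' @param images Training face crops: a list of [gray_image] at one
#'   resolution, or a `face_dataset` (in which case `labels` is taken from
#'   it).
#' @param labels Identity label per image.
#' @param extractor Scheme name: `"ef"` (eigenfaces, default), `"lbph"`,
#'   `"sift_bow"`, `"surf_bow"`.
#' @param classifier A [classifier_spec()]; default SVM with RBF kernel.
#' @param seed Integer seed (codebook fit, tuning).
#' @param extractor_opts Options forwarded to [fit_extractor()].
#' @return A `face_recognizer` with `extractor`, `model`, `classes`.
#' @export
face_recognizer <- function(images, labels = NULL, extractor = "ef",
                            classifier = classifier_spec("svm", "rbf"),
                            seed = 1, extractor_opts = list()) {
  if (inherits(images, "face_dataset")) {
    labels <- images$labels
    images <- images$images
  }
  if (is.null(labels)) stopf("labels are required")
  ex <- fit_extractor(extractor, images, seed = seed, opts = extractor_opts)
  X <- transform_features(ex, images)
  model <- train_classifier(X, labels, classifier, seed = seed)
  structure(list(extractor = ex, model = model, classes = model$classes,
                 crop_size = dim(unclass(images[[1]])),
                 n_train = length(images), seed = seed),
            class = "face_recognizer")
}

#' Predict identities or confidences for new face crops
#'
#' @param object A `face_recognizer`.
#' @param newdata List of [gray_image] crops (or a `face_dataset`), or an
#'   already-extracted feature matrix.
#' @param type `"class"` (default) for predicted identities, `"confidence"`
#'   for the per-class confidence matrix.
#' @param ... Unused.
#' @return Character vector of identities, or a confidence matrix with one
#'   row per crop summing to 1.
#' @export
predict.face_recognizer <- function(object, newdata, type = c("class", "confidence"),
                                    ...) {
  type <- match.arg(type)
  if (inherits(newdata, "face_dataset")) newdata <- newdata$images
  X <- if (is.matrix(newdata)) newdata
       else {
         if (inherits(newdata, "gray_image")) newdata <- list(newdata)
         transform_features(object$extractor, newdata)
       }
  conf <- predict_confidence(object$model, X)
  if (type == "confidence") conf
  else object$classes[max.col(conf, ties.method = "first")]
}

#' @export
print.face_recognizer <- function(x, ...) {
  cat(sprintf("<face_recognizer: %s + %s, %d identities, %d training images>\n",
              x$extractor$scheme, spec_label(x$model$spec),
              length(x$classes), x$n_train))
  invisible(x)
}

#' @export
summary.face_recognizer <- function(object, ...) {
  cat("Face recognizer\n")
  cat(sprintf("  extractor : %s\n", object$extractor$scheme))
  if (object$extractor$scheme == "ef")
    cat(sprintf("    %d components, %.1f%% cumulative variance\n",
                nrow(object$extractor$state$basis),
                100 * sum(object$extractor$state$explained_ratio)))
  if (object$extractor$scheme %in% c("sift_bow", "surf_bow"))
    cat(sprintf("    vocabulary %d words\n", object$extractor$state$k))
  cat(sprintf("  classifier: %s\n", spec_label(object$model$spec)))
  if (length(object$model$chosen_params))
    cat(sprintf("    tuned: %s\n",
                paste(names(object$model$chosen_params),
                      vapply(object$model$chosen_params,
                             function(v) format(v, digits = 4), ""),
                      sep = "=", collapse = ", ")))
  cat(sprintf("  classes   : %s\n", paste(object$classes, collapse = ", ")))
  cat(sprintf("  n_train   : %d\n", object$n_train))
  invisible(object)
}

#' Display the mean face and leading eigenfaces of an EF recognizer
#'
#' @param x A `face_recognizer` fitted with the `"ef"` extractor.
#' @param n_components Number of eigenfaces to draw.
#' @param ... Unused.
#' @export
plot.face_recognizer <- function(x, n_components = 5, ...) {
  if (x$extractor$scheme != "ef") {
    graphics::barplot(rep(1, length(x$classes)), names.arg = x$classes,
                      main = "classes", las = 2)
    return(invisible(x))
  }
  m <- x$extractor$state
  k <- min(n_components, nrow(m$basis))
  op <- graphics::par(mfrow = c(1, k + 1), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  draw <- function(v, title) {
    mm <- matrix(v, m$image_shape[1], m$image_shape[2])
    mm <- (mm - min(mm)) / max(1e-12, diff(range(mm)))
    graphics::image(t(mm)[, nrow(mm):1], col = grDevices::gray.colors(256),
                    axes = FALSE, main = title)
  }
  draw(m$mean_face, "mean face")
  for (i in seq_len(k)) draw(m$basis[i, ], sprintf("PC%d (%.1f%%)",
                                                   i, 100 * m$explained_ratio[i]))
  invisible(x)
}
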