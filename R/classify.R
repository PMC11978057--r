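# Classifier suite: support vector machines (linear, polynomial degree 2/3,
# RBF kernels; one-vs-one; dual solved with quadprog; Platt-style sigmoid
# calibration to per-class confidences), linear discriminant analysis
# (MASS::lda, untuned), and k-nearest neighbors (Euclidean, vote-fraction
# confidences).  Hyperparameters are chosen by Gaussian-process Bayesian
# optimization of inner cross-validated accuracy, capped at max_evals
# objective evaluations.

#' Classifier specification
#'
#' @param family `"svm"`, `"lda"` or `"knn"`.
#' @param kernel SVM kernel: `"rbf"` (default), `"linear"`, `"poly2"`,
#'   `"poly3"`.  Ignored for other families.
#' @param search_space Named list of hyperparameter ranges, each
#'   `list(lower, upper, log = FALSE, integer = FALSE)`; `NULL` uses the
#'   family defaults (SVM cost C in \[1e-3, 1e3\] log-scale, RBF gamma in
#'   \[1e-5, 10\] log-scale, polynomial coef0 in \[0, 10\], kNN k in
#'   \[1, 25\]; LDA untuned).
#' @param max_evals Objective-evaluation cap for the Bayesian search
#'   (default 50).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "lda", "knn"),
                            kernel = c("rbf", "linear", "poly2", "poly3"),
                            search_space = NULL, max_evals = 50L) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  if (max_evals < 1) stopf("max_evals must be >= 1")
  if (is.null(search_space)) search_space <- default_search_space(family, kernel)
  if (family != "lda" && length(search_space) == 0)
    stopf("search_space must be non-empty for tunable family %s", family)
  structure(list(family = family, kernel = if (family == "svm") kernel else NA_character_,
                 search_space = search_space, max_evals = as.integer(max_evals)),
            class = "classifier_spec")
}

default_search_space <- function(family, kernel) {
  switch(family,
    svm = {
      sp <- list(C = list(lower = 1e-3, upper = 1e3, log = TRUE))
      if (kernel == "rbf") sp$gamma <- list(lower = 1e-5, upper = 10, log = TRUE)
      if (kernel %in% c("poly2", "poly3")) sp$coef0 <- list(lower = 0, upper = 10)
      sp
    },
    knn = list(k = list(lower = 1, upper = 25, integer = TRUE)),
    lda = list())
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec: %s%s, %d params, max_evals %d>\n",
              x$family, if (!is.na(x$kernel)) paste0("-", x$kernel) else "",
              length(x$search_space), x$max_evals))
  invisible(x)
}

#' Label for a classifier spec (grid headers)
#' @param spec A `classifier_spec`.
#' @return Short character label, e.g. `"svm_rbf"`.
#' @export
spec_label <- function(spec) {
  if (spec$family == "svm") paste0("svm_", spec$kernel) else spec$family
}

# ---------------------------------------------------------------------------
# kernels

kernel_matrix <- function(X, Z, kernel, params) {
  G <- X %*% t(Z)
  # polynomial scale 1/mean ||z||^2 over the reference (training) rows:
  # scale-stable across feature dimensionalities and invariant under
  # orthogonal reparametrizations of feature space
  s <- function() 1 / max(mean(rowSums(Z^2)), 1e-12)
  switch(kernel,
    linear = G,
    poly2 = (G * s() + (params$coef0 %||% 1))^2,
    poly3 = (G * s() + (params$coef0 %||% 1))^3,
    rbf = {
      d2 <- outer(rowSums(X^2), rep(1, nrow(Z))) +
            outer(rep(1, nrow(X)), rowSums(Z^2)) - 2 * G
      exp(-(params$gamma %||% 1 / ncol(X)) * pmax(d2, 0))
    },
    stopf("unknown kernel %s", kernel))
}

# ---------------------------------------------------------------------------
# binary SVM via the dual QP

# K: training kernel matrix, y in {-1, +1}
svm_binary_fit <- function(K, y, C) {
  n <- length(y)
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8                 # quadprog needs positive definite
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A, bvec = b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  coefs <- alpha * y
  f_no_b <- as.vector(K %*% coefs)
  margin <- alpha > C * 1e-6 & alpha < C * (1 - 1e-6)
  sv <- alpha > C * 1e-6
  b <- if (any(margin)) mean(y[margin] - f_no_b[margin])
       else if (any(sv)) mean(y[sv] - f_no_b[sv]) else 0
  list(coefs = coefs, b = b, decision_train = f_no_b + b)
}

# Platt sigmoid P(y=+1|f) = 1/(1+exp(A f + B)), Newton with backtracking
platt_fit <- function(f, y) {
  prior1 <- sum(y > 0); prior0 <- sum(y <= 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    g1 <- sum(f * (t - p)); g2 <- sum(t - p)
    w <- p * (1 - p)
    h11 <- sum(f * f * w) + 1e-12; h22 <- sum(w) + 1e-12; h12 <- sum(f * w)
    det <- h11 * h22 - h12^2
    if (abs(det) < 1e-15) break
    dA <- -( h22 * g1 - h12 * g2) / det
    dB <- -(-h12 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      nv <- obj(A + step * dA, B + step * dB)
      if (nv <= val + 1e-9 || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    if (abs(val - nv) < 1e-10) { val <- nv; break }
    val <- nv
  }
  list(A = A, B = B)
}

platt_prob <- function(f, cal) 1 / (1 + exp(cal$A * f + cal$B))

svm_ovo_fit <- function(X, y, kernel, params, classes) {
  C <- params$C %||% 1
  pairs <- utils::combn(seq_along(classes), 2)
  fits <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- classes[pairs[1, p]]; b <- classes[pairs[2, p]]
    idx <- which(y %in% c(a, b))
    yy <- ifelse(y[idx] == a, 1, -1)
    K <- kernel_matrix(X[idx, , drop = FALSE], X[idx, , drop = FALSE], kernel, params)
    fit <- svm_binary_fit(K, yy, C)
    cal <- platt_fit(fit$decision_train, yy)
    fits[[p]] <- list(idx = idx, coefs = fit$coefs, b = fit$b, cal = cal,
                      a = pairs[1, p], b_cls = pairs[2, p])
  }
  list(pairs = fits, X = X, kernel = kernel, params = params, classes = classes)
}

svm_ovo_predict <- function(model, Xnew) {
  g <- length(model$classes)
  conf <- matrix(0, nrow(Xnew), g)
  for (f in model$pairs) {
    K <- kernel_matrix(Xnew, model$X[f$idx, , drop = FALSE], model$kernel, model$params)
    dec <- as.vector(K %*% f$coefs) + f$b
    p <- platt_prob(dec, f$cal)             # P(class a beats class b)
    conf[, f$a] <- conf[, f$a] + p
    conf[, f$b_cls] <- conf[, f$b_cls] + (1 - p)
  }
  conf / rowSums(conf)
}

# ---------------------------------------------------------------------------
# kNN and LDA

knn_predict <- function(Xtr, ytr_idx, g, Xnew, k) {
  k <- max(1L, min(as.integer(round(k)), nrow(Xtr)))
  d2 <- outer(rowSums(Xnew^2), rep(1, nrow(Xtr))) +
        outer(rep(1, nrow(Xnew)), rowSums(Xtr^2)) - 2 * Xnew %*% t(Xtr)
  conf <- matrix(0, nrow(Xnew), g)
  for (i in seq_len(nrow(Xnew))) {
    nb <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]  # stable tie order
    tab <- tabulate(ytr_idx[nb], nbins = g)
    conf[i, ] <- tab / k
  }
  conf
}

# LDA behind a variance filter and, when p >= n, a PCA pre-projection
# (within-class scatter is singular in that regime)
lda_fit <- function(X, y, classes) {
  keep <- which(apply(X, 2, stats::sd) > 1e-10)
  if (length(keep) < 1) stopf("no informative features for LDA")
  # pooled within-class sd must be positive: the sphering step divides by it
  within_sd <- sqrt(Reduce(`+`, lapply(classes, function(cl) {
    Xc <- X[y == cl, keep, drop = FALSE]
    colSums(sweep(Xc, 2, colMeans(Xc))^2)
  })) / max(1, nrow(X) - length(classes)))
  keep <- keep[within_sd > 1e-9]
  if (length(keep) < 1) stopf("no informative features for LDA")
  Xk <- X[, keep, drop = FALSE]
  proj <- NULL; center <- NULL
  maxdim <- nrow(X) - length(classes)
  if (ncol(Xk) >= nrow(X) && maxdim >= 1) {
    center <- colMeans(Xk)
    sv <- svd(sweep(Xk, 2, center), nu = 0, nv = min(maxdim, ncol(Xk)))
    rank <- sum(sv$d > sv$d[1] * 1e-10)
    proj <- sv$v[, seq_len(min(rank, maxdim)), drop = FALSE]
    Xk <- sweep(Xk, 2, center) %*% proj
  }
  fit <- suppressWarnings(MASS::lda(Xk, grouping = factor(y, levels = classes)))
  list(fit = fit, keep = keep, proj = proj, center = center, classes = classes)
}

lda_predict <- function(model, Xnew) {
  Xk <- Xnew[, model$keep, drop = FALSE]
  if (!is.null(model$proj)) Xk <- sweep(Xk, 2, model$center) %*% model$proj
  unname(stats::predict(model$fit, Xk)$posterior)
}

# ---------------------------------------------------------------------------
# Bayesian optimization (Gaussian process + expected improvement)

#' Bayesian hyperparameter optimization
#'
#' Maximizes `objective(params)` over a box-bounded space with at most
#' `max_evals` objective evaluations: a seeded Latin-hypercube initial design
#' followed by a Gaussian-process surrogate (squared-exponential kernel on
#' unit-scaled coordinates) with expected-improvement acquisition over a
#' random candidate set.  Deterministic for a fixed seed; a failing objective
#' scores \eqn{-\infty} and the search continues.
#'
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar score to maximize.
#' @param space Named list; each entry `list(lower, upper, log = FALSE,
#'   integer = FALSE)`.
#' @param max_evals Evaluation cap, >= 1.
#' @param seed Integer seed.
#' @return List with `best_params`, `best_score` and `trace` (a data.frame of
#'   every evaluated point and score — the returned best is always the argmax
#'   over the trace).
#' @export
bayes_optimize <- function(objective, space, max_evals = 50L, seed = 1) {
  stopifnot(length(space) >= 1, max_evals >= 1)
  d <- length(space)
  nm <- names(space)
  lo <- vapply(space, function(s) if (isTRUE(s$log)) log10(s$lower) else s$lower, 0)
  hi <- vapply(space, function(s) if (isTRUE(s$log)) log10(s$upper) else s$upper, 0)
  is_log <- vapply(space, function(s) isTRUE(s$log), TRUE)
  is_int <- vapply(space, function(s) isTRUE(s$integer), TRUE)
  to_params <- function(u) {                 # u in [0,1]^d -> named list
    v <- lo + u * (hi - lo)
    v <- ifelse(is_log, 10^v, v)
    v <- ifelse(is_int, round(v), v)
    stats::setNames(as.list(v), nm)
  }
  eval_point <- function(u) {
    p <- to_params(u)
    s <- tryCatch(as.numeric(objective(p)), error = function(e) -Inf)
    if (!is.finite(s)) s <- -Inf
    list(params = p, score = s)
  }
  with_seed(seed, {
    n0 <- min(max_evals, max(4L, 2L * d))
    # Latin hypercube initial design
    U <- sapply(seq_len(d), function(j) (sample(n0) - stats::runif(n0)) / n0)
    U <- matrix(U, n0, d)
    evals <- lapply(seq_len(n0), function(i) eval_point(U[i, ]))
    while (length(evals) < max_evals) {
      scores <- vapply(evals, `[[`, numeric(1), "score")
      finite <- is.finite(scores)
      Xobs <- matrix(U[seq_along(evals), ], ncol = d)
      if (sum(finite) >= 2 && stats::sd(scores[finite]) > 0) {
        ys <- scores; ys[!finite] <- min(scores[finite])  # pessimistic fill
        mu0 <- mean(ys); sd0 <- stats::sd(ys)
        yn <- (ys - mu0) / sd0
        ell <- 0.3
        Kf <- exp(-as.matrix(stats::dist(Xobs))^2 / (2 * ell^2))
        Ki <- tryCatch(solve(Kf + diag(1e-6 + 1e-4, nrow(Xobs))),
                       error = function(e) NULL)
        cand <- matrix(stats::runif(256 * d), ncol = d)
        # local refinement candidates around the incumbent
        bi <- which.max(ys)
        near <- matrix(rep(Xobs[bi, ], 64), ncol = d, byrow = TRUE) +
                matrix(stats::rnorm(64 * d, sd = 0.05), ncol = d)
        cand <- rbind(cand, pmin(pmax(near, 0), 1))
        if (!is.null(Ki)) {
          Kc <- exp(-cross_dist2(cand, Xobs) / (2 * ell^2))
          mu <- as.vector(Kc %*% (Ki %*% yn))
          v <- pmax(1 - rowSums((Kc %*% Ki) * Kc), 1e-12)
          sig <- sqrt(v)
          ymax <- max(yn)
          z <- (mu - ymax - 0.01) / sig
          ei <- sig * (z * stats::pnorm(z) + stats::dnorm(z))
          u_next <- cand[which.max(ei), ]
        } else u_next <- cand[1, ]
      } else {
        u_next <- stats::runif(d)
      }
      U <- rbind(U, u_next)
      evals <- c(evals, list(eval_point(u_next)))
    }
    scores <- vapply(evals, `[[`, numeric(1), "score")
    best <- which.max(scores)
    trace <- cbind(as.data.frame(do.call(rbind, lapply(evals, function(e)
      unlist(e$params)))), score = scores)
    list(best_params = evals[[best]]$params, best_score = scores[best], trace = trace)
  })
}

cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) + outer(rep(1, nrow(A)), rowSums(B^2)) -
    2 * A %*% t(B)
}

# ---------------------------------------------------------------------------
# training surface

#' Train a classifier with Bayesian hyperparameter tuning
#'
#' The tuning objective is mean accuracy over a stratified inner
#' cross-validation split of the training data (5 folds when class counts
#' allow); the search is capped at `spec$max_evals` evaluations.  The final
#' model is refitted on all training data at the chosen hyperparameters.
#' Deterministic for a fixed seed.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Identity per row (>= 2 classes, >= 2 samples per class).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed.
#' @param inner_folds Inner CV folds for the tuning objective.
#' @return A `face_classifier` with fields `spec`, `chosen_params`,
#'   `classes`, `tuning` (the optimizer trace) and the fitted state.
#' @export
train_classifier <- function(features, labels, spec = classifier_spec(), seed = 1,
                             inner_folds = 5L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stopf("features/labels length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stopf("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2))
    stopf("insufficient samples: class %s has %d", names(counts)[which.min(counts)],
          min(counts))
  if (anyNA(features) || any(!is.finite(features))) stopf("features must be finite")

  # center and scale by one global factor (the root mean per-feature
  # variance of the training set): kernel widths and distances become O(dim)
  # for every extraction scheme, while relative feature weights — which carry
  # signal for histogram features — are left untouched
  center <- colMeans(features)
  sg <- sqrt(mean(apply(features, 2, stats::var)))
  scale_ <- rep(if (sg < 1e-12) 1 else sg, ncol(features))
  features <- sweep(sweep(features, 2, center), 2, scale_, "/")

  tuning <- NULL
  chosen <- list()
  if (length(spec$search_space) > 0) {
    ifolds <- min(inner_folds, min(counts))
    assign_inner <- stratified_folds(labels, ifolds, seed = seed + 1L)
    objective <- function(params) {
      accs <- vapply(seq_len(ifolds), function(f) {
        tr <- assign_inner != f; te <- !tr
        fit <- fit_family(features[tr, , drop = FALSE], labels[tr], spec, params, classes)
        conf <- predict_family(fit, features[te, , drop = FALSE], spec)
        mean(classes[max.col(conf, ties.method = "first")] == labels[te])
      }, numeric(1))
      mean(accs)
    }
    tuning <- bayes_optimize(objective, spec$search_space,
                             max_evals = spec$max_evals, seed = seed)
    chosen <- tuning$best_params
  }
  fit <- fit_family(features, labels, spec, chosen, classes)
  structure(list(spec = spec, chosen_params = chosen, classes = classes,
                 fit = fit, tuning = tuning, dim = ncol(features),
                 center = center, scale = scale_, seed = seed),
            class = "face_classifier")
}

fit_family <- function(X, y, spec, params, classes) {
  switch(spec$family,
    svm = svm_ovo_fit(X, y, spec$kernel, params, classes),
    knn = list(X = X, y_idx = match(y, classes), k = params$k %||% 5, g = length(classes)),
    lda = lda_fit(X, y, classes))
}

predict_family <- function(fit, Xnew, spec) {
  switch(spec$family,
    svm = svm_ovo_predict(fit, Xnew),
    knn = knn_predict(fit$X, fit$y_idx, fit$g, Xnew, fit$k),
    lda = lda_predict(fit, Xnew))
}

#' Per-class confidences for new feature vectors
#'
#' @param model A `face_classifier` from [train_classifier()].
#' @param features Numeric matrix (or single vector) of features with the
#'   training dimensionality.
#' @return Matrix (rows = samples) of non-negative confidences over
#'   `model$classes`, each row summing to 1; the row argmax is the predicted
#'   identity.
#' @export
predict_confidence <- function(model, features) {
  stopifnot(inherits(model, "face_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != model$dim)
    stopf("feature dimension %d does not match training dimension %d",
          ncol(features), model$dim)
  features <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  conf <- predict_family(model$fit, features, model$spec)
  conf <- pmax(conf, 0)
  rs <- rowSums(conf)
  rs[rs == 0] <- 1
  conf <- conf / rs
  colnames(conf) <- model$classes
  conf
}

#' @export
print.face_classifier <- function(x, ...) {
  ps <- if (length(x$chosen_params))
    paste(names(x$chosen_params),
          vapply(x$chosen_params, function(v) format(v, digits = 4), ""),
          sep = "=", collapse = ", ") else "none"
  cat(sprintf("<face_classifier: %s, %d classes, dim %d, tuned: %s>\n",
              spec_label(x$spec), length(x$classes), x$dim, ps))
  invisible(x)
}
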