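# Feature extraction: eigenface PCA features, local binary pattern
# histograms, keypoint descriptors (SIFT-like difference-of-Gaussians and
# SURF-like determinant-of-Hessian variants) with strongest-k retention, and
# bag-of-visual-words encoding against a k-means codebook.

# ---------------------------------------------------------------------------
# eigenfaces

#' Fit an eigenface model
#'
#' PCA on mean-centered column-vectorized images, computed by the snapshot
#' method (eigen-decomposition of the n x n Gram matrix) when there are fewer
#' images than pixels, else by SVD.  Components are retained until the
#' cumulative explained-variance ratio reaches `variance_target`; the
#' retained count is the minimum achieving the bound (a component landing
#' exactly on the target is included and retention stops).
#'
#' @param images List of [gray_image] of identical shape, length >= 2.
#' @param variance_target Cumulative explained-variance bound in (0, 1\];
#'   default 0.90.
#' @return An `eigenface_model` with fields `mean_face`, `basis`
#'   (components x pixels, orthonormal rows), `explained_ratio` (retained
#'   components), `full_ratio`, `image_shape`, `n_fit`.
#' @export
fit_eigenfaces <- function(images, variance_target = 0.90) {
  if (length(images) < 2) stopf("need at least 2 images")
  if (variance_target <= 0 || variance_target > 1)
    stopf("variance_target must lie in (0, 1]")
  shp <- dim(unclass(images[[1]]))
  X <- t(vapply(images, function(im) {
    m <- unclass(im)
    if (!identical(dim(m), shp)) stopf("image shape mismatch: %dx%d vs %dx%d",
                                       dim(m)[1], dim(m)[2], shp[1], shp[2])
    as.vector(m)
  }, numeric(prod(shp))))
  mean_face <- colMeans(X)
  Xc <- sweep(X, 2, mean_face)
  n <- nrow(Xc); p <- ncol(Xc)
  if (n <= p) {
    G <- tcrossprod(Xc)                     # snapshot method
    eg <- eigen(G, symmetric = TRUE)
    lam <- eg$values
    keep <- lam > max(lam[1], 0) * 1e-10
    if (!any(keep) || lam[1] <= 0) stopf("degenerate data: all images identical")
    lam <- lam[keep]
    U <- eg$vectors[, keep, drop = FALSE]
    basis <- t(sweep(crossprod(Xc, U), 2, sqrt(lam), "/"))   # comps x pixels
    sv2 <- lam
  } else {
    sv <- svd(Xc)
    keep <- sv$d > max(sv$d[1], 0) * 1e-8
    if (!any(keep) || sv$d[1] <= 0) stopf("degenerate data: all images identical")
    basis <- t(sv$v[, keep, drop = FALSE])
    sv2 <- sv$d[keep]^2
  }
  ratio <- sv2 / sum(sv2)
  k <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  structure(list(mean_face = mean_face,
                 basis = basis[seq_len(k), , drop = FALSE],
                 explained_ratio = ratio[seq_len(k)],
                 full_ratio = ratio,
                 variance_target = variance_target,
                 image_shape = shp, n_fit = n),
            class = "eigenface_model")
}

#' @export
print.eigenface_model <- function(x, ...) {
  cat(sprintf("<eigenface_model: %d components (%.1f%% variance) on %dx%d images, n = %d>\n",
              nrow(x$basis), 100 * sum(x$explained_ratio),
              x$image_shape[1], x$image_shape[2], x$n_fit))
  invisible(x)
}

#' Project an image onto the eigenface basis
#'
#' @param image A [gray_image] of the model's shape.
#' @param model An `eigenface_model`.
#' @return Numeric feature vector of length = retained component count.
#' @export
project_eigenface <- function(image, model) {
  m <- unclass(image)
  if (!identical(dim(m), model$image_shape))
    stopf("image shape %dx%d does not match model shape %dx%d",
          dim(m)[1], dim(m)[2], model$image_shape[1], model$image_shape[2])
  as.vector(model$basis %*% (as.vector(m) - model$mean_face))
}

#' Reconstruct an image from its eigenface projection
#'
#' @param projection Feature vector from [project_eigenface()].
#' @param model An `eigenface_model`.
#' @return Numeric matrix of the model's image shape (not clipped).
#' @export
reconstruct_eigenface <- function(projection, model) {
  v <- model$mean_face + as.vector(crossprod(model$basis, projection))
  matrix(v, model$image_shape[1], model$image_shape[2])
}

# ---------------------------------------------------------------------------
# local binary patterns

#' LBP configuration
#'
#' Defaults follow the classical formulation: radius 1, 8 neighbors, the bit
#' set when neighbor >= center, raw 256-bin codes, and an 8 x 8 cell grid
#' over the canonical crop.
#'
#' @param radius Neighborhood radius in pixels.
#' @param neighbors Number of sampling neighbors; this implementation
#'   supports the 8-neighbor configuration (compass offsets scaled by
#'   `radius`).
#' @param grid_rows,grid_cols Cell partition of the image; remainder rows and
#'   columns are assigned to the last cells.
#' @param comparison `">="` (default) or `">"`: how a neighbor must compare
#'   to the center for its bit to be set.
#' @return An `lbp_spec`.
#' @export
lbp_spec <- function(radius = 1L, neighbors = 8L, grid_rows = 8L, grid_cols = 8L,
                     comparison = c(">=", ">")) {
  comparison <- match.arg(comparison)
  if (neighbors < 4) stopf("neighbors must be >= 4")
  if (neighbors != 8L) stopf("only the 8-neighbor configuration is implemented")
  if (radius < 1) stopf("radius must be >= 1")
  structure(list(radius = as.integer(radius), neighbors = 8L,
                 grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 comparison = comparison),
            class = "lbp_spec")
}

# neighbor offsets (dy, dx), clockwise from top-left
lbp_offsets <- function(radius = 1L) {
  r <- as.integer(radius)
  cbind(dy = c(-r, -r, -r, 0, r, r, r, 0),
        dx = c(-r, 0, r, r, r, 0, -r, -r))
}

#' LBP code of a single 3x3 neighborhood
#'
#' Bit b (value 2^b) is set when neighbor b compares true against the center
#' under the spec's comparison, neighbors ordered clockwise from top-left.
#'
#' @param patch 3x3 numeric matrix (center at `patch[2, 2]`).
#' @param spec An [lbp_spec()] (radius 1 applies).
#' @return Integer code in \[0, 255\].
#' @export
lbp_code <- function(patch, spec = lbp_spec()) {
  stopifnot(is.matrix(patch), all(dim(patch) == c(3, 3)))
  off <- lbp_offsets(1L)
  center <- patch[2, 2]
  nb <- patch[cbind(2 + off[, "dy"], 2 + off[, "dx"])]
  bits <- if (spec$comparison == ">=") nb >= center else nb > center
  sum(bits * 2^(seq_len(8) - 1))
}

# code map over all interior pixels (full neighborhoods only), vectorized
lbp_code_map <- function(m, spec) {
  r <- spec$radius
  h <- nrow(m); w <- ncol(m)
  if (h < 2 * r + 1 || w < 2 * r + 1) stopf("image too small for LBP radius %d", r)
  ci <- (r + 1):(h - r); cj <- (r + 1):(w - r)
  center <- m[ci, cj, drop = FALSE]
  off <- lbp_offsets(r)
  code <- matrix(0, nrow(center), ncol(center))
  for (b in seq_len(8)) {
    nb <- m[ci + off[b, "dy"], cj + off[b, "dx"], drop = FALSE]
    hit <- if (spec$comparison == ">=") nb >= center else nb > center
    code <- code + hit * 2^(b - 1)
  }
  code
}

#' LBP histogram feature of an image
#'
#' Computes codes for every pixel with a full neighborhood, partitions the
#' code map into `grid_rows x grid_cols` cells (remainder to the last cells),
#' L1-normalizes each cell's 256-bin histogram and concatenates them in
#' row-major cell order.
#'
#' @param image A [gray_image].
#' @param spec An [lbp_spec()].
#' @return Numeric vector of length `grid_rows * grid_cols * 256`.
#' @export
lbp_histogram <- function(image, spec = lbp_spec()) {
  code <- lbp_code_map(unclass(image), spec)
  gr <- spec$grid_rows; gc <- spec$grid_cols
  if (nrow(code) < gr || ncol(code) < gc)
    stopf("grid too fine: %dx%d cells over a %dx%d code map", gr, gc, nrow(code), ncol(code))
  rb <- floor(nrow(code) / gr); cb <- floor(ncol(code) / gc)
  out <- numeric(gr * gc * 256L)
  cell <- 0L
  for (i in seq_len(gr)) {
    rows <- ((i - 1L) * rb + 1L):(if (i == gr) nrow(code) else i * rb)
    for (j in seq_len(gc)) {
      cols <- ((j - 1L) * cb + 1L):(if (j == gc) ncol(code) else j * cb)
      hist <- tabulate(code[rows, cols] + 1L, nbins = 256L)
      out[cell * 256L + seq_len(256L)] <- hist / sum(hist)
      cell <- cell + 1L
    }
  }
  out
}

# ---------------------------------------------------------------------------
# keypoint descriptors

# central-difference gradients with replicated edges
image_gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  dx <- (m[, pmin(seq_len(w) + 1L, w), drop = FALSE] -
           m[, pmax(seq_len(w) - 1L, 1L), drop = FALSE]) / 2
  dy <- (m[pmin(seq_len(h) + 1L, h), , drop = FALSE] -
           m[pmax(seq_len(h) - 1L, 1L), , drop = FALSE]) / 2
  list(dx = dx, dy = dy)
}

# TRUE where m is a strict 8-neighborhood local maximum
local_maxima <- function(m, threshold) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) return(matrix(FALSE, h, w))
  ok <- m > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- m[pmin(pmax(seq_len(h) + dy, 1L), h),
                 pmin(pmax(seq_len(w) + dx, 1L), w), drop = FALSE]
    ok <- ok & (m > shifted | (m == shifted & (dy < 0 | (dy == 0 & dx < 0))))
  }
  ok
}

# greedy non-maximum suppression over candidate keypoints
suppress_near <- function(kp, min_dist = 5) {
  if (nrow(kp) <= 1L) return(kp)
  keep <- logical(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- kp[keep, , drop = FALSE]
    d2 <- (sel$y - kp$y[i])^2 + (sel$x - kp$x[i])^2
    if (all(d2 >= min_dist^2)) keep[i] <- TRUE
  }
  kp[keep, , drop = FALSE]
}

# 4x4 spatial cells x 8 orientation bins over a 16x16 gradient patch -> 128-dim
descr_orientation_hist <- function(dx, dy, y, x) {
  ys <- y + (-8:7); xs <- x + (-8:7)
  ys <- pmin(pmax(ys, 1L), nrow(dx)); xs <- pmin(pmax(xs, 1L), ncol(dx))
  gx <- dx[ys, xs]; gy <- dy[ys, xs]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                       # (-pi, pi]
  bin <- pmin(floor((ang + pi) / (2 * pi / 8)), 7)
  # cell index: row block * 4 + col block
  rb <- rep(0:3, each = 4); cbk <- rep(0:3, each = 4)
  cell <- outer(rb, cbk, function(a, b) a * 4 + b)
  idx <- cell * 8 + bin + 1
  v <- numeric(128)
  acc <- tapply(as.vector(mag), as.vector(idx), sum)
  v[as.integer(names(acc))] <- acc
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) { v <- v / nrm; v <- pmin(v, 0.2); v <- v / sqrt(sum(v^2)) }
  v
}

# 4x4 cells x (sum dx, sum |dx|, sum dy, sum |dy|) over a 16x16 patch -> 64-dim
descr_haar_sums <- function(dx, dy, y, x) {
  ys <- y + (-8:7); xs <- x + (-8:7)
  ys <- pmin(pmax(ys, 1L), nrow(dx)); xs <- pmin(pmax(xs, 1L), ncol(dx))
  gx <- dx[ys, xs]; gy <- dy[ys, xs]
  v <- numeric(64)
  for (i in 0:3) for (j in 0:3) {
    rows <- i * 4 + 1:4; cols <- j * 4 + 1:4
    base <- (i * 4 + j) * 4
    v[base + 1] <- sum(gx[rows, cols]); v[base + 2] <- sum(abs(gx[rows, cols]))
    v[base + 3] <- sum(gy[rows, cols]); v[base + 4] <- sum(abs(gy[rows, cols]))
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Extract the strongest keypoint descriptors of an image
#'
#' Two detector/descriptor pairs are provided behind one contract.
#' `"sift"`: keypoints are 8-neighborhood maxima of the absolute
#' difference-of-Gaussians response over a fixed scale ladder, described by a
#' 4x4-cell, 8-orientation-bin gradient histogram (128-dim, L2-normalized
#' with 0.2 clipping).  `"surf"`: keypoints are maxima of the
#' determinant-of-Hessian response on Gaussian-smoothed images, described by
#' per-cell sums of first-derivative (Haar-like) responses (64-dim).
#' Descriptors are sorted by descending detector response (ties by scan
#' order) and truncated to the `top_k` strongest; a featureless image yields
#' an empty set.
#'
#' @param image A [gray_image].
#' @param method `"sift"` or `"surf"`.
#' @param top_k Strongest-keypoint retention; defaults: 5 for sift, 3 for
#'   surf.
#' @param threshold Minimum detector response.
#' @return A `descriptor_set`: list with `values` (n x d matrix),
#'   `response`, `location` (n x 2, x/y), `method`.
#' @export
extract_keypoints <- function(image, method = c("sift", "surf"), top_k = NULL,
                              threshold = 2) {
  method <- match.arg(method)
  if (is.null(top_k)) top_k <- if (method == "sift") 5L else 3L
  if (top_k < 1) stopf("top_k must be >= 1")
  m <- unclass(image)
  d <- if (method == "sift") 128L else 64L
  empty <- structure(list(values = matrix(numeric(0), 0, d),
                          response = numeric(0),
                          location = matrix(numeric(0), 0, 2,
                                            dimnames = list(NULL, c("x", "y"))),
                          method = method),
                     class = "descriptor_set")
  if (stats::sd(m) == 0) return(empty)

  kp <- NULL
  if (method == "sift") {
    sigmas <- 1.6 * 2^((0:4) / 2)
    blurred <- lapply(sigmas, function(s) gaussian_blur(m, s))
    for (i in seq_len(length(sigmas) - 1L)) {
      dog <- blurred[[i + 1L]] - blurred[[i]]
      mx <- local_maxima(abs(dog), threshold)
      if (any(mx)) {
        w <- which(mx, arr.ind = TRUE)
        kp <- rbind(kp, data.frame(y = w[, 1], x = w[, 2],
                                   response = abs(dog)[mx], scale = i))
      }
    }
  } else {
    sigmas <- c(2, 3.2, 5)
    for (i in seq_along(sigmas)) {
      s <- sigmas[i]
      g <- gaussian_blur(m, s)
      gr <- image_gradients(g)
      gxx <- image_gradients(gr$dx); gyy <- image_gradients(gr$dy)
      deth <- (gxx$dx * gyy$dy - (0.9 * gxx$dy)^2) * s^2   # scale-normalized
      mx <- local_maxima(deth, threshold * 0.25)
      if (any(mx)) {
        w <- which(mx, arr.ind = TRUE)
        kp <- rbind(kp, data.frame(y = w[, 1], x = w[, 2],
                                   response = deth[mx], scale = i))
      }
    }
  }
  if (is.null(kp) || nrow(kp) == 0L) return(empty)
  kp <- kp[order(-kp$response, kp$y, kp$x), , drop = FALSE]
  kp <- suppress_near(kp, min_dist = 5)
  kp <- kp[seq_len(min(top_k, nrow(kp))), , drop = FALSE]

  base <- gaussian_blur(m, 1.0)
  gr <- image_gradients(base)
  vals <- t(vapply(seq_len(nrow(kp)), function(i) {
    if (method == "sift") descr_orientation_hist(gr$dx, gr$dy, kp$y[i], kp$x[i])
    else descr_haar_sums(gr$dx, gr$dy, kp$y[i], kp$x[i])
  }, numeric(d)))
  structure(list(values = vals, response = kp$response,
                 location = cbind(x = kp$x, y = kp$y), method = method),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set: %d x %d (%s)>\n", nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

# ---------------------------------------------------------------------------
# bag of visual words

#' Fit a visual-word codebook by k-means
#'
#' @param descriptors A matrix (n x d) of pooled descriptors, or a
#'   `descriptor_set`, or a list of `descriptor_set`s.
#' @param k Vocabulary size (default 200).
#' @param seed Integer seed; the fit is deterministic for fixed inputs and
#'   seed.
#' @return A `codebook` with `centroids` (k x d), `k`, `fit_seed`.
#' @export
fit_codebook <- function(descriptors, k = 200, seed = 1) {
  X <- pool_descriptors(descriptors)
  if (nrow(X) < k)
    stopf("insufficient data: %d descriptors for a %d-word vocabulary", nrow(X), k)
  centroids <- if (k == 1L) {
    matrix(colMeans(X), 1, ncol(X))
  } else if (k == nrow(unique(X))) {
    unique(X)                                # each point its own centroid
  } else {
    fit <- NULL
    for (attempt in seq_len(5L)) {
      fit <- tryCatch(
        with_seed(seed + attempt - 1L,
                  suppressWarnings(stats::kmeans(X, centers = k, iter.max = 100L,
                                                 nstart = 1L))),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stopf("k-means failed for k = %d on %d descriptors", k, nrow(X))
    fit$centers
  }
  structure(list(centroids = unname(centroids), k = as.integer(k),
                 fit_seed = as.integer(seed)),
            class = "codebook")
}

pool_descriptors <- function(descriptors) {
  if (is.matrix(descriptors)) return(descriptors)
  if (inherits(descriptors, "descriptor_set")) return(descriptors$values)
  if (is.list(descriptors))
    return(do.call(rbind, lapply(descriptors, pool_descriptors)))
  stopf("cannot pool descriptors of class %s", class(descriptors)[1])
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook: %d words x %d dims, seed %d>\n",
              x$k, ncol(x$centroids), x$fit_seed))
  invisible(x)
}

#' Encode descriptors as a bag-of-visual-words histogram
#'
#' Each descriptor is assigned to its Euclidean nearest centroid (ties to the
#' lowest centroid index); the length-k count histogram is L1-normalized.  An
#' empty descriptor set encodes to the zero vector.
#'
#' @param descriptors A `descriptor_set` or n x d matrix.
#' @param codebook A `codebook`.
#' @return Numeric vector of length `codebook$k`.
#' @export
encode_bow <- function(descriptors, codebook) {
  X <- pool_descriptors(descriptors)
  if (nrow(X) == 0L) return(numeric(codebook$k))
  C <- codebook$centroids
  if (ncol(X) != ncol(C))
    stopf("descriptor dimension %d does not match codebook dimension %d",
          ncol(X), ncol(C))
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
        outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  nearest <- max.col(-d2, ties.method = "first")
  h <- tabulate(nearest, nbins = codebook$k)
  h / sum(h)
}

# ---------------------------------------------------------------------------
# extractor pipeline (one surface over the four schemes)

#' Feature extraction schemes
#' @return Character vector of scheme names.
#' @export
extractor_schemes <- function() c("ef", "lbph", "sift_bow", "surf_bow")

#' Fit extractor state on a training image set
#'
#' `"ef"` fits the eigenface basis; `"sift_bow"`/`"surf_bow"` extract
#' training descriptors and fit the codebook; `"lbph"` has no fitted state
#' beyond its spec.  Always fit on training folds only.
#'
#' @param scheme One of [extractor_schemes()].
#' @param images Training images (list of [gray_image]).
#' @param seed Seed for the codebook fit.
#' @param opts Named list of options: `variance_target`, `lbp` (an
#'   [lbp_spec()]), `vocabulary` (codebook size), `top_k`.
#' @return A `face_extractor` holding the scheme and its fitted state.
#' @export
fit_extractor <- function(scheme, images, seed = 1, opts = list()) {
  scheme <- match.arg(scheme, extractor_schemes())
  state <- switch(scheme,
    ef = fit_eigenfaces(images, opts$variance_target %||% 0.90),
    lbph = opts$lbp %||% lbp_spec(),
    sift_bow = ,
    surf_bow = {
      method <- sub("_bow", "", scheme)
      k <- opts$vocabulary %||% 200L
      desc <- lapply(images, extract_keypoints, method = method, top_k = opts$top_k)
      fit_codebook(desc, k = k, seed = seed)
    })
  structure(list(scheme = scheme, state = state, opts = opts,
                 n_fit = length(images)),
            class = "face_extractor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transform images into feature vectors
#'
#' @param extractor A fitted `face_extractor`.
#' @param images List of [gray_image].
#' @return Numeric matrix, one row per image.
#' @export
transform_features <- function(extractor, images) {
  stopifnot(inherits(extractor, "face_extractor"))
  rows <- switch(extractor$scheme,
    ef = lapply(images, project_eigenface, model = extractor$state),
    lbph = lapply(images, lbp_histogram, spec = extractor$state),
    sift_bow = ,
    surf_bow = {
      method <- sub("_bow", "", extractor$scheme)
      lapply(images, function(im)
        encode_bow(extract_keypoints(im, method = method,
                                     top_k = extractor$opts$top_k),
                   extractor$state))
    })
  do.call(rbind, rows)
}

#' @export
print.face_extractor <- function(x, ...) {
  cat(sprintf("<face_extractor: %s, fitted on %d images>\n", x$scheme, x$n_fit))
  invisible(x)
}

# ---------------------------------------------------------------------------
# serialization: portable text array container + JSON metadata sidecar

#' Save an eigenface model or codebook to text files
#'
#' Writes `<path>.csv` (the array payload, full double precision) and
#' `<path>.json` (metadata).  Round-trips bit-exactly via [load_model()].
#'
#' @param object An `eigenface_model` or `codebook`.
#' @param path Path stem (no extension).
#' @return `path`, invisibly.
#' @export
save_model <- function(object, path) {
  if (inherits(object, "eigenface_model")) {
    payload <- rbind(object$mean_face, object$basis)
    meta <- list(kind = "eigenface_model",
                 image_shape = object$image_shape,
                 explained_ratio = object$explained_ratio,
                 full_ratio = object$full_ratio,
                 variance_target = object$variance_target,
                 n_fit = object$n_fit)
  } else if (inherits(object, "codebook")) {
    payload <- object$centroids
    meta <- list(kind = "codebook", k = object$k, fit_seed = object$fit_seed)
  } else stopf("cannot serialize object of class %s", class(object)[1])
  utils::write.table(format(payload, digits = 17, scientific = TRUE, trim = TRUE),
                     paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path Path stem used at save time.
#' @return The restored object.
#' @export
load_model <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  payload <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(payload) <- NULL
  if (meta$kind == "eigenface_model") {
    structure(list(mean_face = payload[1, ],
                   basis = payload[-1, , drop = FALSE],
                   explained_ratio = meta$explained_ratio,
                   full_ratio = meta$full_ratio,
                   variance_target = meta$variance_target,
                   image_shape = as.integer(meta$image_shape),
                   n_fit = meta$n_fit),
              class = "eigenface_model")
  } else if (meta$kind == "codebook") {
    structure(list(centroids = payload, k = as.integer(meta$k),
                   fit_seed = as.integer(meta$fit_seed)),
              class = "codebook")
  } else stopf("unknown serialized kind: %s", meta$kind)
}
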