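# Shared fixtures (built once per test run) and independent oracles.
# Unit tests run at reduced resolution; the acceptance tests use the
# pipeline defaults.

.fix <- new.env()

# small 4-identity dataset at 100 x 66 crops, moderate nuisance
small_dataset <- function() {
  if (is.null(.fix$small)) {
    pop <- make_population(4, seed = 42)
    .fix$small <- synth_dataset(pop, images_per_id = 12, seed = 42,
                                target_h = 100, target_w = 66)
  }
  .fix$small
}

small_population <- function() {
  if (is.null(.fix$pop)) .fix$pop <- make_population(4, seed = 42)
  .fix$pop
}

# deterministic non-constant test image
gradient_image <- function(h = 40, w = 30) {
  gray_image(outer(seq(0, 200, length.out = h), seq(0, 55, length.out = w), `+`))
}

rgb_ramp <- function(h = 8, w = 6) {
  r <- matrix(seq(0, 255, length.out = h * w), h, w)
  rgb_image(array(c(r, r / 2, r / 4), dim = c(h, w, 3)))
}

# --- independent oracles -------------------------------------------------

# brute-force bilinear resampler, pixel-center aligned, double loop
oracle_bilinear <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, th, tw)
  for (i in seq_len(th)) {
    for (j in seq_len(tw)) {
      sy <- (i - 0.5) * h / th - 0.5
      sx <- (j - 0.5) * w / tw - 0.5
      y0 <- min(max(floor(sy), 0), h - 1); y1 <- min(y0 + 1, h - 1)
      x0 <- min(max(floor(sx), 0), w - 1); x1 <- min(x0 + 1, w - 1)
      fy <- min(max(sy - y0, 0), 1); fx <- min(max(sx - x0, 0), 1)
      out[i, j] <- m[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        m[y0 + 1, x1 + 1] * (1 - fy) * fx +
        m[y1 + 1, x0 + 1] * fy * (1 - fx) +
        m[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out
}

# full eigendecomposition of the pixel covariance: the slow reference for
# eigenface explained-variance ratios (feasible only for small images)
oracle_pca_ratios <- function(images) {
  X <- t(sapply(images, function(im) as.vector(unclass(im))))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]
  ev / sum(ev)
}

# exhaustive nearest-centroid assignment
oracle_bow <- function(X, centroids) {
  k <- nrow(centroids)
  counts <- numeric(k)
  for (i in seq_len(nrow(X))) {
    d <- apply(centroids, 1, function(cc) sum((X[i, ] - cc)^2))
    counts[which.min(d)] <- counts[which.min(d)] + 1
  }
  counts / sum(counts)
}

# brute-force majority vote on a table of per-row argmax votes:
# modal class, ties by summed confidence over tied classes, then
# lexicographic order
oracle_vote <- function(rows) {
  classes <- colnames(rows)
  votes <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    mx <- max(rows[i, ])
    votes[i] <- sort(classes[rows[i, ] == mx])[1]
  }
  tab <- table(votes)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    sums <- sapply(top, function(cl) sum(rows[, cl]))
    top <- top[sums == max(sums)]
    top <- sort(top)[1]
  }
  top
}

# small synthetic descriptor cloud with cluster structure
random_descriptors <- function(n, d, seed) {
  set.seed(seed)
  centers <- matrix(rnorm(8 * d, sd = 3), 8, d)
  idx <- sample(8, n, replace = TRUE)
  centers[idx, , drop = FALSE] + matrix(rnorm(n * d, sd = 0.5), n, d)
}
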