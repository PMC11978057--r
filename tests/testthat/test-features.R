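# eigenfaces, LBP, keypoints, codebook, bag-of-visual-words

# small synthetic image set from a known 3-factor linear model
factor_images <- function(n = 50, h = 20, w = 15, seed = 99, noise = 2) {
  set.seed(seed)
  basis <- array(rnorm(3 * h * w), dim = c(3, h * w))
  lapply(seq_len(n), function(i) {
    z <- rnorm(3, sd = c(30, 12, 5))
    v <- 128 + as.vector(t(basis) %*% z) + rnorm(h * w, sd = noise)
    gray_image(matrix(clip255(round(v)), h, w))
  })
}
clip255 <- function(x) pmin(255, pmax(0, x))

test_that("eigenface fit matches the full-covariance oracle and is minimal", {
  imgs <- factor_images()
  m <- fit_eigenfaces(imgs, 0.90)
  want <- oracle_pca_ratios(imgs)
  k_want <- which(cumsum(want) >= 0.90)[1]
  expect_equal(nrow(m$basis), k_want)
  expect_equal(sum(m$explained_ratio), sum(want[seq_len(k_want)]),
               tolerance = 1e-8)
  expect_equal(m$full_ratio[seq_len(k_want)], want[seq_len(k_want)],
               tolerance = 1e-8)
  # minimality: dropping the last retained component violates the bound
  expect_lt(sum(m$explained_ratio[-length(m$explained_ratio)]), 0.90)
  # orthonormal rows
  BBt <- m$basis %*% t(m$basis)
  expect_lt(max(abs(BBt - diag(nrow(BBt)))), 1e-8)
  # ratios non-increasing
  expect_true(all(diff(m$explained_ratio) <= 1e-12))
})

test_that("eigenface edge cases: rank-1 pairs and degenerate sets", {
  a <- gray_image(matrix(c(0, 10, 20, 30), 2, 2))
  b <- gray_image(matrix(c(5, 15, 30, 60), 2, 2))
  m <- fit_eigenfaces(list(a, b), 0.9)
  expect_equal(nrow(m$basis), 1L)
  expect_equal(m$explained_ratio, 1.0)

  expect_error(fit_eigenfaces(rep(list(a), 5), 0.9), "degenerate")
  expect_error(fit_eigenfaces(list(a, gray_image(matrix(0, 3, 3))), 0.9),
               "shape mismatch")
})

test_that("eigenface projection: zero at the mean, complete-basis reconstruction, contraction", {
  imgs <- factor_images(n = 12)
  m1 <- fit_eigenfaces(imgs, 1.0)
  mean_img <- gray_image(matrix(m1$mean_face, 20, 15))
  expect_lt(max(abs(project_eigenface(mean_img, m1))), 1e-6)

  # variance_target = 1: training image is reconstructed from its projection
  pr <- project_eigenface(imgs[[3]], m1)
  rec <- reconstruct_eigenface(pr, m1)
  expect_lt(max(abs(rec - unclass(imgs[[3]]))), 1e-6)

  # orthonormal projection contracts the centered norm
  m <- fit_eigenfaces(imgs, 0.9)
  for (im in imgs[1:4]) {
    centered <- as.vector(unclass(im)) - m$mean_face
    expect_lte(sqrt(sum(project_eigenface(im, m)^2)),
               sqrt(sum(centered^2)) + 1e-9)
  }
  expect_error(project_eigenface(gray_image(matrix(0, 3, 3)), m), "shape")
})

test_that("eigenface reconstruction error is non-increasing in component count", {
  imgs <- factor_images(n = 30, noise = 6)
  m <- fit_eigenfaces(imgs, 1.0)
  im <- unclass(imgs[[5]])
  pr <- project_eigenface(imgs[[5]], m)
  errs <- sapply(seq_along(pr), function(k) {
    mk <- list(mean_face = m$mean_face,
               basis = m$basis[seq_len(k), , drop = FALSE],
               image_shape = m$image_shape)
    sum((reconstruct_eigenface(pr[seq_len(k)], mk) - im)^2)
  })
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("lbp_code matches hand enumeration and its edge cases", {
  expect_equal(lbp_code(matrix(5, 3, 3)), 255)           # >= passes on equality
  p0 <- matrix(0, 3, 3); p0[2, 2] <- 5
  expect_equal(lbp_code(p0), 0)
  # patch rows (1,2,3 / 4,5,6 / 7,8,9): clockwise from top-left the
  # neighbors are 1,2,3,6,9,8,7,4, center 5; comparisons >=5 set bits
  # 3,4,5,6 -> 8+16+32+64 = 120
  p <- matrix(1:9, 3, 3, byrow = TRUE)
  nb_clockwise <- c(p[1, 1], p[1, 2], p[1, 3], p[2, 3],
                    p[3, 3], p[3, 2], p[3, 1], p[2, 1])
  want <- sum((nb_clockwise >= p[2, 2]) * 2^(0:7))
  expect_equal(lbp_code(p), want)
  expect_equal(lbp_code(p), 120)
  # strict comparison drops the equality bits
  c5 <- matrix(5, 3, 3)
  expect_equal(lbp_code(c5, lbp_spec(comparison = ">")), 0)
})

test_that("lbp histograms: constant image, cell normalization, grid errors", {
  spec <- lbp_spec(grid_rows = 3, grid_cols = 2)
  const <- gray_image(matrix(100, 31, 20))
  h <- lbp_histogram(const, spec)
  expect_length(h, 3 * 2 * 256)
  cells <- matrix(h, nrow = 256)
  expect_true(all(cells[256, ] == 1))          # all mass in code 255
  expect_true(all(colSums(cells) == 1))

  set.seed(3)
  img <- gray_image(matrix(sample(0:255, 40 * 30, replace = TRUE), 40, 30))
  h2 <- lbp_histogram(img, spec)
  expect_equal(colSums(matrix(h2, nrow = 256)), rep(1, 6), tolerance = 1e-9)

  expect_error(lbp_histogram(gray_image(matrix(1:25 * 10, 5, 5)),
                             lbp_spec(grid_rows = 8, grid_cols = 8)),
               "grid too fine")
  expect_error(lbp_spec(neighbors = 3), ">= 4")
})

test_that("lbp histograms are invariant under strictly increasing maps", {
  set.seed(17)
  img <- matrix(sample(0:240, 50 * 35, replace = TRUE), 50, 35)
  h0 <- lbp_histogram(gray_image(img))
  # additive shift and an expanding affine map both preserve order
  expect_identical(lbp_histogram(gray_image(img + 10)), h0)
  expect_identical(lbp_histogram(gray_image(pmin(img * 1.05 + 2, 255))), h0)
})

test_that("keypoint extraction: empty on constant images, top-k truncation", {
  expect_equal(nrow(extract_keypoints(gray_image(matrix(7, 50, 50)), "sift")$values), 0)
  expect_equal(nrow(extract_keypoints(gray_image(matrix(7, 50, 50)), "surf")$values), 0)

  img <- small_dataset()$images[[1]]
  for (method in c("sift", "surf")) {
    full <- extract_keypoints(img, method, top_k = 1000)
    top <- extract_keypoints(img, method, top_k = 3)
    expect_lte(nrow(top$values), 3)
    # truncation keeps exactly the strongest responses of the full list
    expect_equal(top$response,
                 sort(full$response, decreasing = TRUE)[seq_along(top$response)])
    expect_true(all(diff(top$response) <= 1e-12))
    expect_true(all(is.finite(top$values)))
  }
  expect_equal(ncol(extract_keypoints(img, "sift")$values), 128)
  expect_equal(ncol(extract_keypoints(img, "surf")$values), 64)

  # an image with limited structure yields fewer than top_k, never padded
  two <- matrix(10, 60, 60)
  two[20:24, 20:24] <- 200; two[40:44, 40:44] <- 200
  few <- extract_keypoints(gray_image(two), "sift", top_k = 50)
  expect_lt(nrow(few$values), 50)
  expect_gt(nrow(few$values), 0)
})

test_that("codebook: closed forms, inertia beats random assignment, errors", {
  X <- random_descriptors(60, 16, seed = 5)
  cb1 <- fit_codebook(X, k = 1, seed = 1)
  expect_equal(as.vector(cb1$centroids), colMeans(X), tolerance = 1e-12)

  Xd <- unique(random_descriptors(12, 4, seed = 6))
  cbn <- fit_codebook(Xd, k = nrow(Xd), seed = 1)
  d2 <- as.matrix(dist(rbind(Xd, cbn$centroids)))[seq_len(nrow(Xd)),
                                                  nrow(Xd) + seq_len(nrow(Xd))]
  expect_lt(sum(apply(d2, 1, min)^2), 1e-16)

  cb <- fit_codebook(X, k = 8, seed = 2)
  inertia <- function(X, cent, assign)
    sum((X - cent[assign, , drop = FALSE])^2)
  assign_fit <- apply(X, 1, function(x)
    which.min(colSums((t(cb$centroids) - x)^2)))
  fit_inertia <- inertia(X, cb$centroids, assign_fit)
  set.seed(8)
  for (i in 1:100) {
    cent_r <- X[sample(nrow(X), 8), , drop = FALSE]
    assign_r <- apply(X, 1, function(x)
      which.min(colSums((t(cent_r) - x)^2)))
    expect_lte(fit_inertia, inertia(X, cent_r, assign_r) + 1e-9)
  }

  expect_error(fit_codebook(X[1:5, ], k = 8), "insufficient")
  # determinism
  expect_identical(fit_codebook(X, k = 8, seed = 2)$centroids, cb$centroids)
})

test_that("encode_bow matches the exhaustive nearest-centroid oracle", {
  cb <- fit_codebook(random_descriptors(80, 8, seed = 9), k = 10, seed = 3)
  X <- random_descriptors(10, 8, seed = 10)
  expect_equal(encode_bow(X, cb), oracle_bow(X, cb$centroids), tolerance = 1e-12)

  # descriptor equal to a centroid -> unit mass in that bin
  one <- matrix(cb$centroids[3, ], 1)
  h <- encode_bow(one, cb)
  expect_equal(h[3], 1)
  expect_equal(sum(h), 1)

  # empty set -> zero vector of length k
  empty <- matrix(numeric(0), 0, 8)
  expect_equal(encode_bow(empty, cb), numeric(10))

  expect_error(encode_bow(matrix(0, 2, 5), cb), "dimension")
})

test_that("extractor pipeline produces fixed dims per scheme and round-trips serialization", {
  ds <- small_dataset()
  imgs <- ds$images[1:16]
  ex_ef <- fit_extractor("ef", imgs)
  X <- transform_features(ex_ef, imgs)
  expect_equal(nrow(X), 16)
  expect_equal(ncol(X), nrow(ex_ef$state$basis))

  ex_lbp <- fit_extractor("lbph", imgs, opts = list(lbp = lbp_spec(grid_rows = 4, grid_cols = 4)))
  Xl <- transform_features(ex_lbp, imgs[1:3])
  expect_equal(dim(Xl), c(3L, 4 * 4 * 256))

  ex_bow <- fit_extractor("sift_bow", imgs, seed = 4, opts = list(vocabulary = 12))
  Xb <- transform_features(ex_bow, imgs[1:3])
  expect_equal(dim(Xb), c(3L, 12L))
  expect_true(all(abs(rowSums(Xb) - 1) < 1e-9 | rowSums(Xb) == 0))

  d <- withr::local_tempdir()
  save_model(ex_ef$state, file.path(d, "ef"))
  back <- load_model(file.path(d, "ef"))
  expect_identical(back$basis, ex_ef$state$basis)
  expect_identical(back$mean_face, ex_ef$state$mean_face)
  save_model(ex_bow$state, file.path(d, "cb"))
  cb_back <- load_model(file.path(d, "cb"))
  expect_identical(cb_back$centroids, ex_bow$state$centroids)
  expect_equal(cb_back$k, 12L)
})
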