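# stratified cross-validation, leak hygiene, precision, comparison grid

test_that("stratified folds are disjoint, covering, and balanced per class", {
  labels <- rep(c("A", "B", "C"), times = c(12, 9, 15))
  assign <- stratified_folds(labels, 3, seed = 1)
  expect_length(assign, 36)
  expect_setequal(unique(assign), 1:3)
  # coverage and disjointness are implied by a single assignment per sample;
  # check per-class balance
  for (cls in c("A", "B", "C")) {
    tab <- table(assign[labels == cls])
    expect_lte(diff(range(tab)), 1)
  }
  expect_error(stratified_folds(c("A", "A", "B"), 2, seed = 1),
               "class B has 1")
})

test_that("oracle and constant classifiers give exact accuracies", {
  ds <- small_dataset()   # 4 identities x 12 images, balanced
  # the oracle closes over the true labels and the (deterministic) fold
  # assignment; folds are visited in order, so it can look up each fold's
  # ground truth
  assign <- stratified_folds(ds$labels, 4, seed = 11)
  fold_ptr <- new.env(); fold_ptr$f <- 0L
  oracle <- function(train_x, train_labels, test_x) {
    fold_ptr$f <- fold_ptr$f + 1L
    ds$labels[which(assign == fold_ptr$f)]
  }
  rep_o <- cross_validate(ds, "ef", folds = 4, seed = 11,
                          classifier_override = oracle)
  expect_equal(rep_o$fold_accuracies, rep(1, 4))
  expect_equal(rep_o$mean_accuracy, 1.0)
  expect_equal(rep_o$pooled_accuracy, 1.0)
  expect_true(all(rep_o$confusion == diag(diag(rep_o$confusion))))
  expect_equal(unname(rep_o$per_class_precision), rep(1, 4))

  # constant classifier on a balanced 4-class set: exactly 0.25
  constant <- function(train_x, train_labels, test_x)
    rep(sort(unique(train_labels))[1], nrow(test_x))
  rep_c <- cross_validate(ds, "ef", folds = 4, seed = 11,
                          classifier_override = constant)
  expect_equal(rep_c$mean_accuracy, 0.25)
  expect_equal(rep_c$pooled_accuracy, 0.25)
})

test_that("every sample is tested exactly once and confusion rows match counts", {
  ds <- small_dataset()
  rep1 <- cross_validate(ds, "ef", classifier_spec("knn", max_evals = 3),
                         folds = 4, seed = 3, inner_folds = 3)
  tested <- sort(unlist(lapply(rep1$audit, `[[`, "test_indices")))
  expect_equal(tested, seq_along(ds$labels))
  expect_equal(as.vector(rowSums(rep1$confusion)),
               as.vector(table(ds$labels)))
  expect_equal(rep1$mean_accuracy, mean(rep1$fold_accuracies), tolerance = 1e-12)
})

test_that("per-fold extractor state is fitted on training indices only", {
  ds <- small_dataset()
  rep1 <- cross_validate(ds, "ef", classifier_spec("lda"), folds = 4, seed = 5)
  for (f in seq_along(rep1$audit)) {
    a <- rep1$audit[[f]]
    expect_equal(a$n_fit, length(a$fit_indices))
    expect_length(intersect(a$fit_indices, a$test_indices), 0)
    expect_setequal(c(a$fit_indices, a$test_indices), seq_along(ds$labels))
  }
})

test_that("the fast eigenface CV path equals the direct per-fold fit", {
  ds <- small_dataset()
  assign <- stratified_folds(ds$labels, 3, seed = 21)
  fast <- monkeyid:::cv_features_per_fold(ds, "ef", assign, seed = 21, list())
  for (f in 1:3) {
    tr <- which(assign != f)
    ref <- fit_eigenfaces(ds$images[tr], 0.90)
    Xref <- t(sapply(ds$images[tr], project_eigenface, model = ref))
    Xfast <- fast[[f]]$train_x
    expect_equal(ncol(Xfast), ncol(Xref))
    # projections agree up to per-component sign
    for (j in seq_len(ncol(Xref))) {
      s <- sign(sum(Xref[, j] * Xfast[, j]))
      expect_equal(Xfast[, j] * s, Xref[, j], tolerance = 1e-6)
    }
    expect_equal(fast[[f]]$extractor$state$explained_ratio,
                 ref$explained_ratio, tolerance = 1e-8)
  }
})

test_that("per-class precision follows the column-sum definition", {
  conf <- matrix(c(8, 4, 2, 6), 2, 2,
                 dimnames = list(true = c("A", "B"), predicted = c("A", "B")))
  p <- per_class_precision(conf)
  expect_equal(unname(p["A"]), 8 / 12)
  expect_equal(unname(p["B"]), 6 / 8)

  diag3 <- diag(c(5, 3, 7)); dimnames(diag3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(per_class_precision(diag3)), rep(1, 3))

  never <- matrix(c(5, 3, 0, 0), 2, 2,
                  dimnames = list(c("A", "B"), c("A", "B")))
  p2 <- per_class_precision(never)
  expect_false("B" %in% names(p2))  # never predicted -> absent
})

test_that("accuracy is invariant to identity relabeling", {
  ds <- small_dataset()
  map <- setNames(c("W4", "X1", "Y2", "Z3"), sort(unique(ds$labels)))
  relabeled <- face_dataset(ds$images, unname(map[ds$labels]))
  r1 <- cross_validate(ds, "ef", classifier_spec("knn", max_evals = 2),
                       folds = 3, seed = 9, inner_folds = 2)
  r2 <- cross_validate(relabeled, "ef", classifier_spec("knn", max_evals = 2),
                       folds = 3, seed = 9, inner_folds = 2)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy)
  expect_equal(r1$fold_accuracies, r2$fold_accuracies)
})

test_that("a 1x1 grid equals the direct cross_validate call", {
  ds <- small_dataset()
  spec <- classifier_spec("knn", max_evals = 3)
  grid <- comparison_grid(ds, extractors = "ef", classifiers = list(spec),
                          folds = 3, seed = 13, inner_folds = 2)
  direct <- cross_validate(ds, "ef", spec, folds = 3, seed = 13, inner_folds = 2)
  expect_equal(dim(grid$accuracy), c(1L, 1L))
  expect_equal(grid$accuracy["knn", "ef"], direct$pooled_accuracy)
  expect_equal(grid$reports$ef$knn$fold_accuracies, direct$fold_accuracies)
})

test_that("grid CSV output uses percent formatting and failed cells survive", {
  ds <- small_dataset()
  # the 200-word default vocabulary cannot be fitted from 4x12 images at
  # 5 descriptors each: the sift_bow column must fail, be recorded, and the
  # rest of the grid must complete
  grid <- comparison_grid(ds, extractors = c("ef", "sift_bow"),
                          classifiers = list(classifier_spec("lda")),
                          folds = 3, seed = 2, inner_folds = 2)
  expect_true("sift_bow" %in% names(grid$errors))
  expect_true(is.na(grid$accuracy["lda", "sift_bow"]))
  expect_false(is.na(grid$accuracy["lda", "ef"]))
  d <- withr::local_tempdir()
  f <- write_grid_csv(grid, file.path(d, "grid.csv"))
  df <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(df), c("model", "ef", "sift_bow"))
  expect_true(all(df$ef >= 0 & df$ef <= 100, na.rm = TRUE))
})
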