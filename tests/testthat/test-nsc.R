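test_that("fitted statistics match the longhand oracle on a small fixture", {
  fx <- make_fixture(p = 3, n_per_class = 3, K = 2, seed = 2)
  or <- oracle_nsc(fx$x, fx$labels)
  model <- nsc(fx$x, fx$labels, threshold = 0)
  expect_equal(model$centroids, or$centroids, tolerance = 1e-12)
  expect_equal(unname(model$overall), or$overall, tolerance = 1e-12)
  expect_equal(unname(model$s), or$s, tolerance = 1e-12)
  expect_equal(model$s0, or$s0, tolerance = 1e-12)
  expect_equal(model$m_k, or$m_k, tolerance = 1e-12)
  expect_equal(model$d, or$d, tolerance = 1e-12)
})

test_that("equal class sizes give equal m_k; degenerate dispersion is floored", {
  fx <- make_fixture(p = 3, n_per_class = 5, K = 2, seed = 3)
  model <- nsc(fx$x, fx$labels, threshold = 0)
  expect_equal(model$m_k[1], model$m_k[2])

  # zero within-class dispersion: s_j = 0 everywhere, s0 floor applies
  x <- rbind(f1 = c(0, 0, 2, 2))
  colnames(x) <- paste0("s", 1:4)
  labels <- factor(c("A", "A", "B", "B"))
  m <- nsc(x, labels, threshold = 0)
  expect_equal(unname(m$s), 0)
  expect_equal(m$s0, 1e-6)
  expect_equal(unname(m$centroids[, "f1"]), c(0, 2))
  expect_true(all(is.finite(predict(m, x)$delta)))
})

test_that("fit validates inputs and handles missing-heavy features", {
  fx <- make_fixture(p = 4, n_per_class = 4, K = 2)
  expect_error(nsc(fx$x, rep("A", ncol(fx$x))), "at least 2 classes")
  bad <- fx$labels; bad[1:7] <- "C1"  # leaves C2 with one sample? build explicitly
  labels <- factor(c(rep("A", 7), "B"))
  expect_error(nsc(fx$x, labels), "fewer than 2 samples")

  x <- fx$x
  x[1, 1:6] <- NA  # 6/8 missing -> dropped with warning
  expect_warning(m <- nsc(x, fx$labels, threshold = 0), "dropped")
  expect_false("f1" %in% m$feature_ids)
})

test_that("soft-thresholding obeys its closed form and limits", {
  fx <- make_fixture(p = 5, n_per_class = 6, K = 3, seed = 4)
  model <- nsc(fx$x, fx$labels, threshold = 0)

  # identity at zero
  expect_identical(model$shrunk_centroids, model$centroids)

  # |d'| = max(|d| - delta, 0) at delta = 0.5
  m2 <- nsc_shrink(model, 0.5)
  expect_equal(abs(m2$d_shrunk), pmax(abs(model$d) - 0.5, 0),
               tolerance = 1e-12)
  or <- oracle_nsc(fx$x, fx$labels, delta = 0.5)
  expect_equal(m2$shrunk_centroids, or$shrunk_centroids,
               tolerance = 1e-12)

  # full shrinkage collapses to the overall centroid
  m3 <- nsc_shrink(model, max(abs(model$d)) + 1)
  expect_equal(m3$shrunk_centroids,
               matrix(model$overall, 3, 5, byrow = TRUE,
                      dimnames = dimnames(model$centroids)),
               tolerance = 1e-12)
  expect_error(nsc_shrink(model, -1), "non-negative")
})

test_that("prediction matches the loop oracle on randomized fixtures", {
  for (rep in 1:20) {
    set.seed(100 + rep)
    K <- sample(2:4, 1)
    p <- sample(2:5, 1)
    fx <- make_fixture(p = p, n_per_class = sample(3:5, 1), K = K,
                       seed = 100 + rep)
    delta <- runif(1, 0, 1.5)
    model <- nsc_shrink(nsc(fx$x, fx$labels, threshold = 0), delta)
    or <- oracle_nsc(fx$x, fx$labels, delta = delta)
    expect_equal(model$d, or$d, tolerance = 1e-10)
    expect_equal(model$shrunk_centroids, or$shrunk_centroids,
                 tolerance = 1e-10)
    xnew <- fx$x[, sample(ncol(fx$x), 4), drop = FALSE]
    pred <- predict(model, xnew)
    opred <- oracle_predict(or, xnew)
    expect_equal(pred$delta, opred$delta, tolerance = 1e-10)
    expect_equal(pred$posterior, opred$posterior, tolerance = 1e-10)
    expect_identical(as.character(pred$class), opred$class)
    expect_equal(unname(rowSums(pred$posterior)),
                 rep(1, ncol(xnew)), tolerance = 1e-9)
  }
})

test_that("centroid hits and prior dominance behave as expected", {
  fx <- make_fixture(p = 4, n_per_class = 5, K = 2, seed = 6)
  model <- nsc(fx$x, fx$labels, threshold = 0)
  at_centroid <- matrix(model$centroids["C1", ], ncol = 1,
                        dimnames = list(model$feature_ids, "hit"))
  pred <- predict(model, at_centroid)
  expect_identical(as.character(pred$class), "C1")
  expect_gt(pred$posterior[1, "C1"], 0.5)

  # fully shrunk model with unequal priors assigns everything to the
  # majority class
  labels <- factor(c(rep("A", 7), rep("B", 3)))
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  m <- nsc(x, labels, threshold = 0)
  m <- nsc_shrink(m, max(abs(m$d)) + 1)
  pred <- predict(m, x)
  expect_true(all(pred$class == "A"))
})

test_that("number of active features is non-increasing in the threshold", {
  fx <- make_fixture(p = 12, n_per_class = 8, K = 3, seed = 7)
  model <- nsc(fx$x, fx$labels, threshold = 0)
  grid <- seq(0, max(abs(model$d)), length.out = 15)
  active <- vapply(grid, function(d)
    sum(colSums(nsc_shrink(model, d)$d_shrunk != 0) > 0), integer(1))
  expect_true(all(diff(active) <= 0))
})

test_that("permuting samples or features permutes outputs correspondingly", {
  fx <- make_fixture(p = 6, n_per_class = 5, K = 3, seed = 8)
  model <- nsc(fx$x, fx$labels, threshold = 0)
  set.seed(9)
  sp <- sample(ncol(fx$x)); fp <- sample(nrow(fx$x))
  m2 <- nsc(fx$x[fp, sp], fx$labels[sp], threshold = 0)
  expect_equal(m2$centroids[, rownames(fx$x)], model$centroids,
               tolerance = 1e-12)
  p1 <- predict(model, fx$x)
  p2 <- predict(m2, fx$x[fp, ])
  expect_equal(p2$delta, p1$delta, tolerance = 1e-10)
})

test_that("cross-validation picks the sparsest zero-error model and is
           seed-deterministic", {
  fx <- make_fixture(p = 8, n_per_class = 12, K = 2, sep = 6, seed = 10)
  cv <- nsc_cv(fx$x, fx$labels, n_thresholds = 12, n_folds = 4, seed = 1)
  expect_equal(min(cv$errors), 0L)
  expect_equal(cv$threshold, max(cv$grid[cv$errors == 0L]))

  cv2 <- nsc_cv(fx$x, fx$labels, n_thresholds = 12, n_folds = 4, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$errors, cv2$errors)
  expect_identical(cv$threshold, cv2$threshold)

  cv3 <- nsc_cv(fx$x, fx$labels, n_thresholds = 1, n_folds = 4, seed = 1)
  expect_identical(cv3$threshold, 0)
  expect_error(nsc_cv(fx$x, fx$labels, n_folds = 1), "at least 2")
})

test_that("retraining on the full feature set reproduces the full model", {
  fx <- make_fixture(p = 10, n_per_class = 10, K = 3, seed = 12)
  full <- nsc(fx$x, fx$labels, seed = 5)
  re <- retrain_on_features(fx$x, fx$labels, rownames(fx$x), seed = 5)
  expect_equal(re$threshold, full$threshold)
  expect_equal(re$shrunk_centroids, full$shrunk_centroids,
               tolerance = 1e-12)

  # subsets train and predict; too-small subsets error with advice
  re2 <- retrain_on_features(fx$x, fx$labels, rownames(fx$x)[1:6],
                             seed = 5)
  expect_equal(length(re2$feature_ids), 6L)
  expect_s3_class(predict(re2, fx$x[1:6, , drop = FALSE]),
                  "nsc_classification")
  expect_error(retrain_on_features(fx$x, fx$labels, rownames(fx$x)[1:3]),
               "combined mode")
})

test_that("prediction excludes missing cells and rescales the sums", {
  fx <- make_fixture(p = 6, n_per_class = 6, K = 2, seed = 13)
  model <- nsc(fx$x, fx$labels, threshold = 0)
  xnew <- fx$x[, 1:3]
  xnew[2, 1] <- NA
  pred <- predict(model, xnew)
  # oracle for sample 1: drop feature 2, rescale by 6/5
  keep <- setdiff(rownames(xnew), "f2")
  or <- oracle_nsc(fx$x, fx$labels)
  man <- oracle_predict(or, xnew[keep, 1, drop = FALSE])
  jj <- match(keep, model$feature_ids)
  expected <- (man$delta + 2 * rep(log(or$prior), each = 1)) * 6 / 5 -
    2 * rep(log(or$prior), each = 1)
  expect_equal(unname(pred$delta[1, ]), unname(expected[1, ]),
               tolerance = 1e-10)
})

test_that("models survive a JSON round trip with identical predictions", {
  fx <- make_fixture(p = 6, n_per_class = 6, K = 3, seed = 14)
  model <- nsc(fx$x, fx$labels, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model, path)
  back <- model_from_json(path)
  p1 <- predict(model, fx$x)
  p2 <- predict(back, fx$x)
  expect_identical(as.character(p1$class), as.character(p2$class))
  expect_equal(p1$delta, p2$delta, tolerance = 1e-12)
})
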