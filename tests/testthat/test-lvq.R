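test_that("scale_features maps affinely onto [0, range_max] and inverts", {
  # already spanning the range: identity
  s <- scale_features(matrix(c(0, 5, 10), ncol = 1), range_max = 10)
  expect_equal(as.numeric(s$samples), c(0, 5, 10))
  # two-point affine map
  s <- scale_features(matrix(c(2, 2, 4), ncol = 1), range_max = 1000)
  expect_equal(as.numeric(s$samples), c(0, 0, 1000))
  # round-trip oracle on a random matrix
  set.seed(42)
  raw <- matrix(runif(200, -5, 50), 20, 10)
  s <- scale_features(raw, range_max = 1000)
  expect_true(all(s$samples >= 0 & s$samples <= 1000))
  back <- unscale_features(s$samples, s$scaling)
  expect_equal(back, raw, tolerance = 1e-9)
})

test_that("scale_features rejects degenerate input", {
  expect_error(scale_features(matrix(c(1, 1, 1, 2, 3, 4), ncol = 2)),
               "constant feature")
  expect_error(scale_features(matrix(letters[1:4], 2, 2)), "non-numeric")
  expect_error(scale_features(matrix(c(1, NA, 3), ncol = 1)), "missing")
})

test_that("manhattan_distance matches the elementwise loop oracle", {
  expect_identical(manhattan_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(manhattan_distance(c(10, 0), c(0, 10)), 20)
  expect_error(manhattan_distance(1:3, 1:2), "length mismatch")
  set.seed(11)
  for (rep in 1:100) {
    x <- runif(7, -100, 100)
    w <- runif(7, -100, 100)
    expect_identical(manhattan_distance(x, w), l1_loop(x, w))
  }
})

test_that("lvq with zero learning rate returns its initialization", {
  d <- gen_morphology_like(n = c(30, 30), seed = 3)
  x <- as.matrix(d[, -(1:2)])
  fit <- lvq(x, d$label, n_prototypes = 2, lr0 = 0, seed = 3)
  xs <- scale_features(x, scaling = fit$scaling)$samples
  # every prototype must be one of the scaled training samples of its class
  for (j in seq_len(nrow(fit$weights))) {
    cls_rows <- xs[d$label == fit$prototype_class[j], , drop = FALSE]
    dists <- apply(cls_rows, 1L, function(r) max(abs(r - fit$weights[j, ])))
    expect_lt(min(dists), 1e-12)
  }
})

test_that("lvq prototypes converge near their class means", {
  # two well-separated 10-dim Gaussian classes, one prototype per class
  d <- gen_morphology_like(n = c(100, 100), centers = c(200, 800), sd = 50,
                           seed = 5)
  x <- as.matrix(d[, -(1:2)])
  fit <- lvq(x, d$label, n_prototypes = 2, seed = 5)
  xs <- scale_features(x, scaling = fit$scaling)$samples
  for (j in 1:2) {
    cls <- fit$prototype_class[j]
    mu <- colMeans(xs[d$label == cls, , drop = FALSE])
    sd_scaled <- apply(xs[d$label == cls, , drop = FALSE], 2L, sd)
    # per-feature deviation within a few standard errors of the class mean
    expect_true(all(abs(fit$weights[j, ] - mu) <
                      3 * sd_scaled / sqrt(sum(d$label == cls)) + 1e-8))
  }
})

test_that("lvq trains the paper-scale (10, 3, 2) shape and is reproducible", {
  d <- gen_morphology_like(n = c(326, 193), seed = 9)   # 519-sample cohort
  x <- as.matrix(d[, -(1:2)])
  fit1 <- lvq(x, d$label, n_prototypes = 3, seed = 9)
  fit2 <- lvq(x, d$label, n_prototypes = 3, seed = 9)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(unname(fit1$shape), c(10L, 3L, 2L))
  expect_setequal(unique(fit1$prototype_class), levels(d$label))
})

test_that("lvq rejects invalid prototype counts and classes", {
  d <- gen_morphology_like(n = c(20, 20), seed = 1)
  x <- as.matrix(d[, -(1:2)])
  expect_error(lvq(x, d$label, n_prototypes = 1), "n_prototypes")
  expect_error(lvq(x, rep("a", nrow(x))), "two classes")
})

test_that("a matching-label LVQ1 step strictly shrinks the distance", {
  set.seed(21)
  for (rep in 1:25) {
    w <- runif(6, 0, 1000)
    x <- runif(6, 0, 1000)
    alpha <- runif(1, 0.01, 0.99)
    w2 <- w + alpha * (x - w)
    expect_lt(manhattan_distance(x, w2), manhattan_distance(x, w))
  }
})

test_that("classify_nearest agrees with exhaustive search and flags ties", {
  mk <- make_fit(n_prototypes = 3, seed = 7, n = c(40, 40))
  fit <- mk$fit
  xs <- scale_features(mk$x, scaling = fit$scaling)$samples
  # exact prototype: zero distance to itself
  res <- classify_nearest(fit, fit$weights[2, ])
  expect_equal(res$distances[2], 0)
  expect_identical(res$class, fit$prototype_class[2])
  # brute-force argmin oracle on 50 samples
  for (r in seq_len(50)) {
    d_j <- apply(fit$weights, 1L, l1_loop, x = xs[r, ])
    res <- classify_nearest(fit, xs[r, ])
    expect_equal(res$distances, d_j)
    expect_identical(res$class, fit$prototype_class[which.min(d_j)])
  }
  # equidistant prototypes: lowest index wins and the tie is flagged
  tiefit <- fit
  tiefit$weights <- rbind(rep(0, 10), rep(200, 10))
  tiefit$prototype_class <- c("a", "b")
  res <- classify_nearest(tiefit, rep(100, 10))
  expect_identical(res$class, "a")
  expect_true(res$tie)
  expect_error(classify_nearest(fit, 1:3), "dimension mismatch")
})

test_that("kfold_select_prototypes picks by accuracy with smallest-tie rule", {
  d <- gen_morphology_like(n = c(60, 60), centers = c(200, 800), sd = 50,
                           seed = 13)
  x <- as.matrix(d[, -(1:2)])
  # single candidate is returned as-is
  one <- kfold_select_prototypes(x, d$label, candidates = 4, k = 3,
                                 seed = 13)
  expect_identical(one$best, 4)
  # well-separated data: candidates tie within 2 points, smallest returned
  sel <- kfold_select_prototypes(x, d$label, candidates = c(2, 3, 6), k = 5,
                                 seed = 13)
  expect_lt(diff(range(sel$table$mean_accuracy)), 0.02)
  expect_identical(sel$best, 2)
  # determinism
  sel2 <- kfold_select_prototypes(x, d$label, candidates = c(2, 3, 6), k = 5,
                                  seed = 13)
  expect_identical(sel$table, sel2$table)
  # a class too small to reach every training fold is rejected
  y_bad <- factor(c("a", rep("b", nrow(x) - 1)))
  expect_error(kfold_select_prototypes(x, y_bad, candidates = 2, k = 2,
                                       seed = 1), "missing a class")
})

test_that("model JSON round-trips and is byte-stable for a fixed seed", {
  mk <- make_fit(n_prototypes = 3, seed = 4, n = c(30, 30))
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_lvq(mk$fit, p1)
  refit <- lvq(mk$x, mk$y, n_prototypes = 3, seed = 4)
  write_lvq(refit, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_lvq(p1)
  expect_equal(back$weights, unname(mk$fit$weights))
  expect_identical(back$prototype_class, mk$fit$prototype_class)
  expect_equal(predict(back, mk$x), predict(mk$fit, mk$x))
})
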