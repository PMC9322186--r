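test_that("kernel specs validate their inputs", {
  expect_error(kernel_spec(c("ED", "ED")), "distinct")
  expect_error(kernel_spec(c("ED", "SAC", "SID")), "1 or 2")
  expect_error(kernel_spec("ED", -1), "positive")
  k <- kernel_spec(c("ed", "sac"), c(2, 3))
  expect_equal(k$measures, c("ED", "SAC"))
})

test_that("centroid initialisation is seeded, distinct and from the data", {
  withr::local_seed(1)
  px <- matrix(runif(30 * 6, 0.01, 1), 30, 6)
  cube <- cube_from_pixels(px, 5, 6)
  c1 <- init_centroids(cube, 4, seed = 99)
  c2 <- init_centroids(cube, 4, seed = 99)
  expect_identical(c1, c2)
  expect_false(identical(c1, init_centroids(cube, 4, seed = 100)))
  expect_true(all(apply(c1, 1, function(r) {
    any(apply(px, 1, function(p) all(p == r)))
  })))
  expect_equal(anyDuplicated(c1), 0)
  all_c <- init_centroids(cube, 30, seed = 1)
  expect_equal(nrow(all_c), 30) # k = n pixels: every pixel a centroid
  expect_error(init_centroids(cube, 31, seed = 1), "exceeds")
})

test_that("assignment equals the brute-force triple loop on random instances", {
  withr::local_seed(77)
  for (i in 1:100) {
    n_bands <- sample(3:8, 1)
    rows <- sample(2:8, 1); cols <- sample(2:8, 1)
    px <- matrix(runif(rows * cols * n_bands, 0.05, 1), rows * cols, n_bands)
    cube <- cube_from_pixels(px, rows, cols)
    k <- sample(2:4, 1)
    centroids <- px[sample.int(nrow(px), k), , drop = FALSE]
    n_m <- sample(1:2, 1)
    kern <- kernel_spec(sample(measure_ids(), n_m),
                        runif(n_m, 0.1, 5))
    got <- assign_clusters(cube, centroids, kern)
    want <- oracle_assign(px, centroids, kern$measures, kern$weights)
    expect_equal(got, want)
  }
})

test_that("a pixel equal to a centroid joins that centroid under any kernel", {
  px <- matrix(c(0.2, 0.4, 0.8, 0.3, 0.5, 0.9), 2, 3, byrow = TRUE)
  centroids <- rbind(c(0.9, 0.1, 0.4), px[1, ])
  for (m in measure_ids()) {
    lab <- assign_clusters(px, centroids, kernel_spec(m))
    expect_equal(lab[1], 2L)
  }
  # k = 1: everything in cluster 1
  expect_equal(assign_clusters(px, centroids[1, , drop = FALSE],
                               kernel_spec("ED")),
               c(1L, 1L))
})

test_that("centroid update is the member mean and is idempotent", {
  px <- rbind(c(0, 0), c(2, 4), c(10, 10))
  cent <- update_centroids(px, c(1L, 1L, 2L), 2)
  expect_equal(cent, rbind(c(1, 2), c(10, 10)))
  expect_equal(update_centroids(px, c(1L, 1L, 2L), 2), cent)
  # singleton cluster keeps its one member
  cent2 <- update_centroids(px, c(1L, 2L, 3L), 3)
  expect_equal(cent2, px)
  # empty cluster keeps the previous centroid when given
  cent3 <- update_centroids(px, c(1L, 1L, 1L), 2, previous = rbind(c(0, 0), c(5, 5)))
  expect_equal(cent3[2, ], c(5, 5))
})

test_that("fit recovers two well-separated planted blobs exactly", {
  withr::local_seed(55)
  a <- c(0.1, 0.8, 0.2, 0.1); b <- c(0.9, 0.1, 0.7, 0.9)
  px <- rbind(
    t(replicate(18, a + rnorm(4, 0, 0.01))),
    t(replicate(18, b + rnorm(4, 0, 0.01)))
  )
  cube <- cube_from_pixels(px, 6, 6)
  truth <- rep(c("a", "b"), each = 18)
  for (kern in list(kernel_spec("ED"), kernel_spec(c("SAC", "SID")))) {
    fit <- hkmeans(cube, 2, kern, seed = 1, n_init = 3)
    lab <- fit$labels[!is.na(fit$labels)]
    expect_equal(evaluate_classification(lab, truth)$overall_accuracy, 1)
  }
})

test_that("fits are deterministic given seed and config", {
  sc <- make_scene(rows = 12, cols = 12, seed = 6)
  f1 <- hkmeans(sc$cube, 3, kernel_spec(c("ED", "SAC"), c(0.2, 5)), seed = 8)
  f2 <- hkmeans(sc$cube, 3, kernel_spec(c("ED", "SAC"), c(0.2, 5)), seed = 8)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$centroids, f2$centroids)
  expect_identical(f1$changed_fraction, f2$changed_fraction)
})

test_that("a fit at a fixed point converges immediately", {
  px <- rbind(c(0, 0), c(0, 0.02), c(1, 1), c(1, 1.02))
  cube <- cube_from_pixels(px, 2, 2)
  fit <- hkmeans(cube, 2, kernel_spec("ED"), change_threshold = 0, seed = 3,
                 n_init = 4)
  expect_true(fit$converged)
  expect_equal(utils::tail(fit$changed_fraction, 1), 0)
  expect_lte(fit$iterations, 3)
  expect_equal(sort(table(fit$labels[!is.na(fit$labels)]), decreasing = TRUE),
               sort(c(`1` = 2, `2` = 2), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("single-ED summed assignment distance never increases", {
  withr::local_seed(91)
  px <- matrix(runif(200 * 5, 0.01, 1), 200, 5)
  cube <- cube_from_pixels(px, 10, 20)
  fit <- hkmeans(cube, 4, kernel_spec("ED"), seed = 2, max_iter = 25)
  expect_true(all(diff(fit$objective) <= 1e-9))
})

test_that("centroids are member means after the final update", {
  sc <- make_scene(rows = 10, cols = 10, seed = 12)
  fit <- hkmeans(sc$cube, 3, kernel_spec(c("ED", "SCC"), c(0.1, 2)),
                 seed = 5, max_iter = 7)
  px <- cube_pixels(sc$cube)
  lab <- fit$labels[!is.na(fit$labels)]
  for (j in seq_len(fit$k)) {
    if (any(lab == j)) {
      expect_equal(fit$centroids[j, ],
                   colMeans(px[lab == j, , drop = FALSE]),
                   tolerance = 1e-12)
    }
  }
})

test_that("elbow flags a 3-class scene and hits zero at k = n pixels", {
  # three tight blobs at the corners of an equilateral triangle in band
  # space: the inertia curve drops to ~0 at k = 3 and its second difference
  # peaks there
  withr::local_seed(21)
  blobs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) + 0.05
  px <- blobs[rep(1:3, each = 24), ] + matrix(rnorm(72 * 3, 0, 0.005), 72, 3)
  cube <- cube_from_pixels(px, 8, 9)
  curve <- elbow(cube, k_range = 1:6, kernel_spec("ED"), seed = 2)
  expect_equal(attr(curve, "suggested_k"), 3)
  expect_true(all(diff(curve$inertia) <= 1e-9)) # non-increasing, best-of-5
  full <- elbow(cube, k_range = 72, kernel_spec("ED"), seed = 2,
                n_init = 1)
  expect_lt(full$inertia, 1e-8)
})

test_that("triplet classification separates shape from brightness kernels", {
  wl <- 1:16
  shape_a <- sin(wl / 3) + 2
  shape_b <- cos(wl / 2.5) + 2
  # same shape, very different brightness, vs a different shape nearby in ED
  triplet <- rbind(shape_a * 0.55, shape_a * 1.45, shape_b * 0.95)
  classes <- c("a", "a", "b")
  expect_true(classify_triplet(triplet, classes, kernel_spec("SAC")))
  expect_false(classify_triplet(triplet, classes, kernel_spec("ED")))
  # identical pair plus an orthogonal-ish spectrum: succeeds for all kernels
  easy <- rbind(shape_a, shape_a, shape_b * 3)
  for (m in measure_ids()) {
    expect_true(classify_triplet(easy, c("a", "a", "b"), kernel_spec(m)))
  }
  expect_error(classify_triplet(triplet[1:2, ], classes[1:2], kernel_spec("ED")),
               "3 x bands")
  expect_error(classify_triplet(triplet, c("a", "b", "c"), kernel_spec("ED")),
               "exactly two")
})

test_that("triplet suites report per-group outcomes with accuracy in [0,1]", {
  em <- make_endmembers(4, seed = 3)
  tr <- make_triplets(12, em, seed = 3)
  res <- run_triplets(tr, kernel_spec("SAC"))
  expect_equal(nrow(res), 12)
  expect_true(is.logical(res$success))
  acc <- mean(res$success)
  expect_gte(acc, 0); expect_lte(acc, 1)
})

test_that("hkmeans broom methods are tidy", {
  sc <- make_scene(rows = 9, cols = 9, seed = 14)
  fit <- hkmeans(sc$cube, 3, kernel_spec("SAC"), seed = 4)
  td <- tidy(fit)
  expect_equal(nrow(td), 3 * 30)
  ag <- augment(fit)
  expect_equal(nrow(ag), 81)
  expect_true(all(ag$cluster %in% 1:3))
  gl <- glance(fit)
  expect_equal(gl$k, 3)
  expect_gte(gl$inertia, 0)
})
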