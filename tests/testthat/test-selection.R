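test_that("pearson matches hand values and stays in [-1, 1]", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2)), -1)
  withr::local_seed(21)
  for (i in 1:200) {
    a <- rnorm(20); b <- rnorm(20)
    expect_lte(abs(pearson(a, b)), 1 + 1e-12)
    expect_equal(pearson(a, b), pearson(b, a))
  }
  expect_error(pearson(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson(1:3, 1:4), "mismatch")
})

# build four feature-map stand-ins with a designed correlation structure
fake_map <- function(values) {
  structure(list(values = matrix(values, 1), measure = "X"),
            class = "feature_map")
}

test_that("select_pair finds the designed minimum-|rho| pair", {
  withr::local_seed(3)
  n <- 400
  ed_v <- runif(n, 1, 2)           # independent noise
  sac_v <- runif(n, 1, 2)          # independent of ED
  scc_v <- sac_v * 2 + 0.1         # copy of SAC (|rho| = 1)
  sid_v <- ed_v * 0.5 + 0.2        # copy of ED (|rho| = 1)
  maps <- list(ED = fake_map(ed_v), SAC = fake_map(sac_v),
               SCC = fake_map(scc_v), SID = fake_map(sid_v))
  sel <- select_pair(maps)
  # brute force over all 6 pairs
  vals <- cbind(ED = ed_v, SAC = sac_v, SCC = scc_v, SID = sid_v)
  pairs <- combn(colnames(vals), 2)
  absr <- apply(pairs, 2, function(p) abs(cor(vals[, p[1]], vals[, p[2]])))
  expect_setequal(sel$pair, pairs[, which.min(absr)])
  expect_true(all(abs(sel$rho[sel$pair[1], sel$pair[2]]) <= absr + 1e-15))
  expect_equal(diag(sel$rho), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(sel$rho) <= 1 + 1e-12))
})

test_that("an all-identical tie resolves to the lexicographically first pair", {
  v <- runif(50, 1, 2)
  maps <- setNames(lapply(1:4, function(i) fake_map(v)), measure_ids())
  sel <- select_pair(maps)
  expect_equal(sel$pair, c("ED", "SAC"))
})

test_that("constant maps are excluded from candidacy", {
  withr::local_seed(5)
  maps <- list(ED = fake_map(rep(2, 50)), SAC = fake_map(runif(50)),
               SCC = fake_map(runif(50)), SID = fake_map(runif(50)))
  expect_warning(sel <- select_pair(maps), "constant")
  expect_false("ED" %in% sel$candidates)
  expect_false("ED" %in% sel$pair)
})

test_that("the rho matrix equals a brute-force double loop on a real cube", {
  withr::local_seed(31)
  px <- matrix(runif(16 * 16 * 8, 0.01, 1), 256, 8)
  cube <- cube_from_pixels(px, 16, 16)
  sel <- run_selection(cube)
  maps <- lapply(measure_ids(), oracle_feature_map, cube = cube)
  names(maps) <- measure_ids()
  for (a in measure_ids()) {
    for (b in measure_ids()) {
      expect_equal(sel$rho[a, b], cor(maps[[a]], maps[[b]]),
                   tolerance = 1e-10)
    }
  }
  # the winning pair beats every other pair
  pairs <- combn(measure_ids(), 2)
  absr <- apply(pairs, 2, function(p) abs(sel$rho[p[1], p[2]]))
  expect_lte(abs(sel$rho[sel$pair[1], sel$pair[2]]), min(absr) + 1e-15)
})

test_that("coefficient_of_variation follows the chosen sd convention", {
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5) # population sigma
  expect_equal(coefficient_of_variation(c(1, 3), sd_type = "sample"),
               sd(c(1, 3)) / 2)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  withr::local_seed(9)
  v <- runif(100, 0.5, 2)
  for (c_scale in c(0.1, 3, 1000)) {
    expect_equal(coefficient_of_variation(c_scale * v),
                 coefficient_of_variation(v), tolerance = 1e-12)
  }
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
})

test_that("weights follow the CV-share-over-mean rule", {
  w <- compute_weights(1, 3, 2, 5)
  expect_equal(w$norm_weights, c(0.25, 0.75))
  expect_equal(w$weights, c(0.125, 0.15))
  w2 <- compute_weights(2, 2, 1, 1)
  expect_equal(w2$weights, c(0.5, 0.5))
  expect_error(compute_weights(0, 0, 1, 1), "cv1 \\+ cv2")
  expect_error(compute_weights(1, 1, 0, 1), "positive")
})

test_that("norm weights sum to 1 with ratio equal to the CV ratio", {
  withr::local_seed(17)
  for (i in 1:50) {
    cvs <- runif(2, 0.01, 2); means <- runif(2, 0.1, 10)
    w <- compute_weights(cvs[1], cvs[2], means[1], means[2])
    expect_equal(sum(w$norm_weights), 1, tolerance = 1e-12)
    expect_equal(w$norm_weights[1] / w$norm_weights[2], cvs[1] / cvs[2],
                 tolerance = 1e-12)
    expect_true(all(w$weights > 0))
  }
})

test_that("run_selection is deterministic and tidies cleanly", {
  sc <- make_scene(rows = 16, cols = 16, seed = 2)
  s1 <- run_selection(sc$cube)
  s2 <- run_selection(sc$cube)
  expect_identical(s1$pair, s2$pair)
  expect_equal(s1$weights, s2$weights)
  expect_equal(sum(s1$norm_weights), 1, tolerance = 1e-12)
  td <- tidy(s1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(td$measure, unname(s1$pair))
  gl <- glance(s1)
  expect_equal(gl$abs_rho, abs(s1$rho[s1$pair[1], s1$pair[2]]))
})

test_that("a brightness-uniform shape-varying scene keeps a shape measure", {
  # shape varies between classes, brightness is exactly uniform: the
  # informative measures are the shape ones (SAC/SCC/SID)
  sc <- make_scene(rows = 24, cols = 24, brightness_noise_sd = 0,
                   additive_noise_sd = 0.005, seed = 4)
  sel <- run_selection(sc$cube)
  expect_true(any(c("SAC", "SCC", "SID") %in% sel$pair))
})

test_that("raising one map's noise never lowers its norm weight", {
  withr::local_seed(23)
  base <- runif(500, 0.5, 1.5)
  other_cv <- coefficient_of_variation(base)
  prev <- -Inf
  for (noise_sd in c(0.05, 0.1, 0.2, 0.4)) {
    noisy <- 1 + scale(rnorm(500))[, 1] * noise_sd # mean 1, sd exactly noise_sd
    noisy_cv <- coefficient_of_variation(abs(noisy))
    w <- compute_weights(noisy_cv, other_cv, mean(abs(noisy)), mean(base))
    expect_gte(w$norm_weights[1], prev)
    prev <- w$norm_weights[1]
  }
})
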