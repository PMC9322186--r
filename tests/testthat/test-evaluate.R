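test_that("cluster-to-class mapping is optimal and permutation-proof", {
  # hand case: contingency [[9,1],[2,8]] maps identity
  pred <- rep(c(1, 1, 2, 2), c(9, 1, 2, 8))
  truth <- rep(c("x", "y", "x", "y"), c(9, 1, 2, 8))
  m <- map_clusters(pred, truth)
  expect_equal(unname(m[c("1", "2")]), c("x", "y"))
  # perfect clustering under any permutation of labels -> OA 1
  withr::local_seed(41)
  truth2 <- sample(letters[1:4], 200, replace = TRUE)
  relabel <- setNames(sample(1:4), letters[1:4])
  pred2 <- unname(relabel[truth2])
  ev <- evaluate_classification(pred2, truth2)
  expect_equal(ev$overall_accuracy, 1)
  expect_equal(ev$kappa, 1)
})

test_that("mapping never loses to any one-to-one mapping (exhaustive oracle)", {
  withr::local_seed(43)
  for (i in 1:60) {
    c_classes <- sample(2:5, 1)
    n <- 60
    truth <- sample(letters[1:c_classes], n, replace = TRUE)
    pred <- sample(seq_len(c_classes), n, replace = TRUE)
    # bias some structure in half the cases
    if (i %% 2 == 0) {
      idx <- sample(n, n %/% 2)
      pred[idx] <- match(truth[idx], letters[1:c_classes])
    }
    mapping <- map_clusters(pred, truth)
    mapped <- unname(mapping[as.character(pred)])
    oa <- mean(mapped == truth)
    tab <- table(factor(pred, seq_len(c_classes)),
                 factor(truth, letters[1:c_classes]))
    expect_equal(oa, oracle_best_permutation_oa(tab), tolerance = 1e-12)
    expect_equal(anyDuplicated(mapping), 0) # one-to-one
  }
})

test_that("surplus clusters fall back to their majority class", {
  pred <- rep(1:3, c(10, 10, 6))
  truth <- rep(c("x", "y", "y"), c(10, 10, 6))
  m <- map_clusters(pred, truth)
  expect_equal(unname(m["3"]), "y") # surplus cluster 3: majority class y
  ev <- evaluate_classification(pred, truth)
  expect_equal(ev$overall_accuracy, 1)
})

test_that("overall accuracy is trace over total and permutation-invariant", {
  cm <- structure(rbind(c(40, 10), c(5, 45)),
                  dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(overall_accuracy(cm), 0.85)
  perm <- cm[2:1, 2:1]
  expect_equal(overall_accuracy(perm), 0.85)
  expect_equal(overall_accuracy(diag(5)), 1)
})

test_that("kappa reproduces the hand-worked binary example", {
  cm <- rbind(c(40, 10), c(5, 45))
  # po = 0.85; pe = (50*45 + 50*55)/100^2 = 0.5; kappa = 0.35/0.5
  expect_equal(kappa_coefficient(cm), 0.7)
  expect_equal(kappa_coefficient(diag(c(30, 30))), 1)
  # chance-level prediction (outer-product counts) has kappa 0
  outer_cm <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(kappa_coefficient(outer_cm), 0, tolerance = 1e-12)
  expect_error(kappa_coefficient(rbind(c(10, 0), c(0, 0))), "undefined")
})

test_that("generalised kappa equals the direct oracle on random matrices", {
  withr::local_seed(47)
  for (i in 1:1000) {
    c_classes <- sample(2:6, 1)
    m <- matrix(rpois(c_classes^2, 8) + 1, c_classes, c_classes)
    expect_equal(kappa_coefficient(m), oracle_kappa(m), tolerance = 1e-12)
  }
})

test_that("generalised chance agreement reduces to the binary TP/TN form", {
  withr::local_seed(49)
  for (i in 1:1000) {
    m <- matrix(rpois(4, 20) + 1, 2, 2) # rows predicted, cols true
    tp <- m[1, 1]; fp <- m[1, 2]; fn <- m[2, 1]; tn <- m[2, 2]
    total <- sum(m)
    pe_binary <- ((tn + fp) * (tn + fn) + (fn + tp) * (fp + tp)) / total^2
    pe_general <- sum(rowSums(m) * colSums(m)) / total^2
    expect_equal(pe_general, pe_binary, tolerance = 1e-12)
    po <- sum(diag(m)) / total
    expect_equal(kappa_coefficient(m), (po - pe_binary) / (1 - pe_binary),
                 tolerance = 1e-12)
  }
})

test_that("per-class precision, recall and F1 match hand evaluation", {
  cm <- structure(rbind(c(40, 10), c(5, 45)),
                  dimnames = list(c("x", "y"), c("x", "y")))
  pr <- precision_recall_f1(cm)
  expect_equal(pr$precision[1], 0.8)
  expect_equal(pr$recall[1], 8 / 9)
  expect_equal(pr$f1[1], 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  # perfect class
  perfect <- precision_recall_f1(diag(c(7, 3)))
  expect_equal(perfect$precision, c(1, 1))
  expect_equal(perfect$f1, c(1, 1))
  # harmonic-mean bound
  withr::local_seed(51)
  for (i in 1:100) {
    m <- matrix(rpois(9, 5), 3, 3)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    pr <- precision_recall_f1(m)
    expect_true(all(pr$f1 <= pmax(pr$precision, pr$recall) + 1e-12))
  }
})

test_that("undefined precision/recall flags NA with F1 = 0", {
  m <- rbind(c(10, 5, 0), c(0, 0, 0), c(2, 1, 0))
  # class 2 never predicted (row 2 empty), class 3 never true (col 3 empty)
  pr <- precision_recall_f1(m)
  expect_true(is.na(pr$precision[2]))
  expect_equal(pr$f1[2], 0)
  expect_true(is.na(pr$recall[3]))
  expect_equal(pr$f1[3], 0)
})

test_that("OA bounds kappa and the report tidies", {
  withr::local_seed(53)
  pred <- sample(1:3, 150, replace = TRUE)
  truth <- sample(c("a", "b", "c"), 150, replace = TRUE)
  ev <- evaluate_classification(pred, truth)
  expect_lte(ev$overall_accuracy, 1)
  expect_gte(ev$overall_accuracy, ev$kappa) # pe >= 0
  expect_equal(nrow(tidy(ev)), 3)
  gl <- glance(ev)
  expect_equal(gl$n_pixels, 150L)
  expect_equal(gl$n_classes, 3L)
  expect_error(evaluate_classification(pred, truth[1:10]), "cover")
  expect_error(evaluate_classification(rep(NA, 5), truth[1:5]), "overlap|map")
})
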