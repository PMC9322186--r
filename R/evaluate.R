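#' Map unsupervised cluster labels to ground-truth classes
#'
#' Clustering labels are arbitrary; before a confusion matrix makes sense
#' they must be aligned to the class labels. This finds the one-to-one
#' cluster-to-class assignment maximising the number of matched pixels
#' (exact optimum on the contingency table, via a bitmask dynamic program
#' over classes). When there are more clusters than classes the surplus
#' clusters map to their majority class.
#'
#' @param pred Integer/character vector of predicted cluster labels, or an
#'   `hkmeans` fit.
#' @param truth Vector of true class labels, same pixel coverage (`NA`
#'   entries in either vector are dropped pairwise).
#' @return Named character vector: `mapping[cluster] = class`.
#' @export
map_clusters <- function(pred, truth) {
  p <- align_labels(pred, truth)
  tab <- table(cluster = p$pred, class = p$truth)
  if (sum(tab) == 0) stop("no overlapping labelled pixels to map")
  clusters <- rownames(tab)
  classes <- colnames(tab)
  n_cl <- length(clusters); n_c <- length(classes)
  if (n_c > 25) stop("too many classes for exact assignment (> 25)")
  # dp over clusters x subsets of classes; tiny per-match bonus (< 1 pixel
  # total) forces a full matching whenever one is feasible
  bonus <- 1 / (2 * (n_cl + 1))
  n_states <- bitwShiftL(1L, n_c)
  f <- matrix(-Inf, n_cl + 1, n_states)
  choice <- matrix(NA_integer_, n_cl + 1, n_states)
  f[1, 1] <- 0
  for (i in seq_len(n_cl)) {
    for (s in seq_len(n_states) - 1L) {
      cur <- f[i, s + 1L]
      if (!is.finite(cur)) next
      if (cur > f[i + 1, s + 1L]) { # leave cluster i unmatched
        f[i + 1, s + 1L] <- cur
        choice[i + 1, s + 1L] <- 0L
      }
      for (c in seq_len(n_c)) {
        bit <- bitwShiftL(1L, c - 1L)
        if (bitwAnd(s, bit) > 0) next
        v <- cur + tab[i, c] + bonus
        if (v > f[i + 1, bitwOr(s, bit) + 1L]) {
          f[i + 1, bitwOr(s, bit) + 1L] <- v
          choice[i + 1, bitwOr(s, bit) + 1L] <- c
        }
      }
    }
  }
  best_s <- which.max(f[n_cl + 1, ]) - 1L
  assigned <- rep(NA_integer_, n_cl)
  s <- best_s
  for (i in rev(seq_len(n_cl))) {
    c <- choice[i + 1, s + 1L]
    if (is.na(c)) { # state unreachable by recorded path; cannot happen
      next
    }
    if (c > 0L) {
      assigned[i] <- c
      s <- bitwAnd(s, bitwNot(bitwShiftL(1L, c - 1L)))
    }
  }
  mapping <- character(n_cl)
  for (i in seq_len(n_cl)) {
    mapping[i] <- if (!is.na(assigned[i])) {
      classes[assigned[i]]
    } else {
      classes[which.max(tab[i, ])] # surplus cluster: majority class
    }
  }
  setNames(mapping, clusters)
}

align_labels <- function(pred, truth) {
  if (inherits(pred, "hkmeans")) pred <- pred$labels
  pred <- as.vector(pred); truth <- as.vector(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth must cover the same pixels")
  }
  keep <- !is.na(pred) & !is.na(truth)
  list(pred = pred[keep], truth = truth[keep])
}

#' Confusion matrix with predicted rows and true columns
#'
#' Builds the C x C confusion matrix after mapping clusters to classes:
#' columns hold the true pixel counts per class, rows the predicted counts.
#'
#' @inheritParams map_clusters
#' @param mapping Named character vector taking predicted labels to class
#'   names; defaults to the optimal [map_clusters()] assignment. Pass a
#'   vector mapping each label to itself when predictions already carry
#'   class names.
#' @return A `confusion_matrix`: integer matrix with `mapping` attribute.
#' @export
confusion_matrix <- function(pred, truth, mapping = map_clusters(pred, truth)) {
  p <- align_labels(pred, truth)
  mapped <- unname(mapping[as.character(p$pred)])
  classes <- sort(unique(c(p$truth, mapped)))
  cm <- table(predicted = factor(mapped, classes),
              true = factor(p$truth, classes))
  structure(unclass(cm), mapping = mapping, class = "confusion_matrix")
}

cm_counts <- function(cm) {
  m <- unclass(cm)
  attributes(m)[c("mapping", "class")] <- NULL
  m
}

#' Overall accuracy
#'
#' Fraction of pixels on the confusion-matrix diagonal: correctly classified
#' over total.
#'
#' @param cm A square confusion matrix (predicted rows, true columns).
#' @return Scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  m <- cm_counts(cm)
  if (sum(m) == 0) stop("empty confusion matrix")
  sum(diag(m)) / sum(m)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement: `(po - pe) / (1 - pe)` where `po` is the
#' overall accuracy and `pe` the expected agreement of a random classifier
#' with the same marginals, `pe = sum_c rowSum_c * colSum_c / total^2`. The
#' marginal-product form reduces exactly to the familiar binary
#' TP/TN/FP/FN expression at two classes and generalises it beyond.
#'
#' @param cm A square confusion matrix (predicted rows, true columns).
#' @return Scalar in `[-1, 1]`.
#' @export
kappa_coefficient <- function(cm) {
  m <- cm_counts(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (pe >= 1) stop("kappa undefined: chance agreement is 1")
  (po - pe) / (1 - pe)
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest scores per class from the confusion matrix: for class c,
#' `TP = cm[c,c]`, `FP` the rest of row c (predicted c, other truth), `FN`
#' the rest of column c. Undefined ratios (empty row or column) are reported
#' as `NA` with `F1 = 0` by convention.
#'
#' @param cm A square confusion matrix (predicted rows, true columns).
#' @return Tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support` (true pixel count).
#' @export
precision_recall_f1 <- function(cm) {
  m <- cm_counts(cm)
  classes <- colnames(m)
  tp <- diag(m)
  fp <- rowSums(m) - tp
  fn <- colSums(m) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  tibble(class = classes, precision = unname(precision),
         recall = unname(recall), f1 = unname(f1),
         support = unname(colSums(m)))
}

#' Evaluate a classification against ground truth
#'
#' End-to-end accuracy assessment: map clusters to classes, build the
#' confusion matrix and compute overall accuracy, Cohen's kappa and
#' per-class precision/recall/F1 with their macro average. Pixels masked or
#' unlabelled in the truth are excluded.
#'
#' @inheritParams map_clusters
#' @return An `eval_report` with fields `confusion`, `mapping`,
#'   `overall_accuracy`, `kappa`, `per_class` (tibble), `macro_f1`.
#'   Methods: [tidy()] (per-class), [glance()] (one-row summary),
#'   [autoplot()] (confusion heat map).
#' @export
evaluate_classification <- function(pred, truth) {
  mapping <- map_clusters(pred, truth)
  cm <- confusion_matrix(pred, truth, mapping)
  per_class <- precision_recall_f1(cm)
  structure(
    list(confusion = cm, mapping = mapping,
         overall_accuracy = overall_accuracy(cm),
         kappa = kappa_coefficient(cm),
         per_class = per_class,
         macro_f1 = mean(per_class$f1)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> OA ", signif(x$overall_accuracy, 4),
      ", kappa ", signif(x$kappa, 4),
      ", macro F1 ", signif(x$macro_f1, 4), "\n", sep = "")
  print(cm_counts(x$confusion))
  invisible(x)
}

#' @rdname evaluate_classification
#' @param x,... Method arguments.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @rdname evaluate_classification
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy, kappa = x$kappa,
         macro_f1 = x$macro_f1, n_pixels = sum(cm_counts(x$confusion)),
         n_classes = ncol(x$confusion))
}

#' Serialise an evaluation report
#'
#' Confusion matrix, mapping, OA, kappa and per-class scores as JSON.
#'
#' @param x An `eval_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  jsonlite::write_json(
    list(overall_accuracy = x$overall_accuracy, kappa = x$kappa,
         macro_f1 = x$macro_f1,
         mapping = as.list(x$mapping),
         per_class = x$per_class,
         confusion = as.data.frame(cm_counts(x$confusion))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
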