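#' Kernel specification for hybrid K-means
#'
#' A kernel is one or two dissimilarity measures with positive weights. The
#' assignment rule is `argmin_j sum_k w_k * measure_k(pixel, centroid_j)`:
#' a single measure with weight 1 gives classical single-kernel K-means, two
#' measures with weights (1, 1) give the unweighted hybrid, and the weights
#' from [run_selection()] give the changing-weight hybrid classifier.
#'
#' @param measures Character vector of 1 or 2 measure ids
#'   (`"ED"`, `"SAC"`, `"SCC"`, `"SID"`).
#' @param weights Positive numeric vector matching `measures`; default all 1.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(measures, weights = rep(1, length(measures))) {
  measures <- vapply(measures, match_measure, character(1), USE.NAMES = FALSE)
  if (!length(measures) %in% 1:2) stop("a kernel uses 1 or 2 measures")
  if (anyDuplicated(measures)) stop("kernel measures must be distinct")
  weights <- as.numeric(weights)
  if (length(weights) != length(measures) || any(weights <= 0) ||
      any(!is.finite(weights))) {
    stop("weights must be positive, finite, one per measure")
  }
  structure(list(measures = measures, weights = weights),
            class = "kernel_spec")
}

#' @rdname kernel_spec
#' @param x A `measure_selection` from [run_selection()].
#' @export
as_kernel_spec <- function(x) {
  stopifnot(inherits(x, "measure_selection"))
  kernel_spec(x$pair, unname(x$weights))
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec> ",
      paste(sprintf("%.4g x %s", x$weights, x$measures), collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

# N x K matrix of weighted kernel dissimilarities pixel -> centroid
kernel_dissimilarity <- function(px, centroids, kernel, ...) {
  acc <- 0
  for (k in seq_along(kernel$measures)) {
    acc <- acc + kernel$weights[k] *
      dissimilarity_matrix(px, centroids, kernel$measures[k], ...)
  }
  acc
}

#' Random centroid initialisation
#'
#' Picks K distinct valid pixels uniformly without replacement under the
#' seed, the classical "choose K samples" K-means start.
#'
#' @param cube A [hyper_cube()].
#' @param k Number of clusters (>= 1); must not exceed the number of
#'   distinct valid pixel spectra.
#' @param seed Integer RNG seed.
#' @return K x bands matrix of centroid spectra.
#' @export
init_centroids <- function(cube, k, seed = 1L) {
  px <- cube_pixels(cube)
  distinct <- !duplicated(px)
  if (k > sum(distinct)) {
    stop("k = ", k, " exceeds the ", sum(distinct), " distinct valid pixels")
  }
  idx <- which(distinct)
  withr::with_seed(seed, px[idx[sample.int(length(idx), k)], , drop = FALSE])
}

#' Assign pixels to their nearest centroid under a kernel
#'
#' Each valid pixel gets the index of the centroid minimising the weighted
#' kernel dissimilarity; ties go to the lowest cluster index.
#'
#' @param cube A [hyper_cube()] (or bare pixel matrix).
#' @param centroids K x bands matrix.
#' @param kernel A [kernel_spec()].
#' @param ... Passed to [dissimilarity_matrix()].
#' @return Integer vector of 1-based labels, one per valid pixel.
#' @export
assign_clusters <- function(cube, centroids, kernel, ...) {
  px <- if (is.matrix(cube)) cube else cube_pixels(cube)
  d <- kernel_dissimilarity(px, centroids, kernel, ...)
  max.col(-d, ties.method = "first")
}

#' Recompute centroids as member means
#'
#' The band-wise mean of each cluster's member pixels. A cluster that lost
#' all members keeps its previous centroid here; [hkmeans()] re-seeds empty
#' clusters to the most dissimilar pixel to keep K constant.
#'
#' @param cube A [hyper_cube()] (or bare pixel matrix).
#' @param labels Integer labels per valid pixel, in `1..k`.
#' @param k Number of clusters.
#' @param previous Optional previous K x bands centroid matrix retained for
#'   empty clusters.
#' @return K x bands centroid matrix.
#' @export
update_centroids <- function(cube, labels, k, previous = NULL) {
  px <- if (is.matrix(cube)) cube else cube_pixels(cube)
  out <- matrix(NA_real_, k, ncol(px))
  for (j in seq_len(k)) {
    members <- labels == j
    if (any(members)) {
      out[j, ] <- colMeans(px[members, , drop = FALSE])
    } else if (!is.null(previous)) {
      out[j, ] <- previous[j, ]
    }
  }
  out
}

#' Hybrid-kernel K-means
#'
#' K-means clustering of a hyperspectral cube where the assignment distance
#' is a weighted sum of one or two spectral dissimilarity measures, the
#' centroids acting as the per-cluster reference spectra. Iterates
#' assign/update until the fraction of pixels changing label drops below
#' `change_threshold`, labels stop changing, or `max_iter` is reached.
#'
#' An empty cluster is re-seeded to the valid pixel most dissimilar (under
#' the kernel) to that cluster's previous centroid, keeping K constant and
#' the run deterministic. With `n_init > 1` the best of several random
#' restarts (lowest summed kernel dissimilarity to own centroid) is kept.
#'
#' @param cube A [hyper_cube()].
#' @param k Number of clusters.
#' @param kernel A [kernel_spec()]; default single-ED.
#' @param max_iter Maximum assign/update iterations (>= 1).
#' @param change_threshold Stop once the fraction of relabelled pixels falls
#'   below this (in `[0, 1)`); 0 means run to label stability.
#' @param seed RNG seed for centroid initialisation.
#' @param n_init Number of random restarts; seeds used are
#'   `seed, seed + 1, ...`.
#' @param ... Passed to [dissimilarity_matrix()].
#' @return An `hkmeans` object: `centroids`, rows x cols `labels` matrix
#'   (`NA` at masked pixels), per-iteration `changed_fraction` and
#'   `objective` traces, `iterations`, `converged`, `inertia` (summed squared
#'   kernel dissimilarity), `distortion` (mean kernel dissimilarity).
#'   Methods: [tidy()] (centroid spectra), [augment()] (per-pixel labels),
#'   [glance()], [autoplot()].
#' @export
hkmeans <- function(cube, k, kernel = kernel_spec("ED"), max_iter = 100L,
                    change_threshold = 0, seed = 1L, n_init = 1L, ...) {
  stopifnot(inherits(cube, "hyper_cube") || is.matrix(cube))
  if (is.matrix(cube)) cube <- cube_from_matrix(cube)
  stopifnot(k >= 1, max_iter >= 1,
            change_threshold >= 0, change_threshold < 1, n_init >= 1)
  fits <- lapply(seq_len(n_init) - 1L, function(off) {
    hkmeans_once(cube, k, kernel, max_iter, change_threshold,
                 seed + off, ...)
  })
  best <- which.min(vapply(fits, function(f) f$objective_final, numeric(1)))
  fit <- fits[[best]]
  fit$n_init <- as.integer(n_init)
  fit
}

hkmeans_once <- function(cube, k, kernel, max_iter, change_threshold,
                         seed, ...) {
  px <- cube_pixels(cube)
  centroids <- init_centroids(cube, k, seed)
  labels <- NULL
  changed <- numeric(0)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- kernel_dissimilarity(px, centroids, kernel, ...)
    new_labels <- max.col(-d, ties.method = "first")
    objective <- c(objective, sum(d[cbind(seq_len(nrow(px)), new_labels)]))
    frac <- if (is.null(labels)) 1 else mean(new_labels != labels)
    changed <- c(changed, frac)
    labels <- new_labels
    if (iter > 1 && (frac == 0 || frac < change_threshold)) {
      converged <- TRUE
      break
    }
    centroids <- update_centroids(px, labels, k, previous = centroids)
    # re-seed empty clusters to the pixel farthest from their old centroid
    empty <- setdiff(seq_len(k), unique(labels))
    for (j in empty) {
      dj <- kernel_dissimilarity(px, centroids[j, , drop = FALSE], kernel, ...)
      centroids[j, ] <- px[which.max(dj[, 1]), ]
    }
  }
  # final update so every centroid is the mean of its members
  centroids <- update_centroids(px, labels, k, previous = centroids)
  d <- kernel_dissimilarity(px, centroids, kernel, ...)
  own <- d[cbind(seq_len(nrow(px)), labels)]
  structure(
    list(k = as.integer(k), kernel = kernel,
         centroids = centroids,
         labels = unflatten(labels, cube),
         iterations = iter, changed_fraction = changed,
         objective = objective, objective_final = sum(own),
         inertia = sum(own^2), distortion = mean(own),
         converged = converged, seed = as.integer(seed),
         wavelengths = cube$wavelengths),
    class = "hkmeans"
  )
}

#' @export
print.hkmeans <- function(x, ...) {
  cat("<hkmeans> k = ", x$k, ", kernel ",
      paste(sprintf("%.4g x %s", x$kernel$weights, x$kernel$measures),
            collapse = " + "),
      ", ", x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "max_iter reached",
      ", inertia ", signif(x$inertia, 6), "\n", sep = "")
  invisible(x)
}

label_vector <- function(fit) {
  l <- fit$labels
  as.integer(l[!is.na(l)])
}

#' @rdname hkmeans
#' @param x,... Method arguments.
#' @method tidy hkmeans
#' @export
tidy.hkmeans <- function(x, ...) {
  tibble(cluster = rep(seq_len(x$k), each = ncol(x$centroids)),
         band = rep(seq_len(ncol(x$centroids)), x$k),
         wavelength = rep(x$wavelengths, x$k),
         reflectance = as.vector(t(x$centroids)),
         size = rep(tabulate(label_vector(x), x$k),
                    each = ncol(x$centroids)))
}

#' @rdname hkmeans
#' @method glance hkmeans
#' @export
glance.hkmeans <- function(x, ...) {
  tibble(k = x$k, iterations = x$iterations, converged = x$converged,
         inertia = x$inertia, distortion = x$distortion,
         final_changed_fraction = utils::tail(x$changed_fraction, 1))
}

#' @rdname hkmeans
#' @method augment hkmeans
#' @export
augment.hkmeans <- function(x, ...) {
  idx <- which(!is.na(x$labels), arr.ind = TRUE)
  tibble(row = idx[, 1], col = idx[, 2],
         cluster = as.integer(x$labels[idx])) |>
    dplyr::arrange(.data$row, .data$col)
}

#' Elbow-method diagnostics for the cluster count
#'
#' Fits the kernel K-means at each candidate K and records distortion (mean
#' kernel dissimilarity of pixels to their own centroid) and inertia (summed
#' squared kernel dissimilarity). The suggested K maximises the second
#' difference of inertia — the sharpest bend of the curve — and is advisory
#' only.
#'
#' @param cube A [hyper_cube()].
#' @param k_range Integer vector of candidate cluster counts.
#' @param kernel A [kernel_spec()].
#' @param seed RNG seed.
#' @param n_init Restarts per K (best kept); several restarts keep the
#'   inertia curve monotone.
#' @param ... Passed to [hkmeans()].
#' @return An `elbow_curve`: tibble of `k`, `distortion`, `inertia` plus a
#'   `suggested_k` attribute. Plot with [autoplot()].
#' @export
elbow <- function(cube, k_range = 2:8, kernel = kernel_spec("ED"),
                  seed = 1L, n_init = 5L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(length(k_range) >= 1, all(k_range >= 1))
  fits <- lapply(k_range, function(k) {
    hkmeans(cube, k, kernel, seed = seed, n_init = n_init, ...)
  })
  curve <- tibble(
    k = k_range,
    distortion = vapply(fits, function(f) f$distortion, numeric(1)),
    inertia = vapply(fits, function(f) f$inertia, numeric(1))
  )
  suggested <- if (nrow(curve) >= 3) {
    d2 <- diff(curve$inertia, differences = 2)
    curve$k[which.max(d2) + 1L]
  } else {
    curve$k[which.min(curve$inertia)]
  }
  structure(curve, suggested_k = suggested,
            class = c("elbow_curve", class(curve)))
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("<elbow_curve> suggested k =", attr(x, "suggested_k"), "\n")
  NextMethod()
}

#' Triplet classification protocol
#'
#' Clusters three labelled spectra — two of one class, one of another — with
#' K = 2 under the given kernel and scores success: the two same-class
#' spectra must share a cluster with the third alone. This is the
#' spectral-library benchmark: a measure blind to the property separating
#' the classes (e.g. plain Euclidean distance when classes differ in curve
#' shape but brightness varies within class) fails it.
#'
#' @param spectra 3 x bands numeric matrix.
#' @param classes Length-3 vector of class labels, exactly two equal.
#' @param kernel A [kernel_spec()].
#' @param max_iter,change_threshold K-means controls; defaults follow the
#'   library protocol (2 iterations, 2% change threshold).
#' @param seed RNG seed for the centroid draw.
#' @param ... Passed to [hkmeans()].
#' @return Logical: `TRUE` if the grouping matches the class structure.
#' @export
classify_triplet <- function(spectra, classes, kernel,
                             max_iter = 2L, change_threshold = 0.02,
                             seed = 1L, ...) {
  if (!is.matrix(spectra) || nrow(spectra) != 3) {
    stop("a triplet is a 3 x bands matrix")
  }
  if (length(classes) != 3 || length(unique(classes)) != 2) {
    stop("a triplet has exactly two spectra of one class and one of another")
  }
  fit <- hkmeans(cube_from_matrix(spectra), k = 2, kernel = kernel,
                 max_iter = max_iter, change_threshold = change_threshold,
                 seed = seed, ...)
  lab <- label_vector(fit)
  same <- which(classes == names(which(table(classes) == 2)))
  odd <- setdiff(1:3, same)
  lab[same[1]] == lab[same[2]] && lab[odd] != lab[same[1]]
}

#' Run a triplet suite
#'
#' Applies [classify_triplet()] to every group of a triplet tibble (as made
#' by [make_triplets()]) and returns per-group outcomes.
#'
#' @param triplets Tibble with columns `group`, `class` and list-column
#'   `reflectance` (three rows per group).
#' @param kernel A [kernel_spec()].
#' @param ... Passed to [classify_triplet()].
#' @return Tibble with one row per group: `group`, `success`. The suite
#'   accuracy is `mean(success)`.
#' @export
run_triplets <- function(triplets, kernel, ...) {
  triplets |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(g, key) {
      spectra <- do.call(rbind, g$reflectance)
      tibble(success = classify_triplet(spectra, g$class, kernel, ...))
    }) |>
    dplyr::ungroup()
}
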