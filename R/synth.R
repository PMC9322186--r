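#' Synthetic endmember spectra
#'
#' Generates one smooth, strictly positive reference spectrum per class: a
#' low baseline plus 2-4 Gaussian bumps of varying centre, width and height
#' over a synthetic wavelength axis. Candidate sets are rejection-sampled
#' until every pair of endmembers is separated by at least
#' `class_separation` radians of spectral angle, so between-class shape
#' differences are guaranteed by construction.
#'
#' @param n_classes Number of endmembers (>= 2).
#' @param n_bands Number of spectral bands.
#' @param class_separation Minimum pairwise spectral angle, radians.
#' @param seed Integer RNG seed.
#' @param wl_range Wavelength axis endpoints in nm (default 400-1000 nm,
#'   evenly spaced — the VNIR window typical of airborne imagers).
#' @param max_tries Rejection-sampling cap before a generation error.
#' @return List with `spectra` (n_classes x n_bands matrix, rows named
#'   `class1...`), `wavelengths`, `classes`.
#' @export
make_endmembers <- function(n_classes, n_bands = 30, class_separation = 0.25,
                            seed = 1L, wl_range = c(400, 1000),
                            max_tries = 200L) {
  stopifnot(n_classes >= 2, n_bands >= 2, class_separation >= 0)
  wl <- seq(wl_range[1], wl_range[2], length.out = n_bands)
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      spectra <- t(vapply(seq_len(n_classes), function(i) {
        n_bumps <- sample(2:4, 1)
        s <- rep(runif(1, 0.02, 0.08), n_bands) # baseline reflectance
        for (b in seq_len(n_bumps)) {
          centre <- runif(1, wl_range[1], wl_range[2])
          width <- runif(1, 0.05, 0.25) * diff(wl_range)
          height <- runif(1, 0.1, 0.6)
          s <- s + height * exp(-0.5 * ((wl - centre) / width)^2)
        }
        s
      }, numeric(n_bands)))
      angles <- outer(seq_len(n_classes), seq_len(n_classes), Vectorize(
        function(i, j) acos(min(1, sum(spectra[i, ] * spectra[j, ]) /
                                  sqrt(sum(spectra[i, ]^2) * sum(spectra[j, ]^2))))
      ))
      if (min(angles[upper.tri(angles)]) >= class_separation) {
        rownames(spectra) <- paste0("class", seq_len(n_classes))
        return(list(spectra = spectra, wavelengths = wl,
                    classes = rownames(spectra)))
      }
    }
  })
  stop("could not reach class separation ", class_separation, " for ",
       n_classes, " classes in ", max_tries, " tries; lower the separation")
}

#' Synthetic multi-class hyperspectral scene
#'
#' Builds a labelled scene from per-class endmembers with two independent,
#' separately controllable noise processes:
#'
#' * multiplicative lognormal brightness noise (`brightness_noise_sd`, the
#'   sd of the log factor) — changes a pixel's magnitude but not the shape
#'   of its spectrum, so it moves brightness-sensitive measures (ED) while
#'   leaving shape measures (SAC, SCC) untouched;
#' * additive Gaussian noise (`additive_noise_sd`, reflectance units) —
#'   perturbs the shape as well.
#'
#' Pixels are clipped at 0. The class layout is deterministic:
#' `"blocks"` splits the columns into nearly equal vertical strips,
#' `"voronoi"` assigns each pixel to its nearest of `n_classes` seeded
#' sites.
#'
#' @param rows,cols Scene size in pixels.
#' @param n_bands Number of bands.
#' @param n_classes Number of classes.
#' @param layout `"blocks"` or `"voronoi"`.
#' @param brightness_noise_sd Sd of the lognormal log-factor (0 = off).
#' @param additive_noise_sd Sd of the additive noise (0 = off).
#' @param class_separation Minimum endmember spectral angle, radians.
#' @param seed Integer RNG seed.
#' @param endmembers Optional precomputed [make_endmembers()] result.
#' @return List with `cube` (a [hyper_cube()]), `truth` (rows x cols
#'   character matrix of class names) and `endmembers`.
#' @export
make_scene <- function(rows = 64, cols = 64, n_bands = 30, n_classes = 5,
                       layout = c("blocks", "voronoi"),
                       brightness_noise_sd = 0.15, additive_noise_sd = 0.01,
                       class_separation = 0.25, seed = 1L,
                       endmembers = NULL) {
  layout <- match.arg(layout)
  stopifnot(rows >= 1, cols >= 1, n_classes <= rows * cols,
            brightness_noise_sd >= 0, additive_noise_sd >= 0)
  if (is.null(endmembers)) {
    endmembers <- make_endmembers(n_classes, n_bands, class_separation, seed)
  }
  stopifnot(nrow(endmembers$spectra) == n_classes)
  truth_idx <- switch(
    layout,
    blocks = {
      strip <- pmin(((seq_len(cols) - 1) * n_classes) %/% cols + 1, n_classes)
      matrix(rep(strip, each = rows), rows, cols)
    },
    voronoi = withr::with_seed(seed + 1L, {
      sites <- cbind(runif(n_classes, 1, rows), runif(n_classes, 1, cols))
      idx <- expand.grid(r = seq_len(rows), c = seq_len(cols))
      d <- outer(seq_len(n_classes), seq_len(nrow(idx)), Vectorize(
        function(k, i) (idx$r[i] - sites[k, 1])^2 + (idx$c[i] - sites[k, 2])^2
      ))
      matrix(apply(d, 2, which.min), rows, cols)
    })
  )
  n_px <- rows * cols
  data <- withr::with_seed(seed + 2L, {
    base <- endmembers$spectra[as.vector(truth_idx), , drop = FALSE]
    gain <- if (brightness_noise_sd > 0) {
      rlnorm(n_px, 0, brightness_noise_sd)
    } else {
      rep(1, n_px)
    }
    noisy <- base * gain
    if (additive_noise_sd > 0) {
      noisy <- noisy + matrix(rnorm(n_px * n_bands, 0, additive_noise_sd),
                              n_px, n_bands)
    }
    array(pmax(noisy, 0), dim = c(rows, cols, n_bands))
  })
  truth <- matrix(endmembers$classes[truth_idx], rows, cols)
  list(cube = hyper_cube(data, endmembers$wavelengths),
       truth = truth, endmembers = endmembers)
}

#' Synthetic triplet-group spectral library
#'
#' Emulates the spectral-library benchmark: each group holds three spectra,
#' two perturbed copies of one class and one perturbed copy of another.
#' `within_class_mode = "scaled"` multiplies the same-class copies by
#' uniform brightness factors in `scale_range` (shape preserved exactly, so
#' shape measures separate the classes while plain Euclidean distance sees a
#' large within-class brightness gap); `"jittered"` adds small Gaussian
#' shape noise instead.
#'
#' @param n_groups Number of triplet groups (default 80).
#' @param endmembers A [make_endmembers()] result (>= 2 classes).
#' @param within_class_mode `"scaled"` or `"jittered"`.
#' @param scale_range Brightness factor range for `"scaled"`.
#' @param jitter_sd Additive sd for `"jittered"`.
#' @param seed Integer RNG seed.
#' @return Tibble with one row per spectrum: `group`, `member` (1-3),
#'   `class`, `role` (`"same"`/`"odd"`) and list-column `reflectance`;
#'   attribute `wavelengths`.
#' @export
make_triplets <- function(n_groups = 80, endmembers = make_endmembers(5, seed = seed),
                          within_class_mode = c("scaled", "jittered"),
                          scale_range = c(0.7, 1.3), jitter_sd = 0.005,
                          seed = 1L) {
  within_class_mode <- match.arg(within_class_mode)
  stopifnot(n_groups >= 1, nrow(endmembers$spectra) >= 2)
  n_cl <- nrow(endmembers$spectra)
  withr::with_seed(seed + 3L, {
    out <- purrr::map_dfr(seq_len(n_groups), function(g) {
      cls <- sample.int(n_cl, 2) # cls[1] = same-class pair, cls[2] = odd one
      perturb <- function(class_idx) {
        s <- endmembers$spectra[class_idx, ]
        if (within_class_mode == "scaled") {
          s * runif(1, scale_range[1], scale_range[2])
        } else {
          pmax(s + rnorm(length(s), 0, jitter_sd), 0)
        }
      }
      tibble(group = g, member = 1:3,
             class = endmembers$classes[c(cls[1], cls[1], cls[2])],
             role = c("same", "same", "odd"),
             reflectance = list(perturb(cls[1]), perturb(cls[1]),
                                perturb(cls[2])))
    })
  })
  attr(out, "wavelengths") <- endmembers$wavelengths
  out
}
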