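# shared fixtures and independent oracles, all built in code

# random strictly-positive spectra (pairs drawn under a fixed seed)
random_spectrum <- function(n_bands = 12) runif(n_bands, 0.01, 1)

# tiny cube with known pixel spectra: pixels is an N x bands matrix laid out
# column-major into a rows x cols grid
cube_from_pixels <- function(pixels, rows, cols, wavelengths = NULL) {
  stopifnot(nrow(pixels) == rows * cols)
  a <- array(NA_real_, c(rows, cols, ncol(pixels)))
  for (b in seq_len(ncol(pixels))) {
    a[, , b] <- matrix(pixels[, b], rows, cols)
  }
  suppressWarnings(hcwssc::hyper_cube(a, wavelengths))
}

# scalar-measure dispatch used by the loop oracles (independent of the
# vectorised dissimilarity_matrix path)
oracle_measure <- function(m, x, y) {
  switch(m,
         ED = sqrt(sum((x - y)^2)),
         SAC = 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
         SCC = 1 - stats::cor(x, y),
         SID = {
           p <- x / sum(x) + 1e-12
           q <- y / sum(y) + 1e-12
           sum(p * log(p / q)) + sum(q * log(q / p))
         })
}

# brute-force per-pixel feature map
oracle_feature_map <- function(cube, m) {
  px <- hcwssc::cube_pixels(cube)
  ref <- colMeans(px)
  vapply(seq_len(nrow(px)), function(i) oracle_measure(m, px[i, ], ref),
         numeric(1))
}

# brute-force hybrid-kernel assignment: triple loop over pixel, centroid,
# measure
oracle_assign <- function(px, centroids, measures, weights) {
  vapply(seq_len(nrow(px)), function(i) {
    d <- vapply(seq_len(nrow(centroids)), function(j) {
      sum(vapply(seq_along(measures), function(k) {
        weights[k] * oracle_measure(measures[k], px[i, ], centroids[j, ])
      }, numeric(1)))
    }, numeric(1))
    which.min(d)
  }, integer(1))
}

# exhaustive-permutation optimum for cluster -> class mapping (square case)
oracle_best_permutation_oa <- function(tab) {
  stopifnot(nrow(tab) == ncol(tab))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- 0
  for (p in perms(seq_len(ncol(tab)))) {
    best <- max(best, sum(tab[cbind(seq_len(nrow(tab)), p)]))
  }
  best / sum(tab)
}

# Cohen's kappa straight from the definition (marginal-product pe)
oracle_kappa <- function(m) {
  total <- sum(m)
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  (po - pe) / (1 - pe)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
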