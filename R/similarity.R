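#' Spectral dissimilarity measures
#'
#' The four per-pair spectral dissimilarity measures used throughout the
#' package. All follow the same convention: 0 means identical spectra, larger
#' values mean less similar.
#'
#' * `ed()` — Euclidean distance between the band vectors; sensitive to
#'   brightness (magnitude) differences, not scale-invariant.
#' * `sac()` — spectral angle cosine dissimilarity, `1 - cos(theta)` between
#'   the band vectors; invariant to positive rescaling of either spectrum,
#'   range `[0, 2]`.
#' * `scc()` — spectral correlation dissimilarity, `1 - r` where `r` is the
#'   Pearson correlation across bands; invariant to positive-slope affine
#'   maps of either spectrum, range `[0, 2]`.
#' * `sid()` — spectral information divergence, the symmetric Kullback-Leibler
#'   divergence between the band-normalised probability vectors
#'   `p = x/sum(x)` and `q = y/sum(y)`; invariant to positive rescaling.
#'
#' @param x,y Numeric vectors of reflectance, equal length >= 2.
#' @param log_base Base of the logarithm for `sid()`; `exp(1)` (nats, the
#'   default) or `2` (bits).
#' @param eps Small constant added to the normalised probabilities before the
#'   logarithms in `sid()` so zero bands stay finite.
#'
#' @return A single non-negative dissimilarity value.
#' @examples
#' ed(c(0, 3), c(4, 0))       # 5
#' sac(c(1, 0), c(0, 1))      # 1 (orthogonal)
#' scc(1:5, 5:1)              # 2 (perfect anticorrelation)
#' sid(c(.5, .5), c(.9, .1))  # ~0.879 nats
#' @name measures
NULL

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop("band-count mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 2) stop("spectra need at least 2 bands")
}

#' @rdname measures
#' @export
ed <- function(x, y) {
  check_pair(x, y)
  sqrt(sum((x - y)^2))
}

#' @rdname measures
#' @export
sac <- function(x, y) {
  check_pair(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("sac undefined for an all-zero spectrum")
  1 - sum(x * y) / (nx * ny)
}

#' @rdname measures
#' @export
scc <- function(x, y) {
  check_pair(x, y)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("scc undefined for a band-constant spectrum")
  }
  1 - cor(x, y)
}

#' @rdname measures
#' @export
sid <- function(x, y, log_base = exp(1), eps = 1e-12) {
  check_pair(x, y)
  if (any(x < 0) || any(y < 0)) stop("sid requires non-negative reflectance")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 || sy == 0) stop("sid undefined for a zero-sum spectrum")
  p <- x / sx + eps
  q <- y / sy + eps
  lg <- log(p / q) / log(log_base)
  sum(p * lg) + sum(-q * lg)
}

#' Measure identifiers
#'
#' The four measure ids in their canonical (tie-break) order.
#' @return Character vector `c("ED", "SAC", "SCC", "SID")`.
#' @export
measure_ids <- function() c("ED", "SAC", "SCC", "SID")

match_measure <- function(m) {
  match.arg(toupper(m), measure_ids())
}

measure_fun <- function(m) {
  switch(match_measure(m), ED = ed, SAC = sac, SCC = scc, SID = sid)
}

#' Pairwise dissimilarities between pixel rows and reference spectra
#'
#' Vectorised evaluation of one measure between every row of `x` and every
#' row of `y`. This is the workhorse behind feature-map extraction and
#' K-means assignment; it agrees with the scalar measures ([ed()] etc.) to
#' machine precision.
#'
#' Rows that are degenerate under the measure (all-zero for SAC/SID,
#' band-constant for SCC) yield non-finite entries which are replaced by the
#' largest finite value observed, with a warning, so a degenerate pixel can
#' never win an argmin by accident of NaN ordering.
#'
#' @param x Numeric matrix, N x bands (pixels).
#' @param y Numeric matrix, K x bands (reference spectra), or a single
#'   spectrum as a vector.
#' @param measure One of `"ED"`, `"SAC"`, `"SCC"`, `"SID"`.
#' @param log_base,eps Passed to the SID computation; see [sid()].
#' @return N x K numeric matrix of dissimilarities.
#' @export
dissimilarity_matrix <- function(x, y, measure, log_base = exp(1), eps = 1e-12) {
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  stopifnot(ncol(x) == ncol(y))
  measure <- match_measure(measure)
  out <- switch(
    measure,
    ED = {
      d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
      sqrt(pmax(d2, 0))
    },
    SAC = {
      nx <- sqrt(rowSums(x^2)); ny <- sqrt(rowSums(y^2))
      1 - tcrossprod(x, y) / outer(nx, ny)
    },
    SCC = {
      xc <- x - rowMeans(x); yc <- y - rowMeans(y)
      nx <- sqrt(rowSums(xc^2)); ny <- sqrt(rowSums(yc^2))
      1 - tcrossprod(xc, yc) / outer(nx, ny)
    },
    SID = {
      sx <- rowSums(x); sy <- rowSums(y)
      bad_x <- sx == 0 | apply(x, 1, function(r) any(r < 0))
      bad_y <- sy == 0 | apply(y, 1, function(r) any(r < 0))
      p <- x / ifelse(sx == 0, 1, sx) + eps
      q <- y / ifelse(sy == 0, 1, sy) + eps
      lp <- log(p) / log(log_base); lq <- log(q) / log(log_base)
      # sum_b (p-q) (log p - log q), expanded into rank-1 + matrix products
      m <- tcrossprod(p, lq) + tcrossprod(lp, q) # cross terms
      s <- outer(rowSums(p * lp), rowSums(q * lq), "+") - m
      s[bad_x, ] <- NaN
      s[, bad_y] <- NaN
      s
    }
  )
  patch_degenerate(out, measure)
}

# replace non-finite dissimilarities (degenerate pixels under a measure) by
# the largest finite value observed, so they sort last everywhere
patch_degenerate <- function(m, measure) {
  bad <- !is.finite(m)
  if (any(bad)) {
    fin <- m[!bad]
    fill <- if (length(fin)) max(fin) else 0
    m[bad] <- fill
    warning(sum(bad), " degenerate ", measure,
            " value(s) replaced by the maximum observed (", signif(fill, 6), ")")
  }
  m
}

#' Per-pixel feature map against the scene mean spectrum
#'
#' Extracts the feature the filter selection operates on: for every valid
#' pixel, the chosen dissimilarity between the pixel spectrum and the scene
#' mean spectrum (band-wise mean over valid pixels).
#'
#' @param cube A [hyper_cube()].
#' @param measure One of `"ED"`, `"SAC"`, `"SCC"`, `"SID"`.
#' @param reference Optional reference spectrum; defaults to
#'   [mean_spectrum()] of the cube.
#' @param ... Passed on to [dissimilarity_matrix()] (`log_base`, `eps`).
#' @return A `feature_map` object: the rows x cols value matrix (`NA` where
#'   masked), the measure id and the reference spectrum. Convert with
#'   [as_tibble()] or plot with [autoplot()].
#' @export
feature_map <- function(cube, measure, reference = NULL, ...) {
  measure <- match_measure(measure)
  px <- cube_pixels(cube)
  if (is.null(reference)) reference <- colMeans(px)
  vals <- dissimilarity_matrix(px, reference, measure, ...)[, 1]
  structure(
    list(values = unflatten(vals, cube), measure = measure,
         reference = reference, wavelengths = cube$wavelengths),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<feature_map> ", x$measure, ": ", nrow(x$values), " x ", ncol(x$values),
      ", mean ", signif(mean(v), 4), ", cv ",
      signif(sd(v) / mean(v), 4), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble feature_map
#' @export
as_tibble.feature_map <- function(x, ..., row.names = NULL, optional = FALSE) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  tibble(row = idx[, 1], col = idx[, 2],
         measure = x$measure, value = x$values[idx]) |>
    dplyr::arrange(.data$row, .data$col)
}

map_values <- function(map) {
  v <- map$values
  v[!is.na(v)]
}
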