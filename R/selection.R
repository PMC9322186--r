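#' Compute all four feature maps of a cube
#'
#' @param cube A [hyper_cube()].
#' @param ... Passed to [feature_map()].
#' @return Named list of four `feature_map` objects (ED, SAC, SCC, SID).
#' @export
feature_maps <- function(cube, ...) {
  setNames(lapply(measure_ids(), function(m) feature_map(cube, m, ...)),
           measure_ids())
}

#' Pearson correlation between two feature-value sequences
#'
#' Thin wrapper around [stats::cor()] with the degenerate cases turned into
#' errors, used to correlate feature maps pixel-by-pixel.
#'
#' @param a,b Equal-length numeric vectors (length >= 2), neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 values")
  if (sd(a) == 0 || sd(b) == 0) stop("pearson undefined for a constant input")
  cor(a, b)
}

#' Pick the least-correlated pair of feature maps
#'
#' Computes the 4 x 4 Pearson correlation matrix between the feature maps
#' (pairing valid pixels positionally) and returns the unordered pair of
#' measures with the minimum absolute correlation — the pair carrying the
#' least duplicated information. Ties are broken lexicographically in the
#' canonical order ED < SAC < SCC < SID. A band-constant (degenerate) map is
#' excluded from candidacy with a warning.
#'
#' @param maps List of four `feature_map` objects as returned by
#'   [feature_maps()], computed on the same cube and mask.
#' @return List with `pair` (character 2-vector), `rho` (full 4 x 4 matrix)
#'   and `candidates` (measures that entered the competition).
#' @export
select_pair <- function(maps) {
  ids <- measure_ids()
  stopifnot(setequal(names(maps), ids))
  vals <- vapply(maps[ids], map_values, numeric(length(map_values(maps[[1]]))))
  if (nrow(vals) < 2) stop("need at least 2 valid pixels to correlate maps")
  constant <- apply(vals, 2, sd) == 0
  rho <- suppressWarnings(cor(vals))
  diag(rho) <- 1
  dimnames(rho) <- list(ids, ids)
  if (any(constant)) {
    warning("constant feature map(s) excluded from selection: ",
            paste(ids[constant], collapse = ", "))
  }
  cand <- ids[!constant]
  if (length(cand) < 2) stop("fewer than 2 non-degenerate feature maps")
  pairs <- utils::combn(cand, 2)
  absr <- apply(pairs, 2, function(p) abs(rho[p[1], p[2]]))
  best <- which(absr == min(absr))[1] # combn order is lexicographic in ids
  list(pair = pairs[, best], rho = rho, candidates = cand)
}

#' Coefficient of variation of a feature map
#'
#' Standard deviation of the map values over valid pixels divided by their
#' mean; the dimensionless dispersion score used to weight the kernels. A
#' feature with a large CV varies a lot over the scene and is easy to
#' discriminate on.
#'
#' @param map A `feature_map`, or a bare numeric vector of map values.
#' @param sd_type `"population"` (divide by N, the default — the pixels of a
#'   scene are a complete population) or `"sample"` (divide by N - 1).
#' @return Non-negative scalar.
#' @export
coefficient_of_variation <- function(map, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- if (inherits(map, "feature_map")) map_values(map) else as.numeric(map)
  mu <- mean(v)
  if (mu <= 0) stop("coefficient of variation undefined for mean <= 0")
  s <- sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  s / mu
}

#' Kernel weights from CVs and map means
#'
#' The CV-share weights normalised to sum to one (`norm_weights`, the
#' reported ratio: `w1/w2 = cv1/cv2`, `w1 + w2 = 1`) and the operative
#' clustering weights obtained by dividing each share by its feature-map
#' mean, which removes the measure's dimension so two kernels on very
#' different numeric scales contribute comparably.
#'
#' @param cv1,cv2 Non-negative coefficients of variation; `cv1 + cv2 > 0`.
#' @param mean1,mean2 Positive feature-map means.
#' @return List with `norm_weights` (sum to 1) and `weights` (dimensionless,
#'   used in the hybrid kernel), both named length-2 numerics.
#' @export
compute_weights <- function(cv1, cv2, mean1, mean2) {
  if (cv1 < 0 || cv2 < 0 || cv1 + cv2 <= 0) {
    stop("need non-negative cvs with cv1 + cv2 > 0")
  }
  if (mean1 <= 0 || mean2 <= 0) stop("feature-map means must be positive")
  nw <- c(cv1, cv2) / (cv1 + cv2)
  list(norm_weights = nw, weights = nw / c(mean1, mean2))
}

#' Filter feature selection on a scene or spectra set
#'
#' The full selection pipeline: extract the four feature maps against the
#' mean spectrum, correlate them pairwise, keep the least-correlated pair,
#' score each kept measure by its coefficient of variation and convert the
#' CV shares into dimensionless kernel weights. Deterministic: the same
#' input always yields the same selection.
#'
#' @param x A [hyper_cube()], or a numeric matrix of spectra (one row per
#'   spectrum) treated as a 1 x N scene.
#' @param sd_type Standard-deviation convention for the CVs; see
#'   [coefficient_of_variation()].
#' @param ... Passed to [feature_map()] (`log_base`, `eps`).
#' @return A `measure_selection` object with the chosen `pair`, the full
#'   correlation matrix `rho`, per-measure CVs and map means, the sum-to-one
#'   `norm_weights` and the operative `weights`. Methods: [tidy()] (one row
#'   per selected measure), [glance()] (one-row summary), [as_kernel_spec()].
#' @export
run_selection <- function(x, sd_type = c("population", "sample"), ...) {
  sd_type <- match.arg(sd_type)
  if (is.matrix(x)) x <- cube_from_matrix(x)
  stopifnot(inherits(x, "hyper_cube"))
  maps <- feature_maps(x, ...)
  sel <- select_pair(maps)
  cvs <- vapply(maps, function(m) {
    v <- map_values(m)
    if (mean(v) <= 0) NA_real_ else coefficient_of_variation(v, sd_type)
  }, numeric(1))
  means <- vapply(maps, function(m) mean(map_values(m)), numeric(1))
  p <- sel$pair
  w <- compute_weights(cvs[p[1]], cvs[p[2]], means[p[1]], means[p[2]])
  structure(
    list(pair = p, rho = sel$rho, cv = cvs, map_mean = means,
         norm_weights = setNames(w$norm_weights, p),
         weights = setNames(w$weights, p),
         sd_type = sd_type),
    class = "measure_selection"
  )
}

# wrap a spectra-by-bands matrix as a 1-row scene so every cube operation
# applies to spectral libraries too
cube_from_matrix <- function(m, wavelengths = NULL) {
  stopifnot(is.matrix(m), nrow(m) >= 1)
  a <- array(m, dim = c(1, nrow(m), ncol(m)))
  suppressWarnings(hyper_cube(a, wavelengths))
}

#' @export
print.measure_selection <- function(x, ...) {
  cat("<measure_selection>\n  pair: ", paste(x$pair, collapse = " + "),
      "  (|rho| = ", signif(abs(x$rho[x$pair[1], x$pair[2]]), 4), ")\n",
      "  norm weights: ", paste(signif(x$norm_weights, 4), collapse = ", "),
      "\n  kernel weights: ", paste(signif(x$weights, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname run_selection
#' @param x A `measure_selection`.
#' @method tidy measure_selection
#' @export
tidy.measure_selection <- function(x, ...) {
  tibble(measure = x$pair,
         cv = unname(x$cv[x$pair]),
         map_mean = unname(x$map_mean[x$pair]),
         norm_weight = unname(x$norm_weights),
         weight = unname(x$weights))
}

#' @rdname run_selection
#' @method glance measure_selection
#' @export
glance.measure_selection <- function(x, ...) {
  tibble(measure1 = x$pair[1], measure2 = x$pair[2],
         abs_rho = abs(x$rho[x$pair[1], x$pair[2]]),
         norm_weight1 = unname(x$norm_weights[1]),
         norm_weight2 = unname(x$norm_weights[2]),
         weight1 = unname(x$weights[1]),
         weight2 = unname(x$weights[2]))
}

#' Serialise a selection report
#'
#' Writes the pair, full correlation matrix, CVs and both weight sets as
#' JSON for audit.
#'
#' @param x A `measure_selection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(x, path) {
  jsonlite::write_json(
    list(pair = x$pair,
         rho = as.data.frame(x$rho),
         cv = as.list(x$cv),
         map_mean = as.list(x$map_mean),
         norm_weights = as.list(x$norm_weights),
         weights = as.list(x$weights)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
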