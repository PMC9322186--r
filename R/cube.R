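#' Hyperspectral cube
#'
#' A `hyper_cube` holds a rows x cols x bands reflectance array together with
#' the band-centre wavelengths, a per-pixel validity mask and an optional
#' georeference string carried through unchanged by all operations.
#'
#' @param data Numeric array, rows x cols x bands, reflectance (unitless,
#'   values >= 0 expected but not enforced; negative values only trip the
#'   measures that require non-negativity).
#' @param wavelengths Numeric vector of band centres in nm, strictly
#'   increasing, one per band. If `NULL`, a 1-based band index is used and a
#'   warning is emitted.
#' @param mask Logical rows x cols matrix, `TRUE` where the pixel is valid.
#'   Masked pixels are excluded from every statistic and carry `NA` in all
#'   derived maps. Defaults to all valid.
#' @param geo Optional georeference (an opaque string, e.g. an ENVI
#'   `map info` line) passed through untouched.
#'
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths = NULL, mask = NULL, geo = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  d <- dim(data)
  if (is.null(wavelengths)) {
    warning("no wavelengths supplied; using 1-based band indices")
    wavelengths <- seq_len(d[3])
  }
  if (length(wavelengths) != d[3]) {
    stop("wavelengths length (", length(wavelengths),
         ") does not match band count (", d[3], ")")
  }
  if (d[3] >= 2 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, d[1], d[2])
  }
  stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  if (!any(mask)) stop("cube has no valid pixels")
  structure(
    list(data = data, wavelengths = as.numeric(wavelengths),
         mask = mask, geo = geo),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<hyper_cube> ", d[1], " x ", d[2], " pixels, ", d[3], " bands (",
      round(min(x$wavelengths)), "-", round(max(x$wavelengths)), " nm), ",
      sum(x$mask), " valid pixels\n", sep = "")
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

n_bands <- function(cube) dim(cube$data)[3]

#' Valid-pixel matrix of a cube
#'
#' Flattens the cube to an N x bands matrix over valid pixels only, in
#' column-major pixel order (the order used consistently by every function in
#' the package, so label vectors and map matrices always line up).
#'
#' @param cube A [hyper_cube()].
#' @return Numeric matrix, one row per valid pixel.
#' @export
cube_pixels <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(cube$data, d[1] * d[2], d[3])
  m[as.vector(cube$mask), , drop = FALSE]
}

#' Scene mean spectrum
#'
#' Band-wise mean reflectance over valid pixels; the reference ("competitor")
#' spectrum used when extracting feature maps.
#'
#' @param cube A [hyper_cube()].
#' @return Numeric vector, one value per band.
#' @export
mean_spectrum <- function(cube) {
  colMeans(cube_pixels(cube))
}

# place a per-valid-pixel vector back into a rows x cols matrix (NA = masked)
unflatten <- function(values, cube) {
  d <- dim(cube$data)
  out <- matrix(NA_real_, d[1], d[2])
  out[cube$mask] <- values
  out
}

#' @describeIn hyper_cube Long-format view: one row per valid pixel and band,
#'   with columns `row`, `col`, `band`, `wavelength`, `reflectance`.
#' @param x,row.names,optional,... Standard [as_tibble()] arguments.
#' @method as_tibble hyper_cube
#' @export
as_tibble.hyper_cube <- function(x, ..., row.names = NULL, optional = FALSE) {
  d <- dim(x$data)
  idx <- which(x$mask, arr.ind = TRUE)
  tidyr::expand_grid(band = seq_len(d[3]),
                     pixel = seq_len(nrow(idx))) |>
    dplyr::transmute(
      row = idx[.data$pixel, 1],
      col = idx[.data$pixel, 2],
      band = .data$band,
      wavelength = x$wavelengths[.data$band],
      reflectance = x$data[cbind(.data$row, .data$col, .data$band)]
    ) |>
    dplyr::arrange(.data$row, .data$col, .data$band)
}
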