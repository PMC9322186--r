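#' Read and write hyperspectral rasters
#'
#' `write_cube()` / `read_cube()` round-trip a [hyper_cube()] through the
#' ENVI flat-binary format (a raw data file plus an ASCII `.hdr` sidecar;
#' BSQ/BIL/BIP interleaves, little- or big-endian, common data types) or a
#' plain multi-directory TIFF (via the `tiff` package; no wavelength or geo
#' metadata, so ENVI is preferred). Wavelengths, the validity mask (as an
#' ENVI `data ignore value`) and any `map info`/`coordinate system string`
#' georeference are carried through the ENVI path unchanged.
#'
#' @param cube A [hyper_cube()].
#' @param path Data-file path; the ENVI header is written next to it as
#'   `<path>.hdr`. A `.tif`/`.tiff` extension selects the TIFF path.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data type code for writing: 4 (float32, default)
#'   or 5 (float64).
#' @param ignore_value Value written into masked pixels.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` returns a
#'   [hyper_cube()].
#' @name cube_io
NULL

envi_dtype <- function(code) {
  switch(as.character(code),
         "1" = list(what = "integer", size = 1, signed = FALSE),
         "2" = list(what = "integer", size = 2, signed = TRUE),
         "3" = list(what = "integer", size = 4, signed = TRUE),
         "4" = list(what = "numeric", size = 4, signed = TRUE),
         "5" = list(what = "numeric", size = 8, signed = TRUE),
         "12" = list(what = "integer", size = 2, signed = FALSE),
         stop("unsupported ENVI data type: ", code))
}

#' @rdname cube_io
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4, ignore_value = -9999) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    return(write_cube_tiff(cube, path))
  }
  interleave <- match.arg(interleave)
  data <- cube$data
  if (!all(cube$mask)) {
    bad <- which(!cube$mask, arr.ind = TRUE)
    for (b in seq_len(dim(data)[3])) {
      data[cbind(bad, b)] <- ignore_value
    }
  }
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(2, 3, 1),
                 bip = c(3, 2, 1))
  vec <- as.vector(aperm(data, perm))
  dt <- envi_dtype(data_type)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(if (dt$what == "integer") as.integer(vec) else as.numeric(vec),
           con, size = dt$size, endian = "little")
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = { written by hcwssc }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = Nanometers"),
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                 collapse = ", "), " }")
  )
  if (!all(cube$mask)) {
    hdr <- c(hdr, paste0("data ignore value = ", ignore_value))
  }
  if (!is.null(cube$geo)) hdr <- c(hdr, paste0("map info = {", cube$geo, "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  # brace-delimited (possibly multi-line) entries first, then scalars
  m <- gregexpr("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
      key <- trimws(tolower(sub("=.*", "", piece)))
      val <- sub("^[^{]*\\{", "", piece)
      val <- sub("\\}\\s*$", "", val)
      out[[key]] <- trimws(val)
    }
    txt <- gsub("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*\\{[^}]*\\}", "", txt)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- trimws(tolower(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(key) && nzchar(val)) out[[key]] <- val
  }
  out
}

#' @rdname cube_io
#' @export
read_cube <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    return(read_cube_tiff(path))
  }
  hdr_path <- if (file.exists(paste0(path, ".hdr"))) {
    paste0(path, ".hdr")
  } else {
    sub("\\.[^.]+$", ".hdr", path)
  }
  if (!file.exists(hdr_path)) {
    stop("no ENVI header found for ", path)
  }
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(need, names(h))
  if (length(missing)) {
    stop("malformed ENVI header ", hdr_path, ": missing ",
         paste(missing, collapse = ", "))
  }
  samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  dt <- envi_dtype(h[["data type"]])
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  offset <- as.integer(h[["header offset"]] %||% "0")
  n <- samples * lines * bands
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  vec <- readBin(con, dt$what, n = n, size = dt$size,
                 signed = dt$signed, endian = endian)
  if (length(vec) < n) {
    stop("truncated ENVI file ", path, ": expected ", n, " values (",
         lines, " lines x ", samples, " samples x ", bands, " bands), got ",
         length(vec))
  }
  interleave <- tolower(h[["interleave"]])
  dims <- switch(interleave,
                 bsq = c(samples, lines, bands),
                 bil = c(samples, bands, lines),
                 bip = c(bands, samples, lines),
                 stop("unknown interleave: ", interleave))
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(3, 1, 2),
                 bip = c(3, 2, 1))
  data <- aperm(array(as.numeric(vec), dims), perm)
  wl <- if (!is.null(h[["wavelength"]])) {
    as.numeric(trimws(strsplit(h[["wavelength"]], ",")[[1]]))
  } else {
    NULL # hyper_cube() warns and falls back to band indices
  }
  mask <- NULL
  if (!is.null(h[["data ignore value"]])) {
    iv <- as.numeric(h[["data ignore value"]])
    mask <- apply(data == iv, c(1, 2), all) == FALSE
    data[data == iv] <- NA_real_
    data[is.na(data)] <- 0
  }
  geo <- h[["map info"]]
  hyper_cube(data, wl, mask, geo)
}

write_cube_tiff <- function(cube, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  d <- dim(cube$data)
  pages <- lapply(seq_len(d[3]), function(b) cube$data[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

read_cube_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  warning("TIFF carries no wavelength metadata; using band indices")
  suppressWarnings(hyper_cube(data, NULL))
}

#' Read and write class rasters
#'
#' A truth/classification raster is stored as a single-band integer ENVI
#' raster whose header lists the class names; the in-memory form is a
#' character matrix of class names (`NA` = unlabelled).
#'
#' @param truth Character (or integer) rows x cols matrix.
#' @param path Data-file path (header written as `<path>.hdr`).
#' @param geo Optional georeference string to carry.
#' @return `write_class_raster()` returns `path` invisibly;
#'   `read_class_raster()` returns a character matrix.
#' @name class_raster
NULL

#' @rdname class_raster
#' @export
write_class_raster <- function(truth, path, geo = NULL) {
  stopifnot(is.matrix(truth))
  classes <- sort(unique(as.vector(truth[!is.na(truth)])))
  codes <- matrix(match(as.vector(truth), classes), nrow(truth), ncol(truth))
  codes[is.na(codes)] <- 0L # 0 = unlabelled
  con <- file(path, "wb")
  writeBin(as.integer(t(codes)), con, size = 4, endian = "little") # sample-fastest
  close(con)
  hdr <- c("ENVI",
           paste0("samples = ", ncol(truth)),
           paste0("lines = ", nrow(truth)),
           "bands = 1",
           "header offset = 0",
           "file type = ENVI Classification",
           "data type = 3",
           "interleave = bsq",
           "byte order = 0",
           paste0("classes = ", length(classes)),
           paste0("class names = { ", paste(classes, collapse = ", "), " }"))
  if (!is.null(geo)) hdr <- c(hdr, paste0("map info = {", geo, "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname class_raster
#' @export
read_class_raster <- function(path) {
  hdr_path <- if (file.exists(paste0(path, ".hdr"))) {
    paste0(path, ".hdr")
  } else {
    sub("\\.[^.]+$", ".hdr", path)
  }
  h <- parse_envi_header(hdr_path)
  samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
  con <- file(path, "rb")
  codes <- readBin(con, "integer", n = samples * lines, size = 4,
                   endian = "little")
  close(con)
  m <- t(matrix(codes, samples, lines)) # ENVI sample-fastest order
  m <- matrix(m, lines, samples)
  classes <- if (!is.null(h[["class names"]])) {
    trimws(strsplit(h[["class names"]], ",")[[1]])
  } else {
    as.character(seq_len(max(codes)))
  }
  out <- matrix(NA_character_, lines, samples)
  out[m > 0] <- classes[m[m > 0]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write spectral libraries
#'
#' A spectral library is delimited text: first column the wavelength in nm,
#' then one reflectance column per spectrum. Column headers carry the class
#' label, optionally suffixed `_<n>` to keep ids unique (`"grass_1"`,
#' `"grass_2"`, `"shale_1"`). Several files on different wavelength grids
#' are merged by linear interpolation onto the grid of the first file
#' (values at shared knots are unchanged).
#'
#' @param path One or more file paths (`read_spectral_library`), or one
#'   output path (`write_spectral_library`).
#' @param lib A `spectral_library`: list with `wavelengths`, `spectra`
#'   (spectra x bands matrix), `ids`, `classes`.
#' @param delim Field delimiter (default tab).
#' @return `read_spectral_library()` returns a `spectral_library`;
#'   `write_spectral_library()` returns `path` invisibly.
#' @name library_io
NULL

#' @rdname library_io
#' @export
read_spectral_library <- function(path, delim = "\t") {
  libs <- lapply(path, function(p) {
    df <- readr::read_delim(p, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    wl <- df[[1]]
    if (length(wl) >= 2 && any(diff(wl) <= 0)) {
      stop("non-monotone wavelengths in ", p)
    }
    ids <- names(df)[-1]
    list(wavelengths = as.numeric(wl),
         spectra = t(as.matrix(df[, -1, drop = FALSE])),
         ids = ids,
         classes = sub("_[0-9]+$", "", ids))
  })
  base <- libs[[1]]
  if (length(libs) > 1) {
    for (l in libs[-1]) {
      resampled <- t(apply(l$spectra, 1, function(s) {
        approx(l$wavelengths, s, xout = base$wavelengths, rule = 2)$y
      }))
      base$spectra <- rbind(base$spectra, resampled)
      base$ids <- c(base$ids, l$ids)
      base$classes <- c(base$classes, l$classes)
    }
  }
  structure(base, class = "spectral_library")
}

#' @rdname library_io
#' @export
write_spectral_library <- function(lib, path, delim = "\t") {
  df <- as.data.frame(t(lib$spectra))
  names(df) <- lib$ids
  df <- cbind(wavelength = lib$wavelengths, df)
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library> ", nrow(x$spectra), " spectra, ",
      ncol(x$spectra), " bands, classes: ",
      paste(unique(x$classes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble spectral_library
#' @export
as_tibble.spectral_library <- function(x, ..., row.names = NULL,
                                       optional = FALSE) {
  tibble(id = rep(x$ids, each = ncol(x$spectra)),
         class = rep(x$classes, each = ncol(x$spectra)),
         wavelength = rep(x$wavelengths, nrow(x$spectra)),
         reflectance = as.vector(t(x$spectra)))
}

#' Write or read a triplet suite as a spectral library
#'
#' Triplet groups ([make_triplets()]) serialise to the library text format
#' with ids encoding group, member and class (`g<group>m<member>_<class>`).
#'
#' @param triplets Triplet tibble from [make_triplets()].
#' @param path File path.
#' @param delim Field delimiter.
#' @return `write_triplets()` returns `path` invisibly; `read_triplets()`
#'   the triplet tibble.
#' @name triplet_io
NULL

#' @rdname triplet_io
#' @export
write_triplets <- function(triplets, path, delim = "\t") {
  wl <- attr(triplets, "wavelengths") %||%
    seq_len(length(triplets$reflectance[[1]]))
  lib <- structure(
    list(wavelengths = wl,
         spectra = do.call(rbind, triplets$reflectance),
         ids = sprintf("g%dm%d_%s", triplets$group, triplets$member,
                       triplets$class),
         classes = triplets$class),
    class = "spectral_library")
  write_spectral_library(lib, path, delim)
}

#' @rdname triplet_io
#' @export
read_triplets <- function(path, delim = "\t") {
  lib <- read_spectral_library(path, delim)
  info <- regmatches(lib$ids, regexec("^g([0-9]+)m([0-9]+)_(.*)$", lib$ids))
  if (any(lengths(info) != 4)) stop("not a triplet library: bad ids")
  out <- tibble(
    group = as.integer(vapply(info, `[`, character(1), 2)),
    member = as.integer(vapply(info, `[`, character(1), 3)),
    class = vapply(info, `[`, character(1), 4),
    role = NA_character_,
    reflectance = lapply(seq_len(nrow(lib$spectra)),
                         function(i) lib$spectra[i, ])
  )
  out <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(role = ifelse(duplicated(.data$class) |
                                  duplicated(.data$class, fromLast = TRUE),
                                "same", "odd")) |>
    dplyr::ungroup()
  attr(out, "wavelengths") <- lib$wavelengths
  out
}
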