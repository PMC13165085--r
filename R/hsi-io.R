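#' Hyperspectral cube container
#'
#' A 3-D reflectance (or raw-signal) array with its wavelength grid and
#' acquisition metadata. Dimensions are rows (lines) x cols (samples) x bands.
#'
#' @param data Numeric array, rows x cols x bands.
#' @param wavelengths Strictly increasing numeric vector, one value per band
#'   (nm).
#' @param meta Named list of acquisition metadata (date, plant id, integration
#'   mode, ...).
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths, meta = list()) {
  if (length(dim(data)) != 3) abort("`data` must be a 3-D array")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3]) {
    abort("length of `wavelengths` must equal the number of bands")
  }
  if (any(diff(wavelengths) <= 0)) abort("`wavelengths` must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

envi_dtype <- function(code) {
  switch(as.character(code),
         "4" = list(what = "numeric", size = 4, signed = TRUE),
         "5" = list(what = "numeric", size = 8, signed = TRUE),
         "12" = list(what = "integer", size = 2, signed = FALSE),
         abort(sprintf("unsupported ENVI data type %s", code)))
}

#' Write a cube as an ENVI-style header + flat binary pair
#'
#' The header is a plain-text `key = value` file with a wavelength block; the
#' binary holds the values sample-fastest in BSQ or BIL interleave,
#' little-endian, as 32-bit float (data type 4), 64-bit float (5) or unsigned
#' 16-bit integer (12).
#'
#' @param cube A [hyper_cube()].
#' @param hdr_path,bin_path Output paths for header and binary.
#' @param interleave `"bsq"` or `"bil"`.
#' @param data_type ENVI data-type code: 4, 5 or 12.
#' @return `hdr_path`, invisibly.
#' @export
write_envi <- function(cube, hdr_path, bin_path, interleave = c("bsq", "bil"),
                       data_type = 4) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  dt <- envi_dtype(data_type)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {vinestress synthetic cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, digits = 10, trim = TRUE),
                  collapse = ", "))
  )
  writeLines(hdr, hdr_path)
  # ENVI value order: sample fastest; BSQ = (s, l, b), BIL = (s, b, l).
  arr <- if (interleave == "bsq") aperm(cube$data, c(2, 1, 3)) else aperm(cube$data, c(2, 3, 1))
  v <- as.vector(arr)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  if (dt$what == "integer") {
    v <- as.integer(round(v))
    if (any(v < 0 | v > 65535)) abort("values out of range for unsigned 16-bit output")
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  }
  invisible(hdr_path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\n{]+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NA_character_)
    trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "[,\\s]+")[[1]][nzchar(strsplit(m[2], "[,\\s]+")[[1]])])
  }
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = as.integer(get_scalar("byte order")),
    wavelength = get_block("wavelength")
  )
}

#' Read an ENVI-style header + binary pair
#'
#' @param hdr_path,bin_path Paths to the header and binary written by
#'   [write_envi()] (or by a camera using the same dialect).
#' @return A [hyper_cube()].
#' @export
read_envi <- function(hdr_path, bin_path) {
  h <- parse_envi_header(hdr_path)
  if (is.na(h$samples) || is.na(h$lines) || is.na(h$bands)) {
    abort("header must declare samples, lines and bands")
  }
  if (is.null(h$wavelength)) abort("header is missing the wavelength block")
  if (length(h$wavelength) != h$bands) {
    abort("wavelength list length does not match declared bands")
  }
  if (!h$interleave %in% c("bsq", "bil")) {
    abort(sprintf("unsupported interleave '%s'", h$interleave))
  }
  dt <- envi_dtype(h$data_type)
  n <- h$samples * h$lines * h$bands
  expected_bytes <- n * dt$size
  actual_bytes <- file.info(bin_path)$size
  if (is.na(actual_bytes) || actual_bytes != expected_bytes) {
    abort(sprintf("binary holds %s bytes but header declares %d",
                  format(actual_bytes), expected_bytes))
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- if (dt$what == "integer") {
    as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                       endian = "little"))
  } else {
    readBin(con, "numeric", n = n, size = dt$size, endian = "little")
  }
  arr <- if (h$interleave == "bsq") {
    aperm(array(v, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3))
  } else {
    aperm(array(v, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2))
  }
  hyper_cube(arr, h$wavelength)
}

#' Convert a raw cube to reflectance with dark/white references
#'
#' Per band: `R = (raw - dark) / (white - dark)`. References supplied as
#' per-band vectors, or as spatial frames/cubes that are averaged over their
#' spatial extent first (the white plate is scene-level). Values above 1
#' (specular highlights) are not clipped.
#'
#' @param raw A [hyper_cube()] of raw signal.
#' @param dark,white Per-band numeric vectors, or arrays whose last dimension
#'   is bands.
#' @return A reflectance [hyper_cube()].
#' @export
to_reflectance <- function(raw, dark, white) {
  stopifnot(inherits(raw, "hyper_cube"))
  n_bands <- dim(raw$data)[3]
  as_band_means <- function(x) {
    if (is.null(dim(x))) {
      if (length(x) != n_bands) abort("reference length must equal band count")
      as.numeric(x)
    } else {
      nd <- length(dim(x))
      if (dim(x)[nd] != n_bands) abort("reference last dimension must be bands")
      apply(x, nd, mean)
    }
  }
  dk <- as_band_means(dark)
  wt <- as_band_means(white)
  denom <- wt - dk
  if (any(denom <= 0)) abort("white reference must exceed dark at every band")
  out <- sweep(sweep(raw$data, 3, dk, `-`), 3, denom, `/`)
  hyper_cube(out, raw$wavelengths, c(raw$meta, list(reflectance = TRUE)))
}

#' Trim noisy long-wavelength bands
#'
#' Retains exactly the bands with wavelength strictly below `max_wavelength`
#' (the noisy detector tail above the cutoff is discarded). Works on a
#' [hyper_cube()] or on a wide spectrum table.
#'
#' @param x A `hyper_cube` or a spectrum table with `wl_*` columns.
#' @param max_wavelength Cutoff in nm.
#' @return The same kind of object with the retained bands.
#' @examples
#' # 2025 campaign cutoff: everything from 926 nm up is removed
#' @export
trim_bands <- function(x, max_wavelength) {
  UseMethod("trim_bands")
}

#' @export
trim_bands.hyper_cube <- function(x, max_wavelength) {
  keep <- x$wavelengths < max_wavelength
  if (!any(keep)) abort("no bands retained below the cutoff")
  hyper_cube(x$data[, , keep, drop = FALSE], x$wavelengths[keep], x$meta)
}

#' @export
trim_bands.data.frame <- function(x, max_wavelength) {
  wl <- spectrum_wavelengths(x)
  keep <- wl < max_wavelength
  if (!any(keep)) abort("no bands retained below the cutoff")
  wl_cols <- grep("^wl_", names(x), value = TRUE)
  x[setdiff(names(x), wl_cols[!keep])]
}
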