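#' @importFrom rlang .data abort warn
#' @importFrom stats rnorm runif sd var median quantile
NULL

# Round half away from zero (display convention for reported means/doses).
# Base round() is half-to-even, which prints 4.625 as 4.62.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible substream seed from a root seed and a stream name,
# so independent modules (spectra, noise, potentials, ...) never share a
# random stream. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# Wavelength columns of a spectrum table are named wl_<nm>; these helpers
# move between the wide tibble and the numeric matrix the chemometrics needs.
wl_colnames <- function(wavelengths) sprintf("wl_%.4g", wavelengths)

#' Wavelength grid of a spectrum table
#'
#' @param tbl A spectrum table (tibble with `wl_*` columns).
#' @return Numeric vector of wavelengths in nm, in column order.
#' @export
spectrum_wavelengths <- function(tbl) {
  nm <- grep("^wl_", names(tbl), value = TRUE)
  if (length(nm) == 0) abort("no `wl_*` spectral columns found")
  as.numeric(sub("^wl_", "", nm))
}

#' Spectral matrix of a spectrum table
#'
#' @param tbl A spectrum table.
#' @return Numeric matrix, one row per spectrum, one column per wavelength.
#' @export
spectrum_matrix <- function(tbl) {
  nm <- grep("^wl_", names(tbl), value = TRUE)
  as.matrix(tbl[nm])
}

set_spectrum_matrix <- function(tbl, mat) {
  nm <- grep("^wl_", names(tbl), value = TRUE)
  stopifnot(length(nm) == ncol(mat), nrow(tbl) == nrow(mat))
  tbl[nm] <- as.data.frame(mat)
  tbl
}
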