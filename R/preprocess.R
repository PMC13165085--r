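#' Standard Normal Variate transform
#'
#' Standardizes each spectrum to zero mean and unit standard deviation
#' (sample, n-1 denominator), removing multiplicative scatter and additive
#' illumination effects: the output is invariant to any per-spectrum gain and
#' offset.
#'
#' @param x Numeric vector (one spectrum) or matrix (spectra in rows).
#' @return Same shape as `x`.
#' @examples
#' snv(c(1, 2, 3))
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    if (any(s == 0)) abort("constant spectrum: SNV undefined (sd = 0)")
    (x - mu) / s
  } else {
    if (length(x) < 2) abort("spectrum must have length >= 2")
    s <- sd(x)
    if (s == 0) abort("constant spectrum: SNV undefined (sd = 0)")
    (x - mean(x)) / s
  }
}

# Band x band Savitzky-Golay smoothing operator: interior rows carry the
# central least-squares coefficients; the first/last half-windows use the
# asymmetric rows of the first/last full-window fit (mirror-free), as in
# signal::sgolayfilt. Built once per (window, polyorder, band count) so
# smoothing a whole table is a single matrix product.
sg_operator <- function(n_bands, window, polyorder) {
  if (window %% 2 != 1) abort("`window` must be odd")
  if (window <= polyorder) abort("`window` must exceed `polyorder`")
  if (window > n_bands) abort("`window` must not exceed the number of bands")
  f <- unclass(signal::sgolay(p = polyorder, n = window))
  half <- (window - 1) / 2
  op <- matrix(0, n_bands, n_bands)
  for (i in seq_len(half)) {
    op[i, 1:window] <- f[i, ]
    op[n_bands - i + 1, (n_bands - window + 1):n_bands] <- rev(f[i, ])
  }
  centre <- f[half + 1, ]
  for (i in (half + 1):(n_bands - half)) {
    op[i, (i - half):(i + half)] <- centre
  }
  op
}

#' Savitzky-Golay smoothing
#'
#' Sliding-window least-squares polynomial smoothing (zeroth derivative).
#' Polynomials of degree `<= polyorder` are reproduced exactly, including at
#' the edges, where the first/last full window's fit is evaluated (no
#' mirroring).
#'
#' @param x Numeric vector (one spectrum) or matrix (spectra in rows).
#' @param window Odd window length in points (default 11).
#' @param polyorder Polynomial order (default 2).
#' @return Same shape as `x`.
#' @export
sg_smooth <- function(x, window = 11, polyorder = 2) {
  if (is.matrix(x)) {
    op <- sg_operator(ncol(x), window, polyorder)
    x %*% t(op)
  } else {
    op <- sg_operator(length(x), window, polyorder)
    as.vector(op %*% x)
  }
}

#' Mean-center a spectra matrix
#'
#' Subtracts column (per-band) means; output column means are zero.
#'
#' @param x Numeric matrix, spectra in rows.
#' @return Centered matrix.
#' @export
mean_center <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2) abort("mean centering needs >= 2 spectra")
  sweep(x, 2, colMeans(x), `-`)
}

#' Chemometric preprocessing chain for a spectrum table
#'
#' Applies the treatment chain in order: SNV per spectrum, Savitzky-Golay
#' smoothing, then mean centering. Centering is computed per plant over the
#' plant's full day-stacked matrix by default (`"per_plant_all_days"`), so all
#' of a plant's days share one centered space and day-one scores can serve as
#' a baseline; `"per_plant_day"` centers each plant-day block independently.
#'
#' @param tbl Spectrum table (`wl_*` columns plus `plant_id`, `day` keys).
#' @param snv Apply SNV? (default TRUE)
#' @param window,polyorder Savitzky-Golay parameters (defaults 11 and 2);
#'   `window = 0` disables smoothing.
#' @param center Mean-centering scope: `"per_plant_all_days"` (default),
#'   `"per_plant_day"`, or `"none"`.
#' @return The table with the `wl_*` columns replaced by processed values.
#' @export
preprocess_spectra <- function(tbl, snv = TRUE, window = 11, polyorder = 2,
                               center = c("per_plant_all_days",
                                          "per_plant_day", "none")) {
  center <- match.arg(center)
  x <- spectrum_matrix(tbl)
  if (isTRUE(snv)) x <- snv(x)
  if (window > 0) x <- sg_smooth(x, window, polyorder)
  if (center != "none") {
    key <- if (center == "per_plant_all_days") {
      tbl$plant_id
    } else {
      paste(tbl$plant_id, tbl$day)
    }
    for (k in unique(key)) {
      rows <- which(key == k)
      x[rows, ] <- mean_center(x[rows, , drop = FALSE])
    }
  }
  set_spectrum_matrix(tbl, x)
}
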