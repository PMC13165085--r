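#' Sample leaf pixels from a cube
#'
#' Draws `n` distinct pixels uniformly at random from the eligible in-mask
#' pixels of a reflectance cube. Eligibility excludes saturated pixels (any
#' band at or above the sensor ceiling) and the brightest in-mask pixels
#' (above the `brightness_quantile` of in-mask mean reflectance) — an explicit
#' surrogate for restricting selection to shadowed, non-specular leaf areas.
#' Deterministic given `seed`.
#'
#' @param cube A [hyper_cube()].
#' @param mask Logical matrix matching the cube's spatial dimensions
#'   (TRUE = leaf).
#' @param n Number of pixels to draw.
#' @param seed Integer seed for the draw.
#' @param brightness_quantile In-mask mean-reflectance quantile above which
#'   pixels are excluded (default 0.9); set to 1 to disable.
#' @param saturation_level Sensor ceiling; pixels with any band `>=` this value
#'   are excluded (default `Inf` = disabled, for already-calibrated cubes).
#' @return A `pixel_selection` tibble with columns `row`, `col`, plus
#'   attributes `mode = "mask_random"` and `seed`.
#' @export
sample_pixels <- function(cube, mask, n, seed = 1L,
                          brightness_quantile = 0.9,
                          saturation_level = Inf) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  stopifnot(is.matrix(mask), nrow(mask) == d[1], ncol(mask) == d[2])
  if (!any(mask)) abort("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  lin <- (idx[, 2] - 1) * d[1] + idx[, 1]
  px <- flat[lin, , drop = FALSE]
  saturated <- apply(px, 1, function(v) any(v >= saturation_level))
  means <- rowMeans(px)
  bright <- if (brightness_quantile < 1) {
    means > stats::quantile(means[!saturated], brightness_quantile, names = FALSE)
  } else {
    rep(FALSE, length(means))
  }
  eligible <- !saturated & !bright
  if (sum(eligible) < n) {
    abort(sprintf("only %d eligible pixels after exclusions, %d requested",
                  sum(eligible), n))
  }
  elig_idx <- which(eligible)
  pick <- with_substream(seed, "pixel-sampling", {
    elig_idx[sample.int(length(elig_idx), n)]
  })
  sel <- tibble::tibble(row = idx[pick, 1], col = idx[pick, 2])
  attr(sel, "mode") <- "mask_random"
  attr(sel, "seed") <- as.integer(seed)
  sel
}

#' Manually specified pixel selection
#'
#' Wraps an explicit coordinate list (the manual-picking acquisition mode) in
#' the same selection format [sample_pixels()] produces.
#'
#' @param coords Two-column matrix or data frame of (row, col) coordinates.
#' @return A `pixel_selection` tibble with attribute `mode = "manual"`.
#' @export
manual_selection <- function(coords) {
  coords <- as.data.frame(coords)
  names(coords)[1:2] <- c("row", "col")
  if (anyDuplicated(coords)) abort("coordinates must be unique")
  sel <- tibble::as_tibble(coords[, c("row", "col")])
  attr(sel, "mode") <- "manual"
  sel
}

#' Extract spectra at selected pixels
#'
#' Copies the cube's band values at each selected coordinate unmodified into
#' spectrum-table rows keyed by (plant, day, pixel index).
#'
#' @param cube A [hyper_cube()].
#' @param selection A selection from [sample_pixels()] or [manual_selection()].
#' @param plant_id,day,group Key values for the output rows (defaults taken
#'   from the cube metadata when present).
#' @return A spectrum-table tibble: plant_id, group, day, pixel_id, `wl_*`.
#' @export
extract_spectra <- function(cube, selection,
                            plant_id = cube$meta$plant_id %||% NA_character_,
                            day = cube$meta$day %||% NA_integer_,
                            group = NA_character_) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (any(selection$row < 1 | selection$row > d[1] |
            selection$col < 1 | selection$col > d[2])) {
    abort("selection contains out-of-bounds coordinates")
  }
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  lin <- (selection$col - 1) * d[1] + selection$row
  spec <- flat[lin, , drop = FALSE]
  colnames(spec) <- wl_colnames(cube$wavelengths)
  dplyr::bind_cols(
    tibble::tibble(plant_id = plant_id, group = group, day = day,
                   pixel_id = seq_len(nrow(selection))),
    tibble::as_tibble(spec)
  )
}

#' Log / reload a pixel selection for exact reruns
#'
#' @param selection A selection tibble.
#' @param path JSON path.
#' @return `read_selection_json` returns the selection; the writer returns
#'   `path` invisibly.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(
    list(mode = attr(selection, "mode") %||% "manual",
         seed = attr(selection, "seed"),
         coordinates = as.data.frame(selection)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- tibble::as_tibble(x$coordinates)
  attr(sel, "mode") <- x$mode
  if (!is.null(x$seed)) attr(sel, "seed") <- as.integer(x$seed)
  sel
}

`%||%` <- function(a, b) if (is.null(a)) b else a
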