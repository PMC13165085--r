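#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a per-plant PCA model
#'
#' @param x A `plant_pca`.
#' @param ... Unused.
#' @return Long tibble of loadings: `component`, `wavelength` (or band index),
#'   `loading`.
#' @method tidy plant_pca
#' @export
tidy.plant_pca <- function(x, ...) {
  wl <- x$wavelengths %||% seq_len(nrow(x$loadings))
  purrr::map_dfr(seq_len(x$k), function(j) {
    tibble::tibble(component = j, wavelength = wl, loading = x$loadings[, j])
  })
}

#' @rdname tidy.plant_pca
#' @method glance plant_pca
#' @export
glance.plant_pca <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_spectra = x$n,
    explained_pc1 = x$explained[1],
    explained_total = sum(x$explained)
  )
}

#' Tidy a change report
#'
#' @param x A `change_report`.
#' @param ... Unused.
#' @return The per-day test tibble (day, n, median_md2, p_value, significant).
#' @method tidy change_report
#' @export
tidy.change_report <- function(x, ...) {
  dplyr::mutate(x$tests, plant_id = x$plant_id, .before = 1)
}

#' @rdname tidy.change_report
#' @method glance change_report
#' @export
glance.change_report <- function(x, ...) {
  tibble::tibble(plant_id = x$plant_id, change_day = x$change_day,
                 defaulted = x$defaulted, alpha = x$alpha)
}

#' Tidy a trial monitor
#'
#' @param x A `trial_monitor`.
#' @param ... Unused.
#' @return `tidy`: per-plant, per-day test rows; `glance`: the per-plant
#'   change-day tibble.
#' @method tidy trial_monitor
#' @export
tidy.trial_monitor <- function(x, ...) {
  purrr::map_dfr(x$reports, tidy)
}

#' @rdname tidy.trial_monitor
#' @method glance trial_monitor
#' @export
glance.trial_monitor <- function(x, ...) {
  x$change_days
}
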