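#' Per-plant principal component model
#'
#' Fits a PCA to one plant's preprocessed (centered) spectra spanning all
#' acquisition days, via singular value decomposition. Loadings follow the
#' deterministic sign convention that each component's largest-magnitude
#' element is positive.
#'
#' @param x Centered numeric matrix, spectra in rows, bands in columns.
#' @param k Number of components to retain (default 3), or `"var95"` to
#'   retain the smallest number of components explaining at least 95% of the
#'   variance.
#' @param wavelengths Optional wavelength grid to attach (taken from column
#'   names `wl_*` when present).
#' @return An object of class `plant_pca`: `loadings` (bands x k, orthonormal
#'   columns), `scores` (spectra x k), `explained` (fraction of variance per
#'   retained component), `k`, `wavelengths`.
#' @export
fit_plant_pca <- function(x, k = 3, wavelengths = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(wavelengths) && !is.null(colnames(x)) &&
        all(grepl("^wl_", colnames(x)))) {
    wavelengths <- as.numeric(sub("^wl_", "", colnames(x)))
  }
  sv <- svd(x)
  ev <- sv$d^2
  frac <- ev / sum(ev)
  k_use <- if (identical(k, "var95")) {
    as.integer(max(which(cumsum(frac) >= 0.95)[1], 1))
  } else {
    as.integer(k)
  }
  if (nrow(x) <= k_use) abort("need more spectra than retained components")
  r <- sum(sv$d > sv$d[1] * 1e-10)
  if (r < k_use) {
    abort(sprintf("matrix rank %d is below the requested %d components", r, k_use))
  }
  load <- sv$v[, seq_len(k_use), drop = FALSE]
  # sign convention: largest-|.| element of each loading is positive
  for (j in seq_len(k_use)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  scores <- x %*% load
  structure(
    list(loadings = load, scores = scores, explained = frac[seq_len(k_use)],
         k = k_use, n = nrow(x), wavelengths = wavelengths),
    class = "plant_pca"
  )
}

#' @export
print.plant_pca <- function(x, ...) {
  cat(sprintf("<plant_pca> %d components, %d spectra; explained: %s\n",
              x$k, x$n, paste(sprintf("%.1f%%", 100 * x$explained), collapse = " ")))
  invisible(x)
}

#' Day-one baseline reference in score space
#'
#' The monitoring reference: centroid and sample covariance (n-1 denominator)
#' of the day-one score vectors. If the covariance is ill-conditioned
#' (condition number above `cond_max`) a ridge of `epsilon * trace / k` is
#' added to the diagonal; a covariance that is numerically zero is an error.
#'
#' @param model A [fit_plant_pca()] model.
#' @param day1_rows Integer indices of the day-one rows in the model's score
#'   matrix.
#' @param epsilon Ridge factor (default 1e-8).
#' @param cond_max Condition-number threshold that triggers regularization.
#' @param diagonal If `TRUE`, use only the per-component variances (diagonal
#'   covariance).
#' @return An object of class `baseline_ref`: `centroid` (k-vector),
#'   `sigma` (k x k), `n_baseline`.
#' @export
build_baseline <- function(model, day1_rows, epsilon = 1e-8, cond_max = 1e8,
                           diagonal = FALSE) {
  stopifnot(inherits(model, "plant_pca"))
  s <- model$scores[day1_rows, , drop = FALSE]
  k <- ncol(s)
  if (nrow(s) < k + 2) {
    abort(sprintf("need at least k + 2 = %d baseline rows, got %d", k + 2, nrow(s)))
  }
  centroid <- colMeans(s)
  sigma <- stats::cov(s)
  if (diagonal) sigma <- diag(diag(sigma), k)
  tr <- sum(diag(sigma))
  if (tr <= 0 || !all(is.finite(sigma))) {
    abort("day-one scores are degenerate: zero covariance")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_max) {
    sigma <- sigma + diag(epsilon * tr / k, k)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("baseline covariance not positive definite after regularization")
  }
  structure(
    list(centroid = centroid, sigma = sigma, chol = chol(sigma),
         n_baseline = nrow(s), k = k),
    class = "baseline_ref"
  )
}

#' @export
print.baseline_ref <- function(x, ...) {
  cat(sprintf("<baseline_ref> k = %d, n_baseline = %d\n", x$k, x$n_baseline))
  invisible(x)
}

#' Squared Mahalanobis divergence from the baseline
#'
#' `MD^2 = (mu_t - mu_bar)' Sigma_ref^{-1} (mu_t - mu_bar)` for one score
#' vector or a matrix of score vectors (rows), computed via the Cholesky
#' factor of the baseline covariance (no explicit inverse).
#'
#' @param scores k-vector or (rows x k) matrix of score vectors.
#' @param baseline A [build_baseline()] reference.
#' @return Non-negative numeric vector of MD^2 values.
#' @export
mahalanobis_md2 <- function(scores, baseline) {
  stopifnot(inherits(baseline, "baseline_ref"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != baseline$k) abort("score dimension does not match baseline")
  d <- sweep(scores, 2, baseline$centroid, `-`)
  z <- backsolve(baseline$chol, t(d), transpose = TRUE)
  colSums(z^2)
}

# Leave-one-out MD^2 for the baseline day's own points: each point scored
# against the centroid/covariance of the other n-1 points, so the day-one
# reference distribution is out-of-sample like every later day's.
md2_loo <- function(scores, epsilon = 1e-8, cond_max = 1e8) {
  n <- nrow(scores)
  k <- ncol(scores)
  vapply(seq_len(n), function(i) {
    rest <- scores[-i, , drop = FALSE]
    mu <- colMeans(rest)
    sg <- stats::cov(rest)
    tr <- sum(diag(sg))
    ev <- eigen(sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_max) {
      sg <- sg + diag(epsilon * max(tr, .Machine$double.eps) / k, k)
    }
    dd <- scores[i, ] - mu
    sum(backsolve(chol(sg), dd, transpose = TRUE)^2)
  }, numeric(1))
}

#' Assign the change day from per-day MD^2 distributions
#'
#' For every day after the first, the day's per-pixel MD^2 values are compared
#' with the day-one reference values by a two-sample Mann-Whitney rank test;
#' the change day is the earliest day with `p < alpha`. Plants showing no
#' significant change are assigned the last day by default (`defaulted =
#' TRUE`). No multiple-testing correction is applied across days
#' (earliest-crossing rule); the resulting family-wise false-alarm rate is a
#' documented property, not an error.
#'
#' @param md2_tbl Tibble with columns `day` (integer; the smallest is the
#'   baseline day) and `md2`.
#' @param alpha Significance level (default 0.01, a 99% confidence level).
#' @param plant_id Optional id carried into the report.
#' @return An object of class `change_report`: `tests` tibble (day, n,
#'   median_md2, p_value, significant), `change_day`, `defaulted`, `alpha`,
#'   `md2` (the input), `plant_id`.
#' @export
detect_change_day <- function(md2_tbl, alpha = 0.01, plant_id = NA_character_) {
  stopifnot(all(c("day", "md2") %in% names(md2_tbl)))
  days <- sort(unique(md2_tbl$day))
  if (length(days) < 2) abort("need at least two days")
  counts <- table(md2_tbl$day)
  if (any(counts < 2)) abort("every day needs at least two MD^2 values")
  base <- md2_tbl$md2[md2_tbl$day == days[1]]
  tests <- purrr::map_dfr(days, function(d) {
    v <- md2_tbl$md2[md2_tbl$day == d]
    p <- if (d == days[1]) {
      1
    } else {
      suppressWarnings(stats::wilcox.test(v, base, exact = NULL)$p.value)
    }
    tibble::tibble(day = d, n = length(v),
                   median_md2 = median(v), p_value = p,
                   significant = p < alpha & d != days[1])
  })
  sig_days <- tests$day[tests$significant]
  if (length(sig_days) > 0) {
    change_day <- min(sig_days)
    defaulted <- FALSE
  } else {
    change_day <- max(days)
    defaulted <- TRUE
  }
  structure(
    list(tests = tests, change_day = change_day, defaulted = defaulted,
         alpha = alpha, md2 = tibble::as_tibble(md2_tbl), plant_id = plant_id),
    class = "change_report"
  )
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report%s> change day %s%s (alpha = %g)\n",
              if (is.na(x$plant_id)) "" else paste0(" ", x$plant_id),
              x$change_day, if (x$defaulted) " (defaulted to last day)" else "",
              x$alpha))
  print(x$tests)
  invisible(x)
}

#' Wavelength importance from PC1 loadings
#'
#' Ranks wavelengths by the absolute PC1 loading, thresholds at a quantile of
#' that profile, merges contiguous above-threshold bands (tolerating gaps up
#' to `gap_nm`), and reports each resulting range with its peak wavelength,
#' ranked by peak |loading|.
#'
#' @param model A [fit_plant_pca()] model with a wavelength grid.
#' @param threshold_quantile Quantile of |loading| above which a band counts
#'   as important (default 0.8).
#' @param gap_nm Maximum gap (nm) bridged when merging ranges (default 10).
#' @param component Component to use (default 1).
#' @return Tibble: `rank`, `wl_min`, `wl_max`, `wl_peak`, `peak_loading`,
#'   `n_bands`.
#' @export
wavelength_importance <- function(model, threshold_quantile = 0.8,
                                  gap_nm = 10, component = 1) {
  stopifnot(inherits(model, "plant_pca"))
  wl <- model$wavelengths
  if (is.null(wl)) abort("model has no wavelength grid attached")
  a <- abs(model$loadings[, component])
  thr <- stats::quantile(a, threshold_quantile, names = FALSE)
  above <- which(a > thr)
  if (length(above) == 0) above <- which.max(a)
  gaps <- which(diff(wl[above]) > gap_nm)
  starts <- c(1, gaps + 1)
  ends <- c(gaps, length(above))
  ranges <- purrr::map_dfr(seq_along(starts), function(i) {
    idx <- above[starts[i]:ends[i]]
    peak <- idx[which.max(a[idx])]
    tibble::tibble(
      wl_min = wl[min(idx)], wl_max = wl[max(idx)],
      wl_peak = wl[peak], peak_loading = a[peak], n_bands = length(idx)
    )
  })
  ranges <- dplyr::arrange(ranges, dplyr::desc(.data$peak_loading))
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(ranges))), ranges)
}

#' Monitor one plant's spectra for a change day
#'
#' Runs the per-plant chain: preprocess (SNV, smoothing, per-plant centering),
#' fit the PCA across all days, build the day-one baseline, compute per-pixel
#' MD^2 for every day (day one's reference values computed leave-one-out, so
#' they are exchangeable with later days under no change), and assign the
#' change day.
#'
#' @param tbl Spectrum table for one plant (columns `day`, `pixel_id`,
#'   `wl_*`).
#' @param k Retained components (default 3) or `"var95"`.
#' @param alpha Significance level for the per-day rank test.
#' @param preprocess Apply [preprocess_spectra()] first? (default TRUE; set
#'   FALSE if `tbl` is already preprocessed)
#' @param ... Passed to [preprocess_spectra()].
#' @return A `change_report` with the fitted `model` and `baseline` attached.
#' @export
monitor_plant <- function(tbl, k = 3, alpha = 0.01, preprocess = TRUE, ...) {
  pid <- unique(tbl$plant_id)
  if (length(pid) > 1) abort("monitor_plant expects a single plant")
  if (preprocess) tbl <- preprocess_spectra(tbl, ...)
  x <- spectrum_matrix(tbl)
  model <- fit_plant_pca(x, k = k)
  days <- sort(unique(tbl$day))
  day1_rows <- which(tbl$day == days[1])
  baseline <- build_baseline(model, day1_rows)
  md2 <- numeric(nrow(tbl))
  md2[day1_rows] <- md2_loo(model$scores[day1_rows, , drop = FALSE])
  rest <- setdiff(seq_len(nrow(tbl)), day1_rows)
  md2[rest] <- mahalanobis_md2(model$scores[rest, , drop = FALSE], baseline)
  md2_tbl <- tibble::tibble(day = tbl$day, pixel_id = tbl$pixel_id, md2 = md2)
  report <- detect_change_day(md2_tbl, alpha = alpha,
                              plant_id = if (length(pid)) pid else NA_character_)
  report$model <- model
  report$baseline <- baseline
  report
}

#' Monitor a whole trial
#'
#' Applies [monitor_plant()] to every plant in a spectrum table and collects
#' per-plant change days, models and reports.
#'
#' @param tbl Spectrum table for the full trial (`plant_id`, `group`, `day`,
#'   `pixel_id`, `wl_*`).
#' @inheritParams monitor_plant
#' @return An object of class `trial_monitor`: `reports` (named list of
#'   `change_report`s), `change_days` tibble (plant_id, group, change_day,
#'   defaulted), `alpha`, `k`.
#' @export
monitor_trial <- function(tbl, k = 3, alpha = 0.01, ...) {
  plants <- unique(tbl$plant_id)
  reports <- purrr::map(plants, function(p) {
    monitor_plant(dplyr::filter(tbl, .data$plant_id == p), k = k, alpha = alpha, ...)
  })
  names(reports) <- plants
  groups <- dplyr::distinct(tbl, .data$plant_id, .data$group)
  change_days <- tibble::tibble(
    plant_id = plants,
    group = groups$group[match(plants, groups$plant_id)],
    change_day = purrr::map_dbl(reports, "change_day"),
    defaulted = purrr::map_lgl(reports, "defaulted")
  )
  structure(list(reports = reports, change_days = change_days,
                 alpha = alpha, k = k),
            class = "trial_monitor")
}

#' @export
print.trial_monitor <- function(x, ...) {
  cat(sprintf("<trial_monitor> %d plants (k = %s, alpha = %g)\n",
              nrow(x$change_days), x$k, x$alpha))
  print(x$change_days)
  invisible(x)
}
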