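#' Trial design for a synthetic monitoring campaign
#'
#' Describes the experimental layout the generator emulates: how many vines,
#' their control/stress assignment, the acquisition days, how many leaf pixels
#' are sampled per vine and day, and the irrigation schedule.
#'
#' @param n_plants Number of vines.
#' @param n_stress Number of vines assigned to the stress treatment (the
#'   remainder are controls). Ignored when `groups` is given.
#' @param groups Optional character vector of length `n_plants` with values
#'   `"control"`/`"stress"`, one per plant, overriding `n_stress`.
#' @param days Ordered vector of acquisition-day labels (coerced to character);
#'   day indices 1..length(days) are used throughout.
#' @param pixels_per_plant_day Leaf pixels sampled per vine per day (>= 2 so a
#'   day-one covariance is estimable).
#' @param year_label Free-text campaign label.
#' @param irrigation_minutes_per_day Daily irrigation time, minutes.
#' @param emitter_rate Emitter flow rate, litres per hour.
#' @param stress_dose_fraction Fraction of the control dose the stress group
#'   receives (0 = irrigation withheld).
#' @param seed Root seed; all of the trial's randomness derives from it via
#'   named substreams.
#' @return An object of class `trial_design`.
#' @examples
#' trial_design_2024()
#' @export
trial_design <- function(n_plants = 18,
                         n_stress = 10,
                         groups = NULL,
                         days = 1:5,
                         pixels_per_plant_day = 10,
                         year_label = "synthetic",
                         irrigation_minutes_per_day = 28,
                         emitter_rate = 2.3,
                         stress_dose_fraction = 0,
                         seed = 1L) {
  if (length(days) < 1) abort("`days` must be non-empty")
  if (anyDuplicated(days)) abort("`days` must be strictly ordered with no duplicates")
  if (pixels_per_plant_day < 2) {
    abort("`pixels_per_plant_day` must be >= 2 (day-one covariance must be estimable)")
  }
  if (n_plants < 1) abort("`n_plants` must be positive")
  if (stress_dose_fraction < 0 || stress_dose_fraction > 1) {
    abort("`stress_dose_fraction` must be in [0, 1]")
  }
  if (is.null(groups)) {
    if (n_stress < 0 || n_stress > n_plants) abort("`n_stress` out of range")
    groups <- rep("control", n_plants)
    if (n_stress > 0) groups[seq_len(n_stress) + (n_plants - n_stress)] <- "stress"
  }
  if (length(groups) != n_plants) abort("`groups` must have one entry per plant")
  if (!all(groups %in% c("control", "stress"))) {
    abort("`groups` values must be 'control' or 'stress'")
  }
  plant_ids <- sprintf("P%02d", seq_len(n_plants))
  structure(
    list(
      year_label = year_label,
      n_plants = as.integer(n_plants),
      plant_ids = plant_ids,
      group_of_plant = stats::setNames(groups, plant_ids),
      days = as.character(days),
      n_days = length(days),
      pixels_per_plant_day = as.integer(pixels_per_plant_day),
      irrigation_minutes_per_day = irrigation_minutes_per_day,
      emitter_rate = emitter_rate,
      stress_dose_fraction = stress_dose_fraction,
      seed = as.integer(seed)
    ),
    class = "trial_design"
  )
}

#' @rdname trial_design
#' @param seed Root seed.
#' @export
trial_design_2024 <- function(seed = 1L) {
  # 18 vines over five June acquisition dates, ten manually picked pixels each:
  # 18 x 5 x 10 = 900 spectra; stress treatment = irrigation withheld.
  trial_design(
    n_plants = 18, n_stress = 10, days = 1:5, pixels_per_plant_day = 10,
    year_label = "2024", stress_dose_fraction = 0, seed = seed
  )
}

#' @rdname trial_design
#' @export
trial_design_2025 <- function(seed = 1L) {
  # 18 vines over seven dates, 100 random in-mask pixels each: 12,600 spectra;
  # stress treatment = dose reduced to a third of the control.
  trial_design(
    n_plants = 18, n_stress = 9, days = 1:7, pixels_per_plant_day = 100,
    year_label = "2025", stress_dose_fraction = 1 / 3, seed = seed
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "<trial_design '%s'> %d plants (%d stress), %d days, %d px/plant/day, seed %d\n",
    x$year_label, x$n_plants, sum(x$group_of_plant == "stress"),
    x$n_days, x$pixels_per_plant_day, x$seed
  ))
  invisible(x)
}

#' Spectral scenario: the generating model for vegetation reflectance
#'
#' The synthetic leaf spectrum is a low visible continuum rising through a
#' logistic red edge to a NIR plateau, minus Gaussian absorption wells for the
#' photosynthetic pigments (blue ~445 nm, green ~550 nm, red ~680 nm) and leaf
#' water (~970 nm). Water stress deepens the stress-responsive wells by a
#' severity factor that ramps linearly from a known onset day; day-to-day
#' illumination drift multiplies the whole spectrum; sensor noise is
#' heteroscedastic, with a larger standard deviation above a NIR cutoff
#' (emulating the noisy detector tail).
#'
#' @param wavelengths Wavelength grid, nm (default: 204 bands, 400-1000 nm).
#' @param vis_level Visible continuum reflectance.
#' @param nir_plateau NIR plateau reflectance.
#' @param red_edge_nm,red_edge_steepness Logistic red-edge inflection (nm) and
#'   width scale (nm).
#' @param features Tibble with columns `center`, `width`, `depth` (nm, nm,
#'   reflectance) describing Gaussian absorption wells.
#' @param stress_features Centers (nm) of the wells whose depth responds to
#'   stress severity; defaults to the pigment and water wells.
#' @param stress_onset_day Day index at which stressed plants begin to diverge.
#' @param severity_ramp Per-day increment of the severity factor from onset
#'   (severity on day d >= onset is `severity_ramp * (d - onset + 1)`;
#'   0 before onset). Stress-responsive well depths are scaled by
#'   `1 + severity`.
#' @param illumination_drift Half-width of the uniform day-to-day multiplicative
#'   illumination factor (scale ~ U(1 - drift, 1 + drift)).
#' @param noise_sd_vis Additive noise sd below `nir_noise_cutoff`.
#' @param nir_noise_ratio Ratio of NIR to VIS noise sd (applied at or above the
#'   cutoff).
#' @param nir_noise_cutoff Wavelength (nm) above which the NIR noise sd applies.
#' @param psi_onset_day Day index at which stressed plants' stem water
#'   potential diverges (defaults to `stress_onset_day`).
#' @return An object of class `spectral_scenario`.
#' @export
spectral_scenario <- function(wavelengths = seq(400, 1000, length.out = 204),
                              vis_level = 0.12,
                              nir_plateau = 0.48,
                              red_edge_nm = 715,
                              red_edge_steepness = 14,
                              features = default_features(),
                              stress_features = c(445, 680, 970),
                              stress_onset_day = 3L,
                              severity_ramp = 0.5,
                              illumination_drift = 0.05,
                              noise_sd_vis = 0.004,
                              nir_noise_ratio = 5,
                              nir_noise_cutoff = 900,
                              psi_onset_day = stress_onset_day) {
  wavelengths <- sort(as.numeric(wavelengths))
  if (min(wavelengths) > 400 || max(wavelengths) < 1000 - 1e-9) {
    if (min(wavelengths) < 350 || max(wavelengths) > 1100) {
      abort("`wavelengths` must lie in the VIS-NIR window")
    }
  }
  stopifnot(is.data.frame(features), all(c("center", "width", "depth") %in% names(features)))
  if (any(features$depth < 0)) abort("feature depths must be non-negative")
  if (severity_ramp < 0) abort("`severity_ramp` must be non-negative")
  structure(
    list(
      wavelengths = wavelengths,
      vis_level = vis_level, nir_plateau = nir_plateau,
      red_edge_nm = red_edge_nm, red_edge_steepness = red_edge_steepness,
      features = tibble::as_tibble(features),
      stress_features = stress_features,
      stress_onset_day = as.integer(stress_onset_day),
      severity_ramp = severity_ramp,
      illumination_drift = illumination_drift,
      noise_sd_vis = noise_sd_vis,
      nir_noise_ratio = nir_noise_ratio,
      nir_noise_cutoff = nir_noise_cutoff,
      psi_onset_day = as.integer(psi_onset_day)
    ),
    class = "spectral_scenario"
  )
}

#' @rdname spectral_scenario
#' @export
default_features <- function() {
  tibble::tribble(
    ~center, ~width, ~depth,
    445,     25,     0.06,   # chlorophyll/carotenoid blue absorption
    550,     30,     0.02,   # shallow green well (flattens the green peak)
    680,     22,     0.08,   # chlorophyll red absorption
    970,     30,     0.05    # leaf water O-H band
  )
}

#' @export
print.spectral_scenario <- function(x, ...) {
  cat(sprintf(
    "<spectral_scenario> %d bands %.0f-%.0f nm, onset day %d, ramp %.2f/day\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$stress_onset_day, x$severity_ramp
  ))
  invisible(x)
}

severity_at <- function(scenario, day_index, stressed) {
  if (!stressed || day_index < scenario$stress_onset_day) return(0)
  scenario$severity_ramp * (day_index - scenario$stress_onset_day + 1)
}

# Noise-free expected reflectance for one plant-day (before illumination).
clean_spectrum <- function(scenario, severity = 0) {
  wl <- scenario$wavelengths
  base <- scenario$vis_level +
    (scenario$nir_plateau - scenario$vis_level) *
      stats::plogis((wl - scenario$red_edge_nm) / scenario$red_edge_steepness)
  wells <- rep(0, length(wl))
  for (i in seq_len(nrow(scenario$features))) {
    f <- scenario$features[i, ]
    depth <- f$depth
    if (severity > 0 && f$center %in% scenario$stress_features) {
      depth <- depth * (1 + severity)
    }
    wells <- wells + depth * exp(-(wl - f$center)^2 / (2 * f$width^2))
  }
  pmax(base - wells, 0)
}

noise_sd_vector <- function(scenario) {
  ifelse(scenario$wavelengths >= scenario$nir_noise_cutoff,
         scenario$noise_sd_vis * scenario$nir_noise_ratio,
         scenario$noise_sd_vis)
}

#' Generate a full synthetic monitoring trial
#'
#' Draws one spectrum per (plant, day, pixel) from the scenario's generating
#' model, a stem-water-potential record per plant and day, and the ground-truth
#' stress-onset map. Control plants are stationary up to illumination drift and
#' noise; stressed plants' absorption features deepen monotonically from the
#' onset day. All randomness derives from `design$seed` via named substreams,
#' so reruns with the same design and scenario are identical.
#'
#' @param design A [trial_design()].
#' @param scenario A [spectral_scenario()].
#' @param noise If `FALSE`, sensor noise and illumination drift are switched
#'   off (useful for asserting the noise-free structure).
#' @return A list with elements `spectra` (tibble: plant_id, group, day,
#'   day_label, pixel_id, then one `wl_*` column per band), `psi` (tibble:
#'   plant_id, group, day, day_label, psi_mpa), and `truth` (tibble: plant_id,
#'   group, onset_day — `NA` for controls).
#' @examples
#' trial <- generate_trial(trial_design(n_plants = 2, days = 1:3,
#'                                      pixels_per_plant_day = 4),
#'                         spectral_scenario())
#' dim(trial$spectra)
#' @export
generate_trial <- function(design, scenario, noise = TRUE) {
  stopifnot(inherits(design, "trial_design"), inherits(scenario, "spectral_scenario"))
  wl <- scenario$wavelengths
  n_bands <- length(wl)
  npx <- design$pixels_per_plant_day
  sdv <- noise_sd_vector(scenario)

  illum <- with_substream(design$seed, "illumination", {
    if (noise) runif(design$n_days, 1 - scenario$illumination_drift,
                     1 + scenario$illumination_drift) else rep(1, design$n_days)
  })

  rows <- with_substream(design$seed, "spectra", {
    purrr::map(seq_len(design$n_plants), function(p) {
      pid <- design$plant_ids[p]
      stressed <- design$group_of_plant[[pid]] == "stress"
      purrr::map(seq_len(design$n_days), function(d) {
        mu <- clean_spectrum(scenario, severity_at(scenario, d, stressed))
        eps <- if (noise) {
          matrix(rnorm(npx * n_bands, sd = rep(sdv, each = npx)), npx, n_bands)
        } else {
          matrix(0, npx, n_bands)
        }
        spec <- illum[d] * (matrix(mu, npx, n_bands, byrow = TRUE) + eps)
        tib <- tibble::tibble(
          plant_id = pid,
          group = unname(design$group_of_plant[[pid]]),
          day = d,
          day_label = design$days[d],
          pixel_id = seq_len(npx)
        )
        set_spectrum_matrix(
          dplyr::bind_cols(tib, tibble::as_tibble(
            matrix(0, npx, n_bands, dimnames = list(NULL, wl_colnames(wl)))
          )),
          spec
        )
      })
    })
  })
  spectra <- dplyr::bind_rows(purrr::flatten(rows))

  psi <- simulate_stem_potential(design, scenario)

  truth <- tibble::tibble(
    plant_id = design$plant_ids,
    group = unname(design$group_of_plant[design$plant_ids]),
    onset_day = ifelse(group_is_stress(design), scenario$stress_onset_day, NA_integer_)
  )
  list(spectra = spectra, psi = psi, truth = truth)
}

group_is_stress <- function(design) {
  unname(design$group_of_plant[design$plant_ids]) == "stress"
}

#' Simulate per-plant stem water potential trajectories
#'
#' Control vines fluctuate around a mild baseline (about -0.55 MPa); a shared
#' day effect moves both groups together (weather). Stressed vines track the
#' controls until the potential onset day, then drop by a treatment offset that
#' grows linearly per day, capped near the moderate-stress floor of -0.95 MPa.
#' Magnitudes follow the reference-table scale of the emulated campaigns.
#'
#' @inheritParams generate_trial
#' @param control_mean,control_sd Control-group mean and within-group sd (MPa).
#' @param stress_sd Stress-group within-group sd (MPa).
#' @param day_effect_sd Sd of the shared day-to-day effect (MPa).
#' @param stress_offset0 Group separation (MPa) on the potential onset day.
#' @param stress_offset_slope Additional separation per day after onset (MPa).
#' @return Tibble: plant_id, group, day, day_label, psi_mpa (all negative).
#' @export
simulate_stem_potential <- function(design, scenario,
                                    control_mean = -0.55, control_sd = 0.05,
                                    stress_sd = 0.08, day_effect_sd = 0.06,
                                    stress_offset0 = 0.25,
                                    stress_offset_slope = 0.07) {
  with_substream(design$seed, "potentials", {
    day_eff <- rnorm(design$n_days, 0, day_effect_sd)
    onset <- scenario$psi_onset_day
    purrr::map_dfr(seq_len(design$n_days), function(d) {
      stress_drop <- if (d >= onset) stress_offset0 + stress_offset_slope * (d - onset) else 0
      mu <- ifelse(group_is_stress(design),
                   control_mean + day_eff[d] - stress_drop,
                   control_mean + day_eff[d])
      sdv <- ifelse(group_is_stress(design) & d >= onset, stress_sd, control_sd)
      psi <- pmin(rnorm(design$n_plants, mu, sdv), -0.05)
      psi <- pmax(psi, -0.95 - 0.05 * abs(rnorm(design$n_plants, 0, 1)))
      tibble::tibble(
        plant_id = design$plant_ids,
        group = unname(design$group_of_plant[design$plant_ids]),
        day = d, day_label = design$days[d],
        psi_mpa = psi
      )
    })
  })
}

#' Generate a synthetic hyperspectral cube for one plant-day
#'
#' Vegetation pixels inside the leaf mask follow the scenario's generating
#' model; background pixels follow a flat soil-like continuum. Returns the raw
#' sensor-scale cube together with its dark and white reference spectra and
#' the mask, so the reflectance-calibration path can be exercised end to end
#' (`(raw - dark) / (white - dark)` recovers the reflectance).
#'
#' @inheritParams generate_trial
#' @param plant_id,day Plant id and day index within the design.
#' @param nrow,ncol Spatial size (the emulated camera is 512 x 512; tests use
#'   smaller scenes).
#' @param mask Optional logical matrix (`nrow` x `ncol`, TRUE = leaf); default
#'   is a centred disc covering roughly a third of the scene.
#' @param white_level Sensor-scale signal of the white reference.
#' @param dark_level Mean dark signal.
#' @return List with `cube` (a [hyper_cube()]), `mask`, `dark`, `white`
#'   (per-band reference spectra), and `reflectance` (the noise-free leaf
#'   reflectance used, for ground truth).
#' @export
generate_cube <- function(design, scenario, plant_id, day,
                          nrow = 64, ncol = 64,
                          mask = NULL, white_level = 4000, dark_level = 80) {
  stopifnot(inherits(design, "trial_design"), inherits(scenario, "spectral_scenario"))
  if (!plant_id %in% design$plant_ids) {
    abort(sprintf("unknown plant id '%s'", plant_id))
  }
  if (!day %in% seq_len(design$n_days)) abort(sprintf("unknown day %s", day))
  wl <- scenario$wavelengths
  n_bands <- length(wl)
  if (is.null(mask)) {
    rr <- outer(seq_len(nrow) - (nrow + 1) / 2, rep(1, ncol))
    cc <- outer(rep(1, nrow), seq_len(ncol) - (ncol + 1) / 2)
    mask <- sqrt(rr^2 + cc^2) <= min(nrow, ncol) / 3
  }
  stopifnot(is.matrix(mask), nrow(mask) == nrow, ncol(mask) == ncol)
  if (!any(mask)) abort("mask contains no vegetation pixels")

  stressed <- design$group_of_plant[[plant_id]] == "stress"
  leaf_refl <- clean_spectrum(scenario, severity_at(scenario, day, stressed))
  soil_refl <- 0.18 + 0.12 * (wl - min(wl)) / diff(range(wl)) # dull rising soil line

  with_substream(design$seed, paste("cube", plant_id, day), {
    dark <- dark_level + abs(rnorm(n_bands, 0, 2))
    white <- white_level * (0.95 + 0.1 * stats::dbeta((wl - 380) / 700, 2, 2) / 1.5) + dark
    sdv <- noise_sd_vector(scenario)
    arr <- array(0, dim = c(nrow, ncol, n_bands))
    n_px <- nrow * ncol
    refl <- matrix(rep(soil_refl, each = n_px), n_px, n_bands)
    leaf_idx <- which(as.vector(mask))
    refl[leaf_idx, ] <- matrix(rep(leaf_refl, each = length(leaf_idx)),
                               length(leaf_idx), n_bands)
    refl <- refl + matrix(rnorm(n_px * n_bands, sd = rep(sdv, each = n_px)),
                          n_px, n_bands)
    raw <- sweep(sweep(refl, 2, white - dark, `*`), 2, dark, `+`)
    arr[] <- raw
    cube <- hyper_cube(arr, wl, meta = list(plant_id = plant_id, day = day,
                                            year_label = design$year_label))
    list(cube = cube, mask = mask, dark = dark, white = white,
         reflectance = leaf_refl)
  })
}

#' Daily irrigation dose
#'
#' Converts an irrigation schedule (minutes per day at an emitter flow rate)
#' into litres per day, optionally scaled by a reduced-dose fraction, rounded
#' half-up to 2 decimals for reporting.
#'
#' @param minutes_per_day Minutes of irrigation per day.
#' @param rate_l_per_h Emitter rate, litres per hour.
#' @param fraction Dose fraction in `[0, 1]` (1 = full dose).
#' @return Litres per day (2 decimals).
#' @examples
#' irrigation_dose(28, 2.3)       # 1.07 L/day
#' irrigation_dose(28, 2.3, 1/3)  # reduced dose
#' @export
irrigation_dose <- function(minutes_per_day, rate_l_per_h, fraction = 1) {
  if (minutes_per_day < 0 || rate_l_per_h < 0 || fraction < 0) {
    abort("irrigation inputs must be non-negative")
  }
  if (fraction > 1) abort("`fraction` must be <= 1")
  round_half_up(minutes_per_day / 60 * rate_l_per_h * fraction, 2)
}

#' Write / read the spectrum-table CSV interchange format
#'
#' Columns: plant_id, group, day, day_label, pixel_id, then one `wl_*` column
#' per wavelength.
#'
#' @param tbl Spectrum table.
#' @param path File path.
#' @return `read_spectrum_csv` returns the tibble; `write_spectrum_csv`
#'   returns `path` invisibly.
#' @export
write_spectrum_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
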