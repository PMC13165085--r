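#' Per-group change-day summaries
#'
#' Arithmetic mean and sample standard deviation of the assigned change days
#' per treatment group. Display columns are rounded half-up to two decimals;
#' the unrounded values are kept alongside. A single-plant group has an
#' undefined sd, reported as 0 with `sd_undefined = TRUE`.
#'
#' @param change_days Tibble with columns `plant_id`, `group`, `change_day`
#'   (and optionally `defaulted`), or a [monitor_trial()] result.
#' @return Tibble, one row per group: `group`, `n_plants`, `mean_change_day`,
#'   `sd_change_day` (2-decimal display values), `mean_raw`, `sd_raw`,
#'   `sd_undefined`.
#' @examples
#' summarize_groups(tibble::tibble(
#'   plant_id = paste0("P", 1:8), group = "control",
#'   change_day = c(5, 5, 5, 5, 5, 5, 4, 3)
#' ))
#' @export
summarize_groups <- function(change_days) {
  if (inherits(change_days, "trial_monitor")) change_days <- change_days$change_days
  stopifnot(all(c("plant_id", "group", "change_day") %in% names(change_days)))
  change_days |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_plants = dplyr::n(),
      mean_raw = mean(.data$change_day),
      sd_raw = if (dplyr::n() > 1) sd(.data$change_day) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sd_undefined = is.na(.data$sd_raw),
      mean_change_day = round_half_up(.data$mean_raw, 2),
      sd_change_day = round_half_up(dplyr::coalesce(.data$sd_raw, 0), 2)
    ) |>
    dplyr::select("group", "n_plants", "mean_change_day", "sd_change_day",
                  "mean_raw", "sd_raw", "sd_undefined")
}

validate_trial_config <- function(config) {
  required <- c("seed", "design", "scenario")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(paste("config is missing:", paste(missing, collapse = ", ")))
  }
  d <- config$design
  if (!is.null(d$groups) && !is.null(d$n_plants) &&
        length(d$groups) != d$n_plants) {
    abort("config design: `groups` length must equal `n_plants`")
  }
  if (!is.null(config$group_overrides)) {
    ids <- names(config$group_overrides)
    n <- d$n_plants %||% 18
    valid <- sprintf("P%02d", seq_len(n))
    bad <- setdiff(ids, valid)
    if (length(bad) > 0) {
      abort(sprintf("config names unknown plant id(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  invisible(config)
}

config_to_objects <- function(config) {
  d_args <- config$design %||% list()
  design <- do.call(trial_design, c(d_args, list(seed = config$seed)))
  if (!is.null(config$group_overrides)) {
    for (pid in names(config$group_overrides)) {
      design$group_of_plant[[pid]] <- config$group_overrides[[pid]]
    }
  }
  s_args <- config$scenario %||% list()
  if (!is.null(s_args$features)) s_args$features <- tibble::as_tibble(s_args$features)
  scenario <- do.call(spectral_scenario, s_args)
  list(design = design, scenario = scenario)
}

#' Run a full synthetic monitoring trial from a config
#'
#' Orchestrates the pipeline end to end: generate the trial (spectra, stem
#' potentials, ground truth), trim the noisy band tail, monitor every plant
#' for its change day, summarize groups, extract PC1 wavelength importance,
#' and compute the stem-potential reference table. Writes a deterministic
#' artifact directory (CSV/JSON plus a run log); a rerun with the same config
#' produces identical numeric outputs.
#'
#' @param config A config list, or a path to a YAML/JSON file with fields
#'   `seed`, `design` (arguments to [trial_design()]), `scenario` (arguments
#'   to [spectral_scenario()]), and optionally `trim_nm` (band cutoff,
#'   default 926), `k`, `alpha`, `group_overrides` (named plant-id ->
#'   group map).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all computed objects (`monitor`, `summary`,
#'   `loadings`, `refstats`, `truth`, paths).
#' @export
run_trial <- function(config, out_dir = tempfile("vinestress_run_")) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  validate_trial_config(config)
  obj <- config_to_objects(config)
  design <- obj$design
  scenario <- obj$scenario
  trim_nm <- config$trim_nm %||% 926
  k <- config$k %||% 3
  alpha <- config$alpha %||% 0.01

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- generate_trial(design, scenario)
  spectra <- trim_bands(trial$spectra, trim_nm)
  monitor <- monitor_trial(spectra, k = k, alpha = alpha)
  summary <- summarize_groups(monitor)
  loadings <- purrr::map_dfr(names(monitor$reports), function(p) {
    m <- monitor$reports[[p]]$model
    tibble::tibble(plant_id = p, wavelength = m$wavelengths,
                   pc1_loading = m$loadings[, 1])
  })
  # the per-day ANOVA needs >= 2 plants per treatment group
  group_n <- table(design$group_of_plant)
  refstats <- if (length(group_n) >= 2 && all(group_n >= 2)) {
    psi_reference_table(trial$psi, alpha = alpha,
                        seed = substream_seed(design$seed, "refstats"))
  } else {
    tibble::tibble(day = integer(), group = character(), mean_mpa = double(),
                   sd_mpa = double(), n = integer(), ks_p = double(),
                   log_transformed = logical(), f_statistic = double(),
                   p_value = double(), significant = logical(),
                   letters = character())
  }
  tests <- purrr::map_dfr(monitor$reports, function(r) {
    dplyr::mutate(r$tests, plant_id = r$plant_id, .before = 1)
  })

  write_spectrum_csv(spectra, file.path(out_dir, "spectra.csv"))
  readr::write_csv(tests, file.path(out_dir, "md2_tests.csv"))
  readr::write_csv(monitor$change_days, file.path(out_dir, "change_days.csv"))
  readr::write_csv(summary, file.path(out_dir, "group_summary.csv"))
  readr::write_csv(loadings, file.path(out_dir, "loadings.csv"))
  readr::write_csv(refstats, file.path(out_dir, "refstats.csv"))
  jsonlite::write_json(trial$truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("vinestress %s", as.character(utils::packageVersion("vinestress"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("root seed: %d", design$seed),
    sprintf("substreams: spectra=%d illumination=%d potentials=%d refstats=%d",
            substream_seed(design$seed, "spectra"),
            substream_seed(design$seed, "illumination"),
            substream_seed(design$seed, "potentials"),
            substream_seed(design$seed, "refstats")),
    sprintf("trim cutoff: %g nm; k = %g; alpha = %g", trim_nm, k, alpha),
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), file.path(out_dir, "run_log.txt"))

  invisible(list(monitor = monitor, summary = summary, loadings = loadings,
                 refstats = refstats, truth = trial$truth, psi = trial$psi,
                 out_dir = out_dir))
}
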