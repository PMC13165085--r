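#' Lilliefors (Kolmogorov-Smirnov) normality check
#'
#' One-sample KS statistic against a normal distribution with mean and sd
#' estimated from the data (the Lilliefors variant, appropriate when the
#' hypothesized parameters are not known a priori). The p-value comes from a
#' seeded Monte-Carlo null simulation, so it is reproducible and valid at any
#' sample size.
#'
#' @param values Numeric sample, n >= 5.
#' @param n_sim Monte-Carlo replicates (default 10000).
#' @param seed Seed for the null simulation.
#' @return Tibble with `statistic` (D), `p_value`, `n`, `method`.
#' @export
normality_check <- function(values, n_sim = 10000, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5) abort("normality check needs n >= 5")
  if (sd(values) == 0) abort("constant sample: normality check undefined")
  d_obs <- lilliefors_d(values)
  d_null <- with_substream(seed, "lilliefors-null", {
    vapply(seq_len(n_sim), function(i) lilliefors_d(rnorm(n)), numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_sim + 1)
  tibble::tibble(statistic = d_obs, p_value = p, n = n,
                 method = "Lilliefors KS (Monte-Carlo p)")
}

# KS sup-distance between the empirical CDF and the fitted normal.
lilliefors_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Log transform of stem water potential
#'
#' Stem water potential is strictly negative (a tension); the transform is the
#' natural log of its magnitude, `log(|psi|)`. Order is reversed on the MPa
#' scale: more negative potentials (more stress) map to larger values.
#'
#' @param psi Numeric vector of potentials in MPa, all `< 0`.
#' @return `log(abs(psi))`.
#' @examples
#' log_transform_psi(c(-1, -exp(1)))
#' @export
log_transform_psi <- function(psi) {
  if (any(psi >= 0)) abort("stem water potential must be strictly negative (MPa)")
  log(abs(psi))
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects ANOVA (F statistic and p from the F
#' distribution), on a value ~ group table.
#'
#' @param data Data frame with the response and grouping columns.
#' @param value,group Column names (strings) of the response and the group
#'   factor.
#' @return Tibble: `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
oneway_anova <- function(data, value = "value", group = "group") {
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("every group needs n >= 2")
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  tibble::tibble(
    f_statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2]
  )
}

#' Duncan's multiple range test
#'
#' Post hoc multiple comparison after ANOVA. Group means are sorted; the range
#' of every subset of p adjacent means is compared against the least
#' significant range `R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h)`, where
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` is Duncan's step-dependent protection
#' level, q the studentized-range quantile and `n_h` the harmonic mean group
#' size. Letters are assigned by standard range-merging: groups sharing a
#' letter are not significantly different.
#'
#' @inheritParams oneway_anova
#' @param alpha Significance level (default 0.05; the reference analysis uses
#'   0.01).
#' @return Tibble: `group`, `n`, `mean`, `letters`, ordered by decreasing
#'   mean.
#' @export
duncan_posthoc <- function(data, value = "value", group = "group",
                           alpha = 0.05) {
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2) abort("need at least two groups")
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  df_w <- length(y) - nlevels(g)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_w
  n_h <- nlevels(g) / sum(1 / ns)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  kk <- length(m)
  se <- sqrt(mse / n_h)

  crit_range <- function(p) {
    if (se == 0) return(0)
    stats::qtukey((1 - alpha)^(p - 1), p, df_w, lower.tail = TRUE) * se
  }
  # nonsignificant[i, j]: means i..j (sorted) are NOT separated by Duncan's rule
  nonsig <- matrix(FALSE, kk, kk)
  for (i in seq_len(kk)) {
    for (j in i:kk) {
      p <- j - i + 1
      nonsig[i, j] <- if (p == 1) TRUE else (m[i] - m[j]) < crit_range(p)
    }
  }
  # protection: a subrange inside a nonsignificant range is also nonsignificant
  for (len in (kk - 1):1) {
    if (len < 1) break
    for (i in seq_len(kk - len + 1)) {
      j <- i + len - 1
      if (i > 1 && nonsig[i - 1, j]) nonsig[i, j] <- TRUE
      if (j < kk && nonsig[i, j + 1]) nonsig[i, j] <- TRUE
    }
  }
  # letters: maximal nonsignificant runs get one letter each
  runs <- list()
  for (i in seq_len(kk)) {
    j <- max(which(nonsig[i, i:kk])) + i - 1
    runs[[length(runs) + 1]] <- c(i, j)
  }
  runs <- unique(runs)
  keep <- vapply(runs, function(r) {
    !any(vapply(runs, function(s) (s[1] <= r[1] && r[2] <= s[2]) &&
                  !identical(s, r), logical(1)))
  }, logical(1))
  runs <- runs[keep]
  letters_sorted <- rep("", kk)
  for (li in seq_along(runs)) {
    r <- runs[[li]]
    idx <- r[1]:r[2]
    letters_sorted[idx] <- paste0(letters_sorted[idx], letters[li])
  }
  tibble::tibble(
    group = names(m),
    n = as.integer(ns[ord]),
    mean = as.numeric(m),
    letters = letters_sorted
  )
}

#' Reference table for per-day stem-water-potential comparisons
#'
#' Reproduces the reference-analysis workflow per acquisition day: screen the
#' day's pooled values for normality (Lilliefors KS); if normality is rejected
#' at `alpha_normality`, analyse the log-transformed magnitudes; then a
#' one-way ANOVA between treatment groups and Duncan's post hoc letters.
#' Group means and sds are reported on the raw MPa scale.
#'
#' @param psi_tbl Tibble with columns `plant_id`, `group`, `day`, `psi_mpa`
#'   (and optionally `day_label`).
#' @param alpha Significance level for the ANOVA flag (default 0.01, a 99%
#'   confidence level).
#' @param alpha_normality Level for the normality screen (default 0.05).
#' @param n_sim,seed Monte-Carlo settings for the normality p-value.
#' @return Tibble, one row per day x group: day, group, mean_mpa, sd_mpa, n,
#'   plus per-day columns ks_p, log_transformed, f_statistic, p_value,
#'   significant, letters.
#' @export
psi_reference_table <- function(psi_tbl, alpha = 0.01, alpha_normality = 0.05,
                                n_sim = 10000, seed = 1L) {
  stopifnot(all(c("plant_id", "group", "day", "psi_mpa") %in% names(psi_tbl)))
  if (any(psi_tbl$psi_mpa >= 0)) abort("psi_mpa must be strictly negative")
  purrr::map_dfr(sort(unique(psi_tbl$day)), function(d) {
    dd <- dplyr::filter(psi_tbl, .data$day == d)
    # the normality screen needs a workable sample; tiny days skip it
    if (nrow(dd) >= 5) {
      ks <- normality_check(dd$psi_mpa, n_sim = n_sim,
                            seed = substream_seed(seed, paste("ks", d)))
      ks_p <- ks$p_value
      transform <- ks_p < alpha_normality
    } else {
      ks_p <- NA_real_
      transform <- FALSE
    }
    dd$value <- if (transform) log_transform_psi(dd$psi_mpa) else dd$psi_mpa
    an <- oneway_anova(dd, "value", "group")
    letters <- duncan_posthoc(dd, "value", "group", alpha = alpha)
    summ <- dd |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean_mpa = mean(.data$psi_mpa),
                       sd_mpa = sd(.data$psi_mpa),
                       n = dplyr::n(), .groups = "drop")
    summ |>
      dplyr::mutate(
        day = d,
        ks_p = ks_p,
        log_transformed = transform,
        f_statistic = an$f_statistic,
        p_value = an$p_value,
        significant = an$p_value < alpha,
        letters = letters$letters[match(.data$group, letters$group)]
      ) |>
      dplyr::select("day", dplyr::everything())
  })
}
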