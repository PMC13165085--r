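test_that("PCA recovers closed-form structure", {
  # rank-1 noise-free data: PC1 explains everything
  v <- rnorm(12)
  x <- outer(c(-2, -1, 0.5, 1, 1.5), v)
  m <- fit_plant_pca(x, k = 1)
  expect_equal(m$explained[1], 1, tolerance = 1e-12)

  # two points at (+-2, 0) rotated 45 degrees: PC1 direction (1,1)/sqrt(2)
  pts <- rbind(c(2, 0), c(-2, 0)) %*% t(matrix(c(cos(pi / 4), sin(pi / 4),
                                                 -sin(pi / 4), cos(pi / 4)), 2, 2))
  m2 <- fit_plant_pca(pts, k = 1)
  expect_equal(abs(as.vector(m2$loadings)), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  # sign convention makes the largest element positive
  expect_gt(max(m2$loadings), 0)
})

test_that("loadings are orthonormal, fractions ordered, reconstruction complete", {
  set.seed(21)
  x <- mean_center(matrix(rnorm(30 * 8), 30, 8))
  m <- fit_plant_pca(x, k = 8)
  expect_equal(crossprod(m$loadings), diag(8), tolerance = 1e-8)
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_true(all(m$explained >= 0 & m$explained <= 1))
  expect_equal(sum(m$explained), 1, tolerance = 1e-12)
  # full-rank reconstruction
  expect_equal(m$scores %*% t(m$loadings), x, tolerance = 1e-8)
  expect_error(fit_plant_pca(x[1:3, ], k = 5), "rank|components")
})

test_that("var95 retention rule picks the smallest sufficient k", {
  set.seed(3)
  u <- svd(matrix(rnorm(100), 20, 5))$u[, 1:3]
  x <- u %*% diag(c(10, 5, 1)) %*% t(svd(matrix(rnorm(25), 5, 5))$v[, 1:3])
  m <- fit_plant_pca(x, k = "var95")
  cum <- cumsum(svd(x)$d^2 / sum(svd(x)$d^2))
  expect_identical(m$k, as.integer(which(cum >= 0.95)[1]))
})

test_that("baseline centroid and covariance match hand-computed values", {
  scores <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  fake <- structure(list(scores = scores, k = 2), class = "plant_pca")
  b <- build_baseline(fake, 1:4)
  expect_equal(unname(b$centroid), c(1, 1))
  # sample covariance of {(0,0),(2,0),(0,2),(2,2)}: diag(4/3, 4/3)
  expect_equal(unname(b$sigma), diag(4 / 3, 2), tolerance = 1e-12)

  fake_eq <- structure(list(scores = matrix(1, 5, 2), k = 2), class = "plant_pca")
  expect_error(build_baseline(fake_eq, 1:5), "degenerate")
  expect_error(build_baseline(fake, 1:3), "baseline rows")
})

test_that("MD^2 matches the Euclidean special case and the zero case", {
  set.seed(30)
  scores <- matrix(rnorm(40), 20, 2)
  fake <- structure(list(scores = scores, k = 2), class = "plant_pca")
  b <- build_baseline(fake, 1:20)
  expect_equal(unname(mahalanobis_md2(b$centroid, b)), 0, tolerance = 1e-12)

  # identity covariance: MD^2 is squared Euclidean distance
  b_id <- b
  b_id$sigma <- diag(2)
  b_id$chol <- chol(diag(2))
  expect_equal(unname(mahalanobis_md2(b_id$centroid + c(3, 4), b_id)), 25)

  # cross-check against the stats implementation
  expect_equal(
    unname(mahalanobis_md2(scores, b)),
    unname(stats::mahalanobis(scores, b$centroid, b$sigma)),
    tolerance = 1e-10
  )
})

test_that("sum of in-sample baseline MD^2 equals (n-1) k", {
  set.seed(31)
  for (n in c(10, 50)) {
    for (k in c(2, 3)) {
      scores <- matrix(rnorm(n * k), n, k)
      fake <- structure(list(scores = scores, k = k), class = "plant_pca")
      b <- build_baseline(fake, seq_len(n))
      expect_equal(sum(mahalanobis_md2(scores, b)), (n - 1) * k, tolerance = 1e-8)
      # equivalently the mean is k (n-1) / n
      expect_equal(mean(mahalanobis_md2(scores, b)), k * (n - 1) / n,
                   tolerance = 1e-8)
    }
  }
})

test_that("MD^2 is invariant under invertible linear re-parameterization", {
  set.seed(32)
  scores <- matrix(rnorm(60), 20, 3)
  fake <- structure(list(scores = scores, k = 3), class = "plant_pca")
  b <- build_baseline(fake, 1:12)
  a <- matrix(rnorm(9), 3, 3) + diag(3) * 2 # well-conditioned invertible map
  scores_t <- scores %*% t(a)
  fake_t <- structure(list(scores = scores_t, k = 3), class = "plant_pca")
  b_t <- build_baseline(fake_t, 1:12)
  expect_equal(mahalanobis_md2(scores, b), mahalanobis_md2(scores_t, b_t),
               tolerance = 1e-6)
})

test_that("change-day assignment follows the earliest-crossing rule and defaults", {
  set.seed(33)
  base <- rgamma(10, 2)
  md2 <- tibble::tibble(
    day = rep(1:4, each = 10),
    md2 = c(base, base + 0.01 * rnorm(10), rgamma(10, 2) + 30, rgamma(10, 2) + 60)
  )
  rep <- detect_change_day(md2, alpha = 0.01)
  expect_equal(rep$change_day, 3)
  expect_false(rep$defaulted)

  # comparing day 1 with itself: never significant
  same <- tibble::tibble(day = rep(1:2, each = 10), md2 = rep(base, 2))
  rep2 <- detect_change_day(same, alpha = 0.01)
  expect_gt(rep2$tests$p_value[2], 0.9)
  expect_true(rep2$defaulted)
  expect_equal(rep2$change_day, 2)

  expect_error(detect_change_day(tibble::tibble(day = 1, md2 = 1:5)), "two days")
  expect_error(detect_change_day(tibble::tibble(day = c(1, 1, 2), md2 = c(1, 2, 3))),
               "at least two MD")
})

test_that("an injected large shift from day 3 is assigned to day 3", {
  # full pipeline, strong effect, a handful of seeds
  hits <- vapply(1:8, function(s) {
    d <- trial_design(n_plants = 1, n_stress = 1, days = 1:5,
                      pixels_per_plant_day = 10, seed = s)
    tr <- generate_trial(d, coarse_scenario(60, stress_onset_day = 3,
                                            severity_ramp = 0.8))
    monitor_plant(tr$spectra)$change_day == 3
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("wavelength importance reports the perturbed band and trivial cases", {
  # single nonzero loading element -> that band is the sole range
  load <- matrix(0, 20, 1)
  load[13, 1] <- 1
  fake <- structure(list(loadings = load, k = 1,
                         wavelengths = seq(400, 1000, length.out = 20)),
                    class = "plant_pca")
  imp <- wavelength_importance(fake, threshold_quantile = 0.9)
  expect_identical(nrow(imp), 1L)
  expect_equal(imp$wl_peak, seq(400, 1000, length.out = 20)[13])

  # water-band-only stress: top range contains 970 nm
  d <- trial_design(n_plants = 1, n_stress = 1, days = 1:5,
                    pixels_per_plant_day = 10, seed = 44)
  tr <- generate_trial(d, spectral_scenario(stress_features = 970))
  r <- monitor_plant(trim_bands(tr$spectra, 980))
  imp2 <- wavelength_importance(r$model)
  expect_lte(imp2$wl_min[1], 970)
  expect_gte(imp2$wl_max[1], 970)
})

test_that("white-noise-only loadings show no persistent dominant range", {
  # homoscedastic pure-noise spectra: the top-range peak wanders across seeds
  peaks <- vapply(1:12, function(s) {
    set.seed(s)
    x <- mean_center(matrix(rnorm(50 * 60), 50, 60))
    m <- fit_plant_pca(x, k = 3)
    m$wavelengths <- seq(400, 1000, length.out = 60)
    wavelength_importance(m)$wl_peak[1]
  }, numeric(1))
  expect_gt(diff(range(peaks)), 100) # no stable importance region
})

test_that("change-day group ordering is stable across k = 2, 3, 4", {
  d <- trial_design_2024(seed = 77)
  tr <- generate_trial(d, spectral_scenario())
  sp <- trim_bands(tr$spectra, 926)
  for (k in 2:4) {
    mon <- monitor_trial(sp, k = k)
    s <- summarize_groups(mon)
    expect_lt(s$mean_raw[s$group == "stress"], s$mean_raw[s$group == "control"])
  }
})
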