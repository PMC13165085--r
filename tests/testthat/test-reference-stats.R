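test_that("Lilliefors D matches the reference implementation exactly", {
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(20 + i, mean = i, sd = 1 + i / 5)
    expect_equal(normality_check(x, n_sim = 50)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("normality check holds its size on normal data and rejects uniform data", {
  set.seed(52)
  # type-I error near the nominal 5% level
  p <- vapply(1:200, function(i) {
    normality_check(rnorm(50), n_sim = 400, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.12)

  # power: uniform(0,1) at n = 200 rejected ~96% of the time (oracle rate);
  # bound set three binomial sds below that
  rej <- vapply(1:200, function(i) {
    normality_check(runif(200), n_sim = 400, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.92)

  # near-zero statistic when the sample sits on its fitted normal quantiles
  q <- qnorm((1:100 - 0.5) / 100)
  expect_lt(normality_check(q, n_sim = 50)$statistic, 0.01)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(rnorm(3)), "n >= 5")
})

test_that("log transform of psi is log|psi| and reverses order", {
  expect_equal(log_transform_psi(-1), 0)
  expect_equal(log_transform_psi(-exp(1)), 1)
  psi <- -c(0.3, 0.5, 0.9, 1.4)
  expect_equal(log_transform_psi(psi), log(abs(psi)))
  # more negative potential (more stress) -> larger transform
  expect_true(all(diff(log_transform_psi(sort(psi, decreasing = TRUE))) > 0))
  expect_error(log_transform_psi(c(-1, 0.2)), "negative")
})

test_that("one-way ANOVA matches the hand-computed oracle", {
  d <- data.frame(value = c(1, 2, 3, 4, 5, 6),
                  group = rep(c("a", "b"), each = 3))
  # oracle by definition: SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5 on 1 df;
  # SSW = 2 + 2 = 4 on 4 df; F = 13.5 / 1
  out <- oneway_anova(d)
  expect_equal(out$f_statistic, 13.5)
  expect_identical(c(out$df_between, out$df_within), c(1L, 4L))
  expect_equal(out$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  # identical group means: F = 0
  d0 <- data.frame(value = c(1, 3, 1, 3), group = rep(c("a", "b"), each = 2))
  expect_equal(oneway_anova(d0)$f_statistic, 0)

  # location invariance
  d2 <- d
  d2$value <- d2$value + 100
  expect_equal(oneway_anova(d2)$f_statistic, out$f_statistic)
  expect_error(oneway_anova(data.frame(value = 1:3, group = "a")), "two groups")
})

test_that("Duncan's test reduces to the pooled two-sample comparison for two groups", {
  set.seed(53)
  for (i in 1:25) {
    d <- data.frame(value = rnorm(16, mean = rep(c(0, runif(1, 0, 2)), each = 8)),
                    group = rep(c("a", "b"), each = 8))
    dl <- duncan_posthoc(d, alpha = 0.05)
    same_letter <- dl$letters[1] == dl$letters[2]
    # oracle: for p = 2 the protection level is alpha and the studentized
    # range on two means equals the pooled two-sample t comparison
    p_t <- stats::t.test(value ~ group, data = d, var.equal = TRUE)$p.value
    expect_identical(same_letter, p_t >= 0.05)
  }
})

test_that("Duncan letters separate well-split means and join equal ones", {
  set.seed(54)
  d3 <- data.frame(value = rnorm(30, mean = rep(c(0, 10, 20), each = 10), sd = 1),
                   group = rep(c("a", "b", "c"), each = 10))
  out <- duncan_posthoc(d3, alpha = 0.05)
  expect_identical(length(unique(out$letters)), 3L)

  deq <- data.frame(value = rep(c(1, 2, 1, 2), 2),
                    group = rep(c("a", "b"), each = 4))
  oeq <- duncan_posthoc(deq, alpha = 0.05)
  expect_identical(oeq$letters[1], oeq$letters[2])
})

test_that("Duncan groupings are invariant to relabeling and location shifts", {
  set.seed(55)
  d <- data.frame(value = rnorm(24, mean = rep(c(0, 1.5, 3), each = 8)),
                  group = rep(c("a", "b", "c"), each = 8))
  base <- duncan_posthoc(d, alpha = 0.05)
  shifted <- d
  shifted$value <- shifted$value + 42
  out_s <- duncan_posthoc(shifted, alpha = 0.05)
  expect_identical(base$letters, out_s$letters)
  relabeled <- d
  relabeled$group <- c(a = "z", b = "y", c = "x")[d$group]
  out_r <- duncan_posthoc(relabeled, alpha = 0.05)
  expect_identical(base$letters, out_r$letters) # same ordering by mean
})

test_that("the per-day reference table flips ns -> significant at the divergence day", {
  d <- trial_design(n_plants = 18, n_stress = 10, days = 1:5,
                    pixels_per_plant_day = 2, seed = 61)
  sc <- coarse_scenario(20, stress_onset_day = 3)
  psi <- simulate_stem_potential(d, sc)
  tab <- psi_reference_table(psi, alpha = 0.01, n_sim = 2000, seed = 5)
  per_day <- unique(tab[c("day", "significant")])
  expect_identical(per_day$significant, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # group means on the raw MPa scale, stressed lower after onset
  wide <- tidyr::pivot_wider(tab[c("day", "group", "mean_mpa")],
                             names_from = "group", values_from = "mean_mpa")
  expect_true(all(wide$stress[3:5] < wide$control[3:5]))
  expect_true(all(tab$mean_mpa < 0))
})
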