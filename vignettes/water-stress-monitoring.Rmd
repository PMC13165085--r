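---
title: "Monitoring grapevine water stress with per-plant PCA and Mahalanobis divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring grapevine water stress with per-plant PCA and Mahalanobis divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinestress)
```

## The problem and the model

A vine developing water deficit changes the composition of its leaves —
photosynthetic pigments degrade, nitrogen compounds accumulate, tissue water
content drops — and each of those changes has a spectral signature in the
400–1000 nm window: pigment absorptions near 445, 550 and 680 nm, the red
edge at 690–740 nm, and the O–H water band near 970 nm. The destructive
reference, stem water potential Ψ (xylem tension in MPa, more negative =
more stressed), only separates treatment groups once stress is well
established. The monitoring question is therefore: *for one vine observed
across days, what is the earliest day its spectra stop looking like day
one?*

Vines differ from each other (rootstock, vigor, architecture) far more than
one vine differs from itself day to day, so the analysis is strictly
per-plant. For each vine:

1. **Preprocessing.** Each pixel spectrum is SNV-transformed
   (`(x - mean(x)) / sd(x)`, sample sd), Savitzky–Golay smoothed
   (11 points, order 2, zeroth derivative), and the vine's full day-stacked
   matrix is mean-centered per band.
2. **Score space.** A PCA (SVD of the centered matrix) retains `k = 3`
   components. On vegetation spectra PC1 typically carries 60–95% of the
   variance and its loadings are directly interpretable per wavelength.
3. **Baseline.** Day one's scores define a centroid and a sample covariance
   `Sigma_REF` (n−1 denominator).
4. **Divergence.** Every pixel's squared Mahalanobis distance
   `MD^2 = (mu_t - mu_bar)' Sigma_REF^{-1} (mu_t - mu_bar)` measures how far
   it sits from the baseline cloud, in the baseline's own metric.
5. **Change day.** For each day after the first, the day's MD² values are
   compared with day one's reference values by a two-sample Mann–Whitney
   test at α = 0.01; the change day is the earliest significant day, and a
   vine with no significant day is assigned the last day by default.

```{r pipeline}
design   <- trial_design_2024(seed = 11)
scenario <- spectral_scenario()
trial    <- generate_trial(design, scenario)
monitor  <- monitor_trial(trim_bands(trial$spectra, 926))
summarize_groups(monitor)
```

## Why the day-one reference is computed leave-one-out

The baseline covariance is estimated from the same day-one points whose
MD² would naively serve as the reference distribution. In-sample MD² is
biased small — its values satisfy the exact identity
`sum(MD²) = (n − 1) k` — while points from later days are out-of-sample and
stochastically larger *even when nothing has changed* (with n = 10 baseline
pixels and k = 3 the null mean roughly doubles). Comparing the two directly
would flag changes on perfectly stable vines. `monitor_plant()` therefore
scores each day-one pixel against the centroid and covariance of the *other*
n − 1 pixels (leave-one-out), which makes day one exchangeable with null
later days. The LOO baselines have n − 1 rather than n points, which makes
the test slightly conservative — the right direction for a monitoring alarm.
The pure operations `build_baseline()` / `mahalanobis_md2()` keep the plain
in-sample semantics, and the `(n − 1) k` identity is asserted on them in the
test suite.

```{r identity}
set.seed(1)
scores <- matrix(rnorm(30), 10, 3)
fake <- structure(list(scores = scores, k = 3), class = "plant_pca")
b <- build_baseline(fake, 1:10)
sum(mahalanobis_md2(scores, b)) # = (10 - 1) * 3
```

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` (components) | 3 | – | PC1–PC3 carry essentially all structured variance on vegetation spectra; `"var95"` rule available. Group ordering of change days is stable for k = 2–4. |
| `alpha` | 0.01 | – | 99% confidence level, matching the reference Ψ analysis. |
| SG `window`, `polyorder` | 11, 2 | points, – | standard chemometric smoothing for ~3 nm sampling. |
| trim cutoff | 926 (2025-style), 980 (2024-style) | nm | the detector tail above ~925 nm oscillates; the 2024-style cutoff keeps the 920–970 nm water region. |
| centering scope | per plant, all days | – | the only scope under which day-one scores and later-day scores live in one space; per-day centering would remove exactly the between-day signal being monitored. |
| importance threshold | 0.8 quantile of abs(PC1 loading), 10 nm gap merge | – | reports a handful of contiguous ranges rather than single bands. |

No multiple-testing correction is applied across days: the earliest-crossing
rule mirrors how the monitor would run operationally. Its family-wise
false-alarm rate is a measured property instead — about `1 − 0.99⁴ ≈ 3.9%`
per vine over four test days, and the measured default-to-last-day rate on
null trials stays above 95%.

## The synthetic scene generator

No imagery ships with the package, so validation runs on a generator whose
defaults emulate the monitored pot trial:

- **Spectrum shape**: visible continuum (0.12) rising through a logistic red
  edge (inflection 715 nm, scale 14 nm) to a NIR plateau (0.48), minus
  Gaussian wells at 445/550/680/970 nm — reproducing the two-valley
  vegetation profile with few parameters.
- **Stress**: from a known onset day (default day 3) the pigment and water
  well depths scale by `1 + severity`, with severity ramping 0.5/day. The
  water-band deepening is monotone, which the tests assert on noise-free
  draws.
- **Nuisance structure**: a per-day multiplicative illumination factor
  (±5%), and additive noise with sd 0.004 below 900 nm and 5× that above —
  the noisy NIR detector tail. SNV provably removes the illumination factor.
- **Campaign designs**: `trial_design_2024()` (18 vines, 8 control / 10
  stress with irrigation withheld, 5 days, 10 manually-picked pixels — 900
  spectra) and `trial_design_2025()` (18 vines, 9/9 with a one-third dose,
  7 days, 100 random in-mask pixels — 12,600 spectra). The dose arithmetic
  is `irrigation_dose(28, 2.3, 1)` = 1.07 L/day.
- **Stem potential**: controls fluctuate around −0.55 MPa (within-group sd
  0.05, shared day effect sd 0.06); stressed vines drop by 0.25 MPa at the
  onset day, growing 0.07 MPa/day, with sd 0.08, capped near −0.95 MPa.
  These magnitudes were chosen once to match the reference-table scale of
  the emulated campaigns (group separation ~0.25 MPa with sds 0.03–0.09 at
  the first significant day). The generator treats Ψ and spectral severity
  as independently parameterized: no quantitative Ψ-to-reflectance coupling
  is claimed, only a shared onset clock.

All randomness flows from the design's root seed through named substreams
(spectra, illumination, potentials, pixel sampling), so every module is
independently reproducible.

What the generator does **not** emulate: radiative transfer (no leaf-optics
model), canopy geometry and view angles, leaf veins and specular patches,
weather. Passing recovery tests therefore show the *statistical machinery*
is sound — they do not certify performance on field imagery, where
between-day nuisance variation is richer than a scalar illumination factor.

## Numerical choices

- PCA via SVD with a deterministic sign convention (largest-magnitude
  loading element positive), so loadings are reproducible across platforms.
- `Sigma_REF` is ridge-regularized by `1e-8 · trace/k` on the diagonal only
  if its condition number exceeds 1e8; identical day-one scores are an
  error, not silently regularized.
- MD² uses a Cholesky solve, never an explicit inverse.
- Savitzky–Golay edges are handled by evaluating the first/last full
  window's polynomial fit at the edge positions (mirror-free); polynomials
  up to the filter order are reproduced exactly everywhere, and the five
  edge bands sit far from the diagnostic ranges.
- The Mann–Whitney test is used for the per-day comparison because MD² is
  strongly right-skewed; with 10 pixels per day the exact test's smallest
  achievable two-sided p (~1e-5) is well below α.
- The Lilliefors normality statistic is computed in-package and its p-value
  by seeded Monte-Carlo (default 10,000 null draws), valid at any n.
- Duncan's multiple range test uses `qtukey()` at confidence
  `(1 − α)^(p−1)` with the harmonic-mean group size, so arbitrary error df
  are supported without printed tables.
- Reported group means are rounded half-up (not half-to-even) to two
  decimals for display — `mean(c(5,5,5,5,5,5,4,3))` prints as 4.63 — with
  raw values preserved.

## Reference statistics

`psi_reference_table()` reproduces the Ψ workflow per day: Lilliefors screen
on the day's pooled values (skipped below n = 5), log transform of |Ψ| when
normality is rejected (Ψ is strictly negative, so the transform acts on the
magnitude and reverses order), one-way ANOVA between treatment groups, and
Duncan letters:

```{r refstats}
psi_reference_table(trial$psi, alpha = 0.01, n_sim = 2000, seed = 2)
```

On trials whose Ψ diverges mid-trial this flips from "ns" to significant at
the divergence day, while the spectral monitor above typically flags
stressed vines at least as early — the motivating observation for
spectral monitoring.

## Known limitations

- Change-day resolution is the acquisition schedule; a vine changing between
  visits is flagged at the next visit.
- The monitor detects *change*, not *stress*: any systematic spectral shift
  (disease, mechanical damage, sensor drift not removed by SNV) will be
  flagged. Attribution comes from the loadings ranges, not the alarm itself.
- With 10 pixels per day the rank test cannot reach significance below
  p ≈ 1e-5 and has limited power for subtle shifts; the 100-pixel design is
  preferable when masks are available.
- The last-day default makes "no change" and "change on the last day"
  indistinguishable in group means.
- Synthetic validation, as discussed, bounds what can be claimed for field
  data.
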