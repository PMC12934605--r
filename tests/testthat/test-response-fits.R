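# Boltzmann fitting, normalisation, per-patch and cohort tension curves.

test_that("Boltzmann fit recovers exact generating parameters and obeys
           the midpoint identity", {
  x <- seq(0.5, 6, by = 0.5)
  y <- 1 / (1 + exp(-2 * (x - 3)))
  fit <- fitBoltzmann(x, y)
  expect_equal(plateau(fit), 1, tolerance = 1e-8)
  expect_equal(slopeK(fit), 2, tolerance = 1e-8)
  expect_equal(halfMax(fit), 3, tolerance = 1e-8)

  # response at x50 equals A/2 for whatever parameters were fitted
  set.seed(2)
  y2 <- 80 / (1 + exp(-1.4 * (x - 2.5))) + rnorm(length(x), 0, 2)
  f2 <- fitBoltzmann(x, y2)
  at50 <- plateau(f2) / (1 + exp(-slopeK(f2) * (halfMax(f2) - halfMax(f2))))
  expect_equal(at50, plateau(f2) / 2)

  expect_error(fitBoltzmann(x, rep(1, length(x))), "equal")
})

test_that("17-point protocol recovery stays within 5% (X50) and 10% (k)
           under 5% noise", {
  x <- seq(0, 8, length.out = 17)
  errs <- t(vapply(1:100, function(s) {
    set.seed(s)
    y <- 1 / (1 + exp(-1.8 * (x - 3.2))) + rnorm(17, 0, 0.05)
    f <- fitBoltzmann(x, y)
    c(abs(halfMax(f) - 3.2) / 3.2, abs(slopeK(f) - 1.8) / 1.8)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("normalisation divides by the plateau and closes to A = 1", {
  fit <- fitBoltzmann(seq(0.5, 6, 0.5),
                      80 / (1 + exp(-2 * (seq(0.5, 6, 0.5) - 3))))
  expect_equal(normalizePeaks(80, fit), 1.0, tolerance = 1e-6)
  expect_equal(normalizePeaks(0, fit), 0.0)
  expect_equal(normalizePeaks(c(10, 40, 80), fit), c(0.125, 0.5, 1.0),
               tolerance = 1e-6)

  x <- seq(0.5, 6, 0.5)
  refit <- fitBoltzmann(x, normalizePeaks(80 / (1 + exp(-2 * (x - 3))),
                                          fit))
  expect_equal(plateau(refit), 1, tolerance = 0.02)
})

test_that("a noiseless synthetic patch is recovered essentially exactly
           and fitted k is always positive", {
  spec <- stretchCohortSpec(T50_mean = 2.0, T50_sd = 0, k_mean = 2.3,
                            k_sd = 0, A_sd = 0, radius_rel_noise = 0,
                            current_noise_sigma = 0, rundown_prob = 0,
                            tau_ms_sd = 0)
  g <- genStretchPatch(spec, 1)
  res <- patchTensionResponse(g$patch)
  expect_equal(halfMax(res$fit), 2.0, tolerance = 0.01)
  expect_equal(slopeK(res$fit), 2.3, tolerance = 0.01 * 2.3)
  expect_gt(slopeK(res$fit), 0)
  # estimated response non-decreasing in stimulus on noiseless data
  pts <- res$points[order(res$points$tension), ]
  expect_true(all(diff(pts$I_norm) > -1e-9))
})

test_that("exclusion bookkeeping accounts for every sweep", {
  spec <- stretchCohortSpec(n_patches = 6, rundown_prob = 0.5, seed = 21)
  for (g in genStretchCohort(spec)) {
    res <- tryCatch(patchTensionResponse(g$patch), error = function(e) NULL)
    if (is.null(res)) next
    # included + excluded-for-rundown + unjoined = total sweeps
    expect_equal(sum(res$points$included) + sum(res$points$rundown) +
                 res$excluded$noDome, res$excluded$total)
  }
})

test_that("low-amplitude cohorts are excluded wholesale by the 20 pA rule", {
  spec <- stretchCohortSpec(n_patches = 5, A_mean = 10, A_sd = 0,
                            current_noise_sigma = 0.5, seed = 3)
  res <- lapply(genStretchCohort(spec), function(g)
    tryCatch(patchTensionResponse(g$patch), error = function(e) NULL))
  expect_true(all(vapply(res, is.null, logical(1))))
})

test_that("cohort binning follows the left-closed 1 mN/m convention and
           the weighted fit recovers the generating curve", {
  # bin edges: 0.99 -> [0,1) labelled 0.5; 1.00 -> [1,2) labelled 1.5
  pts <- lapply(1:3, function(i)
    data.frame(tension = c(0.99, 1.00, 2.5 + i * 0.1),
               I_norm = c(0.1, 0.2, 0.8) + i * 0.01))
  cb <- cohortTensionCurve(pts)
  expect_true(0.5 %in% cb$bins$bin_mid)
  expect_true(1.5 %in% cb$bins$bin_mid)
  expect_equal(cb$bins$n[cb$bins$bin_mid == 0.5], 3)

  # weighted fit on a synthetic cohort recovers (k, T50) within 5%
  spec <- stretchCohortSpec(n_patches = 20, T50_mean = 3.7, T50_sd = 0.3,
                            k_mean = 1.2, k_sd = 0.1, A_sd = 20,
                            current_noise_sigma = 3, rundown_prob = 0,
                            seed = 8)
  pl <- Filter(Negate(is.null), lapply(genStretchCohort(spec), function(g) {
    r <- tryCatch(patchTensionResponse(g$patch), error = function(e) NULL)
    if (is.null(r)) NULL else
      r$points[r$points$included, c("tension", "I_norm")]
  }))
  cb2 <- cohortTensionCurve(pl)
  expect_lt(abs(halfMax(cb2$fit) - 3.7) / 3.7, 0.05)
  expect_lt(abs(slopeK(cb2$fit) - 1.2) / 1.2, 0.10)

  expect_error(cohortTensionCurve(pts[1:2]), ">= 3")
})

test_that("pressure response is reported as magnitude P50 and preserves
           cohort contrasts", {
  spec <- stretchCohortSpec(T50_sd = 0, k_sd = 0, A_sd = 0,
                            radius_rel_noise = 0, current_noise_sigma = 0,
                            rundown_prob = 0)
  g <- genStretchPatch(spec, 1)
  pr <- pressureResponse(g$patch)
  expect_gt(halfMax(pr$fit), 0)               # magnitude convention
  expect_equal(plateau(pr$fit), 1, tolerance = 0.02)

  # two cohorts with different T50 keep the sign of their P50 contrast
  mkP50 <- function(T50m, seed) {
    sp <- stretchCohortSpec(n_patches = 8, T50_mean = T50m,
                            T50_sd = 0.1 * T50m, A_sd = 20,
                            current_noise_sigma = 3,
                            rundown_prob = 0, seed = seed)
    p50 <- vapply(genStretchCohort(sp), function(g) {
      r <- tryCatch(pressureResponse(g$patch), error = function(e) NULL)
      if (is.null(r)) NA_real_ else halfMax(r$fit)
    }, numeric(1))
    mean(p50, na.rm = TRUE)
  }
  expect_gt(mkP50(3.7, 5), mkP50(2.0, 6))
})
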