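# Generator contracts: determinism, ground-truth closure, stimulus physics.

test_that("all generators are bit-identical under a repeated seed", {
  s <- domeRenderSpec(radius_um = 1.2, noise_sigma = 12, seed = 5)
  expect_identical(genDomeImage(s)$image, genDomeImage(s)$image)

  sp <- stretchCohortSpec(n_patches = 2, seed = 9)
  expect_identical(genStretchPatch(sp, 1)$peaks,
                   genStretchPatch(sp, 1)$peaks)

  g1 <- genSingleChannel(30, 0, c(-60, -80), seed = 4)
  g2 <- genSingleChannel(30, 0, c(-60, -80), seed = 4)
  expect_identical(lapply(g1$sweeps, currentTrace),
                   lapply(g2$sweeps, currentTrace))

  i1 <- genIndentationSeries(seed = 6)
  i2 <- genIndentationSeries(seed = 6)
  expect_identical(lapply(i1$sweeps, currentTrace),
                   lapply(i2$sweeps, currentTrace))
})

test_that("ground truth is attached everywhere and round-trips through
           JSON losslessly", {
  sp <- stretchCohortSpec(n_patches = 3, seed = 2)
  for (g in genStretchCohort(sp)) {
    p <- truthParams(g$truth)
    expect_true(all(c("T50", "k", "A", "tau_ms") %in% names(p)))
    rt <- truthParams(truthFromJSON(truthToJSON(g$truth)))
    expect_setequal(names(rt), names(p))
    for (n in names(p)) {
      if (length(p[[n]]) == 1L && is.na(p[[n]])) expect_true(is.na(rt[[n]]))
      else if (is.numeric(p[[n]])) expect_identical(as.numeric(rt[[n]]),
                                                    as.numeric(p[[n]]))
      else expect_equal(rt[[n]], p[[n]])
    }
  }
  d <- genDomeImage(domeRenderSpec(1.4, seed = 3))
  expect_true(all(c("radius_um", "r_px", "h", "cy") %in%
                  names(truthParams(d$truth))))
})

test_that("render-spec invariants are enforced", {
  expect_error(domeRenderSpec(radius_um = 0.5,
                              pipette_half_width_um = 0.9), "hemisphere")
  expect_error(domeRenderSpec(1, band_sigma_px = 0), "band_sigma")
  # an arc too large for the frame is a render-geometry error
  expect_error(genDomeImage(domeRenderSpec(3, pipette_half_width_um = 2.9,
                                           image_shape = c(60L, 80L))),
               "does not fit")
  expect_error(stretchCohortSpec(rundown_prob = 1.4), "rundown_prob")
  expect_error(stretchCohortSpec(T50_mean = -1), "positive")
})

test_that("tension is non-decreasing in |P| under the default radius law
           and flat at P = 0", {
  sp <- stretchCohortSpec(radius_rel_noise = 0, current_noise_sigma = 0,
                          rundown_prob = 0)
  g <- genStretchPatch(sp, 2)
  pk <- g$peaks[order(abs(g$peaks$pressure_mmHg)), ]
  expect_equal(pk$tension[1], 0)
  expect_true(all(diff(pk$tension) > 0))
  # radius shrinks monotonically with suction
  expect_true(all(diff(pk$r_um[-1]) < 0))
})

test_that("simulated rundown halves later amplitudes so the filter must
           trigger", {
  sp <- stretchCohortSpec(n_patches = 40, rundown_prob = 1,
                          current_noise_sigma = 0, radius_rel_noise = 0,
                          seed = 13)
  g <- genStretchPatch(sp, 1)
  tr <- truthParams(g$truth)
  expect_true(tr$rundown)
  flags <- detectRundown(g$peaks$Ip)
  expect_true(any(flags))
  expect_gte(tr$rundownFrom, min(which(flags)))
})

test_that("indentation generator honours its threshold and slope", {
  g <- genIndentationSeries(contact_index = 1, threshold_depth_um = 4,
                            amp_slope_pA_per_um = 25, tau_ms = 40,
                            noise_sigma = 0, seed = 1, n_steps = 8)
  al <- alignToContact(g$sweeps, 1L)
  post <- al$peaks[al$postContact]
  depths <- al$depths[al$postContact]
  expect_true(all(post[depths < 4] < 1))
  expect_equal(post[depths == 4], 25, tolerance = 0.2)
  expect_equal(post[depths == 6], 75, tolerance = 0.5)
})
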