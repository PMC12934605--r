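# Band localisation, weighted circle fitting, QC rules and the Laplace
# conversion.

test_that("column band scan finds the darkest segment and a 25-px window", {
  img <- matrix(100, 100, 5)
  img[41:45, 3] <- 50                     # 0-based rows 40-44 darker
  roi <- regionOfInterest(0, 100, 0, 5)
  scan <- columnBandScan(img, roi)
  row <- scan[scan$col == 2, ]
  expect_equal(row$center, 42)
  expect_equal(row$winStart, 30)
  expect_equal(row$winEnd, 54)
  expect_equal(row$winEnd - row$winStart + 1L, 25L)

  # all-constant column: tie broken at the lowest row index
  flat <- scan[scan$col == 0, ]
  expect_equal(flat$center, 2)            # first valid segment centre

  # band at the ROI edge: window shifted inward, still 25 px
  img2 <- matrix(100, 60, 3)
  img2[1:5, 2] <- 10                      # 0-based rows 0-4
  scan2 <- columnBandScan(img2, regionOfInterest(0, 60, 0, 3))
  edge <- scan2[scan2$col == 1, ]
  expect_equal(edge$center, 2)
  expect_equal(edge$winStart, 0)
  expect_equal(edge$winEnd, 24)

  expect_error(columnBandScan(img, regionOfInterest(0, 20, 0, 5)),
               "25")
})

test_that("column Gaussian fit recovers exact and symmetric profiles", {
  rows <- 0:24
  y <- 100 - 40 * exp(-0.5 * ((rows - 12.0) / 2.5)^2)
  g <- fitColumnGaussian(y, rows)
  expect_true(g$valid)
  expect_equal(g$c1, 12.0, tolerance = 1e-6)
  expect_equal(g$sigma1, 2.5, tolerance = 1e-6)
  expect_equal(g$offset, 100, tolerance = 1e-6)
  expect_equal(g$depth, -40, tolerance = 1e-6)

  # any mirror-symmetric dip about row 12 centres there
  ysym <- 100 - 30 * pmax(0, 1 - abs(rows - 12) / 6)^2
  gs <- fitColumnGaussian(ysym, rows)
  expect_equal(gs$c1, 12.0, tolerance = 1e-6)
})

test_that("column Gaussian centre is sub-pixel accurate under noise", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    rows <- 0:24
    truth <- 11.3
    y <- 120 - 50 * exp(-0.5 * ((rows - truth) / 2)^2) + rnorm(25, 0, 5)
    g <- fitColumnGaussian(y, rows)
    if (g$valid) abs(g$c1 - truth) else NA_real_
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.3)
})

test_that("weighted circle fit interpolates exact points and matches the
           algebraic oracle under noise", {
  # 3 exact points, equal weights -> exact interpolation
  b3 <- arcBands(c(30, 50, 70), h = 50, cy = 80, r = 30)
  f3 <- fitCircleWeighted(b3, pixelSizeUm = 0.0325)
  expect_equal(f3@h, 50, tolerance = 1e-6)
  expect_equal(f3@cy, 80, tolerance = 1e-6)
  expect_equal(f3@rPx, 30, tolerance = 1e-6)
  expect_equal(f3@rUm, 30 * 0.0325, tolerance = 1e-6)

  # noisy points: within 1% of truth and 0.5% of the Pratt oracle
  set.seed(4)
  cols <- seq(25, 75, length.out = 40)
  b <- arcBands(cols, h = 50, cy = 80, r = 30.77)
  b$c1 <- b$c1 + rnorm(40, 0, 0.3)
  fw <- fitCircleWeighted(b, pixelSizeUm = 1)
  expect_lt(abs(fw@rPx - 30.77) / 30.77, 0.01)
  po <- prattCircle(b$col, -b$c1)         # oracle in apex-up frame
  expect_lt(abs(fw@rPx - po$r) / po$r, 0.005)

  # collinear points are rejected
  bad <- data.frame(col = 1:10, c1 = rep(5, 10), sigma1 = 1)
  expect_error(fitCircleWeighted(bad, 1), "collinear|degenerate")
  expect_error(fitCircleWeighted(b3[1:2, ], 1), ">= 3")
})

test_that("image QC drops high-variance radii except at zero pressure and
           patch QC tolerates at most two drops", {
  mk <- function(rel) new("CircleFit", h = 1, cy = 1, rPx = 10, rUm = 1,
                          sigmaR = rel * 10, relSd = rel, nColumns = 10L)
  expect_false(qcCircleFit(mk(0.11), -20)$keep)
  expect_true(qcCircleFit(mk(0.11), 0)$keep)
  expect_true(qcCircleFit(mk(0.09), -20)$keep)

  keep <- list(keep = TRUE, reason = "")
  drop <- list(keep = FALSE, reason = "rel_sd")
  expect_true(qcPatchImages(c(rep(list(keep), 15), rep(list(drop), 2)))$keep)
  expect_false(qcPatchImages(c(rep(list(keep), 14), rep(list(drop), 3)))$keep)
  expect_true(qcPatchImages(rep(list(keep), 17))$keep)
})

test_that("Laplace conversion is exact, linear, and sign-converts suction", {
  expect_equal(computeTension(-15, 1.0)$tension_mN_per_m,
               15 * 133.322 * 1e-6 / 2 * 1e3)
  expect_equal(computeTension(-15, 1.0)$tension_mN_per_m, 1.00,
               tolerance = 1e-3)
  expect_equal(computeTension(0, 3.2)$tension_mN_per_m, 0)
  expect_equal(computeTension(-30, 2.0)$tension_mN_per_m, 4.00,
               tolerance = 1e-3)
  expect_error(computeTension(-10, 0), "positive")

  # linear in |P| and in r on a grid
  ps <- c(-5, -10, -20, -40); rs <- c(0.5, 1, 2)
  for (p in ps) for (r in rs) {
    t1 <- computeTension(p, r)$tension_mN_per_m
    expect_equal(computeTension(2 * p, r)$tension_mN_per_m, 2 * t1)
    expect_equal(computeTension(p, 2 * r)$tension_mN_per_m, 2 * t1)
  }
})

test_that("full image pipeline recovers a noiseless dome and is
           deterministic and shift/scale covariant", {
  spec <- domeRenderSpec(radius_um = 1.0, noise_sigma = 0, seed = 3)
  d <- genDomeImage(spec)
  est <- estimateDomeTension(d$image, d$roi, -20, spec$pixel_size_um)
  expect_equal(radiusUm(est$circle), 1.0, tolerance = 0.005)
  expect_equal(est$tension$tension_mN_per_m,
               20 * 133.322 * radiusUm(est$circle) * 1e-6 / 2 * 1e3)

  # seeded noisy render: identical output across runs
  specN <- domeRenderSpec(radius_um = 1.2, noise_sigma = 10, seed = 7)
  e1 <- estimateDomeTension(genDomeImage(specN)$image,
                            genDomeImage(specN)$roi, -20, 0.0325)
  e2 <- estimateDomeTension(genDomeImage(specN)$image,
                            genDomeImage(specN)$roi, -20, 0.0325)
  expect_identical(radiusUm(e1$circle), radiusUm(e2$circle))

  # integer shift moves the centre, leaves r unchanged
  shift <- 4L
  shifted <- rbind(matrix(200, shift, ncol(d$image)),
                   d$image[1:(nrow(d$image) - shift), ])
  roiS <- d$roi; roiS$rowStart <- roiS$rowStart + shift
  roiS$rowEnd <- roiS$rowEnd + shift
  eS <- estimateDomeTension(shifted, roiS, -20, spec$pixel_size_um)
  expect_equal(eS$circle@cy, est$circle@cy + shift, tolerance = 1e-9)
  expect_equal(eS$circle@h, est$circle@h, tolerance = 1e-9)
  expect_equal(eS$circle@rPx, est$circle@rPx, tolerance = 1e-9)

  # doubling pixel size doubles r_um, r_px unchanged
  e2x <- estimateDomeTension(d$image, d$roi, -20, 2 * spec$pixel_size_um)
  expect_equal(e2x$circle@rPx, est$circle@rPx)
  expect_equal(e2x$circle@rUm, 2 * est$circle@rUm)
})
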