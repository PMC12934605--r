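# Baseline subtraction, peak extraction, rundown, qualification, tau.

mkTrace <- function(current, onset = 21L, offset = NULL,
                    stimulus = -20, type = "pressure") {
  n <- length(current)
  if (is.null(offset)) offset <- n
  SweepTrace(seq(0, by = 1e-4, length.out = n), current, stimulus, type,
             onset, offset)
}

test_that("baseline subtraction zeroes the pre-onset mean and is
           idempotent", {
  tr <- mkTrace(rep(-5, 100))
  bs <- baselineSubtract(tr)
  expect_equal(currentTrace(bs), rep(0, 100))

  cur <- c(rep(-3, 20), rep(-53, 80))
  bs2 <- baselineSubtract(mkTrace(cur))
  expect_equal(currentTrace(bs2)[50], -50)
  expect_equal(mean(currentTrace(bs2)[1:20]), 0)

  expect_equal(currentTrace(baselineSubtract(bs2)), currentTrace(bs2))
  expect_error(baselineSubtract(mkTrace(rep(1, 50), onset = 5L)),
               "pre-onset")
})

test_that("peak current averages five samples around the extremum", {
  cur <- rep(0, 100)
  cur[48:52] <- c(-10, -18, -25, -19, -12)
  pk <- peakCurrent(mkTrace(cur))
  expect_equal(pk$Ip, (10 + 18 + 25 + 19 + 12) / 5)   # 16.8
  expect_equal(pk$peakIndex, 50L)

  expect_equal(peakCurrent(mkTrace(rep(0, 100)))$Ip, 0)

  # extremum at the window edge: block shifted inward, still 5 samples
  cur2 <- rep(0, 100)
  cur2[21:25] <- c(-30, -20, -10, -5, -2)             # peak at onset
  pk2 <- peakCurrent(mkTrace(cur2))
  expect_equal(pk2$Ip, (30 + 20 + 10 + 5 + 2) / 5)

  expect_error(peakCurrent(mkTrace(rep(0, 30), onset = 28L, offset = 30L)),
               "5 samples")
})

test_that("peak is invariant to a constant offset followed by baseline
           subtraction", {
  cur <- rep(0, 100); cur[48:52] <- c(-10, -18, -25, -19, -12)
  for (off in c(-7, 3, 40)) {
    pk <- peakCurrent(baselineSubtract(mkTrace(cur + off)))
    expect_equal(pk$Ip, 16.8)
  }
})

test_that("rundown flags a >30% drop from the running maximum and spares
           monotone sequences", {
  expect_equal(detectRundown(c(50, 30)), c(FALSE, TRUE))   # 30 < 0.7*50
  expect_equal(detectRundown(c(50, 40)), c(FALSE, FALSE))  # 40 >= 35
  expect_equal(detectRundown(60), FALSE)

  # once flagged, later sweeps still face the pre-rundown maximum
  expect_equal(detectRundown(c(50, 30, 33)), c(FALSE, TRUE, TRUE))

  # "previous" reference instead rebases on the last unflagged peak
  expect_equal(detectRundown(c(50, 40, 30), reference = "previous"),
               c(FALSE, FALSE, FALSE))

  # property: non-decreasing-to-plateau sequences are never flagged
  set.seed(1)
  for (i in 1:20) {
    A <- runif(1, 30, 120)
    x <- seq(0, 8, length.out = 17)
    peaks <- A / (1 + exp(-runif(1, 1, 3) * (x - runif(1, 2, 5))))
    expect_false(any(detectRundown(peaks)))
  }
})

test_that("patch qualification applies the 20 pA, seal and leak rules
           with the documented boundaries", {
  meta <- list(seal_GOhm = 2, leak_pA = 10)
  expect_false(qualifyPatch(c(5, 19.9), meta)$include)
  expect_true(qualifyPatch(c(5, 20.0), meta)$include)     # inclusive
  expect_false(qualifyPatch(c(50), list(seal_GOhm = 0.8,
                                        leak_pA = 10))$include)
  expect_false(qualifyPatch(c(50), list(seal_GOhm = 2,
                                        leak_pA = 60))$include)
  expect_error(qualifyPatch(c(50), list(seal_GOhm = 2)), "leak_pA")

  wc <- list(series_MOhm = 10, leak_pA = 50, capacitance_pF = 20)
  expect_true(qualifyPatch(c(5), wc, mode = "whole-cell",
                           minPeak = 0)$include)
  wc$series_MOhm <- 16
  expect_false(qualifyPatch(c(5), wc, mode = "whole-cell",
                            minPeak = 0)$include)
})

test_that("inactivation tau is exact on noiseless exponentials and errors
           on flat traces", {
  tr <- expDecaySweep(tau_ms = 4.0)
  fit <- fitInactivationTau(baselineSubtract(tr))
  expect_equal(fit$tau_ms, 4.0, tolerance = 1e-6)
  expect_equal(fit$Ip, -100, tolerance = 1e-4)

  flat <- mkTrace(c(rep(0, 20), rep(-50, 180)), onset = 21L)
  expect_error(fitInactivationTau(flat), "non-decaying|flat")
})

test_that("tau recovery is accurate and nearly unbiased under noise", {
  for (tau in c(2, 4, 8)) {
    est <- vapply(1:40, function(s) {
      set.seed(s)
      tr <- expDecaySweep(tau_ms = tau, peak_pA = 100, noise = 5)
      fitInactivationTau(baselineSubtract(tr))$tau_ms
    }, numeric(1))
    expect_lt(abs(mean(est) - tau) / tau, 0.01)
  }
})
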