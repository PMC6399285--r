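test_that("line shapes have the analytic center heights", {
  for (h in c(0.005, 0.01, 0.02)) {
    sq <- PeakModel("squared_lorentzian", q1 = 0.17, h = h)
    lo <- PeakModel("lorentzian", q1 = 0.17, h = h)
    expect_equal(evaluatePeak(sq, 0.17), 4 / (pi * h))
    expect_equal(evaluatePeak(lo, 0.17), 2 / (pi * h))
    # squared-Lorentzian at |q - q1| = h/2 is a quarter of the center
    expect_equal(evaluatePeak(sq, 0.17 + h / 2),
                 evaluatePeak(sq, 0.17) / 4)
  }
})

test_that("line shapes are symmetric and decreasing away from the center", {
  dq <- seq(0, 0.1, by = 1e-3)
  for (kind in c("squared_lorentzian", "lorentzian")) {
    m <- PeakModel(kind, q1 = 0.3, h = 0.015, amplitude = 2.3)
    expect_equal(evaluatePeak(m, 0.3 + dq), evaluatePeak(m, 0.3 - dq))
    expect_true(all(diff(evaluatePeak(m, 0.3 + dq)) < 0))
  }
  expect_error(PeakModel("squared_lorentzian", q1 = 0.2, h = -0.01),
               "h must be")
})

test_that("fitPeak recovers noiseless parameters to solver tolerance", {
  q <- seq(0.10, 0.24, by = 2e-4)
  for (kind in c("squared_lorentzian", "lorentzian")) {
    truth <- PeakModel(kind, q1 = 0.170, h = 0.02, amplitude = 1.7)
    prof <- Profile1D(q, evaluatePeak(truth, q))
    fit <- fitPeak(prof, c(0.12, 0.22), kind = kind)
    expect_equal(peakCenter(fit), 0.170, tolerance = 1e-6)
    expect_equal(peakWidth(fit), 0.02, tolerance = 1e-6)
    expect_equal(peakAmplitude(fit), 1.7, tolerance = 1e-6)
    expect_true(fit@converged)
  }
})

test_that("fitPeak is robust to 1 percent noise on the peak height", {
  q <- seq(0.10, 0.24, by = 2e-4)
  truth <- PeakModel("squared_lorentzian", q1 = 0.170, h = 0.02)
  clean <- evaluatePeak(truth, q)
  set.seed(42)
  noisy <- clean + rnorm(length(q), 0, 0.01 * max(clean))
  fit <- fitPeak(Profile1D(q, noisy), c(0.12, 0.22))
  expect_equal(peakCenter(fit), 0.170, tolerance = 1e-3)
  expect_true(!is.na(fit@centerUncertainty) && fit@centerUncertainty > 0)
})

test_that("fitPeak enforces its window precondition", {
  p <- Profile1D(seq(0.1, 0.5, by = 0.1), c(1, 2, 5, 2, 1))
  expect_error(fitPeak(p, c(0.1, 0.3)), "at least 5 points")
})

test_that("detectPeaks finds isolated peaks and nothing on flat input", {
  q <- seq(0.05, 0.6, by = 5e-4)
  m1 <- PeakModel("squared_lorentzian", q1 = 0.18, h = 0.01)
  m2 <- PeakModel("squared_lorentzian", q1 = 0.36, h = 0.01,
                  amplitude = 0.5)
  prof <- Profile1D(q, evaluatePeak(m1, q) + evaluatePeak(m2, q))
  found <- detectPeaks(prof, minProminence = 0.05)
  expect_length(found, 2)
  expect_true(all(abs(found - c(0.18, 0.36)) <= 5e-4 + 1e-12))

  flat <- Profile1D(q, rep(1, length(q)))
  expect_length(detectPeaks(flat), 0)
  mono <- Profile1D(q, rev(seq_along(q)))
  expect_length(detectPeaks(mono, minProminence = 0), 0)
})

test_that("detected peak count never exceeds the strict local maxima", {
  set.seed(7)
  for (i in 1:5) {
    q <- seq(0.05, 0.6, by = 2e-3)
    y <- abs(stats::filter(rnorm(length(q)), rep(1, 5), sides = 2))
    y[is.na(y)] <- 0
    prof <- Profile1D(q, as.numeric(y) + 0.1)
    n <- length(q)
    nmax <- sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n])
    expect_lte(length(detectPeaks(prof, minProminence = 0.01,
                                  smoothingHalfwidth = 0L)), nmax)
  }
})

test_that("fitPeaks untangles overlapping neighbors by tail subtraction", {
  q <- seq(0.08, 0.30, by = 2e-4)
  m1 <- PeakModel("squared_lorentzian", q1 = 0.170, h = 0.02)
  m2 <- PeakModel("squared_lorentzian", q1 = 0.192, h = 0.02,
                  amplitude = 0.8)
  prof <- Profile1D(q, evaluatePeak(m1, q) + evaluatePeak(m2, q))
  fits <- fitPeaks(prof, detectPeaks(prof, minProminence = 0.05))
  expect_length(fits, 2)
  expect_equal(peakCenter(fits[[1]]), 0.170, tolerance = 1e-5)
  expect_equal(peakCenter(fits[[2]]), 0.192, tolerance = 1e-5)
  expect_equal(peakWidth(fits[[1]]), 0.02, tolerance = 1e-3)
})
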