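test_that("profiles load from delimited text with unit conversion", {
  path <- writeTempProfile(c("# sample: toy", "0.1 5.0", "0.2 4.0",
                             "0.3 3.0"))
  p <- readProfile(path)
  expect_equal(qValues(p), c(0.1, 0.2, 0.3))
  expect_equal(intensityValues(p), c(5, 4, 3))
  expect_identical(profileMeta(p)$sample, "toy")

  pn <- readProfile(path, qUnit = "inverse_nanometer")
  expect_equal(qValues(pn), c(0.01, 0.02, 0.03))

  # comma delimiter and a third (uncertainty) column
  path3 <- writeTempProfile(c("0.1,5.0,0.5", "0.2,4.0,0.4"))
  p3 <- readProfile(path3)
  expect_equal(sigmaValues(p3), c(0.5, 0.4))
})

test_that("malformed profiles are rejected with informative errors", {
  bad <- writeTempProfile(c("0.3 3.0", "0.2 4.0", "0.1 5.0"))
  expect_error(readProfile(bad), "strictly increasing")
  nonnum <- writeTempProfile(c("0.1 5.0", "0.2 oops", "0.3 3.0"))
  expect_error(readProfile(nonnum), "line 2")
  expect_error(readProfile(tempfile()), "not found")
  expect_error(Profile1D(q = c(0.1), intensity = c(1)), "at least 2")
})

test_that("write/read round trip preserves q and intensity exactly", {
  set.seed(11)
  q <- sort(runif(40, 0.05, 0.7))
  p <- Profile1D(q, rexp(40), sigma = runif(40),
                 meta = list(sample = "rt", ratio = "1:1"))
  path <- tempfile(fileext = ".dat")
  writeProfile(p, path)
  p2 <- readProfile(path)
  expect_identical(qValues(p2), qValues(p))
  expect_identical(intensityValues(p2), intensityValues(p))
  expect_identical(sigmaValues(p2), sigmaValues(p))
  expect_identical(profileMeta(p2)$ratio, "1:1")
})

test_that("unit conversion is a factor-10 involution", {
  q <- c(0.08, 0.17, 0.33)
  expect_equal(convertQ(q, "inverse_angstrom", "inverse_nanometer"),
               q * 10)
  expect_identical(
    convertQ(convertQ(q, "inverse_angstrom", "inverse_nanometer"),
             "inverse_nanometer", "inverse_angstrom"), q)
})

test_that("windowing returns a q subset", {
  p <- Profile1D(seq(0.1, 0.5, by = 0.01), seq_len(41))
  w <- windowProfile(p, 0.2, 0.35)
  expect_true(all(qValues(w) %in% qValues(p)))
  expect_true(min(qValues(w)) >= 0.2 && max(qValues(w)) <= 0.35)
  expect_error(windowProfile(p, 0.9, 1.0), "fewer than 2")
})

test_that("background subtraction removes the fitted model", {
  q <- seq(0.05, 0.6, by = 0.005)
  # constant profile, constant model: exact zero
  pc <- Profile1D(q, rep(2, length(q)))
  out <- subtractBackground(pc, list(c(0.05, 0.15)), model = "constant")
  expect_equal(intensityValues(out), rep(0, length(q)), tolerance = 1e-12)

  # power-law decay plus one Gaussian bump; windows exclude the bump, so
  # the residual should equal the bump alone
  bump <- 0.8 * exp(-(q - 0.35)^2 / (2 * 0.01^2))
  pl <- Profile1D(q, 2e-3 * q^(-1.7) + bump)
  out <- subtractBackground(pl, list(c(0.05, 0.25), c(0.45, 0.6)),
                            model = "power_law")
  expect_equal(intensityValues(out), bump, tolerance = 1e-6)
  expect_identical(profileMeta(out)$background$model, "power_law")

  expect_error(subtractBackground(pc, list()), "non-empty")
  neg <- Profile1D(q, rep(-1, length(q)))
  expect_error(subtractBackground(neg, list(c(0.05, 0.1)),
                                  model = "power_law"), "positive")
})
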