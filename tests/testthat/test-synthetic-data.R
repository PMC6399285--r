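test_that("generated peak centers sit exactly at the phase predictions", {
  s <- syntheticSpec("square_columnar", d = 3.40, noiseLevel = 0)
  gs <- generateSpectrum(s)
  expect_equal(gs$truth$peaks$q[1:5],
               (2 * pi / 34) * sqrt(c(1, 2, 4, 5, 8)), tolerance = 1e-15)

  dis <- generateSpectrum(syntheticSpec("disordered", d = 3.70,
                                        peakKind = "lorentzian"))
  expect_equal(dis$truth$peaks$q, 2 * pi / 37, tolerance = 1e-15)
  expect_equal(round(dis$truth$peaks$q, 4), 0.1698)
})

test_that("a single bare peak reproduces evaluatePeak pointwise", {
  s <- syntheticSpec("disordered", d = 3.70, peakKind = "lorentzian",
                     widthH = 0.015, amplitudes = 2.2,
                     background = list(model = "none"), noiseLevel = 0)
  gs <- generateSpectrum(s)
  model <- PeakModel("lorentzian", q1 = 2 * pi / 37, h = 0.015,
                     amplitude = 2.2)
  expect_equal(intensityValues(gs$profile),
               evaluatePeak(model, qValues(gs$profile)), tolerance = 1e-15)
})

test_that("generation is bit-identical for equal spec and seed", {
  s1 <- syntheticSpec("square_columnar", d = 3.40, noiseLevel = 0.05,
                      seed = 123)
  g1 <- generateSpectrum(s1)
  g2 <- generateSpectrum(s1)
  expect_identical(intensityValues(g1$profile),
                   intensityValues(g2$profile))
  s2 <- syntheticSpec("square_columnar", d = 3.40, noiseLevel = 0.05,
                      seed = 124)
  g3 <- generateSpectrum(s2)
  expect_false(identical(intensityValues(g1$profile),
                         intensityValues(g3$profile)))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateSpectrum(syntheticSpec("lamellar", d = 5,
                                           noiseLevel = 0.05, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("peaks outside the requested grid are reported by label", {
  s <- syntheticSpec("square_columnar", d = 3.40, qRange = c(0.1, 0.3))
  expect_error(generateSpectrum(s), "outside the q grid")
})

test_that("the benchmark suite is deterministic and spans the design", {
  a <- generateBenchmarkSuite(seed = 5)
  b <- generateBenchmarkSuite(seed = 5)
  expect_identical(lapply(a, function(e) intensityValues(e$profile)),
                   lapply(b, function(e) intensityValues(e$profile)))
  expect_length(a, 6 * 3 * 3)
  phases <- unique(vapply(a, function(e) e$truth$phase, character(1)))
  expect_setequal(phases, c("square_columnar", "tetragonal_columnar",
                            "disordered", "cubic_pn3m", "lamellar",
                            "hexagonal_columnar"))
  # the reference-system fixtures carry their nominal parameters
  expect_equal(a[["tetragonal_columnar_h0.01_n0"]]$truth$d, 3.64)
  expect_equal(a[["tetragonal_columnar_h0.01_n0"]]$truth$c, 3.28)
  expect_equal(a[["square_columnar_h0.01_n0"]]$truth$d, 3.40)
  expect_equal(a[["disordered_h0.01_n0"]]$truth$d, 3.70)
  expect_equal(a[["cubic_pn3m_h0.0025_n0"]]$truth$a, 15.4)
})

test_that("fixtures round-trip through the plain-text format", {
  gs <- generateSpectrum(syntheticSpec("lamellar", d = 5, widthH = 0.01,
                                       noiseLevel = 0.01, seed = 3))
  path <- tempfile(fileext = ".dat")
  writeSyntheticFixture(gs, path)
  back <- readProfile(path)
  expect_identical(qValues(back), qValues(gs$profile))
  expect_identical(intensityValues(back), intensityValues(gs$profile))
  truth <- readLines(paste0(path, ".truth"))
  expect_true(any(grepl("^phase: lamellar$", truth)))
})

test_that("the LL37-like noiseless fixture regresses to d = 3.400", {
  e <- generateBenchmarkSuite(seed = 2)[["square_columnar_h0.01_n0"]]
  out <- indexProfile(e$profile)
  expect_identical(out$report$phase, "square_columnar")
  expect_equal(out$report$d_nm, 3.400, tolerance = 5e-4)
})
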