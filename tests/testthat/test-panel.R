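test_that("grid cells agree with independent thermal spectrum calls", {
  g <- gridScan(c(59, 63), c(51, 55), stepC = 2)
  for (tmb in g@tmbAxis) for (tmq in g@tmqAxis) {
    sp <- thermalSpectrum(thermalProbeSet("p", tmbC = tmb, tmqC = tmq))
    i <- as.character(tmb); j <- as.character(tmq)
    expect_equal(g@yieldMap[i, j], signalYield(sp), tolerance = 1e-10)
    expect_equal(g@tsMap[i, j], signalTemp(sp), tolerance = 1e-10)
    expect_equal(g@widthMap[i, j], spectrumWidth(sp), tolerance = 1e-10)
  }
})

test_that("larger Tmb - Tmq separation gives higher yield", {
  g <- gridScan()
  expect_gt(g@yieldMap["80", "35"], g@yieldMap["45", "44"])
})

test_that("crosstalk is symmetric, unity on itself, small for distant channels", {
  s1 <- thermalSpectrum(thermalProbeSet("a", tmbC = 45, tmqC = 38))
  s2 <- thermalSpectrum(thermalProbeSet("b", tmbC = 78, tmqC = 69))
  expect_equal(crosstalk(s1, s1), 1)
  expect_equal(crosstalk(s1, s2), crosstalk(s2, s1))
  expect_gt(abs(signalTemp(s1) - signalTemp(s2)),
            3 * max(spectrumWidth(s1), spectrumWidth(s2)))
  expect_lt(crosstalk(s1, s2), 0.12)
})

test_that("the integral overlap metric behaves like an overlap coefficient", {
  s1 <- thermalSpectrum(thermalProbeSet("a", tmbC = 52, tmqC = 44))
  s2 <- thermalSpectrum(thermalProbeSet("b", tmbC = 78, tmqC = 69))
  expect_equal(crosstalk(s1, s1, method = "integral"), 1, tolerance = 1e-12)
  expect_equal(crosstalk(s1, s2, method = "integral"),
               crosstalk(s2, s1, method = "integral"))
  expect_lt(crosstalk(s1, s2, method = "integral"), 0.12)
  # nearby channels overlap more than distant ones
  s3 <- thermalSpectrum(thermalProbeSet("c", tmbC = 59, tmqC = 51))
  expect_gt(crosstalk(s1, s3, method = "integral"),
            crosstalk(s1, s2, method = "integral"))
})

test_that("crosstalk rejects mismatched grids and zero-yield spectra", {
  s1 <- thermalSpectrum(thermalProbeSet("a", tmbC = 61, tmqC = 53))
  s2 <- thermalSpectrum(thermalProbeSet("a", tmbC = 61, tmqC = 53),
                        tMinC = 30)
  expect_error(crosstalk(s1, s2), "grid")
  flat <- new("ThermalSpectrum", tempsC = s1@tempsC,
              signal = rep(0, length(s1@tempsC)), tsC = s1@tempsC[1],
              yield = 0, widthC = 0)
  expect_error(crosstalk(s1, flat), "zero-yield")
})

test_that("zero overlap tolerance admits exactly one channel", {
  g <- gridScan(c(45, 75), c(38, 68), stepC = 5)
  panel <- selectChannels(g, overlapMax = 0)
  expect_equal(length(probes(panel)), 1L)
})

test_that("greedy selection matches exhaustive search on a coarse grid", {
  g <- gridScan(c(45, 65), c(38, 58), stepC = 5)
  panel <- selectChannels(g)
  oracle <- oracleMaxPanelSize(g, 0.8, 0.12, 37, 75)
  expect_equal(length(probes(panel)), oracle)
  expect_gt(oracle, 0)
})

test_that("panel size responds monotonically to the constraints", {
  g <- gridScan()
  n <- function(...) length(probes(selectChannels(g, ...)))
  expect_lte(n(overlapMax = 0.05), n(overlapMax = 0.12))
  expect_lte(n(overlapMax = 0.12), n(overlapMax = 0.30))
  expect_lte(n(yieldMin = 0.9), n(yieldMin = 0.8))
})

test_that("selected panels withstand post-hoc verification", {
  g <- gridScan()
  panel <- selectChannels(g)
  expect_true(verifyPanel(panel))
  # tightening the recorded constraints must make verification fail
  tight <- panel
  tight@constraintsUsed$overlapMax <- 0.01
  v <- verifyPanel(tight)
  expect_false(v)
  expect_match(attr(v, "failures"), "crosstalk")
})

test_that("infeasible constraints give an empty panel, bad constraints error", {
  g <- gridScan(c(40, 45), c(42, 47), stepC = 1)  # low separation, low yield
  panel <- selectChannels(g, yieldMin = 0.99)
  expect_equal(length(probes(panel)), 0L)
  expect_error(selectChannels(g, yieldMin = 0), "yieldMin")
  expect_error(selectChannels(g, overlapMax = 2), "overlapMax")
  expect_error(selectChannels("nope"), "DesignGrid")
})
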