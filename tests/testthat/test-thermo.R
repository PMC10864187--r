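cond <- bindingConditions()  # 250 nM, 195 mM salt

test_that("nearest-neighbor sums match an independent hand-summation", {
  # fixed case with a hand-checkable stack decomposition
  th <- duplexThermoFromSequence("ACGTACGT")
  or <- oracleDuplex("ACGTACGT")
  expect_equal(th@dH, or$dH, tolerance = 1e-12)
  expect_equal(th@dS, or$dS, tolerance = 1e-12)
  expect_identical(th@source, "from_sequence")

  # self-complementary sequence carries the symmetry entropy term
  pal <- "ACGT"
  expect_identical(reverseComplement(pal), pal)
  thPal <- duplexThermoFromSequence(pal)
  orPal <- oracleDuplex(pal)
  expect_equal(thPal@dS, orPal$dS, tolerance = 1e-12)

  # property: random short duplexes at several salt levels
  set.seed(42)
  for (rep in 1:25) {
    s <- randomSeq(sample(2:8, 1))
    salt <- sample(c(50, 195, 1000), 1)
    th <- duplexThermoFromSequence(s, saltMM = salt)
    or <- oracleDuplex(s, saltMM = salt)
    expect_equal(th@dH, or$dH, tolerance = 1e-12)
    expect_equal(th@dS, or$dS, tolerance = 1e-12)
  }
})

test_that("invalid sequences are rejected", {
  expect_error(duplexThermoFromSequence("A"), "at least 2")
  expect_error(duplexThermoFromSequence(""), "at least 2")
  expect_error(duplexThermoFromSequence("ACGN"), "outside")
})

test_that("melting temperature is the theta = 0.5 root", {
  for (tmTarget in c(45, 53, 61, 72)) {
    th <- thermoFromTm(tmTarget, -110, cond)
    tm <- meltingTemperature(th, cond)
    expect_equal(tm, tmTarget, tolerance = 1e-9)
    at <- fractionBound(th, bindingConditions(tempC = tm))
    expect_equal(at, 0.5, tolerance = 1e-9)
    # brute-force root of theta(T) = 0.5
    root <- uniroot(function(x)
      fractionBound(th, bindingConditions(tempC = x)) - 0.5,
      c(0, 100), tol = 1e-10)$root
    expect_equal(tm, root, tolerance = 1e-6)
  }
})

test_that("Tm increases with strand concentration", {
  th <- thermoFromTm(53, -110, cond)
  tm1 <- meltingTemperature(th, cond)
  tm2 <- meltingTemperature(th, bindingConditions(strandConcM = 500e-9))
  expect_gt(tm2, tm1)
})

test_that("nonphysical parameters are rejected", {
  expect_error(thermoFromTm(53, 10, cond), "negative")
  expect_error(duplexThermo(-50, 100), "dS must be negative")
  th <- duplexThermo(-1, -200)
  expect_error(meltingTemperature(th, bindingConditions(strandConcM = 1e80)),
               "nonphysical")
})

test_that("fraction bound is a decreasing sigmoid saturating around Tm", {
  th <- thermoFromTm(53, -110, cond)
  grid <- bindingConditions(tempC = seq(20, 80, 0.5))
  theta <- fractionBound(th, grid)
  expect_true(all(theta >= 0 & theta <= 1))
  expect_true(all(diff(theta) < 0))
  expect_gt(fractionBound(th, bindingConditions(tempC = 33)), 0.99)
  expect_lt(fractionBound(th, bindingConditions(tempC = 73)), 0.01)
})

test_that("steeper enthalpy narrows the melting transition", {
  width <- function(dH) {
    th <- thermoFromTm(53, dH, cond)
    t25 <- uniroot(function(x)
      fractionBound(th, bindingConditions(tempC = x)) - 0.25, c(0, 100),
      tol = 1e-9)$root
    t75 <- uniroot(function(x)
      fractionBound(th, bindingConditions(tempC = x)) - 0.75, c(0, 100),
      tol = 1e-9)$root
    t25 - t75
  }
  expect_gt(width(-75), width(-150))
  expect_gt(width(-150), 0)
})
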