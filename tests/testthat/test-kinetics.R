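cond <- bindingConditions()
refProbe <- thermalProbeSet("ref", tmbC = 61, tmqC = 53)

test_that("long holds converge to the closed-form equilibrium", {
  prot <- tempProtocol(50, rampS = 5, holdS = 120)
  traj <- simulateProtocol(refProbe, prot, freeConcM = refProbe@concM)
  final <- traj[nrow(traj), ]
  eqB <- fractionBound(refProbe@barcode,
                       bindingConditions(tempC = 50))
  expect_equal(final$thetaBarcode, eqB, tolerance = 1e-6)
})

test_that("ODE equilibria match two-state occupancy at every temperature", {
  for (tc in seq(35, 70, by = 5)) {
    prot <- tempProtocol(tc, rampS = 2, holdS = 300)
    traj <- simulateProtocol(refProbe, prot, freeConcM = refProbe@concM,
                             sampleHz = 2)
    eq <- fractionBound(refProbe@barcode, bindingConditions(tempC = tc))
    expect_equal(traj$thetaBarcode[nrow(traj)], eq, tolerance = 1e-6)
  }
})

test_that("quencher melts off within seconds of reaching the spike", {
  # quencher Tm 53 C with the -75 kcal/mol surrogate enthalpy, spike 57 C
  probe <- thermalProbeSet("k", tmbC = 61, tmqC = 53, dHQuencher = -75)
  prot <- tempProtocol(57, rampS = 5, holdS = 10)
  traj <- simulateProtocol(probe, prot, freeConcM = 0)
  at10 <- traj$thetaQuencher[which.min(abs(traj$timeS - 10))]
  expect_lt(at10, 0.01)          # 5 s after reaching temperature
  expect_gt(traj$thetaBarcode[which.min(abs(traj$timeS - 10))], 0.9)
})

test_that("with no free strand the decay matches quadrature of k_off", {
  prot <- tempProtocol(57, rampS = 5, holdS = 5)
  traj <- simulateProtocol(refProbe, prot, freeConcM = 0,
                           atol = 1e-12, rtol = 1e-10)
  rq <- rateModel(refProbe@quencher)
  theta0 <- traj$thetaQuencher[1]
  for (tEnd in c(2, 5, 8)) {
    integral <- integrate(function(t) kOff(rq, prot$tempAt(t)), 0, tEnd,
                          rel.tol = 1e-12)$value
    expected <- theta0 * exp(-integral)
    got <- traj$thetaQuencher[which.min(abs(traj$timeS - tEnd))]
    expect_equal(got, expected, tolerance = 1e-8)
  }
})

test_that("rebinding at imaging concentrations is negligible", {
  rm53 <- rateModel(thermoFromTm(53, -110, cond))
  expect_lt(rebindingFraction(rm53, 1e-15, 24 * 3600, 30), 1e-4)
  expect_identical(rebindingFraction(rm53, 0, 1e9, 30), 0)
  # closed form at 1 pM over 24 h, kOn 1e6
  got <- rebindingFraction(rm53, 1e-12, 24 * 3600, 5)
  expect_equal(got, 1 - exp(-1e6 * 1e-12 * 24 * 3600), tolerance = 1e-12)
})

test_that("rebinding closed form agrees with the ODE integrator", {
  c0 <- 1e-12
  probe <- thermalProbeSet("rb", tmbC = 80, tmqC = 53)
  prot <- tempProtocol(5, rampS = 1e-6, holdS = 24 * 3600, startC = 5)
  traj <- simulateProtocol(probe, prot, freeConcM = c0,
                           theta0 = c(0, 0), sampleHz = 1 / 600)
  rmq <- rateModel(probe@quencher)
  koff5 <- kOff(rmq, 5)
  rate <- 1e6 * c0 + koff5
  expected <- (1e6 * c0 / rate) * (1 - exp(-rate * 24 * 3600))
  expect_equal(traj$thetaQuencher[nrow(traj)], expected, tolerance = 1e-6)
  # at near-complete equilibrium occupancy the pseudo-first-order estimate
  # 1 - exp(-kOn c t) is an upper bound reached within a few percent
  est <- rebindingFraction(rmq, c0, 24 * 3600, 5)
  expect_lte(traj$thetaQuencher[nrow(traj)], est + 1e-9)
})

test_that("dissociation accelerates as the spike rises above Tmq", {
  rmq <- rateModel(refProbe@quencher)
  times <- vapply(c(55, 60, 65), function(tc) dissociationTime(rmq, tc),
                  numeric(1))
  expect_true(all(diff(times) < 0))
})

test_that("rebinding fraction is monotone in concentration and time", {
  rm53 <- rateModel(thermoFromTm(53, -110, cond))
  cs <- c(1e-15, 1e-13, 1e-11)
  fr <- vapply(cs, function(c0) rebindingFraction(rm53, c0, 3600, 30),
               numeric(1))
  expect_true(all(diff(fr) > 0))
  ts <- c(60, 3600, 86400)
  ft <- vapply(ts, function(t0) rebindingFraction(rm53, 1e-13, t0, 30),
               numeric(1))
  expect_true(all(diff(ft) > 0))
})

test_that("protocol construction validates its inputs", {
  expect_error(tempProtocol(numeric(0)), "at least one")
  expect_error(tempProtocol(57, rampS = -1), "non-negative")
  p <- tempProtocol(c(48, 57), rampS = 5, holdS = 10)
  expect_equal(p$tempAt(0), 23)
  expect_equal(p$tempAt(5), 48)
  expect_equal(p$tempAt(15), 48)
  expect_equal(p$tempAt(20), 57)
  expect_equal(p$tempAt(1e6), 57)  # clamped after the last segment
})
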