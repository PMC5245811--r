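test_that("production spectrum scales correctly with NPP and mass", {
  # PiStar = 0 pins the representative phytoplankton mass, isolating the
  # linear NPP dependence
  ecoFix <- ecoParams(PiStar = 1e-12)
  m <- 10^seq(-2, 4, length.out = 30)
  p1 <- productionSpectrum(800, 12, m, ecoFix)
  p2 <- productionSpectrum(1600, 12, m, ecoFix)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  expect_equal(productionSpectrum(0, 12, m, ecoFix), rep(0, length(m)))

  # pi * m is a pure power law m^tau: tau = -0.25 gives a factor 10^-1
  # over 4 decades of mass
  eco25 <- ecoParams(alphaTe = 5000^-0.25, betaPPMR = 5000, PiStar = 1e-12)
  expect_equal(trophicScaling(eco25), -0.25)
  mPhi <- phytoplanktonMass(1000, 10, eco25)
  pm <- productionSpectrum(1000, 10, c(mPhi, 1e4 * mPhi), eco25) *
    c(mPhi, 1e4 * mPhi)
  expect_equal(pm[2] / pm[1], 0.1, tolerance = 1e-10)
  expect_error(productionSpectrum(-5, 10, m, ecoFix), "invalid")
})

test_that("representative phytoplankton mass shrinks with warming", {
  eco <- ecoParams()
  mW <- phytoplanktonMass(1500, 25, eco)
  mC <- phytoplanktonMass(1500, 5, eco)
  expect_lt(mW, mC)
  # more production -> larger cells at fixed temperature
  expect_gt(phytoplanktonMass(2500, 10, eco), phytoplanktonMass(600, 10, eco))
  # clipped within the anchor masses
  expect_true(all(phytoplanktonMass(c(0, 1e5), 10, eco) >=
                    eco@mPhyS * (1 - 1e-9) &
                  phytoplanktonMass(c(0, 1e5), 10, eco) <=
                    eco@mPhyL * (1 + 1e-9)))
})

test_that("production-limited growth is the per-capita energy quotient", {
  # pi * m = 1e-6 at m = 1, f = 1e-3, phi = 1/3
  expect_equal(xiP(pi = 1e-6, f = 1e-3, m = 1, phiC = 1 / 3), 1e-6 / 3e-3)
  expect_equal(xiP(1e-6, 2e-3, 1, 1 / 3), 0.5 * xiP(1e-6, 1e-3, 1, 1 / 3))
  expect_equal(xiP(1e-6, 1e-3, 1, 0), 0)
  # empty bins fall back on the cap
  expect_equal(xiP(1e-6, 0, 1, 1 / 3, cap = 42), 42)
  expect_error(xiP(1e-6, -1, 1, 1 / 3), "invalid")
})

test_that("physiological growth ceiling follows von Bertalanffy allometry", {
  eco <- unitEco(b = 2 / 3)
  g <- sizeGroup("x", mInf = 8, mAlpha = 2)
  expect_equal(xiVB(8, 10, g, eco), 0)
  expect_equal(xiVB(1, 10, g, eco), 1 - 8^(-1 / 3) * 1)  # = 0.5
  expect_error(xiVB(9, 10, g, eco), "invalid")
  # +10 degC multiplies the whole rate by the Arrhenius ratio
  ecoT <- ecoParams(A0 = 360 * 86400, b = 2 / 3, omegaA = 0.45)
  r <- xiVB(1, 20, g, ecoT) / xiVB(1, 10, g, ecoT)
  expect_equal(r, arrheniusFactor(20, 0.45), tolerance = 1e-12)
  expect_equal(r, 1.877, tolerance = 1e-3)
})

test_that("realised growth takes the minimum and splits by maturity", {
  eco <- ecoParams()
  g <- sizeGroup("x", 1e3)
  # far below maturity: nearly all intake goes to growth
  gr <- realizedGrowth(xiP = 2, xiVB = 1, m = 0.1, g, eco)
  expect_equal(gr$xiI, 1)
  expect_equal(gr$gamma, 1, tolerance = 1e-6)
  expect_equal(gr$limitation, "physiology")
  # starvation dominates regardless of the ceiling
  expect_equal(realizedGrowth(0, 5, 0.1, g, eco)$gamma, 0)
  # near the asymptotic mass almost everything goes to reproduction
  grTop <- realizedGrowth(1, 1, 999, g, eco)
  expect_lt(grTop$gamma, 1e-3)
  expect_equal(grTop$repro, grTop$xiI, tolerance = 1e-3)
  expect_error(realizedGrowth(-1, 1, 1, g, eco), "invalid")
})

test_that("maturity allocation ramps from juveniles to the asymptote", {
  eco <- ecoParams()
  g <- sizeGroup("x", 1e3, mAlpha = 250)
  expect_equal(maturityAllocation(250, g, eco), 0.5)
  expect_lt(maturityAllocation(25, g, eco), 0.01)
  expect_gt(maturityAllocation(1e3, g, eco), 0.99)
  m <- 10^seq(-2, 3, length.out = 100)
  expect_true(all(diff(maturityAllocation(m, g, eco)) > 0))
})

test_that("mortality follows the empirical allometric form", {
  # lambda reduced to 1: zeta1 = 0, unit A0, scale 1, no temperature effect
  eco <- unitEco(b = 2 / 3, zeta1 = 0, h = 0.5)
  g <- sizeGroup("x", 1e4)
  expect_equal(mortalityRate(1e2, 10, g, eco),
               1e2^-0.5 * 1e4^(0.5 + 2 / 3 - 1), tolerance = 1e-12)
  expect_equal(mortalityRate(1e2, 10, g, eco), 0.464, tolerance = 1e-3)
  # exponents collapse at the asymptotic mass
  expect_equal(mortalityRate(1e4, 10, g, eco), 1e4^(2 / 3 - 1))
  # zeta1 + ln 2 doubles the rate everywhere
  eco2 <- unitEco(b = 2 / 3, zeta1 = log(2), h = 0.5)
  expect_equal(mortalityRate(c(1, 50, 1e4), 10, g, eco2),
               2 * mortalityRate(c(1, 50, 1e4), 10, g, eco))
})

test_that("recruitment is the harmonic mean of its two limiting fluxes", {
  eco <- ecoParams(sE = 0.025, phiC = 1)
  grid <- massGrid(0.01, 100, 5)
  f <- rep(1, 5)
  # no primary-production path to recruits
  expect_equal(recruitmentFlux(f, pi0 = 0, repro = rep(1e-6, 5), grid, eco,
                               phiC = 1), 0)
  # craft RP = Re = 2 exactly
  RPtarget <- 2
  pi0 <- RPtarget / recruitMass(grid)
  repro <- rep(1, 5)
  ReRaw <- (eco@sE / 2) * sum(repro * f / binCenters(grid) *
                                binWidths(grid))
  repro <- repro * (2 / ReRaw)
  expect_equal(recruitmentFlux(f, pi0, repro, grid, eco, 1), 1)
  # Re -> infinity saturates at RP (limiting-factor asymptote)
  expect_equal(recruitmentFlux(f, pi0, repro * 1e12, grid, eco, 1),
               RPtarget, tolerance = 1e-10)
  expect_equal(recruitmentFlux(rep(0, 5), 0, rep(0, 5), grid, eco, 1), 0)
})

test_that("ecology tendency telescopes to the analytic mass balance", {
  eco <- ecoParams()
  g <- defaultGroups()[[2]]
  grid <- massGrid(0.01, asymptoticMass(g), 25)
  m <- binCenters(grid)
  w <- binWidths(grid)
  f <- 0.1 * (m / m[1])^-1

  # general state: discrete sum of the tendency must equal
  # recruitment + dilation - mortality exactly (upwind telescoping)
  td <- ecologyTendency(f, npp = 1200, temperature = 8, g, eco, grid,
                        phiC = 1 / 3)
  lhs <- sum(td$dfdt * w)
  rhs <- td$recruit + sum(td$gamma * f * w / m) - sum(td$lambda * f * w)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # no energy input and no mortality: static spectrum
  ecoStill <- ecoParams(mortalityScale = 1e-300)
  tdStill <- ecologyTendency(f, npp = 0, temperature = 8, g, ecoStill, grid,
                             phiC = 1 / 3)
  expect_equal(max(abs(tdStill$dfdt)), 0, tolerance = 1e-25)

  # pure mortality: total biomass decays at the mortality integral
  tdMort <- ecologyTendency(f, npp = 0, temperature = 8, g, eco, grid,
                            phiC = 1 / 3)
  expect_equal(sum(tdMort$dfdt * w), -sum(tdMort$lambda * f * w),
               tolerance = 1e-12)
})

test_that("growth limitation switches from physiology to production as f grows", {
  eco <- ecoParams()
  g <- defaultGroups()[[2]]
  grid <- massGrid(0.01, asymptoticMass(g), 25)
  m <- binCenters(grid)
  fBase <- 30 * (m / m[1])^-1
  fracProd <- vapply(c(0.01, 0.1, 1, 10, 100), function(s) {
    td <- ecologyTendency(fBase * s, 1200, 8, g, eco, grid, 1 / 3)
    mean(td$limitation == "production")
  }, numeric(1))
  expect_true(all(diff(fracProd) >= 0))
  expect_lt(fracProd[1], fracProd[5])
})

test_that("growth characteristic matches the closed-form von Bertalanffy curve", {
  skip_if_not_installed("deSolve")
  eco <- unitEco(b = 2 / 3)   # unit per-second rate, b = 2/3
  g <- sizeGroup("x", mInf = 1000, mAlpha = 250)
  ka <- 1000^(2 / 3 - 1)
  m0 <- 1
  times <- seq(0, 15, length.out = 40)
  sol <- deSolve::ode(y = c(m = m0), times = times,
                      func = function(t, y, p)
                        list(xiVB(min(y, 1000), 10, g, eco)),
                      rtol = 1e-10, atol = 1e-12)
  closed <- 1000 * (1 - (1 - (m0 / 1000)^(1 / 3)) * exp(-ka * times / 3))^3
  expect_equal(unname(sol[, "m"]), closed, tolerance = 1e-6)
})

test_that("unharvested spectrum reaches a reproducibly steady state", {
  # warm productive site so the slowest (adult large-fish) modes relax
  # within a few hundred years
  mod <- tinyModel(nBins = 15)
  fc <- forcing(npp = 1200, temperature = 28)
  long <- fishingProtocol(spinupYears = 400, rampYears = 0, dtDays = 30,
                          q0 = 0)
  seg <- fishingProtocol(spinupYears = 50, rampYears = 0, dtDays = 30,
                         q0 = 0)
  st <- runCell(fc, mod, long)@finalState
  r1 <- runCell(fc, mod, seg, state = st)
  r2 <- runCell(fc, mod, seg, state = r1@finalState)
  b1 <- mean(annualTotals(r1)$biomass)
  b2 <- mean(annualTotals(r2)$biomass)
  expect_lt(abs(b2 - b1) / b1, 1e-3)
})
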