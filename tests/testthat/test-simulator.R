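test_that("catchability trajectory is flat then compounds", {
  p <- fishingProtocol()
  expect_equal(catchabilityTrajectory(0, p), 1e-5)
  expect_equal(catchabilityTrajectory(100, p), 1e-5)
  expect_equal(catchabilityTrajectory(300, p), 1e-5 * 1.05^200)
  expect_equal(catchabilityTrajectory(300, p), 0.1729, tolerance = 1e-3)
  expect_equal(catchabilityTrajectory(c(0, 50, 100), p), rep(1e-5, 3))
  expect_error(catchabilityTrajectory(-1, p), "invalid")
  expect_error(fishingProtocol(dtDays = 7), "divide")
})

test_that("a step with q = 0 reduces to the pure ecology step", {
  sp <- spunState(npp = 1500, temperature = 10, years = 100, nBins = 15)
  dt <- 30 * 86400
  s0 <- stepCell(sp$state, 1500, 10, sp$model, q = 0, dt = dt)
  # effort at the floor with unprofitable q: same trajectory to 1e-10
  sFloor <- stepCell(sp$state, 1500, 10, sp$model, q = 1e-5, dt = dt)
  for (k in 1:3) {
    expect_equal(s0$harvest[k, 1], 0)
    expect_equal(sFloor$state$f[[k]], s0$state$f[[k]], tolerance = 1e-10)
  }
})

test_that("zero primary production starves the ecosystem", {
  # single fast-turnover group so decay is visible within decades
  mod <- fisheryModel(groups = list(sizeGroup("small", 30)), nBins = 12)
  fc <- forcing(npp = 0, temperature = 10)
  pr <- fishingProtocol(spinupYears = 50, rampYears = 0, dtDays = 30)
  res <- runCell(fc, mod, pr)
  tot <- annualTotals(res)
  expect_equal(max(tot$harvest), 0)
  expect_lt(tot$biomass[50], tot$biomass[1] * 0.05)
  expect_true(all(diff(tot$biomass) < 0))
})

test_that("grid runs are cell-independent and area-aggregated", {
  mod <- tinyModel(nBins = 12)
  fc4 <- syntheticForcing(4, nppRange = c(600, 2400), tRange = c(5, 25),
                          seed = 5, cellArea = 1e12)
  pr <- fishingProtocol(spinupYears = 30, rampYears = 30, dtDays = 30)
  res <- runGrid(fc4, mod, pr)
  # single-cell forcing reproduces column 1 of the grid run
  fc1 <- forcing(npp = fc4@npp[, 1, drop = FALSE],
                 temperature = fc4@temperature[, 1, drop = FALSE],
                 area = fc4@area[1], lme = fc4@lme[1])
  res1 <- runCell(fc1, mod, pr)
  expect_equal(res1@biomass[, , 1], res@biomass[, , 1], tolerance = 1e-12)
  expect_equal(res1@harvest[, , 1], res@harvest[, , 1], tolerance = 1e-12)
  # permuting cells leaves per-cell results and aggregates unchanged
  perm <- c(3, 1, 4, 2)
  fcP <- forcing(fc4@npp[, perm, drop = FALSE],
                 fc4@temperature[, perm, drop = FALSE],
                 area = fc4@area[perm], lme = fc4@lme[perm])
  resP <- runGrid(fcP, mod, pr)
  expect_equal(resP@biomass[, , 2], res@biomass[, , 1], tolerance = 1e-12)
  expect_equal(annualTotals(resP)$harvest, annualTotals(res)$harvest,
               tolerance = 1e-12)
  expect_error(runCell(fc4, mod, pr), "single-cell")
})

test_that("equilibrium peak harvest is non-decreasing in NPP", {
  mod <- tinyModel(nBins = 12)
  fc4 <- forcing(npp = c(500, 1000, 2000, 3000),
                 temperature = rep(10, 4), area = 1)
  pr <- fishingProtocol(spinupYears = 40, rampYears = 120, dtDays = 30)
  res <- runGrid(fc4, mod, pr)
  hCell <- apply(res@harvest, c(1, 3), sum)
  peaks <- apply(hCell, 2, max)
  expect_true(all(diff(peaks) >= 0))
  # the peak falls strictly inside the ramp window
  pk <- detectPeak(rowSums(hCell))
  expect_gt(pk$year, 41)
  expect_lt(pk$year, 160)
})

test_that("detectPeak finds the earliest maximum", {
  expect_equal(detectPeak(c(1, 3, 2)), list(year = 2L, value = 3))
  expect_equal(detectPeak(rep(4, 7))$year, 1L)
  expect_equal(detectPeak(numeric(3)), list(year = 1L, value = 0))
  expect_error(detectPeak(numeric(0)), "empty")
})

test_that("synthetic forcing is seeded, bounded and labelled", {
  f1 <- syntheticForcing(16, seed = 9)
  f2 <- syntheticForcing(16, seed = 9)
  expect_identical(f1@npp, f2@npp)
  expect_identical(f1@temperature, f2@temperature)
  f3 <- syntheticForcing(16, seed = 10)
  expect_false(identical(f3@temperature, f1@temperature))
  expect_true(all(f1@npp >= 500 & f1@npp <= 3000))
  expect_true(all(f1@temperature >= 0 & f1@temperature <= 30))
  expect_equal(range(f1@npp), c(500, 3000))
  expect_equal(sort(unique(lmeIndex(f1))), 1:8)
  expect_equal(length(cellAreas(f1)), 16)
  # degenerate single cell is constant forcing
  f0 <- syntheticForcing(1, nppRange = c(1000, 1000), tRange = c(10, 10),
                         seed = 1)
  expect_equal(as.vector(f0@npp), 1000)
  # seasonal mode produces a 12-row cyclic climatology within bounds
  fs <- syntheticForcing(4, seed = 2, seasonal = TRUE)
  expect_equal(nrow(fs@npp), 12)
  expect_true(all(fs@npp >= 500 & fs@npp <= 3000))
})

test_that("initial condition is forgotten after spin-up", {
  # warm site so the slow adult modes relax within the run
  mod <- tinyModel(nBins = 12)
  fc <- forcing(npp = 1500, temperature = 28)
  pr <- fishingProtocol(spinupYears = 150, rampYears = 0, dtDays = 30)
  rA <- runCell(fc, mod, pr, state = initialState(mod, 1, fSeed = 1e-6))
  rB <- runCell(fc, mod, pr, state = initialState(mod, 1, fSeed = 1e-4))
  bA <- tail(annualTotals(rA)$biomass, 1)
  bB <- tail(annualTotals(rB)$biomass, 1)
  expect_equal(bA, bB, tolerance = 1e-2)
})

test_that("peak diagnostics aggregate by pseudo-LME at the global peak year", {
  mod <- tinyModel(nBins = 12)
  fc <- syntheticForcing(6, seed = 3, nLME = 3, cellArea = 2e12)
  pr <- fishingProtocol(spinupYears = 30, rampYears = 90, dtDays = 30)
  res <- runGrid(fc, mod, pr)
  pd <- peakDiagnostics(res)
  tot <- annualTotals(res)
  expect_equal(pd$peakYear, which.max(tot$harvest))
  expect_equal(pd$globalPeak, max(tot$harvest))
  expect_equal(sum(pd$lme$peakHarvest), tot$harvest[pd$peakYear],
               tolerance = 1e-12)
  expect_equal(pd$lme$lme, 1:3)
  expect_equal(sum(pd$groupPeak), pd$globalPeak, tolerance = 1e-12)
  expect_true(all(pd$lme$area == 2 * 2e12))
})
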