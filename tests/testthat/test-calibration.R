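test_that("prior sampling matches the stated mean/SD parameterisation", {
  d <- samplePriors(10000, seed = 1)
  # uniform bounds are mean +/- sqrt(3) SD
  expect_gte(min(d$alphaTe), 0.13 - sqrt(3) * 0.04)
  expect_lte(max(d$alphaTe), 0.13 + sqrt(3) * 0.04)
  expect_equal(range(d$alphaTe), c(0.0607, 0.1993), tolerance = 1e-3)
  expect_gte(min(d$b), 0.70 - sqrt(3) * 0.05)
  expect_lte(max(d$b), 0.70 + sqrt(3) * 0.05)
  # positivity-flagged normals never go non-positive
  expect_true(all(d$A0 > 0 & d$kE > 0 & d$PiStar > 0 & d$sE > 0))
  # derived trophic scaling, never sampled
  expect_equal(d$tau, log(d$alphaTe) / log(d$betaPPMR))
  # sample means reproduce the two-decimal tabulated values: half a printed ULP
  # (0.005) plus 3 Monte Carlo standard errors of a 10^4-draw sample mean
  expect_lt(abs(mean(d$tau) - (-0.25)), 0.005 + 3 * 0.045 / 100)
  expect_lt(abs(mean(d$b) - 0.70), 0.005 + 3 * 0.05 / 100)
  expect_lt(abs(mean(d$zeta1) - 0.55), 0.005 + 3 * 0.57 / 100)
  # determinism
  expect_identical(d, samplePriors(10000, seed = 1))
  bad <- priorTable(); bad$sd[1] <- -1
  expect_error(samplePriors(10, priors = bad), "invalid")
})

test_that("peak harvest estimate is the top-ten-year mean", {
  expect_equal(observedPeakHarvest(1:12), mean(3:12))  # 7.5
  expect_equal(observedPeakHarvest(rep(3.2, 25)), 3.2)
  expect_equal(observedPeakHarvest(c(100, rep(0, 9))), 10)
  expect_equal(observedPeakHarvest(c(5, 1)), 3)  # fewer than 10 years
  expect_error(observedPeakHarvest(numeric(0)), "invalid")
})

test_that("other-group harvest is reallocated proportionally", {
  expect_equal(adjustSizeGroups(2, 1, 1, 4), c(Sa = 4, Ma = 2, La = 2))
  expect_equal(adjustSizeGroups(3, 2, 1, 0), c(Sa = 3, Ma = 2, La = 1))
  expect_equal(adjustSizeGroups(3, 0, 0, 3), c(Sa = 6, Ma = 0, La = 0))
  # total is always preserved
  expect_equal(sum(adjustSizeGroups(7, 2, 0.5, 1.3)), 7 + 2 + 0.5 + 1.3)
  expect_warning(out <- adjustSizeGroups(0, 0, 0, 2), "unallocatable")
  expect_true(all(is.na(out)))
  expect_equal(adjustSizeGroups(0, 0, 0, 0), c(Sa = 0, Ma = 0, La = 0))
})

test_that("the four ensemble constraints apply their printed thresholds", {
  expect_equal(constraintGlobalHarvest(100e12), "pass")
  expect_equal(constraintGlobalHarvest(60e12), "fail-low")
  expect_equal(constraintGlobalHarvest(200e12), "fail-high")
  expect_equal(constraintGlobalHarvest(70e12), "pass")   # closed interval
  expect_equal(constraintGlobalHarvest(150e12), "pass")

  expect_equal(as.character(constraintSizeStructure(50, 20, 10)), "pass")
  expect_equal(as.character(constraintSizeStructure(50, 10, 10)), "fail")
  # 80% boundary is excluded ("less than 80%")
  expect_equal(as.character(constraintSizeStructure(50, 20, 40)), "fail")
  expect_equal(as.character(constraintSizeStructure(50, 20, 39.9)), "pass")
  expect_equal(as.character(constraintSizeStructure(50, 20, 4)), "fail")
  expect_equal(as.character(constraintSizeStructure(0, 1, 1)), "fail")

  expect_equal(as.character(constraintHB(rep(0.2, 8))), "pass")
  expect_equal(as.character(constraintHB(c(rep(0.2, 7), 0.5))), "fail")
  expect_equal(as.character(constraintHB(rep(0.4, 8))), "pass")  # inclusive
  expect_equal(as.character(constraintHB(c(0.1, Inf))), "fail")
})

test_that("correlation scoring is area-specific and scale-aware", {
  areas <- c(1, 2, 4, 8) * 1e12
  obs <- c(1, 2, 3, 4) * areas
  sc <- correlationScore(obs, obs, areas)
  expect_equal(sc$r2, 1)
  expect_equal(sc$rs, 1)
  expect_equal(sc$r2log, 1)
  sc2 <- correlationScore(2 * obs, obs, areas)
  expect_equal(sc2$r2, 1)
  anti <- correlationScore(c(1, 2, 3) * 1e12, c(3, 2, 1) * 1e12,
                           rep(1e12, 3))
  expect_equal(anti$rs, -1)
  # zero variance rejects the member
  expect_true(is.na(correlationScore(rep(5, 4) * areas, obs, areas)$r2))
  # exclusions drop LMEs before scoring
  scEx <- correlationScore(c(obs[1:3], 999), obs, areas,
                           exclude = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(scEx$r2, 1)
  expect_error(correlationScore(1:2, 1:2, 1:2), "at least 3")
})

test_that("ensemble selection filters, ranks and breaks ties deterministically", {
  mk <- function(n) data.frame(
    draw = seq_len(n),
    peakGlobal = 100e12, c1 = "pass", c2 = "pass", c3 = "pass",
    r2 = 0.5, rs = 0.5, r2log = 0.5)
  # all fail constraint 1: empty selection, zero survival at stage 1
  m <- mk(10); m$c1 <- "fail-low"
  sel <- selectEnsemble(m, fraction = 0.1)
  expect_equal(nrow(sel$selected), 0)
  expect_equal(sel$stages$fraction[1], 0)
  # ranking keeps the requested fraction of the TOTAL
  m <- mk(100); m$r2 <- seq(0.99, 0, length.out = 100)
  sel <- selectEnsemble(m, fraction = 0.05)
  expect_equal(nrow(sel$selected), 5)
  expect_equal(sel$selected$draw, 1:5)
  # tie at the cutoff: earlier draw id wins
  m <- mk(4); m$r2 <- c(0.9, 0.5, 0.5, 0.2)
  sel <- selectEnsemble(m, fraction = 0.5)
  expect_equal(sel$selected$draw, c(1, 2))
  # constraint flags commute: filtering order cannot change membership
  m <- mk(50)
  m$c1 <- sample(c("pass", "fail-low"), 50, TRUE)
  m$c2 <- sample(c("pass", "fail"), 50, TRUE)
  m$c3 <- sample(c("pass", "fail"), 50, TRUE)
  keep1 <- m$draw[m$c1 == "pass" & m$c2 == "pass" & m$c3 == "pass"]
  keep2 <- m$draw[m$c3 == "pass" & m$c1 == "pass" & m$c2 == "pass"]
  expect_equal(keep1, keep2)
  expect_true(all(selectEnsemble(m, 1)$selected$draw %in% keep1))
})

test_that("two-sample KS comparison matches the ECDF enumeration", {
  same <- ksCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ksCompare(1:3, 101:104)$D, 1)
  # max ECDF gap of {1,2,3} vs {1,2,3,4} is 1/4 (just below x = 4)
  expect_equal(ksCompare(c(1, 2, 3), c(1, 2, 3, 4))$D, 0.25)
  expect_error(ksCompare(numeric(0), 1:3), "invalid")
})

test_that("synthetic observations reproduce the truth run when noiseless", {
  fc <- syntheticForcing(4, seed = 21, nLME = 4, cellArea = 1e12)
  pr <- fishingProtocol(spinupYears = 20, rampYears = 60, dtDays = 45)
  pt <- priorTable()
  truth <- as.data.frame(as.list(setNames(pt$mean, pt$param)))
  truth$draw <- 0
  obs0 <- generateSyntheticObservations(truth, fc, pr, nBins = 10,
                                        noiseSd = 0, seed = 5)
  tp <- attr(obs0, "truthPeak")
  expect_equal(obs0$peakHarvest, tp$lme$peakHarvest)
  expect_equal(obs0$lme, 1:4)
  obsA <- generateSyntheticObservations(truth, fc, pr, nBins = 10,
                                        noiseSd = 0.3, seed = 7)
  obsB <- generateSyntheticObservations(truth, fc, pr, nBins = 10,
                                        noiseSd = 0.3, seed = 7)
  expect_identical(obsA$peakHarvest, obsB$peakHarvest)
  expect_false(identical(obsA$peakHarvest, obs0$peakHarvest))
  # lognormal factor-of-two scale noise stays within a factor of ~4
  ratio <- obsA$peakHarvest / obs0$peakHarvest
  expect_true(all(ratio > 1 / 16 & ratio < 16))
})

test_that("calibration report summarises optimised vs non-optimised draws", {
  d <- samplePriors(400, seed = 3)
  sel <- d$draw[d$zeta1 < stats::quantile(d$zeta1, 0.1)]
  rep <- calibrationReport(d, sel, params = c("zeta1", "b"))
  expect_equal(rep$param, c("zeta1", "b"))
  expect_lt(rep$meanOpt[1], rep$meanNO[1])    # construction: low-zeta subset
  expect_lt(rep$ksP[1], 1e-6)                 # strongly shifted
  expect_gt(rep$ksP[2], 0.01)                 # b untouched by the selection
  expect_error(calibrationReport(d, integer(0)), "invalid")
})

test_that("LME metadata encodes the exclusion and reference sets", {
  meta <- lmeMetadata()
  expect_equal(nrow(meta), 66)
  expect_equal(sum(meta$excluded), 11)
  expect_equal(sum(meta$refHB), 8)
  expect_true(meta$excluded[meta$name == "Black Sea"])
  expect_true(all(c("East Bering Sea", "North Sea", "Baltic Sea") %in%
                    meta$name[meta$refHB]))
  expect_false(any(meta$excluded & meta$refHB))
})

test_that("observed harvest tables aggregate reconstruction-style CSVs", {
  tf <- tempfile(fileext = ".csv")
  rows <- expand.grid(lme = c(22, 62), year = 1980:1999,
                      sizeGroup = c("S", "M", "L", "O"))
  rows$harvest <- 10 + rows$year - 1980   # tonnes, increasing
  write.csv(rows, tf, row.names = FALSE)
  areas <- data.frame(lme = c(22, 62), area = c(6e11, 4e11))
  obs <- readObservedHarvest(tf, areas)
  expect_equal(nrow(obs), 2)
  # annual total = 4 groups x harvest; top-10 mean in grams
  expect_equal(obs$peakHarvest[1], mean(4 * (20:29)) * 1e6)
  # equal group shares after O reallocation: each a third of the peak
  expect_equal(obs$Sa[1], obs$peakHarvest[1] / 3, tolerance = 1e-12)
  expect_false(obs$excluded[obs$lme == 22])
  expect_true(obs$excluded[obs$lme == 62])   # Black Sea
  expect_true(obs$refHB[obs$lme == 22])      # North Sea
})
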