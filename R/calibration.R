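#' Monte Carlo prior specification
#'
#' The sampling distribution of each uncertain parameter: family (normal or
#' uniform), mean and standard deviation, and whether the parameter is
#' physically constrained to be positive (normals are then resampled until
#' positive). Uniform distributions are parameterised by mean and SD; their
#' bounds are `mean +/- sqrt(3) * SD`, which matches the stated moments
#' exactly. The trophic scaling `tau = log(alphaTe)/log(betaPPMR)` is
#' derived per draw, never sampled.
#'
#' The growth constant `A0` prior is N(4.46, 0.50) in units of
#' g^(1-b) yr^-1 (the scale on which ensemble means of ~4.4 are reported);
#' override via the `mean`/`sd` columns if a different convention is wanted.
#'
#' @return data.frame with columns `param`, `family` ("normal"/"uniform"),
#'   `mean`, `sd`, `positive`.
#' @examples
#' priorTable()
#' @export
priorTable <- function() {
  data.frame(
    param = c("omegaA", "omegaLambda", "b", "A0", "alphaTe", "betaPPMR",
              "kE", "PiStar", "zeta1", "h", "sE", "eTheta", "cSigma"),
    family = c("normal", "normal", "uniform", "normal", "uniform",
               "uniform", "normal", "normal", "normal", "normal",
               "uniform", "uniform", "uniform"),
    mean = c(0.45, 0.45, 0.70, 4.46, 0.13, 5000,
             0.0631, 0.37, 0.55, 0.54, 0.025, 1, 18),
    sd = c(0.09, 0.09, 0.05, 0.50, 0.04, 2500,
           0.009, 0.10, 0.57, 0.09, 0.014, 0.288, 3.46),
    positive = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                 TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Sample parameter draws from the priors
#'
#' Uniforms are sampled on `mean +/- sqrt(3) * sd`; normals are resampled
#' until positive where flagged. The derived trophic scaling `tau` is
#' appended per draw.
#'
#' @param n number of draws (>= 1).
#' @param priors a prior specification, default [priorTable()].
#' @param seed integer seed for reproducible draw matrices.
#' @return data.frame with a `draw` id column, one column per parameter,
#'   and `tau`.
#' @examples
#' d <- samplePriors(1000, seed = 1)
#' mean(d$tau) # about -0.25
#' @export
samplePriors <- function(n, priors = priorTable(), seed = NULL) {
  if (n < 1) stop("invalid argument: n must be >= 1")
  if (any(priors$sd < 0)) stop("invalid argument: prior sd must be >= 0")
  .withSeed(seed, {
    cols <- lapply(seq_len(nrow(priors)), function(i) {
      p <- priors[i, ]
      if (p$family == "uniform") {
        lo <- p$mean - sqrt(3) * p$sd
        hi <- p$mean + sqrt(3) * p$sd
        if (p$positive && lo < 0)
          stop("invalid argument: uniform prior for ", p$param,
               " extends below zero")
        runif(n, lo, hi)
      } else if (p$family == "normal") {
        x <- rnorm(n, p$mean, p$sd)
        if (p$positive) {
          while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), p$mean, p$sd)
        }
        x
      } else stop("invalid argument: unknown family '", p$family, "'")
    })
    d <- as.data.frame(setNames(cols, priors$param))
    d$tau <- log(d$alphaTe) / log(d$betaPPMR)
    cbind(draw = seq_len(n), d)
  })
}

#' Peak harvest estimate from an annual series
#'
#' The mean of the `min(10, length)` largest annual harvests: a multi-year
#' peak estimate robust to single-year spikes in catch reconstructions.
#'
#' @param series annual harvest values (>= 1 year).
#' @return peak harvest estimate, same units as `series`.
#' @examples
#' observedPeakHarvest(1:12) # 7.5
#' @export
observedPeakHarvest <- function(series) {
  if (length(series) < 1) stop("invalid argument: empty series")
  k <- min(10L, length(series))
  mean(sort(series, decreasing = TRUE)[seq_len(k)])
}

#' Reallocate the "other" harvest over the size groups
#'
#' Observed harvests whose size class is ambiguous ("other", O) are assumed
#' to follow the size distribution of the identified groups:
#' `Ga = G * (S + M + L + O) / (S + M + L)`, so the adjusted groups sum to
#' the full harvest.
#'
#' @param S,M,L harvests attributed to the small, medium, large groups.
#' @param O harvest of ambiguous size class.
#' @return named numeric `c(Sa, Ma, La)`; `NA`s with a warning if
#'   `S + M + L == 0` while `O > 0` (unallocatable).
#' @examples
#' adjustSizeGroups(2, 1, 1, 4) # 4 2 2
#' @export
adjustSizeGroups <- function(S, M, L, O) {
  if (any(c(S, M, L, O) < 0)) stop("invalid argument: harvests must be >= 0")
  tot <- S + M + L
  if (tot == 0) {
    if (O > 0) {
      warning("unallocatable: other-group harvest with no identified groups")
      return(c(Sa = NA_real_, Ma = NA_real_, La = NA_real_))
    }
    return(c(Sa = 0, Ma = 0, La = 0))
  }
  fac <- (tot + O) / tot
  c(Sa = S * fac, Ma = M * fac, La = L * fac)
}

#' Constraint 1: global peak harvest window
#'
#' Pass iff the global peak harvest lies in the closed window, by default
#' 70-150 x 10^12 g wB yr^-1 (a generous uncertainty band around the
#' reconstructed global peak). For synthetic-observation experiments pass a
#' window scaled to the synthetic domain, e.g. 0.7-1.5 times the total
#' observed peak.
#'
#' @param peak global peak harvest (g wB yr^-1).
#' @param window closed interval `c(lo, hi)`.
#' @return "pass", "fail-low" or "fail-high".
#' @export
constraintGlobalHarvest <- function(peak, window = c(70e12, 150e12)) {
  if (peak < window[1]) "fail-low"
  else if (peak > window[2]) "fail-high"
  else "pass"
}

#' Constraint 2: size structure of the peak harvest
#'
#' Pass iff the medium-group harvest is at least 30% of the small-group
#' harvest and the large-group harvest is at least 10% but strictly less
#' than 80% of it, so no single group unrealistically dominates.
#'
#' @param Sa,Ma,La adjusted peak harvests of the three groups.
#' @return "pass" or "fail" (with a `reason` attribute on failure).
#' @export
constraintSizeStructure <- function(Sa, Ma, La) {
  if (Sa <= 0)
    return(structure("fail", reason = "no small-group harvest"))
  if (Ma / Sa < 0.3)
    return(structure("fail", reason = "medium/small ratio below 0.3"))
  if (La / Sa < 0.1 || La / Sa >= 0.8)
    return(structure("fail", reason = "large/small ratio outside [0.1, 0.8)"))
  "pass"
}

#' Constraint 3: harvest-to-biomass ratio of reference ecosystems
#'
#' Pass iff H:B at the peak-harvest state is at most `cap` (default
#' 0.4 yr^-1, the upper end observed across well-assessed ecosystems) in
#' every reference LME. The boundary is inclusive. Zero biomass at a
#' reference LME fails.
#'
#' @param hb H:B (yr^-1) at the reference LMEs.
#' @param cap maximum admissible H:B (yr^-1).
#' @return "pass" or "fail".
#' @export
constraintHB <- function(hb, cap = 0.4) {
  if (any(!is.finite(hb)))
    return(structure("fail", reason = "zero biomass at a reference LME"))
  if (all(hb <= cap)) "pass" else "fail"
}

#' Correlation of simulated and observed per-LME peak harvests
#'
#' Converts both to area-specific harvests (per m^2) over the non-excluded
#' LMEs and reports the squared Pearson correlation, Spearman's rank
#' correlation, and the squared Pearson correlation of the log10-transformed
#' values.
#'
#' @param sim simulated per-LME peak harvests (g wB yr^-1).
#' @param obs observed per-LME peak harvests (g wB yr^-1), same order.
#' @param areas LME areas (m^2).
#' @param exclude logical (or index) vector of LMEs to drop.
#' @return list `r2`, `rs`, `r2log`; all NA (member rejected) if fewer than
#'   3 usable LMEs or either vector has zero variance.
#' @export
correlationScore <- function(sim, obs, areas, exclude = NULL) {
  keep <- rep(TRUE, length(sim))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) keep <- !exclude else keep[exclude] <- FALSE
  }
  x <- sim[keep] / areas[keep]
  y <- obs[keep] / areas[keep]
  if (length(x) < 3)
    stop("invalid argument: need at least 3 non-excluded LMEs")
  bad <- list(r2 = NA_real_, rs = NA_real_, r2log = NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(bad)
  r <- cor(x, y)
  rs <- cor(x, y, method = "spearman")
  pos <- x > 0 & y > 0
  r2log <- if (sum(pos) >= 3 && stats::sd(log10(x[pos])) > 0 &&
               stats::sd(log10(y[pos])) > 0)
    cor(log10(x[pos]), log10(y[pos]))^2 else NA_real_
  list(r2 = r^2, rs = rs, r2log = r2log)
}

# eco/econ/groups for one draw, overriding the base parameter objects
.modelFromDraw <- function(draw, baseEco, baseEcon, mInf, mAlphaFrac,
                           dTheta, nBins, m0) {
  eco <- ecoParams(
    A0 = draw$A0, b = draw$b, omegaA = draw$omegaA,
    omegaLambda = draw$omegaLambda, zeta1 = draw$zeta1,
    mortalityScale = baseEco@mortalityScale, h = draw$h,
    alphaTe = draw$alphaTe, betaPPMR = draw$betaPPMR, kE = draw$kE,
    PiStar = draw$PiStar, sE = draw$sE,
    delta1 = baseEco@delta1, delta2 = baseEco@delta2,
    phiC = baseEco@phiC, Tref = baseEco@Tref,
    wetBPerC = baseEco@wetBPerC, mPhyS = baseEco@mPhyS,
    mPhyL = baseEco@mPhyL, nppRef = baseEco@nppRef,
    cRepro = baseEco@cRepro, xiPCapFactor = baseEco@xiPCapFactor)
  econ <- econParams(price = baseEcon@price,
                     costPerEffort = baseEcon@costPerEffort,
                     kappaE = baseEcon@kappaE, cSigma = draw$cSigma,
                     eFloor = baseEcon@eFloor)
  groups <- defaultGroups(mInf = mInf, mAlphaFrac = mAlphaFrac,
                          dTheta = dTheta, eTheta = draw$eTheta)
  fisheryModel(eco, econ, groups, nBins = nBins, m0 = m0)
}

#' Run a Monte Carlo ensemble of transient simulations
#'
#' Runs the spin-up + catchability-ramp experiment for every parameter draw
#' and extracts the peak-harvest diagnostics the calibration constraints
#' need. Each draw overrides the sampled ecological parameters, the
#' selectivity slope `cSigma` and the selectivity mass scaling `eTheta`;
#' everything else comes from the base parameter objects.
#'
#' @param draws data.frame from [samplePriors()].
#' @param forcing a [Forcing-class] (cells partitioned into pseudo-LMEs).
#' @param protocol a [FishingProtocol-class].
#' @param baseEco,baseEcon base parameter objects for the non-sampled
#'   fields.
#' @param mInf,mAlphaFrac,dTheta community definition (see
#'   [defaultGroups()]).
#' @param nBins bins per group; ensembles typically use a reduced grid.
#' @param m0 recruit mass (g).
#' @param refLME pseudo-LME ids whose H:B is constrained; default all.
#' @param progress print a dot every 10 members?
#' @return data.frame, one row per draw: `draw`, `peakGlobal`
#'   (g wB yr^-1), `peakYear`, adjusted group peaks `Sa`, `Ma`, `La`,
#'   `hbMax` (max H:B over reference LMEs, yr^-1), constraint flags `c1`,
#'   `c2`, `c3`. Per-LME peak harvests are attached as attribute
#'   `lmePeaks` (draws x LMEs), LME areas as `lmeAreas`, ids as `lmeIds`.
#' @export
runEnsemble <- function(draws, forcing, protocol,
                        baseEco = ecoParams(), baseEcon = econParams(),
                        mInf = c(30, 1e3, 1e5), mAlphaFrac = 0.25,
                        dTheta = c(1, 0.5, 0.25), nBins = 20L, m0 = 0.01,
                        refLME = NULL, progress = FALSE) {
  n <- nrow(draws)
  ids <- sort(unique(lmeIndex(forcing)))
  lmePeaks <- matrix(NA_real_, n, length(ids),
                     dimnames = list(NULL, paste0("lme", ids)))
  lmeAreas <- NULL
  out <- vector("list", n)
  if (is.null(refLME)) refLME <- ids
  for (i in seq_len(n)) {
    d <- draws[i, ]
    model <- .modelFromDraw(d, baseEco, baseEcon, mInf, mAlphaFrac,
                            dTheta, nBins, m0)
    res <- runGrid(forcing, model, protocol)
    pk <- peakDiagnostics(res)
    lmePeaks[i, ] <- pk$lme$peakHarvest
    lmeAreas <- pk$lme$area
    adj <- adjustSizeGroups(pk$groupPeak[1], pk$groupPeak[2],
                            pk$groupPeak[3], 0)
    hbRef <- pk$lme$hb[pk$lme$lme %in% refLME]
    out[[i]] <- data.frame(
      draw = d$draw, peakGlobal = pk$globalPeak, peakYear = pk$peakYear,
      Sa = adj[["Sa"]], Ma = adj[["Ma"]], La = adj[["La"]],
      hbMax = max(hbRef))
    if (progress && i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  members <- do.call(rbind, out)
  attr(members, "lmePeaks") <- lmePeaks
  attr(members, "lmeAreas") <- lmeAreas
  attr(members, "lmeIds") <- ids
  members
}

#' Score ensemble members against observed per-LME peak harvests
#'
#' Adds the constraint flags and correlation scores to the output of
#' [runEnsemble()].
#'
#' @param members output of [runEnsemble()].
#' @param obs observed LME table: data.frame with columns `lme`, `area`
#'   (m^2), `peakHarvest` (g wB yr^-1), and optionally `excluded`.
#' @param window constraint-1 window (g wB yr^-1); default the real-data
#'   window `c(70e12, 150e12)`. Pass `relativeWindow = TRUE` to use
#'   `c(0.7, 1.5)` times the total observed peak instead (synthetic mode).
#' @param relativeWindow logical, see `window`.
#' @param hbCap constraint-3 H:B cap (yr^-1).
#' @return `members` with added columns `c1`, `c2`, `c3`, `r2`, `rs`,
#'   `r2log`.
#' @export
scoreEnsemble <- function(members, obs, window = c(70e12, 150e12),
                          relativeWindow = FALSE, hbCap = 0.4) {
  ids <- attr(members, "lmeIds")
  lmePeaks <- attr(members, "lmePeaks")
  o <- obs[match(ids, obs$lme), ]
  excl <- if ("excluded" %in% names(o)) o$excluded else
    rep(FALSE, nrow(o))
  if (relativeWindow)
    window <- c(0.7, 1.5) * sum(o$peakHarvest[!excl])
  n <- nrow(members)
  members$c1 <- members$c2 <- members$c3 <- NA_character_
  members$r2 <- members$rs <- members$r2log <- NA_real_
  for (i in seq_len(n)) {
    members$c1[i] <- constraintGlobalHarvest(members$peakGlobal[i], window)
    members$c2[i] <- as.character(
      constraintSizeStructure(members$Sa[i], members$Ma[i], members$La[i]))
    members$c3[i] <- as.character(constraintHB(members$hbMax[i], hbCap))
    sc <- correlationScore(lmePeaks[i, ], o$peakHarvest, o$area,
                           exclude = excl)
    members$r2[i] <- sc$r2
    members$rs[i] <- sc$rs
    members$r2log[i] <- sc$r2log
  }
  members
}

#' Select the optimised ensemble
#'
#' Applies the three range constraints in sequence, then ranks the
#' survivors by Pearson r^2 against the observed per-LME peak harvests and
#' keeps the best `fraction` of the TOTAL number of draws (ties broken by
#' earlier draw id). Members with undefined correlation are rejected.
#'
#' @param members scored ensemble from [scoreEnsemble()].
#' @param fraction fraction of all draws to keep. Default 0.01.
#' @return list: `selected` (the kept rows, ranked), `stages` (data.frame
#'   of per-stage survivor counts and fractions).
#' @export
selectEnsemble <- function(members, fraction = 0.01) {
  n <- nrow(members)
  s1 <- members[members$c1 == "pass", ]
  s2 <- s1[s1$c2 == "pass", ]
  s3 <- s2[s2$c3 == "pass", ]
  s4 <- s3[!is.na(s3$r2), ]
  stages <- data.frame(
    stage = c("global-harvest", "size-structure", "hb-ratio", "scored"),
    survivors = c(nrow(s1), nrow(s2), nrow(s3), nrow(s4)),
    fraction = c(nrow(s1), nrow(s2), nrow(s3), nrow(s4)) / n)
  nKeep <- min(nrow(s4), max(0L, round(fraction * n)))
  s4 <- s4[order(-s4$r2, s4$draw), ]
  list(selected = utils::head(s4, nKeep), stages = stages)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D statistic (maximum ECDF gap) and asymptotic p-value comparing the
#' optimised and non-optimised values of one parameter.
#'
#' @param optimized,nonOptimized numeric samples.
#' @return list `D`, `p`.
#' @examples
#' ksCompare(c(1, 2, 3), c(1, 2, 3, 4))$D # 0.25
#' @export
ksCompare <- function(optimized, nonOptimized) {
  if (!length(optimized) || !length(nonOptimized))
    stop("invalid argument: both samples must be non-empty")
  k <- suppressWarnings(ks.test(optimized, nonOptimized))
  list(D = unname(k$statistic), p = unname(k$p.value))
}

#' Parameter-shift report for a calibrated ensemble
#'
#' Per-parameter means and standard deviations of the optimised and
#' non-optimised subsets, with the two-sample KS p-value: the standard
#' summary of which parameters the observational constraints actually
#' narrowed.
#'
#' @param draws the full draw table from [samplePriors()].
#' @param selectedDraws draw ids of the optimised subset.
#' @param params parameters to report; default all sampled plus `tau`.
#' @return data.frame: `param`, `meanOpt`, `meanNO`, `sdOpt`, `sdNO`, `D`,
#'   `ksP`.
#' @export
calibrationReport <- function(draws, selectedDraws,
                              params = setdiff(names(draws), "draw")) {
  sel <- draws$draw %in% selectedDraws
  if (!any(sel) || all(sel))
    stop("invalid argument: need non-empty optimised and non-optimised sets")
  rows <- lapply(params, function(p) {
    ks <- ksCompare(draws[[p]][sel], draws[[p]][!sel])
    data.frame(param = p,
               meanOpt = mean(draws[[p]][sel]),
               meanNO = mean(draws[[p]][!sel]),
               sdOpt = stats::sd(draws[[p]][sel]),
               sdNO = stats::sd(draws[[p]][!sel]),
               D = ks$D, ksP = ks$p)
  })
  do.call(rbind, rows)
}

#' Synthetic observed-LME table from a known-truth run
#'
#' Runs the model at the truth parameters and perturbs the per-pseudo-LME
#' peak harvests with lognormal noise (`sd` in log10 units; the default 0.3
#' emulates catch-reconstruction uncertainties on the order of a factor of
#' two). Enables parameter-recovery testing of the calibration pipeline
#' without any real observational database.
#'
#' @param truth a one-row data.frame of truth parameters (the columns of
#'   [samplePriors()] output).
#' @param forcing,protocol,baseEco,baseEcon,mInf,mAlphaFrac,dTheta,nBins,m0
#'   as in [runEnsemble()].
#' @param noiseSd lognormal noise SD in log10 units. 0 gives exact truth
#'   peaks.
#' @param seed integer seed for the noise.
#' @return data.frame: `lme`, `area` (m^2), `peakHarvest` (g wB yr^-1),
#'   `excluded` (all FALSE), `refHB` (all TRUE). The truth run's
#'   peak diagnostics are attached as attribute `truthPeak`.
#' @export
generateSyntheticObservations <- function(truth, forcing, protocol,
                                          baseEco = ecoParams(),
                                          baseEcon = econParams(),
                                          mInf = c(30, 1e3, 1e5),
                                          mAlphaFrac = 0.25,
                                          dTheta = c(1, 0.5, 0.25),
                                          nBins = 20L, m0 = 0.01,
                                          noiseSd = 0.3, seed = NULL) {
  model <- .modelFromDraw(truth, baseEco, baseEcon, mInf, mAlphaFrac,
                          dTheta, nBins, m0)
  res <- runGrid(forcing, model, protocol)
  pk <- peakDiagnostics(res)
  obs <- .withSeed(seed, {
    noise <- 10^rnorm(nrow(pk$lme), 0, noiseSd)
    data.frame(lme = pk$lme$lme, area = pk$lme$area,
               peakHarvest = pk$lme$peakHarvest * noise,
               excluded = FALSE, refHB = TRUE)
  })
  attr(obs, "truthPeak") <- pk
  obs
}

#' Large Marine Ecosystem metadata
#'
#' The 66 standard LME numbers and names, with the exclusion flag for the
#' 11 LMEs left out of calibration in real-data mode (10 high-latitude
#' systems with biased satellite NPP, plus the Black Sea inland system) and
#' the flag for the 8 well-assessed reference LMEs whose H:B constrains the
#' ensemble.
#'
#' @return data.frame: `lme`, `name`, `excluded`, `refHB`.
#' @export
lmeMetadata <- function() {
  path <- system.file("extdata", "lme_metadata.csv", package = "openfish")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read an observed harvest table (reconstruction-style CSV)
#'
#' Expects long-format columns `lme`, `year`, `sizeGroup` (values S, M, L,
#' O) and `harvest` (tonnes yr^-1), plus an LME area table. Computes, per
#' LME: the peak harvest (top-10-year mean of the annual totals, converted
#' to g wB yr^-1) and the size-group shares adjusted for the O fraction.
#' Exclusion flags from [lmeMetadata()] are applied.
#'
#' @param path CSV path.
#' @param areas data.frame with columns `lme`, `area` (m^2).
#' @return data.frame: `lme`, `area`, `peakHarvest` (g wB yr^-1), `Sa`,
#'   `Ma`, `La` (g wB yr^-1 at the peak, adjusted), `excluded`, `refHB`.
#' @export
readObservedHarvest <- function(path, areas) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("lme", "year", "sizeGroup", "harvest")
  if (!all(need %in% names(d)))
    stop("invalid argument: observed table must have columns ",
         paste(need, collapse = ", "))
  meta <- lmeMetadata()
  out <- lapply(sort(unique(d$lme)), function(l) {
    dl <- d[d$lme == l, ]
    annual <- tapply(dl$harvest, dl$year, sum) * 1e6   # tonnes -> g
    byGroup <- tapply(dl$harvest, dl$sizeGroup, sum) * 1e6
    gg <- function(g) if (g %in% names(byGroup)) byGroup[[g]] else 0
    adj <- adjustSizeGroups(gg("S"), gg("M"), gg("L"), gg("O"))
    share <- if (all(is.finite(adj)) && sum(adj) > 0)
      adj / sum(adj) else c(Sa = NA, Ma = NA, La = NA)
    pk <- observedPeakHarvest(as.numeric(annual))
    m <- meta[meta$lme == l, ]
    data.frame(lme = l,
               area = areas$area[match(l, areas$lme)],
               peakHarvest = pk,
               Sa = pk * share[["Sa"]], Ma = pk * share[["Ma"]],
               La = pk * share[["La"]],
               excluded = if (nrow(m)) m$excluded else FALSE,
               refHB = if (nrow(m)) m$refHB else FALSE)
  })
  do.call(rbind, out)
}
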