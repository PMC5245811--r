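#' FishingProtocol: spin-up plus catchability-ramp experiment design
#'
#' The standard transient experiment: spin the ecosystem up for
#' `spinupYears` at a low constant catchability `q0` (negligible harvest),
#' then increase catchability by `rampRate` (fraction) per year for
#' `rampYears`, sweeping the fishery from unprofitable through its peak
#' harvest and into depletion.
#'
#' @slot spinupYears years of constant-q spin-up (>= 0).
#' @slot rampYears years of catchability ramp (>= 0).
#' @slot dtDays timestep in days; must divide the 360-day model year.
#' @slot q0 initial catchability (m^2 W^-1 s^-1).
#' @slot rampRate fractional catchability increase per year.
#'
#' @seealso [fishingProtocol()], [catchabilityTrajectory()]
#' @exportClass FishingProtocol
setClass("FishingProtocol",
  representation(
    spinupYears = "numeric",
    rampYears = "numeric",
    dtDays = "numeric",
    q0 = "numeric",
    rampRate = "numeric"
  )
)

setValidity("FishingProtocol", function(object) {
  msgs <- character()
  if (object@spinupYears < 0 || object@rampYears < 0)
    msgs <- c(msgs, "years must be >= 0")
  if (object@dtDays <= 0 || (.daysPerYear %% object@dtDays) != 0)
    msgs <- c(msgs, "dtDays must be positive and divide the 360-day year")
  if (object@q0 < 0) msgs <- c(msgs, "q0 must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Fishing protocol constructor
#'
#' Defaults reproduce the standard experiment: 100-year spin-up at
#' `q0 = 1e-5 m^2 W^-1 s^-1`, then a 5%-per-year ramp for 200 years, with a
#' 15-day timestep.
#'
#' @param spinupYears,rampYears,dtDays,q0,rampRate see
#'   [FishingProtocol-class].
#' @return a [FishingProtocol-class].
#' @export
fishingProtocol <- function(spinupYears = 100, rampYears = 200, dtDays = 15,
                            q0 = 1e-5, rampRate = 0.05) {
  new("FishingProtocol", spinupYears = spinupYears, rampYears = rampYears,
      dtDays = dtDays, q0 = q0, rampRate = rampRate)
}

setMethod("show", "FishingProtocol", function(object) {
  cat(sprintf(
    "FishingProtocol: %g yr spin-up at q0 = %g, then %g yr ramp at %g%%/yr (dt = %g d)\n",
    object@spinupYears, object@q0, object@rampYears,
    100 * object@rampRate, object@dtDays))
})

#' Catchability trajectory
#'
#' Constant at `q0` through the spin-up, then compounding at `rampRate` per
#' year: `q(t) = q0 (1 + rampRate)^(t - spinupYears)` for
#' `t >= spinupYears`.
#'
#' @param t time since the start of the run (years, >= 0); vectorised.
#' @param protocol a [FishingProtocol-class].
#' @return catchability (m^2 W^-1 s^-1).
#' @examples
#' p <- fishingProtocol()
#' catchabilityTrajectory(c(0, 100, 300), p)
#' @export
catchabilityTrajectory <- function(t, protocol) {
  if (any(t < 0)) stop("invalid argument: t must be >= 0")
  q <- rep(protocol@q0, length(t))
  ramp <- t > protocol@spinupYears
  q[ramp] <- protocol@q0 *
    (1 + protocol@rampRate)^(t[ramp] - protocol@spinupYears)
  q
}

#' Initial state for a run
#'
#' A small uniform seed spectrum (default 1e-5 g wB m^-2 g^-1 in every bin)
#' and all efforts at the floor. The spin-up renders results independent of
#' this choice.
#'
#' @param model a [FisheryModel-class].
#' @param nCells number of cells.
#' @param fSeed seed spectrum level (g wB m^-2 g^-1).
#' @return list with `f` (list of bins x cells matrices, one per group) and
#'   `E` (groups x cells matrix, W m^-2).
#' @export
initialState <- function(model, nCells = 1L, fSeed = 1e-5) {
  K <- nGroups(model)
  list(
    f = lapply(seq_len(K), function(k)
      matrix(fSeed, nBins(model@grids[[k]]), nCells)),
    E = matrix(model@econ@eFloor, K, nCells)
  )
}

# Per-cell environment factors shared by all groups at one time slice.
.envFactors <- function(cache, npp, temp) {
  arrA <- exp((cache$omegaA / .kBoltzmann) *
                (1 / cache$Tref - 1 / (temp + 273.15)))
  arrL <- exp((cache$omegaL / .kBoltzmann) *
                (1 / cache$Tref - 1 / (temp + 273.15)))
  nppWB <- npp / 1000 * cache$wetBPerC / .secondsPerDay
  xLarge <- pmin(pmax(cache$PiStar * (npp / cache$nppRef) /
                        exp(cache$kE * temp), 0), 1)
  logMphi <- (1 - xLarge) * cache$logMphyS + xLarge * cache$logMphyL
  # per-cell amplitude of the production spectrum: NPPwB * mPhi^(-tau)/ln(beta)
  piAmp <- nppWB * exp(-cache$tau * logMphi) / cache$lnBeta
  list(A = cache$A0s * arrA, lambdaC = cache$lambda0 * arrL, piAmp = piAmp)
}

# One coupled step of length dt (s) for all groups and cells.
#
# Growth, mortality, harvest and recruitment rates are frozen at the start
# of the step (they vary smoothly); the advection-decay cascade is then
# integrated EXACTLY bin by bin: each bin obeys df/dt = a - b f with
# a = (upwind inflow)/width and b collecting outflow, dilation and the
# linear sinks, whose exact solution and time average are closed form.
# The time-averaged biomass of a bin feeds the upwind inflow of the next,
# so the sweep is conservative to round-off, unconditionally stable and
# positivity-preserving -- no CFL restriction on the stiff smallest bins.
# Returns the new state plus per-group budget and harvest diagnostics.
.advanceState <- function(state, cache, npp, temp, q, dt) {
  env <- .envFactors(cache, npp, temp)
  K <- cache$K
  nc <- length(npp)
  harvest <- matrix(0, K, nc)      # g wB m^-2 taken over the step
  budgets <- vector("list", K)
  fOut <- vector("list", K)
  Eout <- state$E
  sE2 <- cache$sE / 2
  for (k in seq_len(K)) {
    g <- cache$groups[[k]]
    f <- state$f[[k]]
    nb <- g$nb
    Ek <- state$E[k, ]
    # rate fields frozen at the start of the step
    vb <- outer(g$vbShape, env$A)                      # growth ceiling
    num <- g$phi * outer(g$piShape * g$m, env$piAmp)   # phi * pi * m
    lambda <- outer(g$mhTerm, env$lambdaC)
    qsE <- q * outer(g$sigma, Ek)                      # harvest rate (s^-1)
    selB <- colSums(g$sigma * f * g$w)
    rev <- q * Ek * cache$price * selB
    cost <- cache$cost * Ek
    xiI <- pmin(num / pmax(f, 1e-300), vb)
    gamma <- g$oneMinusPsi * xiI
    repro <- xiI - gamma
    Re <- sE2 * colSums(repro * f * g$wOverM)
    RP <- g$phi * g$pi0Shape * env$piAmp * g$m0
    rec <- ifelse(RP + Re > 0, RP * Re / (RP + Re), 0)
    sink <- lambda + qsE
    # upwind exponential sweep from the recruit bin to the asymptotic bin:
    # bin j obeys df/dt = a - b f with frozen rates; G = (1 - e^-x)/x and
    # H = (1 - G)/x (x = b dt) give its exact end value and time average
    # without dividing by b, so b = 0 needs no special case
    bout <- gamma / g$w
    bout[nb, ] <- 0                    # no outflow past the asymptotic mass
    B <- bout - gamma / g$m + sink
    x <- B * dt
    ebx <- exp(-pmin(x, 700))
    small <- abs(x) < 1e-6
    G <- (1 - ebx) / x
    G[small] <- 1 - x[small] / 2 + x[small]^2 / 6
    H <- (1 - G) / x
    H[small] <- 0.5 - x[small] / 6
    Hdt <- H * dt
    fbar <- f
    inflow <- rec                      # flux through the lower edge
    for (j in seq_len(nb)) {
      aj <- inflow / g$w[j]
      fb <- f[j, ] * G[j, ] + aj * Hdt[j, ]
      f[j, ] <- f[j, ] + (aj - B[j, ] * fb) * dt
      fbar[j, ] <- fb
      inflow <- gamma[j, ] * fb
    }
    dil <- colSums(gamma * fbar * g$wOverM)
    mort <- colSums(lambda * fbar * g$w)
    harv <- colSums(qsE * fbar * g$w)
    f[f < 0] <- 0                            # round-off guard
    if (anyNA(f)) stop("non-finite biomass encountered in group ", k)
    fOut[[k]] <- f
    harvest[k, ] <- harv * dt
    Eout[k, ] <- effortStep(Ek, rev, cost, cache$kappaE, dt, cache$eFloor)
    budgets[[k]] <- list(recruit = rec * dt, dilation = dil * dt,
                         mortality = mort * dt, harvest = harv * dt,
                         revenue = rev, cost = cost)
  }
  list(f = fOut, E = Eout, harvest = harvest, budgets = budgets)
}

#' Advance one cell (or grid) state by one coupled step
#'
#' Applies one timestep of the coupled system: the ecological tendency with
#' recruitment inflow, the harvest sink `-q sigma E f`, and the open-access
#' effort update. Rates are frozen over the step and the advection-decay
#' cascade is integrated exactly bin by bin (an upwind exponential sweep),
#' so biomass stays non-negative for any timestep and the returned budget
#' diagnostics close the mass balance to round-off.
#'
#' @param state a state list from [initialState()] or a previous step.
#' @param npp NPP per cell (mg C m^-2 d^-1).
#' @param temperature temperature per cell (degrees C).
#' @param model a [FisheryModel-class].
#' @param q catchability (m^2 W^-1 s^-1).
#' @param dt timestep (s).
#' @return list: `state` (new state), `harvest` (groups x cells, g wB m^-2
#'   removed during the step), `budgets` (per group: recruit, dilation,
#'   mortality, harvest in g wB m^-2; revenue and cost rates in $ m^-2
#'   s^-1).
#' @export
stepCell <- function(state, npp, temperature, model, q, dt) {
  cache <- .modelCache(model)
  out <- .advanceState(state, cache, npp, temperature, q, dt)
  list(state = list(f = out$f, E = out$E), harvest = out$harvest,
       budgets = out$budgets)
}

#' RunResult: annual output of a transient run
#'
#' Annual series per cell and group from [runGrid()] / [runCell()]:
#' mean total biomass (g wB m^-2), harvest accumulated over the year
#' (g wB m^-2 yr^-1) and mean effort (W m^-2), plus the annual catchability
#' and the cell metadata needed for aggregation.
#'
#' @slot biomass array (year x group x cell), g wB m^-2.
#' @slot harvest array (year x group x cell), g wB m^-2 yr^-1.
#' @slot effort array (year x group x cell), W m^-2.
#' @slot q numeric per year (m^2 W^-1 s^-1, value at the start of the year).
#' @slot area numeric per cell (m^2).
#' @slot lme integer per cell.
#' @slot finalState list: the state at the end of the run.
#'
#' @seealso [annualTotals()], [detectPeak()], [peakDiagnostics()]
#' @exportClass RunResult
setClass("RunResult",
  representation(
    biomass = "array",
    harvest = "array",
    effort = "array",
    q = "numeric",
    area = "numeric",
    lme = "integer",
    finalState = "list"
  )
)

setMethod("show", "RunResult", function(object) {
  tot <- annualTotals(object)
  pk <- detectPeak(tot$harvest)
  cat(sprintf(
    "RunResult: %d yr x %d group(s) x %d cell(s); peak harvest %.3g g wB/yr in year %d\n",
    dim(object@biomass)[1], dim(object@biomass)[2], dim(object@biomass)[3],
    pk$value, pk$year))
})

#' Aggregate a run to annual global totals
#'
#' Sums over groups and area-weights over cells.
#'
#' @param result a [RunResult-class].
#' @return data.frame: `year`, `q`, `biomass` (g wB), `harvest`
#'   (g wB yr^-1), `effort` (W).
#' @export
annualTotals <- function(result) {
  a <- result@area
  byCell <- function(x) apply(x, c(1, 3), sum)   # year x cell, over groups
  data.frame(
    year = seq_len(dim(result@biomass)[1]),
    q = result@q,
    biomass = as.vector(byCell(result@biomass) %*% a),
    harvest = as.vector(byCell(result@harvest) %*% a),
    effort = as.vector(byCell(result@effort) %*% a))
}

# linear interpolation of a cyclic monthly climatology to a step midpoint
.forcingSlice <- function(fc, stepInYear, stepsPerYear) {
  nt <- nrow(fc@npp)
  if (nt == 1L)
    return(list(npp = fc@npp[1, ], temp = fc@temperature[1, ]))
  tm <- (stepInYear - 0.5) / stepsPerYear * nt + 0.5  # month centers at 1..nt
  lower <- floor(tm)
  wgt <- tm - lower
  i0 <- ((lower - 1) %% nt) + 1
  i1 <- (lower %% nt) + 1
  list(npp = (1 - wgt) * fc@npp[i0, ] + wgt * fc@npp[i1, ],
       temp = (1 - wgt) * fc@temperature[i0, ] + wgt * fc@temperature[i1, ])
}

#' Run the coupled model on a forcing grid
#'
#' Steps every cell independently (no movement of fish or vessels between
#' cells) through the spin-up and catchability ramp of `protocol`, cycling
#' the forcing climatology, and aggregates to annual series.
#'
#' @param forcing a [Forcing-class].
#' @param model a [FisheryModel-class].
#' @param protocol a [FishingProtocol-class].
#' @param state optional initial state; default [initialState()].
#' @return a [RunResult-class].
#' @export
runGrid <- function(forcing, model, protocol, state = NULL) {
  stopifnot(is(forcing, "Forcing"), is(model, "FisheryModel"),
            is(protocol, "FishingProtocol"))
  cache <- .modelCache(model)
  nc <- nCells(forcing)
  K <- cache$K
  if (is.null(state)) state <- initialState(model, nc)
  stepsPerYear <- as.integer(.daysPerYear / protocol@dtDays)
  dt <- protocol@dtDays * .secondsPerDay
  nYears <- as.integer(round(protocol@spinupYears + protocol@rampYears))
  biomass <- array(0, c(nYears, K, nc))
  harvest <- array(0, c(nYears, K, nc))
  effort <- array(0, c(nYears, K, nc))
  qYear <- numeric(nYears)
  totB <- function(st) {
    do.call(rbind, lapply(seq_len(K), function(k)
      colSums(st$f[[k]] * cache$groups[[k]]$w)))   # groups x cells
  }
  for (yr in seq_len(nYears)) {
    qYear[yr] <- catchabilityTrajectory(yr - 1, protocol)
    accB <- matrix(0, K, nc)
    accH <- matrix(0, K, nc)
    accE <- matrix(0, K, nc)
    for (s in seq_len(stepsPerYear)) {
      tYears <- (yr - 1) + (s - 1) / stepsPerYear
      q <- catchabilityTrajectory(tYears, protocol)
      sl <- .forcingSlice(forcing, s, stepsPerYear)
      out <- .advanceState(state, cache, sl$npp, sl$temp, q, dt)
      state <- list(f = out$f, E = out$E)
      accB <- accB + totB(state)
      accH <- accH + out$harvest
      accE <- accE + state$E
    }
    biomass[yr, , ] <- accB / stepsPerYear
    harvest[yr, , ] <- accH                 # accumulated over the year
    effort[yr, , ] <- accE / stepsPerYear
  }
  new("RunResult", biomass = biomass, harvest = harvest, effort = effort,
      q = qYear, area = cellAreas(forcing), lme = lmeIndex(forcing),
      finalState = state)
}

#' @describeIn runGrid single-site convenience wrapper; `forcing` must have
#'   exactly one cell.
#' @export
runCell <- function(forcing, model, protocol, state = NULL) {
  if (nCells(forcing) != 1L)
    stop("invalid argument: runCell expects a single-cell forcing")
  runGrid(forcing, model, protocol, state)
}

#' Locate the peak of an annual series
#'
#' @param x numeric series (e.g. annual harvest), or a [RunResult-class]
#'   (its annual global harvest totals are used).
#' @return list with `year` (index of the maximum; earliest on ties) and
#'   `value` (the maximum). An all-zero series gives value 0 in year 1.
#' @examples
#' detectPeak(c(1, 3, 2)) # year 2, value 3
#' @export
detectPeak <- function(x) {
  if (is(x, "RunResult")) x <- annualTotals(x)$harvest
  if (length(x) == 0) stop("invalid argument: empty series")
  i <- which.max(x)
  list(year = as.integer(i), value = x[i])
}

#' Peak-harvest diagnostics of a run
#'
#' Finds the year of maximum global (area-integrated) harvest and reports,
#' at that year: the global peak harvest, per-pseudo-LME harvests, the
#' per-LME harvest-to-biomass ratios, and per-size-group harvests. These
#' are the quantities the calibration constraints act on.
#'
#' @param result a [RunResult-class].
#' @return list: `peakYear`, `globalPeak` (g wB yr^-1), `lme` (data.frame
#'   with lme id, area m^2, peak harvest g wB yr^-1, hb yr^-1), `groupPeak`
#'   (g wB yr^-1 per group).
#' @export
peakDiagnostics <- function(result) {
  a <- result@area
  lme <- result@lme
  hCell <- apply(result@harvest, c(1, 3), sum)   # year x cell, g/m2/yr
  bCell <- apply(result@biomass, c(1, 3), sum)
  hGlob <- as.vector(hCell %*% a)
  pk <- detectPeak(hGlob)
  yr <- pk$year
  ids <- sort(unique(lme))
  hL <- vapply(ids, function(l) sum(hCell[yr, lme == l] * a[lme == l]),
               numeric(1))
  bL <- vapply(ids, function(l) sum(bCell[yr, lme == l] * a[lme == l]),
               numeric(1))
  aL <- vapply(ids, function(l) sum(a[lme == l]), numeric(1))
  groupPeak <- vapply(seq_len(dim(result@harvest)[2]), function(k)
    sum(result@harvest[yr, k, ] * a), numeric(1))
  list(peakYear = yr, globalPeak = pk$value,
       lme = data.frame(lme = ids, area = aL, peakHarvest = hL,
                        hb = ifelse(bL > 0, hL / bL, Inf)),
       groupPeak = groupPeak)
}
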