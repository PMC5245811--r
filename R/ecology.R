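#' Representative phytoplankton mass
#'
#' Reduces the phytoplankton community to a single representative cell mass
#' through an Eppley-type partition between small and large cells: the
#' large-cell fraction `xL = PiStar * (npp / nppRef) / exp(kE * T)`, clipped
#' to [0, 1], interpolates the representative mass geometrically between the
#' small- and large-cell anchor masses. Warmer water (at fixed NPP) therefore
#' gives a smaller representative phytoplankton mass, and more productive
#' water a larger one.
#'
#' @param npp net primary production (mg C m^-2 d^-1), >= 0.
#' @param temperature temperature (degrees C).
#' @param eco an [EcoParams-class].
#' @return representative phytoplankton mass (g), vectorised over inputs.
#' @export
phytoplanktonMass <- function(npp, temperature, eco) {
  if (any(npp < 0)) stop("invalid argument: npp must be >= 0")
  xL <- eco@PiStar * (npp / eco@nppRef) / exp(eco@kE * temperature)
  xL <- pmin(pmax(xL, 0), 1)
  exp((1 - xL) * log(eco@mPhyS) + xL * log(eco@mPhyL))
}

#' Spectrum of energy available from primary production
#'
#' The flux density of biomass energy that trophic transfer from primary
#' production can deliver to consumers of mass `m`:
#' `pi(m) = NPPwB * (m / mPhi)^tau / (m * log(betaPPMR))`, where `NPPwB` is
#' NPP converted to g wet biomass m^-2 s^-1, `mPhi` is the representative
#' phytoplankton mass and `tau = log(alphaTe)/log(betaPPMR)` is the trophic
#' scaling. `pi` is linear in NPP at fixed `mPhi`, and `pi * m` falls as a
#' power law `m^tau` with trophic distance from the phytoplankton.
#'
#' @param npp net primary production (mg C m^-2 d^-1), scalar, >= 0.
#' @param temperature temperature (degrees C), scalar.
#' @param m masses (g) at which to evaluate, or a [MassGrid-class] (its bin
#'   centers are used).
#' @param eco an [EcoParams-class].
#' @return pi (g wB m^-2 g^-1 s^-1) at each mass.
#' @examples
#' eco <- ecoParams()
#' pi1 <- productionSpectrum(1000, 10, massGrid(0.01, 30, 10), eco)
#' @export
productionSpectrum <- function(npp, temperature, m, eco) {
  if (any(npp < 0)) stop("invalid argument: npp must be >= 0")
  if (is(m, "MassGrid")) m <- binCenters(m)
  nppWB <- npp / 1000 * eco@wetBPerC / .secondsPerDay
  mPhi <- phytoplanktonMass(npp, temperature, eco)
  tau <- trophicScaling(eco)
  nppWB * exp(tau * (log(m) - log(mPhi))) / (m * log(eco@betaPPMR))
}

#' Production-limited growth rate per individual
#'
#' Per-capita energy supply from primary production: the flux `phiC * pi * dm`
#' available to a group in a mass bin, divided equally among the `f / m * dm`
#' individuals in it, giving `xiP = phiC * pi * m / f` (g s^-1 per
#' individual). Where the spectrum is empty the per-capita supply is
#' unbounded; it is returned as the configured cap so growth is then limited
#' by physiology.
#'
#' @param pi production spectrum (g wB m^-2 g^-1 s^-1) per bin.
#' @param f biomass spectrum (g wB m^-2 g^-1) per bin, >= 0.
#' @param m bin masses (g).
#' @param phiC fraction of primary production allocated to this group.
#' @param cap value returned where `f` is 0 (g s^-1); also an upper bound
#'   elsewhere to keep near-empty bins finite.
#' @return xiP (g s^-1 per individual) per bin.
#' @export
xiP <- function(pi, f, m, phiC, cap = Inf) {
  if (any(f < 0)) stop("invalid argument: f must be >= 0")
  out <- ifelse(f > 0, phiC * pi * m / f, cap)
  pmin(out, cap)
}

#' Physiological (von Bertalanffy) growth ceiling
#'
#' Maximum rate at which an individual of mass `m` can grow:
#' `xiVB = A m^b - ka m`, with `A = (A0 / secondsPerYear) *`
#' [arrheniusFactor()] and the activity coefficient closed as
#' `ka = A mInf^(b-1)` so that growth ceases exactly at the asymptotic mass.
#'
#' @param m mass (g), in `[m0, mInf]`.
#' @param temperature temperature (degrees C).
#' @param group a [SizeGroup-class].
#' @param eco an [EcoParams-class].
#' @return xiVB (g s^-1 per individual), >= 0 on `[0, mInf]`, 0 at `mInf`.
#' @export
xiVB <- function(m, temperature, group, eco) {
  if (any(m > group@mInf * (1 + 1e-12)))
    stop("invalid argument: m exceeds the asymptotic mass")
  A <- eco@A0 / .secondsPerYear * arrheniusFactor(temperature, eco@omegaA,
                                                  eco@Tref)
  ka <- activityCoefficient(A, eco@b, group@mInf)
  pmax(A * m^eco@b - ka * m, 0)
}

#' Maturity (reproductive) allocation
#'
#' Fraction of realised energy intake allocated to reproduction rather than
#' somatic growth: a sigmoid in log mass centered at the maturity mass,
#' `Psi(m) = [1 + (m / mAlpha)^(-cRepro / delta2)]^-1`, rising from ~0 for
#' juveniles to ~1 near the asymptotic mass.
#'
#' @param m mass (g).
#' @param group a [SizeGroup-class].
#' @param eco an [EcoParams-class].
#' @return Psi in (0, 1).
#' @export
maturityAllocation <- function(m, group, eco) {
  1 / (1 + (m / group@mAlpha)^(-eco@cRepro / eco@delta2))
}

#' Realised growth and reproductive flux
#'
#' The realised energy input `xiI` is the minimum of the production-limited
#' supply and the physiological ceiling; a fraction `Psi(m)` of it goes to
#' reproduction, the rest to somatic growth.
#'
#' @param xiP production-limited rate (g s^-1) per bin.
#' @param xiVB physiological ceiling (g s^-1) per bin.
#' @param m masses (g).
#' @param group a [SizeGroup-class].
#' @param eco an [EcoParams-class].
#' @return list with `gamma` (somatic growth, g s^-1), `repro`
#'   (reproductive allocation, g s^-1), `xiI`, and `limitation` (character,
#'   "production" or "physiology" per bin).
#' @export
realizedGrowth <- function(xiP, xiVB, m, group, eco) {
  if (any(xiP < 0) || any(xiVB < 0))
    stop("invalid argument: growth rates must be >= 0")
  xiI <- pmin(xiP, xiVB)
  psi <- maturityAllocation(m, group, eco)
  list(gamma = (1 - psi) * xiI,
       repro = psi * xiI,
       xiI = xiI,
       limitation = ifelse(xiP <= xiVB, "production", "physiology"))
}

#' Natural mortality rate
#'
#' Empirical allometric mortality, first order in biomass:
#' `Lambda = lambda * m^(-h) * mInf^(h + b - 1)` with the mass-independent
#' factor `lambda = mortalityScale * exp(zeta1) * (A0 / secondsPerYear) *`
#' [arrheniusFactor()] at the mortality activation energy
#' (`mortalityScale` is the proportionality constant of the empirical
#' relationship; see [EcoParams-class]).
#'
#' @param m mass (g).
#' @param temperature temperature (degrees C).
#' @param group a [SizeGroup-class].
#' @param eco an [EcoParams-class].
#' @return Lambda (s^-1) per bin.
#' @export
mortalityRate <- function(m, temperature, group, eco) {
  lambda <- eco@mortalityScale * exp(eco@zeta1) * eco@A0 / .secondsPerYear *
    arrheniusFactor(temperature, eco@omegaLambda, eco@Tref)
  lambda * m^(-eco@h) * group@mInf^(eco@h + eco@b - 1)
}

#' Recruitment boundary flux
#'
#' The biomass flux entering the spectrum at the recruit mass,
#' `f(m0) gamma(m0) = RP * Re / (RP + Re)`: the harmonic mean (limiting
#' factor) of `RP = phiC * pi(m0) * m0`, the potential primary-production
#' flux into juveniles, and `Re = (sE / 2) * integral(Psi xiI f / m dm)`,
#' the egg production of the mature stock surviving to recruit size (the
#' factor 1/2 is the female fraction).
#'
#' @param f biomass spectrum per bin (g wB m^-2 g^-1).
#' @param pi0 production spectrum evaluated at the recruit mass `m0`
#'   (g wB m^-2 g^-1 s^-1), e.g. `productionSpectrum(npp, T, m0, eco)`.
#' @param repro reproductive allocation `Psi * xiI` per bin (g s^-1), as
#'   returned by [realizedGrowth()].
#' @param grid the group's [MassGrid-class].
#' @param eco an [EcoParams-class].
#' @param phiC fraction of primary production allocated to this group.
#' @return recruitment flux (g wB m^-2 s^-1); 0 if both limiting fluxes are 0.
#' @export
recruitmentFlux <- function(f, pi0, repro, grid, eco, phiC) {
  if (any(f < 0) || any(repro < 0) || pi0 < 0)
    stop("invalid argument: inputs must be >= 0")
  RP <- phiC * pi0 * recruitMass(grid)
  Re <- (eco@sE / 2) *
    sum(repro * f / binCenters(grid) * binWidths(grid))
  if (RP + Re <= 0) return(0)
  RP * Re / (RP + Re)
}

#' Ecological tendency of the biomass spectrum (pre-harvest)
#'
#' Instantaneous right-hand side of the biomass-spectrum equation
#' `df/dt = -d(gamma f)/dm + gamma f / m - Lambda f`, discretised as a
#' conservative first-order upwind finite volume in mass: the growth flux
#' `gamma_j f_j` leaves bin j through its upper edge, the recruitment flux
#' enters through the lowest edge, and the outflow at the asymptotic mass is
#' zero (growth ceases there). Summed over bins the scheme telescopes, so
#' total biomass changes only through recruitment, the dilation source
#' `gamma f / m` and mortality.
#'
#' @param f biomass spectrum per bin (g wB m^-2 g^-1).
#' @param npp net primary production (mg C m^-2 d^-1), scalar.
#' @param temperature temperature (degrees C), scalar.
#' @param group a [SizeGroup-class].
#' @param eco an [EcoParams-class].
#' @param grid the group's [MassGrid-class].
#' @param phiC fraction of primary production allocated to this group.
#' @return list with `dfdt` (g wB m^-2 g^-1 s^-1 per bin), the rates
#'   `gamma`, `lambda`, `recruit` (boundary flux), `xiP`, `xiVB`,
#'   `limitation`, and `cfl` (max `gamma dt / dm` per unit dt, s^-1).
#' @export
ecologyTendency <- function(f, npp, temperature, group, eco, grid,
                            phiC = 1) {
  m <- binCenters(grid)
  w <- binWidths(grid)
  nb <- nBins(grid)
  stopifnot(length(f) == nb)
  piSpec <- productionSpectrum(npp, temperature, m, eco)
  vb <- xiVB(m, temperature, group, eco)
  cap <- eco@xiPCapFactor * max(vb, 0)
  xp <- xiP(piSpec, f, m, phiC, cap = cap)
  gr <- realizedGrowth(xp, vb, m, group, eco)
  lam <- mortalityRate(m, temperature, group, eco)
  pi0 <- productionSpectrum(npp, temperature, recruitMass(grid), eco)
  rec <- recruitmentFlux(f, pi0, gr$repro, grid, eco, phiC)
  flux <- c(rec, gr$gamma * f)     # flux through each edge; upwind
  flux[nb + 1L] <- 0               # no outflow past the asymptotic mass
  dfdt <- -(flux[-1] - flux[-(nb + 1L)]) / w + gr$gamma * f / m - lam * f
  list(dfdt = dfdt, gamma = gr$gamma, lambda = lam, recruit = rec,
       xiP = xp, xiVB = vb, limitation = gr$limitation,
       cfl = max(gr$gamma / w))
}
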