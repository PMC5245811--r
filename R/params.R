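#' EcoParams: ecological parameters of the size-spectrum model
#'
#' Holds every parameter of the ecological module. Rate constants are quoted
#' per model year (360 days) at the Arrhenius reference temperature and
#' converted to per-second internally by the model builder. The trophic
#' scaling `tau = log(alphaTe) / log(betaPPMR)` is always derived, never set.
#'
#' Defaults are the central values of the Monte Carlo sampling distributions
#' (see [priorTable()]), plus conventional constants for the mass-length
#' relationship and the wet-biomass carbon content.
#'
#' @slot A0 allometric growth constant (g^(1-b) yr^-1) at the reference
#'   temperature.
#' @slot b allometric scaling exponent (unitless, in (0,1)).
#' @slot omegaA growth activation energy (eV).
#' @slot omegaLambda mortality activation energy (eV).
#' @slot zeta1 mortality constant (unitless); the mass-independent mortality
#'   factor is `mortalityScale * exp(zeta1) * A0 * aLambda(T)`.
#' @slot mortalityScale proportionality constant linking the mortality
#'   factor to `exp(zeta1) * A0` (the literature states only the
#'   proportionality). The default 0.025 is fixed once so that all three
#'   default groups are demographically viable (egg-production loop gain
#'   well above 1 under ceiling growth) at the central parameter values;
#'   see the methods vignette.
#' @slot h mortality allometric scaling (unitless, > 0).
#' @slot alphaTe trophic efficiency (unitless, in (0,1)).
#' @slot betaPPMR predator-to-prey mass ratio (unitless, > 1).
#' @slot kE Eppley constant (per degree C) for the phytoplankton-community
#'   partition.
#' @slot PiStar nutrient concentration parameter (unitless) for the same
#'   partition.
#' @slot sE egg survival fraction (unitless, in (0,1)).
#' @slot delta1 mass-length condition constant (g cm^-delta2).
#' @slot delta2 mass-length exponent (unitless).
#' @slot phiC fraction of primary production allocated to each group; NA
#'   means equal allocation 1/K over the K groups in the model.
#' @slot Tref Arrhenius reference temperature (K).
#' @slot wetBPerC wet biomass per unit carbon (g wB per g C).
#' @slot mPhyS mass of a "small" phytoplankton cell (g), lower anchor of the
#'   representative phytoplankton mass.
#' @slot mPhyL mass of a "large" phytoplankton cell (g), upper anchor.
#' @slot nppRef NPP normalisation (mg C m^-2 d^-1) in the phytoplankton
#'   partition.
#' @slot cRepro slope of the maturity (reproductive allocation) sigmoid,
#'   same family as the selectivity slope.
#' @slot xiPCapFactor cap on production-limited growth in empty bins,
#'   expressed as a multiple of the maximum physiological rate.
#'
#' @seealso [ecoParams()], [econParams()]
#' @exportClass EcoParams
setClass("EcoParams",
  representation(
    A0 = "numeric", b = "numeric",
    omegaA = "numeric", omegaLambda = "numeric",
    zeta1 = "numeric", mortalityScale = "numeric", h = "numeric",
    alphaTe = "numeric", betaPPMR = "numeric",
    kE = "numeric", PiStar = "numeric", sE = "numeric",
    delta1 = "numeric", delta2 = "numeric",
    phiC = "numeric", Tref = "numeric", wetBPerC = "numeric",
    mPhyS = "numeric", mPhyL = "numeric", nppRef = "numeric",
    cRepro = "numeric", xiPCapFactor = "numeric"
  )
)

setValidity("EcoParams", function(object) {
  msgs <- character()
  if (object@alphaTe <= 0 || object@alphaTe >= 1)
    msgs <- c(msgs, "alphaTe must be in (0, 1)")
  if (object@betaPPMR <= 1) msgs <- c(msgs, "betaPPMR must be > 1")
  if (object@b <= 0 || object@b >= 1) msgs <- c(msgs, "b must be in (0, 1)")
  if (object@h <= 0) msgs <- c(msgs, "h must be > 0")
  if (object@mortalityScale <= 0)
    msgs <- c(msgs, "mortalityScale must be > 0")
  if (object@sE <= 0 || object@sE >= 1) msgs <- c(msgs, "sE must be in (0, 1)")
  if (object@A0 <= 0) msgs <- c(msgs, "A0 must be > 0")
  if (object@omegaA < 0 || object@omegaLambda < 0)
    msgs <- c(msgs, "activation energies must be >= 0")
  if (!is.na(object@phiC) && (object@phiC <= 0 || object@phiC > 1))
    msgs <- c(msgs, "phiC must be in (0, 1] or NA for equal allocation")
  if (object@mPhyS >= object@mPhyL)
    msgs <- c(msgs, "need mPhyS < mPhyL")
  if (length(msgs)) msgs else TRUE
})

#' Ecological parameters
#'
#' Constructor for [EcoParams-class]; see that page for slot meanings and
#' units. Arguments override the defaults.
#'
#' @param A0,b,omegaA,omegaLambda,zeta1,h,alphaTe,betaPPMR,kE,PiStar,sE see
#'   [EcoParams-class]; defaults are the central prior values.
#' @param delta1,delta2 mass-length constants (cube law by default).
#' @param phiC per-group primary-production allocation; NA = 1/K.
#' @param Tref Arrhenius reference temperature (K).
#' @param wetBPerC wet biomass to carbon conversion (g wB / g C).
#' @param mPhyS,mPhyL,nppRef phytoplankton-partition constants.
#' @param cRepro maturity sigmoid slope.
#' @param xiPCapFactor empty-bin growth cap factor.
#' @return An [EcoParams-class] object.
#' @examples
#' eco <- ecoParams()
#' trophicScaling(eco) # about -0.24
#' @export
ecoParams <- function(A0 = 4.46, b = 0.70, omegaA = 0.45, omegaLambda = 0.45,
                      zeta1 = 0.55, mortalityScale = 0.025, h = 0.54,
                      alphaTe = 0.13,
                      betaPPMR = 5000, kE = 0.0631, PiStar = 0.37,
                      sE = 0.025, delta1 = 0.01, delta2 = 3, phiC = NA_real_,
                      Tref = 283.15, wetBPerC = 10, mPhyS = 1e-10,
                      mPhyL = 1e-6, nppRef = 1000, cRepro = 16.7787,
                      xiPCapFactor = 1e3) {
  new("EcoParams",
    A0 = A0, b = b, omegaA = omegaA, omegaLambda = omegaLambda,
    zeta1 = zeta1, mortalityScale = mortalityScale, h = h,
    alphaTe = alphaTe, betaPPMR = betaPPMR,
    kE = kE, PiStar = PiStar, sE = sE, delta1 = delta1, delta2 = delta2,
    phiC = phiC, Tref = Tref, wetBPerC = wetBPerC, mPhyS = mPhyS,
    mPhyL = mPhyL, nppRef = nppRef, cRepro = cRepro,
    xiPCapFactor = xiPCapFactor)
}

#' @describeIn ecoParams derived trophic scaling
#'   `tau = log(alphaTe) / log(betaPPMR)` (< 0).
#' @param x an `EcoParams`
#' @export
trophicScaling <- function(x) log(x@alphaTe) / log(x@betaPPMR)

setMethod("show", "EcoParams", function(object) {
  cat("EcoParams:\n")
  cat(sprintf("  growth:    A0 = %.3g g^(1-b)/yr, b = %.3g, omegaA = %.3g eV\n",
              object@A0, object@b, object@omegaA))
  cat(sprintf("  mortality: zeta1 = %.3g, h = %.3g, omegaLambda = %.3g eV\n",
              object@zeta1, object@h, object@omegaLambda))
  cat(sprintf("  trophic:   alpha = %.3g, beta = %.4g, tau = %.3g\n",
              object@alphaTe, object@betaPPMR, trophicScaling(object)))
  cat(sprintf("  recruit:   sE = %.3g; Eppley kE = %.3g /degC, Pi* = %.3g\n",
              object@sE, object@kE, object@PiStar))
})

#' EconParams: economic parameters of the open-access fishery
#'
#' @slot price ex-vessel price ($ per g wet biomass), globally constant.
#' @slot costPerEffort cost per unit effort ($ W^-1 s^-1), globally constant.
#' @slot kappaE fleet dynamics parameter (W^2 m^-2 $^-1); sets the roughly
#'   decadal timescale at which effort responds to average profit.
#' @slot cSigma selectivity slope (unitless).
#' @slot eFloor effort floor (W m^-2) from which effort can re-enter when
#'   fishing becomes profitable (the effort equation is singular at E = 0).
#'
#' @seealso [econParams()], [criticalBiomass()]
#' @exportClass EconParams
setClass("EconParams",
  representation(
    price = "numeric",
    costPerEffort = "numeric",
    kappaE = "numeric",
    cSigma = "numeric",
    eFloor = "numeric"
  )
)

setValidity("EconParams", function(object) {
  msgs <- character()
  if (object@price <= 0) msgs <- c(msgs, "price must be > 0")
  if (object@costPerEffort < 0) msgs <- c(msgs, "costPerEffort must be >= 0")
  if (object@kappaE <= 0) msgs <- c(msgs, "kappaE must be > 0")
  if (object@cSigma <= 0) msgs <- c(msgs, "cSigma must be > 0")
  if (object@eFloor <= 0) msgs <- c(msgs, "eFloor must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Economic parameters
#'
#' Constructor for [EconParams-class]. Defaults: ex-vessel price 1.1e-3 $/g
#' (about 1100 $/tonne), cost per unit effort 1e-7 $ W^-1 s^-1, fleet
#' dynamics parameter 1e-6 W^2 m^-2 $^-1 (decadal effort adjustment),
#' selectivity slope 16.7787, effort floor 1e-15 W m^-2.
#'
#' @param price,costPerEffort,kappaE,cSigma,eFloor see [EconParams-class].
#' @return An [EconParams-class] object.
#' @examples
#' econ <- econParams()
#' criticalBiomass(econ@costPerEffort, econ@price, q = 1e-4)
#' @export
econParams <- function(price = 1.1e-3, costPerEffort = 1e-7, kappaE = 1e-6,
                       cSigma = 16.7787, eFloor = 1e-15) {
  new("EconParams", price = price, costPerEffort = costPerEffort,
      kappaE = kappaE, cSigma = cSigma, eFloor = eFloor)
}

setMethod("show", "EconParams", function(object) {
  cat("EconParams:\n")
  cat(sprintf("  price = %.3g $/gwB, cost = %.3g $/W/s, kappaE = %.3g W2/m2/$\n",
              object@price, object@costPerEffort, object@kappaE))
  cat(sprintf("  selectivity slope cSigma = %.4g, effort floor = %.1g W/m2\n",
              object@cSigma, object@eFloor))
})
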