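#' FisheryModel: assembled community, grids and parameters
#'
#' Binds together the ecological and economic parameters, the size-group
#' community, one log-spaced [MassGrid-class] per group (from the shared
#' recruit mass up to each group's asymptotic mass) and the per-group
#' selectivity and maturity curves evaluated on those grids. All simulator
#' entry points take a `FisheryModel`.
#'
#' @slot eco an [EcoParams-class].
#' @slot econ an [EconParams-class].
#' @slot groups list of [SizeGroup-class].
#' @slot grids list of [MassGrid-class], one per group.
#' @slot sigma list of numeric vectors: gear selectivity per bin per group.
#' @slot psi list of numeric vectors: maturity allocation per bin per group.
#' @slot phi numeric per group: primary-production allocation fractions
#'   (sum <= 1).
#'
#' @seealso [fisheryModel()]
#' @exportClass FisheryModel
setClass("FisheryModel",
  representation(
    eco = "EcoParams",
    econ = "EconParams",
    groups = "list",
    grids = "list",
    sigma = "list",
    psi = "list",
    phi = "numeric"
  )
)

setValidity("FisheryModel", function(object) {
  msgs <- character()
  K <- length(object@groups)
  if (length(object@grids) != K || length(object@sigma) != K ||
      length(object@psi) != K || length(object@phi) != K)
    msgs <- c(msgs, "per-group slots must all have one entry per group")
  if (sum(object@phi) > 1 + 1e-12)
    msgs <- c(msgs, "allocation fractions phi must sum to <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Assemble a fishery model
#'
#' @param eco an [EcoParams-class]; default [ecoParams()].
#' @param econ an [EconParams-class]; default [econParams()].
#' @param groups list of [SizeGroup-class]; default [defaultGroups()].
#' @param nBins bins per group grid. Default 50.
#' @param m0 recruit mass (g). Default 0.01 (10 mg).
#' @return a [FisheryModel-class].
#' @examples
#' mod <- fisheryModel(nBins = 20)
#' mod
#' @export
fisheryModel <- function(eco = ecoParams(), econ = econParams(),
                         groups = defaultGroups(), nBins = 50L,
                         m0 = 0.01) {
  K <- length(groups)
  grids <- lapply(groups, function(g) massGrid(m0, g@mInf, nBins))
  sigma <- mapply(function(g, gr) {
    selectivity(binCenters(gr), thresholdMass(g), econ@cSigma, eco@delta2)
  }, groups, grids, SIMPLIFY = FALSE)
  psi <- mapply(function(g, gr) {
    maturityAllocation(binCenters(gr), g, eco)
  }, groups, grids, SIMPLIFY = FALSE)
  phi <- if (is.na(eco@phiC)) rep(1 / K, K) else rep(eco@phiC, K)
  new("FisheryModel", eco = eco, econ = econ, groups = groups,
      grids = grids, sigma = sigma, psi = psi, phi = phi)
}

#' @describeIn fisheryModel number of groups
#' @param x a `FisheryModel`
#' @export
nGroups <- function(x) length(x@groups)

setMethod("show", "FisheryModel", function(object) {
  cat(sprintf("FisheryModel: %d group(s), %d bins each\n",
              nGroups(object), nBins(object@grids[[1]])))
  for (k in seq_len(nGroups(object))) show(object@groups[[k]])
  cat(sprintf("  phi (PP allocation): %s\n",
              paste(signif(object@phi, 3), collapse = ", ")))
})

# Flatten the model into plain lists for the inner time loop (avoids S4
# dispatch in hot code). All rates in per-second units.
.modelCache <- function(model) {
  eco <- model@eco
  econ <- model@econ
  A0s <- eco@A0 / .secondsPerYear
  tau <- trophicScaling(eco)
  groups <- lapply(seq_len(nGroups(model)), function(k) {
    g <- model@groups[[k]]
    gr <- model@grids[[k]]
    m <- binCenters(gr)
    w <- binWidths(gr)
    psi <- model@psi[[k]]
    list(
      m = m, w = w, nb = nBins(gr), m0 = recruitMass(gr),
      mInf = g@mInf,
      mb = m^eco@b,
      vbShape = m^eco@b - m * g@mInf^(eco@b - 1),
      mhTerm = m^(-eco@h) * g@mInf^(eco@h + eco@b - 1),
      piShape = m^tau / m,             # (m^tau)/m; scaled per cell later
      pi0Shape = recruitMass(gr)^tau / recruitMass(gr),
      kaFac = g@mInf^(eco@b - 1),
      psi = psi, oneMinusPsi = 1 - psi,
      sigma = model@sigma[[k]],
      wOverM = w / m,
      phi = model@phi[[k]]
    )
  })
  list(
    groups = groups, K = length(groups),
    A0s = A0s, b = eco@b,
    lambda0 = eco@mortalityScale * exp(eco@zeta1) * A0s,
    omegaA = eco@omegaA, omegaL = eco@omegaLambda, Tref = eco@Tref,
    tau = tau, lnBeta = log(eco@betaPPMR),
    kE = eco@kE, PiStar = eco@PiStar, nppRef = eco@nppRef,
    logMphyS = log(eco@mPhyS), logMphyL = log(eco@mPhyL),
    wetBPerC = eco@wetBPerC, sE = eco@sE,
    capFactor = eco@xiPCapFactor,
    price = econ@price, cost = econ@costPerEffort,
    kappaE = econ@kappaE, eFloor = econ@eFloor
  )
}
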