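#' SizeGroup: a community group defined by its asymptotic mass
#'
#' The simulated community is partitioned into a small number of
#' "super-organism" groups distinguished only by asymptotic mass. Each group
#' carries its maturity mass and the two factors that place its gear
#' selectivity threshold relative to the maturity mass.
#'
#' @slot label character(1), e.g. "small", "medium", "large".
#' @slot mInf numeric(1), asymptotic mass (g): the mass at which individual
#'   growth ceases and the upper end of the group's spectrum.
#' @slot mAlpha numeric(1), maturity mass (g), with `m0 < mAlpha < mInf`.
#' @slot dTheta numeric(1) in (0, 1], selectivity mass adjustment. Smaller
#'   values for larger groups represent proportionally greater bycatch of
#'   juveniles of large species.
#' @slot eTheta numeric(1) > 0, selectivity mass scaling, used to explore
#'   uncertainty in the threshold mass.
#'
#' @seealso [sizeGroup()], [defaultGroups()], [thresholdMass()]
#' @exportClass SizeGroup
setClass("SizeGroup",
  representation(
    label = "character",
    mInf = "numeric",
    mAlpha = "numeric",
    dTheta = "numeric",
    eTheta = "numeric"
  )
)

setValidity("SizeGroup", function(object) {
  msgs <- character()
  if (length(object@label) != 1L) msgs <- c(msgs, "label must be length 1")
  if (object@mInf <= 0 || object@mAlpha <= 0)
    msgs <- c(msgs, "masses must be positive")
  if (object@mAlpha >= object@mInf)
    msgs <- c(msgs, "need mAlpha < mInf")
  if (object@dTheta <= 0 || object@dTheta > 1)
    msgs <- c(msgs, "dTheta must be in (0, 1]")
  if (object@eTheta <= 0) msgs <- c(msgs, "eTheta must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Create a size group
#'
#' @param label group name.
#' @param mInf asymptotic mass (g).
#' @param mAlpha maturity mass (g); default `0.25 * mInf`.
#' @param dTheta selectivity mass adjustment in (0, 1].
#' @param eTheta selectivity mass scaling (> 0).
#' @return A [SizeGroup-class].
#' @export
sizeGroup <- function(label, mInf, mAlpha = 0.25 * mInf, dTheta = 1,
                      eTheta = 0.6198) {
  new("SizeGroup", label = as.character(label), mInf = mInf,
      mAlpha = mAlpha, dTheta = dTheta, eTheta = eTheta)
}

#' Default three-group community
#'
#' Small, medium and large groups with asymptotic masses approximately
#' log-spaced at 30 g, 1 kg and 100 kg; maturity mass 25% of asymptotic mass;
#' selectivity mass adjustments (1, 0.5, 0.25), so the harvest threshold of
#' the medium (large) group sits at 50% (25%) of its maturity mass.
#'
#' @param mInf asymptotic masses (g) of the groups.
#' @param mAlphaFrac maturity mass as a fraction of asymptotic mass.
#' @param dTheta selectivity mass adjustments, one per group.
#' @param eTheta selectivity mass scaling, shared by all groups.
#' @return list of [SizeGroup-class] objects.
#' @examples
#' gs <- defaultGroups()
#' vapply(gs, thresholdMass, numeric(1))
#' @export
defaultGroups <- function(mInf = c(30, 1e3, 1e5), mAlphaFrac = 0.25,
                          dTheta = c(1, 0.5, 0.25), eTheta = 0.6198) {
  labels <- c("small", "medium", "large")[seq_along(mInf)]
  if (length(dTheta) != length(mInf))
    stop("invalid argument: dTheta must have one value per group")
  mapply(function(l, mi, d) {
    sizeGroup(l, mInf = mi, mAlpha = mAlphaFrac * mi, dTheta = d,
              eTheta = eTheta)
  }, labels, mInf, dTheta, SIMPLIFY = FALSE)
}

#' @describeIn sizeGroup asymptotic mass (g)
#' @param x a `SizeGroup`
#' @export
asymptoticMass <- function(x) x@mInf

#' @describeIn sizeGroup maturity mass (g)
#' @export
maturityMass <- function(x) x@mAlpha

#' @describeIn sizeGroup group label
#' @export
groupLabel <- function(x) x@label

setMethod("show", "SizeGroup", function(object) {
  cat(sprintf("SizeGroup '%s': mInf = %g g, mAlpha = %g g, mTheta = %g g\n",
              object@label, object@mInf, object@mAlpha,
              thresholdMass(object)))
})

#' Van't Hoff-Arrhenius temperature factor
#'
#' Exponential (Boltzmann-Arrhenius) temperature dependence of metabolic
#' rates, normalised to 1 at the reference temperature:
#' `exp[(omega / kB) (1/Tref - 1/(T + 273.15))]` with
#' `kB = 8.617e-5 eV / K`.
#'
#' @param temperature temperature in degrees C (> -273.15).
#' @param omega activation energy (eV), >= 0.
#' @param Tref reference temperature (K). Default 283.15 K (10 degrees C), a
#'   mid-latitude surface-ocean reference at which rate constants are quoted.
#' @return unitless factor, 1 at `T = Tref - 273.15` or at `omega = 0`.
#' @examples
#' arrheniusFactor(10, 0.45) # 1
#' arrheniusFactor(20, 0.45) # ~1.877
#' @export
arrheniusFactor <- function(temperature, omega, Tref = 283.15) {
  if (any(temperature <= -273.15))
    stop("invalid argument: temperature at or below absolute zero")
  if (any(omega < 0)) stop("invalid argument: omega must be >= 0")
  TK <- temperature + 273.15
  exp((omega / .kBoltzmann) * (1 / Tref - 1 / TK))
}

#' Harvest threshold mass of a group
#'
#' The mass at which gear selectivity reaches one half, defined from the
#' maturity mass as `mTheta = dTheta * eTheta * mAlpha`.
#'
#' @param group a [SizeGroup-class].
#' @return threshold mass (g).
#' @export
thresholdMass <- function(group) {
  stopifnot(is(group, "SizeGroup"))
  group@dTheta * group@eTheta * group@mAlpha
}

#' Sigmoidal gear selectivity
#'
#' Probability that towed gear retains an individual of mass `m`:
#' `sigma(m) = [1 + (m / mTheta)^(-cSigma / delta2)]^-1`. The curve is
#' sigmoidal in length (the physical constraint of net meshes) and converted
#' to mass through the cube-law exponent `delta2`; it is 1/2 at the threshold
#' mass and strictly increasing in `m`.
#'
#' @param m individual mass (g), scalar or vector.
#' @param mTheta threshold mass (g).
#' @param cSigma selectivity slope (unitless), > 0.
#' @param delta2 mass-length exponent (unitless), > 0.
#' @return selectivity in (0, 1), same length as `m`.
#' @examples
#' selectivity(154.95, 154.95, 16.7787, 3) # 0.5
#' @export
selectivity <- function(m, mTheta, cSigma = 16.7787, delta2 = 3) {
  if (any(m <= 0) || mTheta <= 0 || cSigma <= 0 || delta2 <= 0)
    stop("invalid argument: all selectivity inputs must be positive")
  1 / (1 + (m / mTheta)^(-cSigma / delta2))
}

#' Mass-length conversion
#'
#' Classic allometric mass-length relationship `m = delta1 * l^delta2`
#' (cube law by default) and its exact inverse.
#'
#' @param l length (cm).
#' @param m mass (g).
#' @param delta1 condition constant (g cm^-delta2). Default 0.01.
#' @param delta2 exponent. Default 3.
#' @return mass in g (`massFromLength`) or length in cm (`lengthFromMass`).
#' @examples
#' massFromLength(10) # 10 g
#' @export
massFromLength <- function(l, delta1 = 0.01, delta2 = 3) {
  if (any(l <= 0)) stop("invalid argument: length must be positive")
  delta1 * l^delta2
}

#' @rdname massFromLength
#' @export
lengthFromMass <- function(m, delta1 = 0.01, delta2 = 3) {
  if (any(m <= 0)) stop("invalid argument: mass must be positive")
  (m / delta1)^(1 / delta2)
}

#' Activity cost coefficient
#'
#' Mass-specific investment in activity, closed so that von Bertalanffy
#' growth `A m^b - ka m` vanishes exactly at the asymptotic mass:
#' `ka = A * mInf^(b - 1)`. This is the only closure consistent with
#' asymptotic size being the trait that defines each group.
#'
#' @param A allometric growth rate (g^(1-b) per unit time); `ka` inherits
#'   A's time unit.
#' @param b allometric scaling exponent in (0, 1).
#' @param mInf asymptotic mass (g).
#' @return ka (per unit time of `A`).
#' @examples
#' activityCoefficient(1, 2 / 3, 8) # 0.5
#' @export
activityCoefficient <- function(A, b, mInf) {
  if (any(A <= 0) || any(mInf <= 0))
    stop("invalid argument: A and mInf must be positive")
  A * mInf^(b - 1)
}
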