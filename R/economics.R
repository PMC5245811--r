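#' Harvest spectrum
#'
#' Harvest is linear in biomass and effort: for catchability `q`, selectivity
#' `sigma(m)` and effort `E`, the harvest flux density in each mass bin is
#' `h = q * sigma * E * f` (g wB m^-2 s^-1 g^-1).
#'
#' @param f biomass spectrum per bin (g wB m^-2 g^-1).
#' @param E fishing effort (W m^-2), scalar.
#' @param q catchability (m^2 W^-1 s^-1), scalar.
#' @param sigma selectivity per bin (unitless in (0, 1)).
#' @return harvest spectrum per bin.
#' @examples
#' harvestSpectrum(10, E = 0.01, q = 1e-4, sigma = 0.5) # 5e-6
#' @export
harvestSpectrum <- function(f, E, q, sigma) {
  if (any(f < 0) || E < 0 || q < 0 || any(sigma < 0))
    stop("invalid argument: inputs must be >= 0")
  q * sigma * E * f
}

#' Revenue rate from harvesting a group
#'
#' With a globally constant ex-vessel price the revenue rate is
#' `q * E * price * integral(sigma f dm)` ($ m^-2 s^-1), identical to
#' `price` times the integrated harvest spectrum.
#'
#' @inheritParams harvestSpectrum
#' @param price ex-vessel price ($ per g wB).
#' @param grid the group's [MassGrid-class].
#' @return revenue rate ($ m^-2 s^-1).
#' @export
revenueRate <- function(f, E, q, sigma, price, grid) {
  q * E * price * sum(sigma * f * binWidths(grid))
}

#' Open-access effort update
#'
#' Effort evolves with the average profit (profit per unit effort):
#' `dE/dt = kappaE * (revenue - cost) / E`, with `cost = costPerEffort * E`
#' computed by the caller. One explicit Euler step, floored at `eFloor` so
#' effort can re-enter when profitability returns. Because the average
#' profit is singular as E approaches the floor, the per-step relative
#' change is rate-limited to a doubling (or halving) per 15 days of model
#' time; entry from the floor is then a fast, timestep-independent
#' exponential rather than an unbounded jump, and the limiter never binds
#' near equilibrium where revenue is close to cost.
#'
#' @param E effort (W m^-2), >= eFloor.
#' @param revenue revenue rate ($ m^-2 s^-1).
#' @param cost cost rate ($ m^-2 s^-1).
#' @param kappaE fleet dynamics parameter (W^2 m^-2 $^-1).
#' @param dt timestep (s).
#' @param eFloor effort floor (W m^-2).
#' @return updated effort (W m^-2).
#' @examples
#' effortStep(0.01, revenue = 2e-8, cost = 1e-8, kappaE = 1e-6, dt = 1)
#' @export
effortStep <- function(E, revenue, cost, kappaE, dt, eFloor = 1e-15) {
  dE <- dt * kappaE * (revenue - cost) / E
  r <- 2^(dt / (15 * 86400))       # doubling per 15 d, timestep-independent
  dE <- pmin(pmax(dE, E * (1 / r - 1)), E * (r - 1))
  pmax(E + dE, eFloor)
}

#' Critical biomass of the open-access fishery
#'
#' At the open-access equilibrium, revenue equals cost, which fixes the
#' selectable biomass `integral(sigma f dm)` at
#' `Fcrit = costPerEffort / (price * q)` -- a purely economic quantity.
#' Unharvested selectable biomass below `Fcrit` means fishing can never be
#' profitable there; above it, effort grows until harvest drives the
#' selectable biomass down to `Fcrit`.
#'
#' @param costPerEffort cost per unit effort ($ W^-1 s^-1).
#' @param price ex-vessel price ($ per g wB).
#' @param q catchability (m^2 W^-1 s^-1).
#' @return critical selectable biomass (g wB m^-2).
#' @examples
#' criticalBiomass(1e-7, 1.1e-3, 1e-4) # ~0.909
#' @export
criticalBiomass <- function(costPerEffort, price, q) {
  if (price <= 0 || q <= 0)
    stop("invalid argument: price and q must be > 0 (fishery undefined)")
  costPerEffort / (price * q)
}

#' Estimate cost per unit effort from an assumed open-access equilibrium
#'
#' If a fishery is near open-access equilibrium, total revenue equals total
#' cost, so the cost per unit effort is the observed total revenue divided
#' by the observed total effort: `c = revenue / (effort * secondsPerYear)`.
#' The model year is 360 days (3.1104e7 s).
#'
#' @param totalRevenue total revenue ($ per year).
#' @param totalEffort total nominal effort (W).
#' @return cost per unit effort ($ W^-1 s^-1).
#' @export
estimateCostFromEquilibrium <- function(totalRevenue, totalEffort) {
  if (totalEffort <= 0)
    stop("invalid argument: totalEffort must be > 0")
  totalRevenue / (totalEffort * .secondsPerYear)
}
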