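#' Diagnostic plot: biomass and harvest spectra
#'
#' Log-log plot of the per-group biomass spectra of a state, optionally
#' overlaid with a second (e.g. unharvested) state for comparison.
#'
#' @param model a [FisheryModel-class].
#' @param state a state list (see [initialState()]); single cell (first
#'   column used).
#' @param reference optional second state drawn in grey.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotSpectra <- function(model, state, reference = NULL,
                        main = "Biomass spectra") {
  K <- nGroups(model)
  allF <- unlist(lapply(state$f, function(x) x[, 1]))
  ylim <- range(allF[allF > 0], na.rm = TRUE)
  xlim <- range(unlist(lapply(model@grids, binCenters)))
  plot(NA, xlim = xlim, ylim = ylim, log = "xy",
       xlab = "individual mass (g)",
       ylab = expression(f ~ (g ~ wB ~ m^-2 ~ g^-1)), main = main)
  for (k in seq_len(K)) {
    m <- binCenters(model@grids[[k]])
    if (!is.null(reference))
      graphics::lines(m, pmax(reference$f[[k]][, 1], ylim[1] * 1e-3),
                      col = "grey60", lty = k)
    graphics::lines(m, pmax(state$f[[k]][, 1], ylim[1] * 1e-3),
                    col = "black", lty = k)
  }
  graphics::legend("topright", legend = vapply(model@groups, groupLabel,
                                               character(1)),
                   lty = seq_len(K), bty = "n")
  invisible(NULL)
}

#' Diagnostic plot: annual global biomass, harvest and effort
#'
#' Three stacked panels of the area-integrated annual series of a run.
#'
#' @param result a [RunResult-class].
#' @return invisibly, the [annualTotals()] data.frame.
#' @export
plotAnnualTotals <- function(result) {
  tot <- annualTotals(result)
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(tot$year, tot$biomass, type = "l", xlab = "",
       ylab = "biomass (g wB)")
  plot(tot$year, tot$harvest, type = "l", xlab = "",
       ylab = "harvest (g wB/yr)")
  plot(tot$year, tot$effort, type = "l", xlab = "year",
       ylab = "effort (W)")
  invisible(tot)
}
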