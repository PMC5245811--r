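#' MassGrid: log-spaced discretisation of the individual-mass axis
#'
#' A `MassGrid` discretises the continuous body-mass axis of a size spectrum
#' into finite-volume bins. Edges are strictly log-spaced from the recruit
#' mass `m0` up to `mMax`; bin centers are the geometric means of the edges so
#' that centers sit strictly inside their bins on a log axis.
#'
#' @slot edges numeric, bin edges in g, strictly increasing, `edges[1] == m0`.
#' @slot centers numeric, bin centers in g (geometric means of adjacent edges).
#' @slot widths numeric, bin widths in g, `diff(edges)`.
#' @slot m0 numeric(1), recruit mass in g.
#'
#' @seealso [massGrid()]
#' @exportClass MassGrid
setClass("MassGrid",
  representation(
    edges = "numeric",
    centers = "numeric",
    widths = "numeric",
    m0 = "numeric"
  )
)

setValidity("MassGrid", function(object) {
  msgs <- character()
  e <- object@edges
  if (length(e) < 3) msgs <- c(msgs, "grid needs at least 2 bins")
  if (any(e <= 0)) msgs <- c(msgs, "edges must be positive")
  if (any(diff(e) <= 0)) msgs <- c(msgs, "edges must be strictly increasing")
  if (abs(e[1] - object@m0) > 1e-12 * object@m0)
    msgs <- c(msgs, "edges[1] must equal m0")
  r <- exp(diff(log(e)))
  if (max(abs(r / r[1] - 1)) > 1e-10)
    msgs <- c(msgs, "edges must be log-spaced (constant ratio)")
  if (length(object@centers) != length(e) - 1L ||
      length(object@widths) != length(e) - 1L)
    msgs <- c(msgs, "centers/widths must have length(edges) - 1")
  if (any(object@centers <= e[-length(e)]) || any(object@centers >= e[-1]))
    msgs <- c(msgs, "centers must lie strictly inside their bins")
  if (max(abs(object@widths - diff(e))) > 1e-12 * max(e))
    msgs <- c(msgs, "widths must equal diff(edges)")
  if (length(msgs)) msgs else TRUE
})

#' Build a log-spaced mass grid
#'
#' @param m0 recruit mass (g), lower edge of the first bin. Default 0.01 g
#'   (10 mg).
#' @param mMax largest resolved mass (g), upper edge of the last bin;
#'   typically the asymptotic mass of a group.
#' @param nBins number of bins (>= 2). Default 50.
#'
#' @return A [MassGrid-class] object.
#' @examples
#' g <- massGrid(1, 100, 2)
#' binEdges(g) # 1 10 100
#' @export
massGrid <- function(m0 = 0.01, mMax, nBins = 50L) {
  if (!is.numeric(m0) || !is.numeric(mMax) || m0 <= 0 || mMax <= m0)
    stop("invalid argument: need 0 < m0 < mMax")
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 2L)
    stop("invalid argument: nBins must be >= 2")
  edges <- exp(seq(log(m0), log(mMax), length.out = nBins + 1L))
  edges[1] <- m0
  edges[nBins + 1L] <- mMax
  centers <- sqrt(edges[-1] * edges[-(nBins + 1L)])
  new("MassGrid",
    edges = edges, centers = centers, widths = diff(edges), m0 = m0)
}

#' @describeIn massGrid bin edges (g)
#' @param x a `MassGrid`
#' @export
binEdges <- function(x) x@edges

#' @describeIn massGrid bin centers (g)
#' @export
binCenters <- function(x) x@centers

#' @describeIn massGrid bin widths (g)
#' @export
binWidths <- function(x) x@widths

#' @describeIn massGrid number of bins
#' @export
nBins <- function(x) length(x@widths)

#' @describeIn massGrid recruit mass m0 (g)
#' @export
recruitMass <- function(x) x@m0

setMethod("show", "MassGrid", function(object) {
  cat("MassGrid:", nBins(object), "log-spaced bins from",
      format(object@m0), "to", format(max(object@edges)), "g\n")
})
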