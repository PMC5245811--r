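#' Forcing: NPP and temperature driving one or more grid cells
#'
#' Environmental forcing for the simulator. Rows are time slices (one row
#' for constant forcing, twelve for a monthly climatology, cycled over the
#' run); columns are grid cells. Each cell carries an area and a pseudo-LME
#' (Large Marine Ecosystem) label used for calibration aggregation.
#'
#' @slot npp matrix (time x cell) of net primary production
#'   (mg C m^-2 d^-1), >= 0.
#' @slot temperature matrix (time x cell) of temperature (degrees C).
#' @slot area numeric per cell (m^2), > 0.
#' @slot lme integer per cell: pseudo-LME membership.
#'
#' @seealso [syntheticForcing()], [readForcing()]
#' @exportClass Forcing
setClass("Forcing",
  representation(
    npp = "matrix",
    temperature = "matrix",
    area = "numeric",
    lme = "integer"
  )
)

setValidity("Forcing", function(object) {
  msgs <- character()
  if (!all(dim(object@npp) == dim(object@temperature)))
    msgs <- c(msgs, "npp and temperature must have identical dimensions")
  if (any(object@npp < 0)) msgs <- c(msgs, "npp must be >= 0")
  if (length(object@area) != ncol(object@npp) ||
      length(object@lme) != ncol(object@npp))
    msgs <- c(msgs, "area and lme must have one entry per cell")
  if (any(object@area <= 0)) msgs <- c(msgs, "areas must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Assemble a Forcing object
#'
#' @param npp matrix or vector of NPP (mg C m^-2 d^-1); a vector is one
#'   constant value per cell.
#' @param temperature matrix or vector of temperature (degrees C), same
#'   shape as `npp`. Values outside (-5, 40) trigger a realism warning.
#' @param area cell areas (m^2); recycled.
#' @param lme pseudo-LME label per cell; recycled.
#' @return a [Forcing-class].
#' @export
forcing <- function(npp, temperature, area = 1, lme = seq_len(nc)) {
  if (!is.matrix(npp)) npp <- matrix(npp, nrow = 1)
  if (!is.matrix(temperature)) temperature <- matrix(temperature, nrow = 1)
  nc <- ncol(npp)
  if (any(temperature < -5) || any(temperature > 40))
    warning("temperature outside (-5, 40) degC: outside the realistic ocean range")
  new("Forcing", npp = npp, temperature = temperature,
      area = rep_len(area, nc), lme = as.integer(rep_len(lme, nc)))
}

#' @describeIn forcing number of cells
#' @param x a `Forcing`
#' @export
nCells <- function(x) ncol(x@npp)

#' @describeIn forcing cell areas (m^2)
#' @export
cellAreas <- function(x) x@area

#' @describeIn forcing pseudo-LME label per cell
#' @export
lmeIndex <- function(x) x@lme

setMethod("show", "Forcing", function(object) {
  cat(sprintf(
    "Forcing: %d cell(s) x %d time slice(s); npp %.0f-%.0f mgC/m2/d, T %.1f-%.1f degC\n",
    nCells(object), nrow(object@npp), min(object@npp), max(object@npp),
    min(object@temperature), max(object@temperature)))
})

# run a block with a local, seeded RNG without disturbing the caller's state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Synthetic forcing generator
#'
#' Builds a reproducible multi-cell forcing spanning requested NPP and
#' temperature ranges, emulating the environmental contrast across coastal
#' Large Marine Ecosystems: NPP from oligotrophic to eutrophic (default
#' 500-3000 mg C m^-2 d^-1) and temperatures from polar to tropical (default
#' 0-30 degrees C). NPP values are log-spaced across the range; temperatures
#' span their range in a seeded random pairing with NPP so the two gradients
#' are not collinear. Optionally a 12-month seasonal cycle (+/-20% of NPP,
#' +/-3 degrees C, clipped to the ranges) is superimposed. Cells are
#' assigned round-robin to `nLME` pseudo-LMEs; the default cell area makes a
#' 16-cell grid comparable in total area to the real combined LME system
#' (~1e14 m^2).
#'
#' @param nCells number of cells (>= 1).
#' @param nppRange range of NPP (mg C m^-2 d^-1).
#' @param tRange range of temperature (degrees C).
#' @param seed integer seed; the same seed gives bit-identical forcing.
#' @param seasonal logical; add a 12-month cycle?
#' @param cellArea area per cell (m^2). Default 5e12.
#' @param nLME number of pseudo-LMEs. Default `max(1, nCells %/% 2)`.
#' @return a [Forcing-class].
#' @examples
#' f <- syntheticForcing(4, seed = 1)
#' range(f@npp)
#' @export
syntheticForcing <- function(nCells, nppRange = c(500, 3000),
                             tRange = c(0, 30), seed = NULL,
                             seasonal = FALSE, cellArea = 5e12,
                             nLME = max(1L, nCells %/% 2L)) {
  if (nCells < 1 || any(nppRange < 0) || diff(nppRange) < 0 ||
      diff(tRange) < 0)
    stop("invalid argument: need nCells >= 1 and non-decreasing ranges")
  .withSeed(seed, {
    nppBase <- if (nCells == 1) mean(nppRange) else
      exp(seq(log(max(nppRange[1], 1e-6)), log(nppRange[2]),
              length.out = nCells))
    nppBase <- pmin(pmax(nppBase, nppRange[1]), nppRange[2])
    if (nppRange[1] == 0 && nCells > 1) nppBase[1] <- 0
    tBase <- if (nCells == 1) mean(tRange) else
      seq(tRange[1], tRange[2], length.out = nCells)
    if (length(tBase) > 1) tBase <- sample(tBase)  # decouple the gradients
    if (seasonal) {
      phase <- 2 * pi * (seq_len(12) - 0.5) / 12
      npp <- outer(sin(phase), nppBase, function(s, n) n * (1 + 0.2 * s))
      temp <- outer(sin(phase), tBase, function(s, t) t + 3 * s)
      npp <- pmin(pmax(npp, nppRange[1]), nppRange[2])
      temp <- pmin(pmax(temp, tRange[1]), tRange[2])
    } else {
      npp <- matrix(nppBase, nrow = 1)
      temp <- matrix(tBase, nrow = 1)
    }
    forcing(npp, temp, area = cellArea,
            lme = rep_len(seq_len(nLME), nCells))
  })
}

.nppUnitFactor <- function(units) {
  switch(units,
    "mgC m-2 d-1" = 1,
    "gC m-2 yr-1" = 1000 / 365.25,
    stop("invalid argument: unsupported npp units '", units,
         "' (expected 'mgC m-2 d-1' or 'gC m-2 yr-1')"))
}

#' Read forcing from CSV
#'
#' Two layouts are supported. A site file has columns `npp` and
#' `temperature` (and optionally `time` or `month`) and describes a single
#' cell; twelve rows are treated as a cyclic monthly climatology. A grid
#' file additionally has a `cell` column, and optionally `area` and `lme`
#' columns (constant within cell). NPP units may be declared in a leading
#' comment line `# npp_units: <unit>`; `gC m-2 yr-1` is converted to the
#' internal `mgC m-2 d-1` by the factor 1000/365.25.
#'
#' @param path CSV file path.
#' @param area cell area (m^2) used when the file has no `area` column.
#' @param nppUnits NPP units, overriding any declaration in the file.
#' @return a [Forcing-class].
#' @export
readForcing <- function(path, area = 1, nppUnits = NULL) {
  if (!file.exists(path)) stop("invalid argument: no such file: ", path)
  header <- readLines(path, n = 10)
  header <- header[startsWith(header, "#")]
  if (is.null(nppUnits)) {
    decl <- grep("npp_units:", header, value = TRUE)
    nppUnits <- if (length(decl))
      trimws(sub(".*npp_units:", "", decl[1])) else "mgC m-2 d-1"
  }
  fac <- .nppUnitFactor(nppUnits)
  d <- read.csv(path, comment.char = "#")
  need <- c("npp", "temperature")
  if (!all(need %in% names(d)))
    stop("invalid argument: forcing file must have columns ",
         paste(need, collapse = ", "))
  if ("cell" %in% names(d)) {
    cells <- sort(unique(d$cell))
    times <- sort(unique(if ("month" %in% names(d)) d$month else 1))
    npp <- matrix(NA_real_, length(times), length(cells))
    temp <- npp
    d$month <- if ("month" %in% names(d)) d$month else 1
    for (j in seq_along(cells)) {
      dj <- d[d$cell == cells[j], ]
      dj <- dj[order(dj$month), ]
      npp[, j] <- dj$npp * fac
      temp[, j] <- dj$temperature
    }
    areas <- if ("area" %in% names(d))
      vapply(cells, function(cl) d$area[d$cell == cl][1], numeric(1))
    else rep(area, length(cells))
    lme <- if ("lme" %in% names(d))
      vapply(cells, function(cl) d$lme[d$cell == cl][1], numeric(1))
    else seq_along(cells)
    forcing(npp, temp, area = areas, lme = lme)
  } else {
    forcing(matrix(d$npp * fac, ncol = 1),
            matrix(d$temperature, ncol = 1), area = area, lme = 1L)
  }
}

#' Write forcing to CSV
#'
#' Writes the grid layout understood by [readForcing()], with an
#' `# npp_units: mgC m-2 d-1` declaration.
#'
#' @param x a [Forcing-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeForcing <- function(x, path) {
  stopifnot(is(x, "Forcing"))
  nt <- nrow(x@npp)
  d <- data.frame(
    cell = rep(seq_len(nCells(x)), each = nt),
    month = rep(seq_len(nt), nCells(x)),
    npp = as.vector(x@npp),
    temperature = as.vector(x@temperature),
    area = rep(x@area, each = nt),
    lme = rep(x@lme, each = nt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# npp_units: mgC m-2 d-1", con)
  write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
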