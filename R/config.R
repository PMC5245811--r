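#' Default run configuration
#'
#' The full configuration tree with every model parameter addressable by a
#' dotted key (e.g. `ecology.A0`). Sections and units:
#' \describe{
#'   \item{ecology}{arguments of [ecoParams()]: `A0` (g^(1-b) yr^-1), `b`,
#'     `omegaA`/`omegaLambda` (eV), `zeta1`, `h`, `alphaTe`, `betaPPMR`,
#'     `kE` (per degC), `PiStar`, `sE`, `delta1` (g cm^-delta2), `delta2`,
#'     `phiC` (NA = 1/K), `Tref` (K), `wetBPerC` (g wB / g C), `mPhyS`,
#'     `mPhyL` (g), `nppRef` (mg C m^-2 d^-1), `cRepro`, `xiPCapFactor`.}
#'   \item{economics}{arguments of [econParams()]: `price` ($ per g wB),
#'     `costPerEffort` ($ W^-1 s^-1), `kappaE` (W^2 m^-2 $^-1), `cSigma`,
#'     `eFloor` (W m^-2).}
#'   \item{community}{`mInf` (g, per group), `mAlphaFrac`, `dTheta` (per
#'     group), `eTheta`.}
#'   \item{grid}{`nBins` per group, `m0` (g).}
#'   \item{protocol}{arguments of [fishingProtocol()]: `spinupYears`,
#'     `rampYears`, `dtDays` (days), `q0` (m^2 W^-1 s^-1), `rampRate`
#'     (yr^-1 fraction).}
#'   \item{calibration}{`nDraws`, `selectFraction`, `hbCap` (yr^-1),
#'     `window` (g wB yr^-1, length 2), `relativeWindow` (logical),
#'     `noiseSd` (log10 units).}
#'   \item{seeds}{integer seeds: `priors`, `observations`, `forcing`.}
#' }
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    ecology = list(
      A0 = 4.46, b = 0.70, omegaA = 0.45, omegaLambda = 0.45,
      zeta1 = 0.55, mortalityScale = 0.025, h = 0.54, alphaTe = 0.13,
      betaPPMR = 5000,
      kE = 0.0631, PiStar = 0.37, sE = 0.025, delta1 = 0.01, delta2 = 3,
      phiC = NA_real_, Tref = 283.15, wetBPerC = 10, mPhyS = 1e-10,
      mPhyL = 1e-6, nppRef = 1000, cRepro = 16.7787, xiPCapFactor = 1e3),
    economics = list(
      price = 1.1e-3, costPerEffort = 1e-7, kappaE = 1e-6,
      cSigma = 16.7787, eFloor = 1e-15),
    community = list(
      mInf = c(30, 1e3, 1e5), mAlphaFrac = 0.25,
      dTheta = c(1, 0.5, 0.25), eTheta = 0.6198),
    grid = list(nBins = 50L, m0 = 0.01),
    protocol = list(
      spinupYears = 100, rampYears = 200, dtDays = 15, q0 = 1e-5,
      rampRate = 0.05),
    calibration = list(
      nDraws = 10000L, selectFraction = 0.01, hbCap = 0.4,
      window = c(70e12, 150e12), relativeWindow = FALSE, noiseSd = 0.3),
    seeds = list(priors = 1L, observations = 2L, forcing = 3L)
  )
}

# merge user values over defaults, rejecting keys the schema does not know
.mergeConfig <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("config error: unknown key '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("config error: key '", full, "' must be a section, got a value")
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                      c(path, key))
    } else if (!is.null(user[[key]])) {
      got <- user[[key]]
      if (is.list(got)) got <- unlist(got)
      defaults[[key]] <- got
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads a YAML file, validates every key against [defaultConfig()]
#' (unknown keys are rejected by dotted name) and fills unset keys with
#' their defaults. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return validated nested configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("invalid argument: no such file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  .mergeConfig(defaultConfig(), user)
}

#' Save a configuration to YAML
#'
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical YAML serialisation, for embedding in run
#' outputs so results can be traced to the exact configuration.
#'
#' @param config configuration list.
#' @return character(1) hex digest.
#' @export
configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Build model objects from a configuration
#'
#' @param config a configuration list from [loadConfig()] or
#'   [defaultConfig()].
#' @return `modelFromConfig`: a [FisheryModel-class];
#'   `protocolFromConfig`: a [FishingProtocol-class].
#' @export
modelFromConfig <- function(config) {
  eco <- do.call(ecoParams, config$ecology)
  econ <- do.call(econParams, config$economics)
  groups <- defaultGroups(mInf = config$community$mInf,
                          mAlphaFrac = config$community$mAlphaFrac,
                          dTheta = config$community$dTheta,
                          eTheta = config$community$eTheta)
  fisheryModel(eco, econ, groups, nBins = config$grid$nBins,
               m0 = config$grid$m0)
}

#' @rdname modelFromConfig
#' @export
protocolFromConfig <- function(config) {
  do.call(fishingProtocol, config$protocol)
}
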