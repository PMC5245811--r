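# shared small fixtures; heavy simulations live in the tests that need them

# eco parameters with unit rate constants: A0 chosen so the per-second
# allometric rate is exactly 1, no temperature dependence, mortality formula
# reduced to lambda = exp(zeta1)
unitEco <- function(b = 2 / 3, zeta1 = 0, h = 0.5, ...) {
  ecoParams(A0 = 360 * 86400, b = b, omegaA = 0, omegaLambda = 0,
            zeta1 = zeta1, mortalityScale = 1, h = h, ...)
}

tinyModel <- function(nBins = 15, eco = ecoParams(), econ = econParams()) {
  fisheryModel(eco, econ, nBins = nBins)
}

# deterministic spin-up state for a single cell, reused across tests
.spinCache <- new.env()
spunState <- function(npp = 1500, temperature = 10, years = 150,
                      nBins = 20, q0 = 0) {
  key <- paste(npp, temperature, years, nBins, q0, sep = "_")
  if (!is.null(.spinCache[[key]])) return(.spinCache[[key]])
  mod <- tinyModel(nBins = nBins)
  fc <- forcing(npp = npp, temperature = temperature)
  pr <- fishingProtocol(spinupYears = years, rampYears = 0, dtDays = 30,
                        q0 = q0)
  res <- runCell(fc, mod, pr)
  out <- list(model = mod, forcing = fc, state = res@finalState,
              result = res)
  .spinCache[[key]] <- out
  out
}

selectableBiomass <- function(model, state) {
  vapply(seq_len(nGroups(model)), function(k)
    sum(model@sigma[[k]] * state$f[[k]][, 1] *
          binWidths(model@grids[[k]])), numeric(1))
}

totalBiomass <- function(model, state) {
  vapply(seq_len(nGroups(model)), function(k)
    sum(state$f[[k]][, 1] * binWidths(model@grids[[k]])), numeric(1))
}
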