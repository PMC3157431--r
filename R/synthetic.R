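#' @include AllClasses.R geometry.R bias.R
#' @importFrom stats rlnorm runif
NULL

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Expected spot intensity at a ring position
#'
#' The generator's phenomenological ring-mean model: a flat interior
#' plateau plus an exponentially decaying boundary enhancement,
#' `abundance * (baseIntensity + boundaryAmplitude *
#' exp(-(ring - 1)/decayLength))`, hard-clipped at `saturationCeiling`
#' when one is set.  With a low ceiling and unequal channel abundances
#' the clipping compresses the abundant channel most where both signals
#' are high -- at the boundary -- which inflates the ring-wise channel
#' ratio towards the array center (the mechanism behind ratio bias in
#' competitive hybridizations).
#'
#' @param ring ring position(s), 1-based.
#' @param params a [SyntheticArrayParams-class].
#' @param channel channel index.
#' @return Expected intensity (a.u.), vectorized over `ring`.
#' @export
ringMeanModel <- function(ring, params, channel = 1L) {
  stopifnot(is(params, "SyntheticArrayParams"))
  if (channel > length(params@channelAbundances))
    stop("channel ", channel, " not defined by these parameters")
  v <- params@channelAbundances[channel] *
    (params@baseIntensity +
       params@boundaryAmplitude * exp(-(ring - 1) / params@decayLength))
  if (!is.na(params@saturationCeiling))
    v <- pmin(v, params@saturationCeiling)
  v
}

#' Generate synthetic replicate hybridization tables
#'
#' Draws `nReplicates` per-spot intensity tables from the ring-mean model
#' with lognormal multiplicative noise of coefficient of variation
#' `noiseCV` (unit mean, so empirical ring means converge to the model),
#' flags a random `flagFraction` of spots as bad, and returns the exact
#' generating ring means alongside the tables so recovery can be tested.
#' Fully reproducible from `params@seed`.
#'
#' @param params a [SyntheticArrayParams-class].
#' @return List with `tables` (list of [SpotIntensityTable-class], one
#'   per replicate hybridization) and `truth` (list: `positions`,
#'   `ringMeans` matrix positions x channels, `params`).
#' @examples
#' sim <- generateTables(syntheticArrayParams(nRows = 8, nCols = 8))
#' summarizeByPosition(sim$tables)
#' @export
generateTables <- function(params) {
  stopifnot(is(params, "SyntheticArrayParams"))
  nR <- params@nRows; nC <- params@nCols
  g <- expand.grid(row = seq_len(nR) - 1L, col = seq_len(nC) - 1L)
  ring <- ringPosition(g$row, g$col, nR, nC)
  nCh <- length(params@channelAbundances)
  mu <- vapply(seq_len(nCh),
               function(ch) ringMeanModel(ring, params, ch),
               numeric(nrow(g)))
  cv <- params@noiseCV
  sdlog <- sqrt(log(1 + cv^2))

  tables <- .with_seed(params@seed, lapply(seq_len(params@nReplicates),
    function(rep) {
      draw <- function(ch) {
        if (cv == 0) mu[, ch]
        else mu[, ch] * rlnorm(nrow(g), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
      }
      spots <- data.frame(
        block = 1L, row = g$row, col = g$col,
        ch1 = draw(1L),
        ch2 = if (nCh == 2L) draw(2L) else NA_real_,
        flag = ifelse(runif(nrow(g)) < params@flagFraction, -100L, 0L))
      spotIntensityTable(spots, nR, nC,
                         metadata = list(replicate = rep,
                                         seed = params@seed))
    }))

  positions <- seq_len(maxRing(nR, nC))
  ringMeans <- vapply(seq_len(nCh),
                      function(ch) ringMeanModel(positions, params, ch),
                      numeric(length(positions)))
  list(tables = tables,
       truth = list(positions = positions,
                    ringMeans = matrix(ringMeans, ncol = nCh),
                    params = params))
}

#' Generator settings for the two-colour ratio-bias fixture
#'
#' Convenience parameter set emulating a competitive two-colour
#' hybridization of targets mixed near 3:1 whose abundant channel
#' saturates at the boundary: effective channel abundances 2.9:1 with an
#' intensity ceiling placed so the ring-1 ratio of channel means is 2.6
#' while unclipped interior positions approach 2.9.  Illustrative
#' clipping mechanism, not a mechanistic model.
#'
#' @param seed integer seed.
#' @param noiseCV noise coefficient of variation.
#' @param nReplicates replicate hybridizations.
#' @return A [SyntheticArrayParams-class].
#' @export
ratioBiasParams <- function(seed = 1L, noiseCV = 0.1, nReplicates = 3) {
  base <- 5000; amp <- 15000
  syntheticArrayParams(nRows = 30, nCols = 30, baseIntensity = base,
                       boundaryAmplitude = amp, decayLength = 3,
                       noiseCV = noiseCV, nReplicates = nReplicates,
                       channelAbundances = c(2.9, 1),
                       saturationCeiling = 2.6 * (base + amp),
                       flagFraction = 0, seed = seed)
}

#' Intensity table proportional to simulated spot fluxes
#'
#' Converts a simulated [SpotFluxSeries-class] (or a flux table
#' data.frame) into a [SpotIntensityTable-class] whose channel-1
#' intensity is proportional to each spot's cumulative absorbed flux,
#' optionally with multiplicative lognormal noise -- the bridge between
#' the diffusion model's predictions and the intensity-analysis layer.
#'
#' @param flux a [SpotFluxSeries-class], or a data.frame with columns
#'   `row`, `col`, `cumulative_flux` (then `nRows`/`nCols` are required).
#' @param abundance proportionality constant (a.u. per flux unit).
#' @param noiseCV lognormal noise CV (default 0, exact proportionality).
#' @param seed integer seed for the noise.
#' @param nRows,nCols grid dimensions for data.frame input.
#' @return A [SpotIntensityTable-class].
#' @export
tableFromFlux <- function(flux, abundance = 1, noiseCV = 0, seed = 1L,
                          nRows = NULL, nCols = NULL) {
  if (is(flux, "SpotFluxSeries")) {
    ft <- fluxTable(flux)
    nRows <- flux@layout@nRows; nCols <- flux@layout@nCols
  } else {
    ft <- as.data.frame(flux)
    if (is.null(ft$cumulative_flux) || is.null(ft$row) || is.null(ft$col))
      stop("flux table must have columns row, col, cumulative_flux")
    if (is.null(nRows) || is.null(nCols))
      stop("supply 'nRows' and 'nCols' with a data.frame flux table")
    if (any(ft$row >= nRows) || any(ft$col >= nCols))
      stop("flux table does not match the declared grid dimensions")
  }
  mult <- if (noiseCV == 0) 1 else .with_seed(seed, {
    sdlog <- sqrt(log(1 + noiseCV^2))
    rlnorm(nrow(ft), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  spots <- data.frame(block = 1L, row = ft$row, col = ft$col,
                      ch1 = abundance * ft$cumulative_flux * mult,
                      ch2 = NA_real_, flag = 0L)
  spotIntensityTable(spots, nRows, nCols,
                     metadata = list(source = "simulated_flux"))
}
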