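#' @include AllClasses.R
NULL

#' Accessors for spotbias classes
#'
#' Small accessor generics so that slots never need to be touched directly.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("halfLength", function(x) standardGeneric("halfLength"))
#' @rdname accessors
#' @export
setGeneric("chamberHeight", function(x) standardGeneric("chamberHeight"))
#' @rdname accessors
#' @export
setGeneric("arrayDim", function(x) standardGeneric("arrayDim"))
#' @rdname accessors
#' @export
setGeneric("spotDiameter", function(x) standardGeneric("spotDiameter"))
#' @rdname accessors
#' @export
setGeneric("spotPitch", function(x) standardGeneric("spotPitch"))
#' @rdname accessors
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))
#' @rdname accessors
#' @export
setGeneric("spotData", function(x) standardGeneric("spotData"))
#' @rdname accessors
#' @export
setGeneric("fluxTable", function(x) standardGeneric("fluxTable"))
#' @rdname accessors
#' @export
setGeneric("fluxTimes", function(x) standardGeneric("fluxTimes"))
#' @rdname accessors
#' @export
setGeneric("damkohlerNumber", function(x) standardGeneric("damkohlerNumber"))

#' Inner-to-outer signal or flux ratio
#'
#' Ratio (in percent) of the mean value of the innermost ring of spots to
#' the mean of the outermost ring (ring 1); the headline measure of the
#' boundary bias.
#'
#' @param x per-spot values: a [SpotFluxSeries-class] (final cumulative
#'   flux), a [SpotIntensityTable-class] (channel intensities), or a
#'   data.frame with columns `row`, `col`, `value`.
#' @param ... passed to methods (e.g. `nRows`, `nCols` for data.frames;
#'   `channel` for intensity tables).
#' @return Percentage, 100 * mean(innermost ring)/mean(ring 1).
#' @export
setGeneric("innerOuterRatio", function(x, ...) standardGeneric("innerOuterRatio"))

setMethod("halfLength", "ChamberGeometry", function(x) x@halfLength)
setMethod("chamberHeight", "ChamberGeometry", function(x) x@height)
setMethod("arrayDim", "SpotArrayLayout", function(x) c(x@nRows, x@nCols))
setMethod("arrayDim", "SpotIntensityTable", function(x) c(x@nRows, x@nCols))
setMethod("spotDiameter", "SpotArrayLayout", function(x) x@spotDiameter)
setMethod("spotPitch", "SpotArrayLayout", function(x) x@pitch)
setMethod("nSpots", "SpotArrayLayout", function(x) as.integer(x@nRows) * x@nCols)
setMethod("spotData", "SpotIntensityTable", function(x) x@spots)
setMethod("spotData", "SpotFluxSeries", function(x) x@spots)
setMethod("fluxTimes", "SpotFluxSeries", function(x) x@times)
setMethod("damkohlerNumber", "ScalingReport", function(x) x@P)

#' @describeIn SpotFluxSeries-class final per-spot cumulative flux as a
#'   data.frame (`row`, `col`, `ring_position`, `cumulative_flux`, `x`, `y`).
#' @param x a `SpotFluxSeries`.
#' @export
setMethod("fluxTable", "SpotFluxSeries", function(x) {
  data.frame(row = x@spots$row, col = x@spots$col,
             ring_position = x@spots$ring,
             cumulative_flux = x@cumulative[nrow(x@cumulative), ],
             x = x@spots$x, y = x@spots$y)
})

setMethod("show", "ChamberGeometry", function(object) {
  cat(sprintf("ChamberGeometry: footprint %.1f x %.1f mm, height %.0f um\n",
              2e3 * object@halfLength, 2e3 * object@halfLength,
              1e6 * object@height))
})

setMethod("show", "SpotArrayLayout", function(object) {
  cat(sprintf("SpotArrayLayout: %d x %d spots, diameter %.0f um, pitch %.0f um\n",
              object@nRows, object@nCols, 1e6 * object@spotDiameter,
              1e6 * object@pitch))
})

setMethod("show", "KineticParams", function(object) {
  cat("KineticParams:\n")
  cat(sprintf("  D  = %.3g m^2/s   k = %.3g /M/s\n", object@D, object@k))
  cat(sprintf("  B0 = %.3g M (%.3g mM)   R = %.0f um   h = %.0f um\n",
              object@B0, 1e3 * object@B0, 1e6 * object@R, 1e6 * object@h))
})

setMethod("show", "ScalingReport", function(object) {
  cat("Scaling analysis (perfect-sink check):\n")
  cat(sprintf("  reaction timescale 1/(k B0):  %.2g s\n", object@tReaction))
  cat(sprintf("  diffusion timescale %s^2/D:   %.2g s (limiting length: %s)\n",
              object@limitingLength, object@tDiffusion, object@limitingLength))
  cat(sprintf("  P = %.2g  (threshold %.2g): perfect-sink assumption %s\n",
              object@P, object@sinkThreshold,
              if (object@sinkAssumptionValid) "JUSTIFIED" else "NOT justified"))
})

setMethod("show", "SimulationGrid", function(object) {
  cat(sprintf("SimulationGrid (%s): %d x %d x %d cells (dx %.0f um, dz %.1f um), %d spots\n",
              object@symmetry, object@nx, object@ny, object@nz,
              1e6 * object@dx, 1e6 * object@dz, nrow(object@spotTable)))
})

setMethod("show", "SpotFluxSeries", function(object) {
  nt <- length(object@times)
  cat(sprintf("SpotFluxSeries: %d spots, %d output times over %.1f h\n",
              nrow(object@spots), nt, object@times[nt] / 3600))
  cat(sprintf("  absorbed fraction of target: %.3f\n",
              sum(object@cumulative[nt, ]) / object@initialMass))
})

setMethod("show", "SpotIntensityTable", function(object) {
  two <- !all(is.na(object@spots$ch2))
  cat(sprintf("SpotIntensityTable: %d spots on a %d x %d grid, %s, %d flagged\n",
              nrow(object@spots), object@nRows, object@nCols,
              if (two) "two channels" else "one channel",
              sum(object@spots$flag < 0)))
})

setMethod("show", "SyntheticArrayParams", function(object) {
  cat(sprintf(
    "SyntheticArrayParams: %d x %d grid, %d replicate(s), %d channel(s)\n",
    object@nRows, object@nCols, object@nReplicates,
    length(object@channelAbundances)))
  cat(sprintf("  ring mean: %g + %g * exp(-(ring-1)/%g), noise CV %g%s\n",
              object@baseIntensity, object@boundaryAmplitude,
              object@decayLength, object@noiseCV,
              if (is.na(object@saturationCeiling)) ""
              else sprintf(", ceiling %g", object@saturationCeiling)))
})
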