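#' @import methods
NULL

.scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    return(sprintf("'%s' must be a single finite positive number", what))
  NULL
}

#' ChamberGeometry: hybridization chamber dimensions
#'
#' A sealed hybridization chamber with a square footprint of side `2 * L`
#' (half-length `L`) and fluid height `H`, both in meters.  The spot array
#' sits on the chamber floor; all other chamber surfaces are impermeable
#' to the target.
#'
#' @slot halfLength half-length L of the square footprint (m).
#' @slot height chamber (well) height H (m).
#' @export
setClass("ChamberGeometry",
  slots = c(halfLength = "numeric", height = "numeric"))

setValidity("ChamberGeometry", function(object) {
  msg <- c(.scalar_pos(object@halfLength, "halfLength"),
           .scalar_pos(object@height, "height"))
  if (length(msg)) msg else TRUE
})

#' @param halfLength half-length L of the square chamber footprint (m).
#' @param height chamber height H (m).
#' @return A [ChamberGeometry-class] object.
#' @examples
#' chamberGeometry(halfLength = 10.8e-3, height = 0.25e-3)
#' @rdname ChamberGeometry-class
#' @export
chamberGeometry <- function(halfLength, height) {
  new("ChamberGeometry", halfLength = as.numeric(halfLength),
      height = as.numeric(height))
}

#' SpotArrayLayout: regular grid of probe spot disks
#'
#' A regular `nRows` x `nCols` grid of circular probe spots printed on the
#' chamber floor and centered within the chamber footprint.  `pitch` is the
#' center-to-center spacing.
#'
#' @slot nRows,nCols grid dimensions (>= 2).
#' @slot spotDiameter spot disk diameter (m).
#' @slot pitch center-to-center spot spacing (m); must be >= `spotDiameter`
#'   so that spots never overlap.
#' @export
setClass("SpotArrayLayout",
  slots = c(nRows = "integer", nCols = "integer",
            spotDiameter = "numeric", pitch = "numeric"))

setValidity("SpotArrayLayout", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 2L)
    msg <- c(msg, "'nRows' must be a single integer >= 2")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 2L)
    msg <- c(msg, "'nCols' must be a single integer >= 2")
  msg <- c(msg, .scalar_pos(object@spotDiameter, "spotDiameter"),
           .scalar_pos(object@pitch, "pitch"))
  if (!length(msg) && object@pitch < object@spotDiameter)
    msg <- "'pitch' must be >= 'spotDiameter' (spots must not overlap)"
  if (length(msg)) msg else TRUE
})

#' @param nRows,nCols grid dimensions.
#' @param spotDiameter spot diameter (m); default 150 um, the printed spot
#'   size of the simplified single-probe array.
#' @param pitch center-to-center spacing (m); default 300 um (150 um spot
#'   plus 150 um gap).
#' @return A [SpotArrayLayout-class] object.
#' @examples
#' spotArrayLayout(30, 30)
#' @rdname SpotArrayLayout-class
#' @export
spotArrayLayout <- function(nRows, nCols, spotDiameter = 150e-6,
                            pitch = 300e-6) {
  new("SpotArrayLayout", nRows = as.integer(nRows), nCols = as.integer(nCols),
      spotDiameter = as.numeric(spotDiameter), pitch = as.numeric(pitch))
}

#' KineticParams: transport and hybridization kinetics
#'
#' Physical parameters feeding the dimensionless scaling analysis: target
#' diffusion coefficient `D`, hybridization rate constant `k`, effective
#' probe concentration in the dried spot `B0`, spot radius `R`, chamber
#' height `h`, and optionally the spotting-solution probe concentration
#' `BS` and dried-spot height `hD` from which `B0` can be estimated.
#'
#' Defaults are the values used for the simplified single-probe array:
#' D = 1e-9 m^2/s (single-stranded RNA), k = 5.0e4 /M/s (Wetmur-Davidson
#' estimate, supplied as an input, not re-derived), R = 75 um, h = 250 um,
#' B_S = 50 uM, h_D = 2 um.
#'
#' @slot D target diffusion coefficient (m^2/s).
#' @slot k hybridization rate constant (1/M/s).
#' @slot B0 effective probe concentration in the spot (M).
#' @slot R spot radius (m).
#' @slot h chamber height used for the scaling (m).
#' @slot C0 reference target concentration (arbitrary; the model is linear
#'   in C so results are reported relative to C0 = 1).
#' @slot BS spotting-solution probe concentration (M), may be `NA`.
#' @slot hD dried spot height (m), may be `NA`.
#' @export
setClass("KineticParams",
  slots = c(D = "numeric", k = "numeric", B0 = "numeric", R = "numeric",
            h = "numeric", C0 = "numeric", BS = "numeric", hD = "numeric"))

setValidity("KineticParams", function(object) {
  msg <- c(.scalar_pos(object@D, "D"), .scalar_pos(object@k, "k"),
           .scalar_pos(object@B0, "B0"), .scalar_pos(object@R, "R"),
           .scalar_pos(object@h, "h"), .scalar_pos(object@C0, "C0"))
  for (nm in c("BS", "hD")) {
    v <- slot(object, nm)
    if (!(length(v) == 1L && is.na(v))) msg <- c(msg, .scalar_pos(v, nm))
  }
  if (length(msg)) msg else TRUE
})

#' @param D diffusion coefficient (m^2/s).
#' @param k hybridization rate constant (1/M/s).
#' @param B0 effective probe concentration (M); if `NULL`, estimated from
#'   `R`, `hD` and `BS` via [estimateProbeConcentration()].
#' @param R spot radius (m).
#' @param h chamber height (m).
#' @param C0 reference target concentration (default 1).
#' @param BS spotting-solution probe concentration (M) or `NA`.
#' @param hD dried spot height (m) or `NA`.
#' @return A [KineticParams-class] object.
#' @examples
#' kineticParams()          # the study's defaults; B0 = 1.25 mM
#' @rdname KineticParams-class
#' @export
kineticParams <- function(D = 1e-9, k = 5.0e4, B0 = NULL, R = 75e-6,
                          h = 250e-6, C0 = 1, BS = 50e-6, hD = 2e-6) {
  if (is.null(B0)) {
    if (is.na(BS) || is.na(hD))
      stop("supply 'B0' directly, or both 'BS' and 'hD' to estimate it")
    B0 <- estimateProbeConcentration(R = R, hD = hD, BS = BS)
  }
  new("KineticParams", D = as.numeric(D), k = as.numeric(k),
      B0 = as.numeric(B0), R = as.numeric(R), h = as.numeric(h),
      C0 = as.numeric(C0), BS = as.numeric(BS), hD = as.numeric(hD))
}

#' ScalingReport: timescales and the dimensionless parameter P
#'
#' Result of the scaling analysis: the hybridization (reaction) timescale
#' 1/(k B0), the diffusion timescale set by the limiting length (the spot
#' radius R when R < h, else the chamber height h), their ratio P, and
#' whether P is small enough to justify the perfect-sink boundary
#' condition C = 0 at the spots.
#'
#' @slot tReaction hybridization timescale 1/(k B0) (s).
#' @slot tDiffusion diffusion timescale (limiting length)^2 / D (s).
#' @slot P dimensionless ratio tReaction / tDiffusion.
#' @slot limitingLength `"R"` or `"h"`, whichever set the diffusion scale.
#' @slot sinkThreshold threshold below which P is considered << 1.
#' @slot sinkAssumptionValid logical, `P < sinkThreshold` (strict).
#' @slot params the [KineticParams-class] used.
#' @export
setClass("ScalingReport",
  slots = c(tReaction = "numeric", tDiffusion = "numeric", P = "numeric",
            limitingLength = "character", sinkThreshold = "numeric",
            sinkAssumptionValid = "logical", params = "KineticParams"))

setValidity("ScalingReport", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@P, object@tReaction / object@tDiffusion,
                        tolerance = 1e-12)))
    msg <- c(msg, "P must equal tReaction / tDiffusion")
  if (!object@limitingLength %in% c("R", "h"))
    msg <- c(msg, "limitingLength must be \"R\" or \"h\"")
  if (length(msg)) msg else TRUE
})

#' SimulationGrid: finite-difference discretization of the chamber
#'
#' Regular grid tiling the chamber (or, in quadrant mode, one quarter of
#' it, with the symmetry planes carrying no-flux conditions).  Floor cells
#' whose centers lie inside a spot disk are flagged as perfect sinks and
#' assigned to that spot.
#'
#' @slot nx,ny,nz cell counts; @slot dx,dy,dz spacings (m).
#' @slot x0,y0 coordinates of the low corner of the domain (m, chamber-
#'   centered frame).
#' @slot spotId integer matrix (nx x ny): 0 for plain floor, otherwise the
#'   1-based spot id within `spotTable`.
#' @slot spotTable data.frame of the spots present in the domain
#'   (id, row, col, x, y).
#' @slot symmetry `"full"` or `"quadrant"`.
#' @slot allAbsorbing if `TRUE` the whole floor is a single perfect sink
#'   (used for the 1D slab validation).
#' @slot chamber,layout the geometry the grid was built from.
#' @export
setClass("SimulationGrid",
  slots = c(nx = "integer", ny = "integer", nz = "integer",
            dx = "numeric", dy = "numeric", dz = "numeric",
            x0 = "numeric", y0 = "numeric",
            spotId = "matrix", spotTable = "data.frame",
            symmetry = "character", allAbsorbing = "logical",
            chamber = "ChamberGeometry", layout = "SpotArrayLayout"))

#' ConcentrationField: target concentration on a SimulationGrid
#'
#' Dimensionless target concentration C/C0 per cell at a given time.
#' Values obey the maximum principle 0 <= C <= 1 up to solver round-off.
#'
#' @slot values numeric array of dim (nx, ny, nz).
#' @slot time simulation time (s).
#' @export
setClass("ConcentrationField",
  slots = c(values = "array", time = "numeric"))

#' SpotFluxSeries: per-spot absorbed target flux over time
#'
#' Instantaneous Fickian absorption rate and cumulative absorbed amount
#' for every spot at each output time, plus the remaining chamber mass
#' (all C0-normalized; amounts are in m^3 of initial-concentration
#' equivalent fluid).  Per-spot values always refer to whole spots of the
#' full layout, also when the simulation exploited quadrant symmetry.
#'
#' @slot times output times (s).
#' @slot instantaneous matrix (times x spots) of absorption rates (m^3/s).
#' @slot cumulative matrix (times x spots) of cumulative absorbed amount.
#' @slot spots data.frame (row, col, ring, x, y) for the full layout.
#' @slot mass remaining target amount in the full chamber at each time.
#' @slot initialMass initial target amount (chamber volume, C0 = 1).
#' @slot D diffusion coefficient used (m^2/s).
#' @slot chamber,layout geometry of the run.
#' @slot finalField concentration array (simulated domain) at the final
#'   time, for diagnostics.
#' @export
setClass("SpotFluxSeries",
  slots = c(times = "numeric", instantaneous = "matrix",
            cumulative = "matrix", spots = "data.frame", mass = "numeric",
            initialMass = "numeric", D = "numeric",
            chamber = "ChamberGeometry", layout = "SpotArrayLayout",
            finalField = "array"))

setValidity("SpotFluxSeries", function(object) {
  msg <- character()
  if (nrow(object@cumulative) != length(object@times))
    msg <- c(msg, "cumulative must have one row per output time")
  if (ncol(object@cumulative) != nrow(object@spots))
    msg <- c(msg, "cumulative must have one column per spot")
  if (any(diff(object@times) <= 0)) msg <- c(msg, "times must increase")
  dec <- apply(object@cumulative, 2, function(x) any(diff(x) < -1e-12))
  if (any(dec)) msg <- c(msg, "cumulative series must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' SpotIntensityTable: per-spot scanned or synthetic intensities
#'
#' One hybridization's worth of per-spot records: block id, 0-based row
#' and column on the grid, one or two channel intensities and a quality
#' flag (negative = excluded, the GenePix convention).  Grid dimensions
#' are carried so that ring positions can be computed.
#'
#' @slot spots data.frame with columns `block`, `row`, `col`, `ch1`,
#'   `ch2` (may be `NA` throughout for single-channel data), `flag`.
#' @slot nRows,nCols grid dimensions.
#' @slot metadata free-form list (source file, generator truth id, ...).
#' @export
setClass("SpotIntensityTable",
  slots = c(spots = "data.frame", nRows = "integer", nCols = "integer",
            metadata = "list"))

setValidity("SpotIntensityTable", function(object) {
  msg <- character()
  need <- c("block", "row", "col", "ch1", "ch2", "flag")
  if (!all(need %in% names(object@spots)))
    msg <- c(msg, paste("spots must have columns:", paste(need, collapse = ", ")))
  else {
    s <- object@spots
    if (anyDuplicated(s[c("block", "row", "col")]))
      msg <- c(msg, "(block, row, col) must be unique")
    if (any(s$row < 0L | s$row >= object@nRows |
            s$col < 0L | s$col >= object@nCols))
      msg <- c(msg, "row/col indices out of the declared grid")
    ok <- s$flag >= 0
    if (any(s$ch1[ok] < 0, na.rm = TRUE) || any(s$ch2[ok] < 0, na.rm = TRUE))
      msg <- c(msg, "unflagged intensities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param spots data.frame of per-spot records; missing `block`, `ch2` or
#'   `flag` columns are filled with defaults (block 1, `NA`, 0).
#' @param nRows,nCols grid dimensions.
#' @param metadata optional list.
#' @return A [SpotIntensityTable-class] object.
#' @rdname SpotIntensityTable-class
#' @export
spotIntensityTable <- function(spots, nRows, nCols, metadata = list()) {
  spots <- as.data.frame(spots)
  if (is.null(spots$block)) spots$block <- 1L
  if (is.null(spots$ch2)) spots$ch2 <- NA_real_
  if (is.null(spots$flag)) spots$flag <- 0L
  spots <- spots[c("block", "row", "col", "ch1", "ch2", "flag")]
  spots$row <- as.integer(spots$row); spots$col <- as.integer(spots$col)
  spots$ch1 <- as.numeric(spots$ch1); spots$ch2 <- as.numeric(spots$ch2)
  spots$flag <- as.integer(spots$flag)
  new("SpotIntensityTable", spots = spots, nRows = as.integer(nRows),
      nCols = as.integer(nCols), metadata = metadata)
}

#' SyntheticArrayParams: generator settings for synthetic spot tables
#'
#' Parameters of the synthetic per-spot intensity generator.  The ring-mean
#' model is `abundance * (baseIntensity + boundaryAmplitude *
#' exp(-(ring - 1)/decayLength))`, clipped at `saturationCeiling` when set;
#' spot intensities are the ring mean times lognormal multiplicative noise
#' of coefficient of variation `noiseCV`.
#'
#' @slot nRows,nCols grid dimensions.
#' @slot baseIntensity plateau intensity of interior spots (a.u.).
#' @slot boundaryAmplitude extra intensity of ring-1 spots (a.u.).
#' @slot decayLength e-folding scale of the boundary enhancement (rings).
#' @slot noiseCV fractional coefficient of variation of spot noise.
#' @slot nReplicates number of replicate hybridizations to generate.
#' @slot channelAbundances relative target abundance of each channel
#'   (length 1 = single-colour, length 2 = two-colour).
#' @slot saturationCeiling intensity ceiling (a.u.) or `NA` for none.
#' @slot flagFraction fraction of spots flagged bad at random (< 0.1).
#' @slot seed integer seed fixing all randomness.
#' @export
setClass("SyntheticArrayParams",
  slots = c(nRows = "integer", nCols = "integer", baseIntensity = "numeric",
            boundaryAmplitude = "numeric", decayLength = "numeric",
            noiseCV = "numeric", nReplicates = "integer",
            channelAbundances = "numeric", saturationCeiling = "numeric",
            flagFraction = "numeric", seed = "integer"))

setValidity("SyntheticArrayParams", function(object) {
  msg <- character()
  if (object@baseIntensity <= 0) msg <- c(msg, "baseIntensity must be > 0")
  if (object@boundaryAmplitude < 0)
    msg <- c(msg, "boundaryAmplitude must be >= 0")
  if (object@decayLength <= 0) msg <- c(msg, "decayLength must be > 0")
  if (object@noiseCV < 0) msg <- c(msg, "noiseCV must be >= 0")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (!length(object@channelAbundances) %in% 1:2 ||
      any(object@channelAbundances <= 0))
    msg <- c(msg, "channelAbundances must be 1 or 2 positive values")
  if (object@flagFraction < 0 || object@flagFraction >= 0.1)
    msg <- c(msg, "flagFraction must be in [0, 0.1)")
  if (length(msg)) msg else TRUE
})

#' @param nRows,nCols grid dimensions (default 30 x 30, the simplified
#'   single-probe block).
#' @param baseIntensity,boundaryAmplitude,decayLength ring-mean model
#'   parameters; defaults give a ~3.9x boundary-to-center contrast.
#' @param noiseCV multiplicative noise CV (default 0.1).
#' @param nReplicates replicate hybridizations (default 3, as in the
#'   triplicate experiments).
#' @param channelAbundances one or two relative channel abundances.
#' @param saturationCeiling intensity ceiling or `NA`.
#' @param flagFraction random bad-spot fraction (default 0.02).
#' @param seed integer seed.
#' @return A [SyntheticArrayParams-class] object.
#' @examples
#' syntheticArrayParams()
#' @rdname SyntheticArrayParams-class
#' @export
syntheticArrayParams <- function(nRows = 30, nCols = 30,
                                 baseIntensity = 5000,
                                 boundaryAmplitude = 15000,
                                 decayLength = 3, noiseCV = 0.1,
                                 nReplicates = 3, channelAbundances = 1,
                                 saturationCeiling = NA_real_,
                                 flagFraction = 0.02, seed = 1L) {
  new("SyntheticArrayParams", nRows = as.integer(nRows),
      nCols = as.integer(nCols), baseIntensity = as.numeric(baseIntensity),
      boundaryAmplitude = as.numeric(boundaryAmplitude),
      decayLength = as.numeric(decayLength), noiseCV = as.numeric(noiseCV),
      nReplicates = as.integer(nReplicates),
      channelAbundances = as.numeric(channelAbundances),
      saturationCeiling = as.numeric(saturationCeiling),
      flagFraction = as.numeric(flagFraction), seed = as.integer(seed))
}
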