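#' @include AllClasses.R geometry.R
#' @useDynLib spotbias, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Chamber/layout presets for the simulation study
#'
#' The three chamber configurations compared in the modeling study, plus
#' the full-coverage design: `"default"` (large shallow chamber,
#' L = 10.8 mm, H = 150 um, 30 x 30 spots), `"deep"` (L = 10.8 mm,
#' H = 750 um, 30 x 30), `"small"` (L = 4.5 mm, H = 150 um, 30 x 30, no
#' spotless margin to speak of), and `"full_coverage"` (the experimental
#' chamber, L = 10.8 mm, H = 250 um, with a 70 x 72 block of 5040 spots
#' reaching the chamber walls).  All presets share 150 um spot diameter
#' and 300 um pitch.
#'
#' @param name one of `"default"`, `"deep"`, `"small"`, `"full_coverage"`.
#' @return List with elements `chamber` ([ChamberGeometry-class]) and
#'   `layout` ([SpotArrayLayout-class]).
#' @examples
#' nSpots(configPreset("default")$layout)        # 900
#' nSpots(configPreset("full_coverage")$layout)  # 5040
#' @export
configPreset <- function(name = c("default", "deep", "small",
                                  "full_coverage")) {
  name <- match.arg(name)
  switch(name,
    default = list(chamber = chamberGeometry(10.8e-3, 150e-6),
                   layout = spotArrayLayout(30, 30)),
    deep = list(chamber = chamberGeometry(10.8e-3, 750e-6),
                layout = spotArrayLayout(30, 30)),
    small = list(chamber = chamberGeometry(4.5e-3, 150e-6),
                 layout = spotArrayLayout(30, 30)),
    full_coverage = list(chamber = chamberGeometry(10.8e-3, 250e-6),
                         layout = spotArrayLayout(70, 72)))
}

#' Build the finite-difference grid for a chamber and spot layout
#'
#' Discretizes the chamber into a regular grid of cells that tile it
#' exactly (the requested lateral resolution is rounded so an integer
#' number of cells fits).  A floor cell is a perfect sink iff its center
#' lies inside a spot disk.  In `"quadrant"` mode only one quarter of the
#' chamber is discretized; the symmetry planes carry the same no-flux
#' condition as the walls.  Quadrant mode requires even grid dimensions
#' (so no spot straddles a symmetry plane).
#'
#' @param chamber a [ChamberGeometry-class].
#' @param layout a [SpotArrayLayout-class].
#' @param lateralResolution target lateral cell size (m), default 50 um
#'   (3 cells across a 150 um spot).
#' @param verticalCells number of vertical cells; default one cell per
#'   25 um of chamber height (minimum 3).
#' @param symmetry `"quadrant"` (default) or `"full"`.
#' @param allAbsorbingFloor if `TRUE`, ignore the layout and make the
#'   entire floor one absorbing patch (1D slab validation case).
#' @return A [SimulationGrid-class].
#' @export
buildGrid <- function(chamber, layout,
                      lateralResolution = 50e-6, verticalCells = NULL,
                      symmetry = c("quadrant", "full"),
                      allAbsorbingFloor = FALSE) {
  symmetry <- match.arg(symmetry)
  stopifnot(is(chamber, "ChamberGeometry"), is(layout, "SpotArrayLayout"))
  if (lateralResolution > layout@pitch)
    stop("lateral resolution coarser than the spot pitch")
  if (lateralResolution > layout@spotDiameter / 3 + 1e-12 &&
      !allAbsorbingFloor)
    warning("fewer than 3 cells across a spot; results will be coarse")

  L <- chamber@halfLength
  nR <- layout@nRows; nC <- layout@nCols
  spotCenters(layout, chamber)   # errors if the layout does not fit

  if (symmetry == "quadrant") {
    if (nR %% 2L || nC %% 2L)
      stop("quadrant symmetry requires even grid dimensions")
    nx <- max(2L, as.integer(round(L / lateralResolution)))
    dx <- L / nx
    x0 <- 0
  } else {
    nx <- max(2L, as.integer(round(2 * L / lateralResolution)))
    dx <- 2 * L / nx
    x0 <- -L
  }
  ny <- nx; dy <- dx; y0 <- x0
  nz <- if (is.null(verticalCells))
    max(3L, as.integer(round(chamber@height / 25e-6)))
  else as.integer(verticalCells)
  dz <- chamber@height / nz

  xc <- x0 + (seq_len(nx) - 0.5) * dx
  yc <- y0 + (seq_len(ny) - 0.5) * dy

  if (allAbsorbingFloor) {
    spotId <- matrix(1L, nx, ny)
    spotTable <- data.frame(id = 1L, row = NA_integer_, col = NA_integer_,
                            x = 0, y = 0)
  } else {
    # nearest spot by rounding; sink iff cell center within the disk
    p <- layout@pitch; rad <- layout@spotDiameter / 2
    cx0 <- -(nC - 1) / 2 * p   # x of column 0 centers
    cy0 <- -(nR - 1) / 2 * p
    colIdx <- pmin(pmax(round((xc - cx0) / p), 0), nC - 1)
    rowIdx <- pmin(pmax(round((yc - cy0) / p), 0), nR - 1)
    dxs <- xc - (cx0 + colIdx * p)
    dys <- yc - (cy0 + rowIdx * p)
    inX <- outer(dxs, dys, function(a, b) a^2 + b^2) <= rad^2
    cellCol <- matrix(colIdx, nx, ny)
    cellRow <- matrix(rowIdx, nx, ny, byrow = TRUE)
    present <- unique(data.frame(row = cellRow[inX], col = cellCol[inX]))
    present <- present[order(present$row, present$col), , drop = FALSE]
    if (nrow(present) == 0L)
      stop("no spot is resolved by the grid; refine the resolution")
    present$id <- seq_len(nrow(present))
    idLookup <- matrix(0L, nR, nC)
    idLookup[cbind(present$row + 1L, present$col + 1L)] <- present$id
    spotId <- matrix(0L, nx, ny)
    spotId[inX] <- idLookup[cbind(cellRow[inX] + 1L, cellCol[inX] + 1L)]
    ctr <- spotCenters(layout, row = present$row, col = present$col)
    spotTable <- data.frame(id = present$id, row = present$row,
                            col = present$col, x = ctr$x, y = ctr$y)
  }

  new("SimulationGrid", nx = nx, ny = ny, nz = nz, dx = dx, dy = dy,
      dz = dz, x0 = x0, y0 = y0, spotId = spotId, spotTable = spotTable,
      symmetry = symmetry, allAbsorbing = allAbsorbingFloor,
      chamber = chamber, layout = layout)
}

#' Uniform initial concentration field
#'
#' The initial condition of every simulation: C = 1 everywhere in the
#' chamber (well-mixed target at the reference concentration).
#'
#' @param grid a [SimulationGrid-class].
#' @return A [ConcentrationField-class] at time 0.
#' @export
initializeField <- function(grid) {
  stopifnot(is(grid, "SimulationGrid"))
  new("ConcentrationField",
      values = array(1, dim = c(grid@nx, grid@ny, grid@nz)), time = 0)
}

#' Advance a concentration field by one implicit time step
#'
#' One step of the unconditionally stable implicit scheme (sequential
#' backward-Euler sweeps in x, y, z): C = 0 is enforced at the floor face
#' of sink cells, homogeneous Neumann everywhere else.
#'
#' @param grid a [SimulationGrid-class].
#' @param field a [ConcentrationField-class].
#' @param dt time step (s), > 0.
#' @param D diffusion coefficient (m^2/s), > 0.
#' @param theta implicitness weight of the per-direction solves (1/2 =
#'   second-order Douglas-Gunn, 1 = fully implicit).
#' @return The advanced [ConcentrationField-class].
#' @export
advanceField <- function(grid, field, dt, D, theta = 0.5) {
  stopifnot(is(grid, "SimulationGrid"), is(field, "ConcentrationField"))
  .pos_num(dt, "dt"); .pos_num(D, "D")
  stopifnot(theta >= 0.5, theta <= 1)
  res <- diffusionCore(as.numeric(field@values), grid@nx, grid@ny,
                       grid@nz, grid@dx, grid@dy, grid@dz, D,
                       as.integer(grid@spotId),
                       nrow(grid@spotTable), dt, 1L, theta)
  new("ConcentrationField",
      values = array(res$field, dim = c(grid@nx, grid@ny, grid@nz)),
      time = field@time + dt)
}

#' Instantaneous Fickian flux into each spot
#'
#' Per-spot absorption rate `-D A dC/dz` evaluated with a one-sided
#' two-point stencil at the floor (ghost value C = 0 at the wall face),
#' summed over the spot's sink cells.  Positive values mean absorption.
#'
#' @param grid a [SimulationGrid-class].
#' @param field a [ConcentrationField-class].
#' @param D diffusion coefficient (m^2/s).
#' @return Numeric vector of rates, one per spot in `grid@spotTable`
#'   (empty when the grid has no sinks).
#' @export
spotFlux <- function(grid, field, D) {
  stopifnot(is(grid, "SimulationGrid"), is(field, "ConcentrationField"))
  floorC <- field@values[, , 1]
  coef <- 2 * D * grid@dx * grid@dy / grid@dz
  sel <- grid@spotId > 0L
  if (!any(sel)) return(numeric(0))
  f <- factor(grid@spotId[sel], levels = seq_len(nrow(grid@spotTable)))
  as.numeric(tapply(coef * floorC[sel], f, sum, default = 0))
}

#' Total target mass in the chamber
#'
#' Volume integral of C over the whole chamber (C0-normalized; in
#' quadrant mode the domain integral is multiplied by 4).
#'
#' @param grid a [SimulationGrid-class].
#' @param field a [ConcentrationField-class].
#' @return Amount in m^3 of reference-concentration fluid.
#' @export
totalMass <- function(grid, field) {
  m <- sum(field@values) * grid@dx * grid@dy * grid@dz
  if (grid@symmetry == "quadrant") 4 * m else m
}

.step_schedule <- function(duration, dt, nRefine = 10L, subdiv = 10L) {
  fine <- dt / subdiv
  nFine <- min(nRefine * subdiv, ceiling(duration / fine - 1e-9))
  tFine <- nFine * fine
  rem <- duration - tFine
  nCoarse <- floor(rem / dt + 1e-9)
  last <- rem - nCoarse * dt
  steps <- c(rep(fine, nFine), rep(dt, nCoarse))
  if (last > 1e-9 * dt) steps <- c(steps, last)
  steps
}

#' Run the 3D diffusion simulation and integrate per-spot flux
#'
#' Solves the unsteady diffusion equation in the chamber from the
#' well-mixed initial condition C = 1, with perfect-sink spot disks on the
#' floor and no-flux walls, over the hybridization time (default 24 h).
#' Per-spot instantaneous Fickian flux and cumulative absorbed target are
#' recorded at each output time.  The first `refineInitialSteps` base
#' steps are subdivided tenfold to resolve the initial boundary-layer
#' transient.  With quadrant symmetry (the default for centered
#' even-dimension layouts) only a quarter of the chamber is solved and
#' per-spot results are mirrored onto the full layout.
#'
#' @param chamber a [ChamberGeometry-class].
#' @param layout a [SpotArrayLayout-class].
#' @param D diffusion coefficient (m^2/s), default 1e-9 (single-stranded
#'   RNA target).
#' @param duration total simulated time (s), default 24 h.
#' @param dt base time step (s), default 30.
#' @param lateralResolution,verticalCells,symmetry,allAbsorbingFloor
#'   passed to [buildGrid()].
#' @param outputInterval spacing of recorded outputs (s), default 1 h.
#' @param refineInitialSteps number of initial base steps subdivided
#'   tenfold (default 10).
#' @param theta implicitness weight of the Douglas ADI sweeps (1/2 =
#'   second-order Douglas-Gunn, the default; 1 = fully implicit,
#'   first-order but maximally damped).
#' @param verbose if `TRUE`, print the mass-balance error per output step.
#' @return A [SpotFluxSeries-class].
#' @examples
#' \donttest{
#' cfg <- configPreset("small")
#' fx <- runSimulation(cfg$chamber, cfg$layout, duration = 3600)
#' innerOuterRatio(fx)
#' }
#' @export
runSimulation <- function(chamber, layout, D = 1e-9,
                          duration = 24 * 3600, dt = 30,
                          lateralResolution = 50e-6, verticalCells = NULL,
                          symmetry = c("quadrant", "full"),
                          outputInterval = 3600, refineInitialSteps = 10L,
                          theta = 0.5, allAbsorbingFloor = FALSE,
                          verbose = FALSE) {
  symmetry <- match.arg(symmetry)
  .pos_num(D, "D"); .pos_num(duration, "duration"); .pos_num(dt, "dt")
  stopifnot(theta >= 0.5, theta <= 1)
  grid <- buildGrid(chamber, layout, lateralResolution, verticalCells,
                    symmetry, allAbsorbingFloor)

  steps <- .step_schedule(duration, dt, refineInitialSteps)
  cumT <- cumsum(steps)
  targets <- if (outputInterval < duration)
    unique(c(seq(outputInterval, duration, by = outputInterval), duration))
  else duration
  rec <- vapply(targets, function(tt) which(cumT >= tt - 1e-9)[1], 1L)
  rec <- sort(unique(rec))

  res <- diffusionCore(rep(1, grid@nx * grid@ny * grid@nz),
                       grid@nx, grid@ny, grid@nz,
                       grid@dx, grid@dy, grid@dz, D,
                       as.integer(grid@spotId), nrow(grid@spotTable),
                       steps, as.integer(rec), theta)

  symFactor <- if (symmetry == "quadrant") 4 else 1
  mass <- symFactor * res$mass
  initialMass <- (2 * chamber@halfLength)^2 * chamber@height

  if (allAbsorbingFloor) {
    inst <- symFactor * res$inst
    cum <- symFactor * res$cum
    spots <- data.frame(row = NA_integer_, col = NA_integer_,
                        ring = NA_integer_, x = 0, y = 0)
  } else {
    full <- spotCenters(layout)
    full$ring <- ringPosition(full$row, full$col, layout@nRows,
                              layout@nCols)
    if (symmetry == "quadrant") {
      nR <- layout@nRows; nC <- layout@nCols
      repRow <- pmax(full$row, nR - 1L - full$row)
      repCol <- pmax(full$col, nC - 1L - full$col)
      lut <- matrix(NA_integer_, nR, nC)
      lut[cbind(grid@spotTable$row + 1L, grid@spotTable$col + 1L)] <-
        grid@spotTable$id
      idx <- lut[cbind(repRow + 1L, repCol + 1L)]
      if (anyNA(idx)) stop("internal error: quadrant spot lookup failed")
    } else {
      lut <- matrix(NA_integer_, layout@nRows, layout@nCols)
      lut[cbind(grid@spotTable$row + 1L, grid@spotTable$col + 1L)] <-
        grid@spotTable$id
      idx <- lut[cbind(full$row + 1L, full$col + 1L)]
      keep <- !is.na(idx)
      full <- full[keep, , drop = FALSE]; idx <- idx[keep]
    }
    inst <- res$inst[, idx, drop = FALSE]
    cum <- res$cum[, idx, drop = FALSE]
    spots <- data.frame(row = full$row, col = full$col, ring = full$ring,
                        x = full$x, y = full$y)
  }

  if (verbose) {
    bal <- abs(initialMass - (mass + rowSums(cum))) / initialMass
    for (i in seq_along(res$times))
      message(sprintf("t = %8.0f s  mass-balance error %.2e",
                      res$times[i], bal[i]))
  }

  new("SpotFluxSeries", times = as.numeric(res$times), instantaneous = inst,
      cumulative = cum, spots = spots, mass = mass,
      initialMass = initialMass, D = D, chamber = chamber, layout = layout,
      finalField = array(res$field, dim = c(grid@nx, grid@ny, grid@nz)))
}

#' Relative mass-balance error of a flux series
#'
#' `|initial - (remaining + sum of cumulative spot fluxes)| / initial` at
#' each output time; a diagnostic of solver conservation.
#'
#' @param series a [SpotFluxSeries-class].
#' @return Numeric vector, one value per output time.
#' @export
massBalanceError <- function(series) {
  stopifnot(is(series, "SpotFluxSeries"))
  abs(series@initialMass - (series@mass + rowSums(series@cumulative))) /
    series@initialMass
}
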