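#' @include AllClasses.R
NULL

.check_index <- function(row, col, nRows, nCols) {
  if (any(row < 0L) || any(row >= nRows) || any(col < 0L) || any(col >= nCols))
    stop("spot index out of range for a ", nRows, " x ", nCols, " grid")
}

#' Ring position of a spot on the grid
#'
#' Spots are grouped into concentric square rings ("spot positions"):
#' position 1 is the outermost ring of the block, increasing inwards.  The
#' ring of cell (row, col) on an `nRows` x `nCols` grid is
#' `min(row, col, nRows - 1 - row, nCols - 1 - col) + 1`.  On a 30 x 30
#' block positions run from 1 to 15; on a 72 x 70 block from 1 to 35.
#' Spots within a position are treated as replicate spots.
#'
#' @param row,col 0-based spot indices (vectorized).
#' @param nRows,nCols grid dimensions.
#' @return Integer ring position(s), 1-based.
#' @examples
#' ringPosition(0, 0, 30, 30)    # corner -> 1
#' ringPosition(14, 14, 30, 30)  # center -> 15
#' @export
ringPosition <- function(row, col, nRows, nCols) {
  row <- as.integer(row); col <- as.integer(col)
  .check_index(row, col, nRows, nCols)
  as.integer(pmin(row, col, nRows - 1L - row, nCols - 1L - col) + 1L)
}

#' Maximum ring position of a grid
#' @inheritParams ringPosition
#' @return The innermost position index.
#' @export
maxRing <- function(nRows, nCols) {
  as.integer(min((nRows - 1L) %/% 2L, (nCols - 1L) %/% 2L) + 1L)
}

#' Spots belonging to a ring position
#'
#' @param ring 1-based ring position.
#' @inheritParams ringPosition
#' @return data.frame with 0-based `row`, `col` of every spot in the ring.
#'   The union over all rings partitions the grid; ring 1 has
#'   `2 * nRows + 2 * nCols - 4` members.
#' @examples
#' nrow(ringMembers(1, 30, 30))   # 116 replicate spots at position 1
#' nrow(ringMembers(15, 30, 30))  # 4 central spots
#' @export
ringMembers <- function(ring, nRows, nCols) {
  ring <- as.integer(ring)
  if (length(ring) != 1L || ring < 1L || ring > maxRing(nRows, nCols))
    stop("'ring' out of range: must be in 1..", maxRing(nRows, nCols))
  g <- expand.grid(row = seq_len(nRows) - 1L, col = seq_len(nCols) - 1L)
  g[ringPosition(g$row, g$col, nRows, nCols) == ring, , drop = FALSE]
}

#' Physical spot centers within the chamber
#'
#' Spot centers form a regular grid with spacing `pitch`, centered on the
#' chamber origin (chamber-centered Cartesian coordinates, meters; x along
#' columns, y along rows).
#'
#' @param layout a [SpotArrayLayout-class].
#' @param chamber optional [ChamberGeometry-class]; when given, the layout
#'   is checked to fit within the footprint.
#' @param row,col optional 0-based indices; default all spots.
#' @return data.frame with `row`, `col`, `x`, `y` (m).
#' @export
spotCenters <- function(layout, chamber = NULL, row = NULL, col = NULL) {
  nR <- layout@nRows; nC <- layout@nCols; p <- layout@pitch
  if (!is.null(chamber)) {
    span <- spanLengths(layout)
    if (any(span > 2 * chamber@halfLength + 1e-12))
      stop(sprintf(
        "layout span (%.2f x %.2f mm) exceeds the chamber footprint (%.2f mm)",
        1e3 * span[1], 1e3 * span[2], 2e3 * chamber@halfLength))
  }
  if (is.null(row)) {
    g <- expand.grid(row = seq_len(nR) - 1L, col = seq_len(nC) - 1L)
    row <- g$row; col <- g$col
  }
  .check_index(row, col, nR, nC)
  data.frame(row = as.integer(row), col = as.integer(col),
             x = (col - (nC - 1) / 2) * p, y = (row - (nR - 1) / 2) * p)
}

#' Physical span of the spot block
#' @param layout a [SpotArrayLayout-class].
#' @return c(x =, y =) span in meters: `(n - 1) * pitch + diameter` per axis
#'   (8.85 mm for the 30 x 30 block at 300 um pitch).
#' @export
spanLengths <- function(layout) {
  c(x = (layout@nCols - 1) * layout@pitch + layout@spotDiameter,
    y = (layout@nRows - 1) * layout@pitch + layout@spotDiameter)
}

#' Spotless margin between block edge and chamber wall
#'
#' Width of the unspotted floor strip between the spot block and the
#' chamber wall, per axis: `(2 L - span) / 2`.  This spotless area is the
#' reservoir that feeds excess target to the boundary spots.
#'
#' @param chamber a [ChamberGeometry-class].
#' @param layout a [SpotArrayLayout-class].
#' @return c(x =, y =) margins in meters.
#' @examples
#' spotlessMargin(chamberGeometry(10.8e-3, 0.25e-3), spotArrayLayout(30, 30))
#' @export
spotlessMargin <- function(chamber, layout) {
  m <- (2 * chamber@halfLength - spanLengths(layout)) / 2
  if (any(m < -1e-12))
    stop("layout exceeds the chamber footprint (negative spotless margin)")
  pmax(m, 0)
}

#' Transects across the spot block
#'
#' Ordered paths of spots from the block edge to its center, used to
#' profile the boundary bias.  `"diagonal"` gives the 4 half-diagonals
#' from each corner to the center; `"center_line"` gives the 8 half-rows /
#' half-columns along the two middle rows and two middle columns.  Each
#' path visits ring positions 1, 2, ..., maxRing in order.  Only
#' even-dimension grids are supported (the center of an odd grid is a
#' single spot, for which these path definitions are ambiguous).
#'
#' @param layout a [SpotArrayLayout-class] with even `nRows` and `nCols`.
#' @param kind `"diagonal"` or `"center_line"`.
#' @return List of data.frames (`row`, `col`, `ring`), one per path.
#' @examples
#' length(transects(spotArrayLayout(30, 30), "diagonal"))      # 4 paths
#' length(transects(spotArrayLayout(30, 30), "center_line"))   # 8 paths
#' @export
transects <- function(layout, kind = c("diagonal", "center_line")) {
  kind <- match.arg(kind)
  nR <- layout@nRows; nC <- layout@nCols
  if (nR %% 2L || nC %% 2L)
    stop("transects are only defined for even-dimension grids")
  m <- maxRing(nR, nC)
  steps <- seq_len(m) - 1L
  paths <- if (kind == "diagonal") {
    list(cbind(steps, steps),
         cbind(steps, nC - 1L - steps),
         cbind(nR - 1L - steps, steps),
         cbind(nR - 1L - steps, nC - 1L - steps))
  } else {
    midR <- c(nR %/% 2L - 1L, nR %/% 2L)
    midC <- c(nC %/% 2L - 1L, nC %/% 2L)
    c(lapply(midR, function(r) cbind(rep(r, m), steps)),
      lapply(midR, function(r) cbind(rep(r, m), nC - 1L - steps)),
      lapply(midC, function(cc) cbind(steps, rep(cc, m))),
      lapply(midC, function(cc) cbind(nR - 1L - steps, rep(cc, m))))
  }
  lapply(paths, function(p) {
    data.frame(row = p[, 1], col = p[, 2],
               ring = ringPosition(p[, 1], p[, 2], nR, nC))
  })
}
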