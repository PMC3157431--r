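#' @include AllClasses.R
#' @importFrom utils read.delim read.csv write.csv
NULL

.gpr_cols <- c("Block", "Column", "Row", "X", "Y", "Dia.",
               "F635 Median", "F532 Median", "Flags")

#' Write a spot table in the GPR-subset dialect
#'
#' Tab-separated GenePix-results-style file with an optional two-line ATF
#' preamble plus quoted header records, carrying the minimal column
#' subset `Block, Column, Row, X, Y, Dia., F635 Median[, F532 Median],
#' Flags`.  Row/Column are written 1-based (GenePix convention; the
#' in-memory table is 0-based), X/Y are spot centers in um relative to
#' the array's top-left spot, Dia. is the nominal spot diameter in um.
#'
#' @param table a [SpotIntensityTable-class].
#' @param path output file.
#' @param spotDiameter nominal diameter (m) written to `Dia.`.
#' @param pitch center-to-center spacing (m) used for the X/Y columns.
#' @param atfHeader write the ATF preamble (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writeGprSubset <- function(table, path, spotDiameter = 150e-6,
                           pitch = 300e-6, atfHeader = TRUE) {
  stopifnot(is(table, "SpotIntensityTable"))
  s <- table@spots
  two <- !all(is.na(s$ch2))
  cols <- if (two) .gpr_cols else setdiff(.gpr_cols, "F532 Median")
  d <- data.frame(
    Block = s$block, Column = s$col + 1L, Row = s$row + 1L,
    X = round(s$col * pitch * 1e6), Y = round(s$row * pitch * 1e6),
    Dia. = round(spotDiameter * 1e6),
    `F635 Median` = s$ch1, check.names = FALSE)
  if (two) d$`F532 Median` <- s$ch2
  d$Flags <- s$flag
  con <- file(path, "w")
  on.exit(close(con))
  if (atfHeader) {
    writeLines(c("ATF\t1.0",
                 sprintf("2\t%d", ncol(d)),
                 "\"Type=GenePix Results 3\"",
                 "\"Note=spotbias GPR-subset dialect; Row/Column 1-based\""),
               con)
  }
  writeLines(paste(sprintf('"%s"', cols), collapse = "\t"), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GPR-subset spot table
#'
#' Reads the tab-separated dialect written by [writeGprSubset()] (an ATF
#' preamble, if present, is validated and skipped; full GenePix results
#' files that contain the subset columns also parse).  Column names are
#' matched case-insensitively; `F532 Median` (second channel) is
#' optional; records with `Flags < 0` are marked excluded.  Row/Column
#' are converted to 0-based indices; the original 1-based values are
#' kept in the metadata.
#'
#' @param path file to read.
#' @param nRows,nCols grid dimensions; default inferred from the maximum
#'   Row/Column present.
#' @return A [SpotIntensityTable-class].
#' @export
readGprSubset <- function(path, nRows = NULL, nCols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  skip <- 0L
  if (length(lines) && grepl("^\\s*\"?ATF", lines[1], ignore.case = TRUE)) {
    if (length(lines) < 2L)
      stop("malformed ATF header: missing record-count line")
    counts <- suppressWarnings(
      as.integer(strsplit(gsub('"', "", lines[2]), "\t")[[1]]))
    if (length(counts) < 2L || anyNA(counts))
      stop("malformed ATF header: record-count line is not two integers")
    skip <- 2L + counts[1]
  }
  d <- utils::read.delim(path, skip = skip, check.names = FALSE,
                         stringsAsFactors = FALSE)
  nm <- tolower(trimws(names(d)))
  pick <- function(col, required = TRUE) {
    i <- match(tolower(col), nm)
    if (is.na(i)) {
      if (required) stop("missing mandatory column '", col, "' in ", path)
      return(NULL)
    }
    d[[i]]
  }
  blk <- pick("Block"); col1 <- pick("Column"); row1 <- pick("Row")
  ch1 <- pick("F635 Median")
  ch2 <- pick("F532 Median", required = FALSE)
  flags <- pick("Flags", required = FALSE)
  if (is.null(flags)) flags <- rep(0L, nrow(d))
  if (is.null(nRows)) nRows <- max(row1)
  if (is.null(nCols)) nCols <- max(col1)
  spots <- data.frame(block = as.integer(blk),
                      row = as.integer(row1) - 1L,
                      col = as.integer(col1) - 1L,
                      ch1 = as.numeric(ch1),
                      ch2 = if (is.null(ch2)) NA_real_ else as.numeric(ch2),
                      flag = as.integer(flags))
  spotIntensityTable(spots, nRows, nCols,
                     metadata = list(source = path, rowColBase = 1L))
}

#' Write / read spot tables as CSV
#'
#' Plain comma-separated dialect (UTF-8, header row, '.' decimal) with
#' columns `block, row, col, ch1, ch2, flag`; `row`/`col` are 0-based, as
#' in memory.
#'
#' @param table a [SpotIntensityTable-class].
#' @param path file path.
#' @return `writeSpotCsv`: `path`, invisibly.
#' @export
writeSpotCsv <- function(table, path) {
  stopifnot(is(table, "SpotIntensityTable"))
  utils::write.csv(table@spots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpotCsv
#' @param nRows,nCols grid dimensions; default inferred from the indices.
#' @return `readSpotCsv`: a [SpotIntensityTable-class].
#' @export
readSpotCsv <- function(path, nRows = NULL, nCols = NULL) {
  d <- utils::read.csv(path)
  need <- c("row", "col", "ch1")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (is.null(nRows)) nRows <- max(d$row) + 1L
  if (is.null(nCols)) nCols <- max(d$col) + 1L
  spotIntensityTable(d, nRows, nCols, metadata = list(source = path))
}

#' Write / read simulated per-spot flux tables
#'
#' CSV with columns `row, col, ring_position, cumulative_flux, x, y`
#' (0-based indices, SI units).
#'
#' @param series a [SpotFluxSeries-class].
#' @param path file path.
#' @return `writeFluxTable`: `path`, invisibly; `readFluxTable`: a
#'   data.frame of the same columns.
#' @export
writeFluxTable <- function(series, path) {
  stopifnot(is(series, "SpotFluxSeries"))
  utils::write.csv(fluxTable(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFluxTable
#' @export
readFluxTable <- function(path) {
  d <- utils::read.csv(path)
  need <- c("row", "col", "ring_position", "cumulative_flux")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  d
}

.config_keys <- list(
  top = c("preset", "chamber", "layout", "kinetics", "solver", "analysis",
          "generator", "seed", "outDir"),
  chamber = c("halfLength", "height"),
  layout = c("nRows", "nCols", "spotDiameter", "pitch"),
  kinetics = c("D", "k", "B0", "R", "h", "C0", "BS", "hD"),
  solver = c("duration", "dt", "lateralResolution", "verticalCells",
             "symmetry", "outputInterval"),
  analysis = c("normalize", "channel", "testRings"),
  generator = c("nRows", "nCols", "baseIntensity", "boundaryAmplitude",
                "decayLength", "noiseCV", "nReplicates",
                "channelAbundances", "saturationCeiling", "flagFraction",
                "seed"))

#' Read and validate a JSON run configuration
#'
#' Run configurations describe a complete analysis: a geometry preset or
#' explicit chamber/layout, kinetic parameters, solver controls, analysis
#' options, generator parameters, seed and output directory.  Unknown
#' keys are rejected with a message naming them, before any computation.
#'
#' @param path JSON file.
#' @return Validated configuration as a named list.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  checkKeys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  checkKeys(cfg, .config_keys$top, "top level")
  for (sec in c("chamber", "layout", "kinetics", "solver", "analysis",
                "generator"))
    if (!is.null(cfg[[sec]]))
      checkKeys(cfg[[sec]], .config_keys[[sec]], sec)
  if (!is.null(cfg$preset))
    cfg$preset <- match.arg(cfg$preset,
                            c("default", "deep", "small", "full_coverage"))
  if (is.null(cfg$preset) && (is.null(cfg$chamber) || is.null(cfg$layout)) &&
      is.null(cfg$generator))
    stop("configuration needs a 'preset', explicit 'chamber' + 'layout', ",
         "or a 'generator' section")
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed and software versions alongside a
#' command's outputs so deterministic runs can be reproduced exactly.
#'
#' @param path output JSON file.
#' @param config configuration list (as from [readRunConfig()]).
#' @param seed the seed used.
#' @param extra optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, config, seed, extra = list()) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- c(list(
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("spotbias")),
    r_version = R.version.string), extra)
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
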