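#' @include AllClasses.R AllGenerics.R geometry.R
#' @importFrom stats sd pt
NULL

.as_table_list <- function(tables) {
  if (is(tables, "SpotIntensityTable")) tables <- list(tables)
  if (!is.list(tables) || !length(tables) ||
      !all(vapply(tables, is, TRUE, "SpotIntensityTable")))
    stop("'tables' must be a SpotIntensityTable or a list of them")
  dims <- vapply(tables, arrayDim, integer(2))
  if (length(tables) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stop("replicate tables must share grid dimensions")
  tables
}

.ring_values <- function(tab, channel) {
  s <- tab@spots[tab@spots$flag >= 0, , drop = FALSE]
  val <- if (channel == 1L) s$ch1 else s$ch2
  if (channel == 2L && all(is.na(val)))
    stop("table has no second channel")
  data.frame(ring = ringPosition(s$row, s$col, tab@nRows, tab@nCols),
             value = val)
}

#' Summarize spot signals by ring position
#'
#' Mean and standard deviation of the (unflagged) spot values at each
#' ring position, pooling spots across replicate hybridizations when a
#' list of tables is supplied.  With more than one replicate the spread
#' of the per-hybridization ring means is also reported
#' (`repMeanSd`, the error-bar convention of the position profiles).
#'
#' @param tables a [SpotIntensityTable-class] or list of replicates.
#' @param channel 1 or 2.
#' @return data.frame with `position`, `n`, `mean`, `sd` (and `repMeanSd`
#'   for replicated input).  Rings left empty by flag filtering are
#'   omitted with a warning.
#' @export
summarizeByPosition <- function(tables, channel = 1L) {
  tables <- .as_table_list(tables)
  rv <- lapply(tables, .ring_values, channel = channel)
  pooled <- do.call(rbind, rv)
  dims <- arrayDim(tables[[1]])
  rings <- seq_len(maxRing(dims[1], dims[2]))
  out <- do.call(rbind, lapply(rings, function(r) {
    v <- pooled$value[pooled$ring == r]
    if (!length(v)) return(NULL)
    data.frame(position = r, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0)
  }))
  missing <- setdiff(rings, out$position)
  if (length(missing))
    warning("no unflagged spots at position(s) ",
            paste(missing, collapse = ", "), "; summaries omitted")
  if (length(tables) > 1L) {
    perTab <- vapply(rv, function(d)
      vapply(out$position, function(r) mean(d$value[d$ring == r]), 1),
      numeric(nrow(out)))
    out$repMeanSd <- apply(matrix(perTab, nrow = nrow(out)), 1, sd)
  }
  out
}

#' Normalize position summaries to the maximum or minimum ring mean
#'
#' `mode = "max"` expresses each ring mean as a fraction of the position
#' with the highest mean signal (profile plots of mean relative
#' intensity); `mode = "min"` divides by the lowest ring mean (transect
#' profile convention).  The two modes differ only by a multiplicative
#' constant.
#'
#' @param summaries output of [summarizeByPosition()].
#' @param mode `"max"` or `"min"`.
#' @return The summaries with `relativeMean` and `relativeSd` columns.
#' @export
normalizePositions <- function(summaries, mode = c("max", "min")) {
  mode <- match.arg(mode)
  ref <- if (mode == "max") max(summaries$mean) else min(summaries$mean)
  if (!is.finite(ref) || ref <= 0)
    stop("reference ring mean must be positive for normalization")
  summaries$relativeMean <- summaries$mean / ref
  summaries$relativeSd <- summaries$sd / ref
  if (!is.null(summaries$repMeanSd))
    summaries$relativeRepSd <- summaries$repMeanSd / ref
  summaries
}

.inner_outer <- function(row, col, value, nRows, nCols) {
  ring <- ringPosition(row, col, nRows, nCols)
  mr <- maxRing(nRows, nCols)
  inner <- value[ring == mr]; outer <- value[ring == 1L]
  if (!length(inner) || !length(outer))
    stop("both ring 1 and the innermost ring must be populated")
  mo <- mean(outer)
  if (mo == 0) stop("outer-ring mean is zero; ratio undefined")
  100 * mean(inner) / mo
}

#' @rdname innerOuterRatio
#' @param nRows,nCols grid dimensions (data.frame method).
#' @export
setMethod("innerOuterRatio", "data.frame", function(x, nRows, nCols, ...) {
  .inner_outer(x$row, x$col, x$value, nRows, nCols)
})

#' @rdname innerOuterRatio
#' @param channel channel to use for intensity tables (default 1).
#' @export
setMethod("innerOuterRatio", "SpotIntensityTable", function(x, channel = 1L, ...) {
  rv <- .ring_values(x, channel)
  s <- x@spots[x@spots$flag >= 0, , drop = FALSE]
  .inner_outer(s$row, s$col, rv$value, x@nRows, x@nCols)
})

#' @rdname innerOuterRatio
#' @export
setMethod("innerOuterRatio", "SpotFluxSeries", function(x, ...) {
  fx <- fluxTable(x)
  .inner_outer(fx$row, fx$col, fx$cumulative_flux,
               x@layout@nRows, x@layout@nCols)
})

#' Two-colour channel ratio by ring position
#'
#' Per-position ratio of channel means (channel 1 over channel 2) from a
#' competitive two-colour hybridization, with the spread of the
#' per-replicate ratios when replicates are supplied.  The default
#' statistic is the ratio of the pooled channel means per position
#' (matching ratios of averaged position signals); `"mean_of_ratios"`
#' averages per-spot ratios instead.
#'
#' @param tables a two-channel [SpotIntensityTable-class] or list of
#'   replicates.
#' @param statistic `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return data.frame with `position`, `n`, `ratio`, `ratioSd` (`NA`
#'   without replication).
#' @export
channelRatioByPosition <- function(tables,
                                   statistic = c("ratio_of_means",
                                                 "mean_of_ratios")) {
  statistic <- match.arg(statistic)
  tables <- .as_table_list(tables)
  dims <- arrayDim(tables[[1]])
  rings <- seq_len(maxRing(dims[1], dims[2]))
  perTab <- lapply(tables, function(tab) {
    s <- tab@spots[tab@spots$flag >= 0, , drop = FALSE]
    if (all(is.na(s$ch2))) stop("two channels are required")
    ring <- ringPosition(s$row, s$col, tab@nRows, tab@nCols)
    vapply(rings, function(r) {
      a <- s$ch1[ring == r]; b <- s$ch2[ring == r]
      if (!length(a)) return(NA_real_)
      if (statistic == "ratio_of_means") {
        if (mean(b) == 0) stop("zero channel-2 mean at position ", r)
        mean(a) / mean(b)
      } else {
        if (any(b == 0)) stop("zero channel-2 intensity at position ", r)
        mean(a / b)
      }
    }, 1)
  })
  rm <- do.call(cbind, perTab)
  n <- vapply(rings, function(r) sum(vapply(tables, function(tab) {
    s <- tab@spots[tab@spots$flag >= 0, , drop = FALSE]
    sum(ringPosition(s$row, s$col, tab@nRows, tab@nCols) == r)
  }, 1L)), 1L)
  pooledRatio <- vapply(seq_along(rings), function(i) {
    if (statistic == "ratio_of_means") {
      num <- den <- 0
      for (tab in tables) {
        s <- tab@spots[tab@spots$flag >= 0, , drop = FALSE]
        ring <- ringPosition(s$row, s$col, tab@nRows, tab@nCols)
        num <- num + sum(s$ch1[ring == rings[i]])
        den <- den + sum(s$ch2[ring == rings[i]])
      }
      num / den
    } else mean(rm[i, ], na.rm = TRUE)
  }, 1)
  data.frame(position = rings, n = n, ratio = pooledRatio,
             ratioSd = if (length(tables) > 1L) apply(rm, 1, sd)
                       else NA_real_)
}

#' Student's t-test between ring positions
#'
#' Two-sample pooled-variance (classical Student's) t-test comparing two
#' ring positions within one condition, or the same position across two
#' conditions.  By default the unit of replication is the hybridization:
#' each replicate table contributes its ring mean, so triplicate
#' hybridizations give n = 3 per group.  `unit = "spot"` pools individual
#' spots instead.
#'
#' @param tables list of replicate [SpotIntensityTable-class] objects.
#' @param ringA first ring position.
#' @param ringB second ring position (same condition); ignored when
#'   `tables2` is given.
#' @param tables2 optional second condition, compared to `tables` at
#'   `ringA`.
#' @param channel channel to test.
#' @param unit `"hybridization"` (default) or `"spot"`.
#' @return List with `t`, `df`, `p` (two-sided), `nA`, `nB`.
#' @export
positionTTest <- function(tables, ringA, ringB = NULL, tables2 = NULL,
                          channel = 1L,
                          unit = c("hybridization", "spot")) {
  unit <- match.arg(unit)
  tables <- .as_table_list(tables)
  grab <- function(tabs, ring) {
    vals <- lapply(tabs, function(tab) {
      rv <- .ring_values(tab, channel)
      rv$value[rv$ring == ring]
    })
    if (unit == "hybridization") vapply(vals, mean, 1)
    else unlist(vals)
  }
  if (is.null(tables2)) {
    if (is.null(ringB)) stop("supply 'ringB' or 'tables2'")
    a <- grab(tables, ringA); b <- grab(tables, ringB)
  } else {
    a <- grab(tables, ringA)
    b <- grab(.as_table_list(tables2), if (is.null(ringB)) ringA else ringB)
  }
  if (length(a) < 2L || length(b) < 2L)
    stop("at least 2 observations per group are required ",
         "(unit = \"hybridization\" needs replicate tables)")
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 <= .Machine$double.eps * max(mean(a)^2, mean(b)^2, 1)) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = df, p = 1, nA = length(a), nB = length(b)))
    warning("zero within-group variance with unequal means")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                nA = length(a), nB = length(b)))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df),
       nA = length(a), nB = length(b))
}

#' Signal profile along diagonal or center-line transects
#'
#' Mean signal at each position along the 4 diagonal or 8 center-line
#' transect paths (pooled over paths and replicate tables), normalized to
#' the lowest position mean.  Flagged spots on a path reduce n with a
#' warning.
#'
#' @param tables a [SpotIntensityTable-class] or list of replicates.
#' @param kind `"diagonal"` or `"center_line"`.
#' @param channel channel to profile.
#' @return data.frame with `position`, `n`, `mean`, `relativeMean`
#'   (min-normalized).
#' @export
transectProfile <- function(tables, kind = c("diagonal", "center_line"),
                            channel = 1L) {
  kind <- match.arg(kind)
  tables <- .as_table_list(tables)
  dims <- arrayDim(tables[[1]])
  paths <- transects(spotArrayLayout(dims[1], dims[2]), kind)
  want <- do.call(rbind, paths)
  vals <- lapply(tables, function(tab) {
    s <- tab@spots
    key <- paste(s$row, s$col)
    m <- match(paste(want$row, want$col), key)
    if (anyNA(m)) stop("transect spot missing from the table")
    flagged <- s$flag[m] < 0
    if (any(flagged))
      warning(sum(flagged), " flagged spot(s) on transect paths excluded")
    v <- if (channel == 1L) s$ch1[m] else s$ch2[m]
    v[flagged] <- NA
    v
  })
  v <- unlist(vals)
  ring <- rep(want$ring, length(tables))
  rings <- sort(unique(want$ring))
  out <- data.frame(
    position = rings,
    n = vapply(rings, function(r) sum(!is.na(v[ring == r])), 1L),
    mean = vapply(rings, function(r) mean(v[ring == r], na.rm = TRUE), 1))
  out$relativeMean <- out$mean / min(out$mean)
  out
}

#' Fit the boundary-enhancement ring profile
#'
#' Least-squares fit of the phenomenological ring-mean model
#' `base + amplitude * exp(-(position - 1)/decayLength)` to the empirical
#' per-position means, via Levenberg-Marquardt.  Used to recover
#' generator parameters from synthetic tables and to quantify the
#' boundary contrast of measured profiles.
#'
#' @param tables a [SpotIntensityTable-class] or list of replicates.
#' @param channel channel to fit.
#' @return List with `baseIntensity`, `boundaryAmplitude`, `decayLength`
#'   and the `fit` object.
#' @export
fitBoundaryProfile <- function(tables, channel = 1L) {
  s <- summarizeByPosition(tables, channel = channel)
  start <- list(b = min(s$mean),
                A = max(max(s$mean) - min(s$mean), 1e-6 * max(s$mean)),
                lam = 2)
  fit <- minpack.lm::nlsLM(mean ~ b + A * exp(-(position - 1) / lam),
                           data = s, start = start,
                           lower = c(0, 0, 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(baseIntensity = unname(cf["b"]), boundaryAmplitude = unname(cf["A"]),
       decayLength = unname(cf["lam"]), fit = fit)
}
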