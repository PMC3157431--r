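#' @include AllClasses.R
NULL

.pos_num <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("'", what, "' must be a single finite positive number")
  as.numeric(x)
}

#' Hybridization (reaction) timescale
#'
#' The characteristic time for a target strand at a spot to hybridize,
#' `1 / (k * B0)`.
#'
#' @param k hybridization rate constant (1/M/s).
#' @param B0 effective probe concentration (M).
#' @return Timescale in seconds.
#' @examples
#' reactionTimescale(5e4, 1.25e-3)  # 0.016 s
#' @export
reactionTimescale <- function(k, B0) {
  1 / (.pos_num(k, "k") * .pos_num(B0, "B0"))
}

#' Diffusion timescale and its limiting length
#'
#' The limiting timescale for diffusion to the spot is set by the shorter
#' of the spot radius `R` and the chamber height `h`: `R^2 / D` when
#' `R < h` (radial diffusion limits, the usual microarray case), else
#' `h^2 / D`.
#'
#' @param R spot radius (m).
#' @param h chamber height (m).
#' @param D diffusion coefficient (m^2/s).
#' @return List with `time` (s) and `limitingLength` (`"R"` or `"h"`).
#' @examples
#' diffusionTimescale(75e-6, 250e-6, 1e-9)  # 5.625 s, limited by R
#' @export
diffusionTimescale <- function(R, h, D) {
  R <- .pos_num(R, "R"); h <- .pos_num(h, "h"); D <- .pos_num(D, "D")
  if (R < h) list(time = R^2 / D, limitingLength = "R")
  else       list(time = h^2 / D, limitingLength = "h")
}

#' Dimensionless parameter P (a Damkohler-type number)
#'
#' Ratio of the hybridization timescale `1/(k B0)` to the diffusion
#' timescale set by the limiting length.  `P << 1` means reaction is much
#' faster than diffusion near the spot, so the spot acts as a perfect
#' sink (C = 0 at its surface).
#'
#' @param params a [KineticParams-class].
#' @return Dimensionless P.
#' @examples
#' damkohlerP(kineticParams())  # ~2.8e-3 for the study parameters
#' @export
damkohlerP <- function(params) {
  stopifnot(is(params, "KineticParams"))
  reactionTimescale(params@k, params@B0) /
    diffusionTimescale(params@R, params@h, params@D)$time
}

#' Effective probe concentration of a dried spot
#'
#' A freshly printed spot is approximately hemispherical with radius `R`
#' and probe concentration `BS`; it dries to a disk of the same radius and
#' height `hD` while conserving the total probe amount, giving
#' `B0 = (2/3) * (R / hD) * BS` (hemisphere volume `(2/3) pi R^3` spread
#' over disk volume `pi R^2 hD`).
#'
#' @param R spot radius (m).
#' @param hD dried spot height (m).
#' @param BS spotting-solution probe concentration (M).
#' @return Effective probe concentration B0 (M).
#' @examples
#' estimateProbeConcentration(75e-6, 2e-6, 50e-6)  # 1.25e-3 M = 1.25 mM
#' @export
estimateProbeConcentration <- function(R, hD, BS) {
  (2 / 3) * (.pos_num(R, "R") / .pos_num(hD, "hD")) * .pos_num(BS, "BS")
}

#' Is the perfect-sink assumption justified?
#'
#' @param P dimensionless parameter from [damkohlerP()].
#' @param threshold strict cut-off below which P counts as "much less
#'   than 1" (default 0.01).
#' @return `TRUE` iff `P < threshold`.
#' @export
sinkAssumptionValid <- function(P, threshold = 0.01) {
  .pos_num(P, "P") < .pos_num(threshold, "threshold")
}

#' Full scaling report
#'
#' Computes both timescales, P, and the perfect-sink verdict in one
#' object; printed values are rounded to 2 significant figures, full
#' precision is retained in the slots.
#'
#' @param params a [KineticParams-class].
#' @param threshold perfect-sink threshold (default 0.01).
#' @return A [ScalingReport-class].
#' @examples
#' scalingReport(kineticParams())
#' @export
scalingReport <- function(params, threshold = 0.01) {
  stopifnot(is(params, "KineticParams"))
  tr <- reactionTimescale(params@k, params@B0)
  td <- diffusionTimescale(params@R, params@h, params@D)
  P <- tr / td$time
  new("ScalingReport", tReaction = tr, tDiffusion = td$time, P = P,
      limitingLength = td$limitingLength, sinkThreshold = threshold,
      sinkAssumptionValid = sinkAssumptionValid(P, threshold),
      params = params)
}

#' Serialize a ScalingReport to a plain list (for JSON output)
#' @param report a [ScalingReport-class].
#' @return Named list of plain values.
#' @export
scalingReportAsList <- function(report) {
  stopifnot(is(report, "ScalingReport"))
  list(reaction_timescale_s = report@tReaction,
       diffusion_timescale_s = report@tDiffusion,
       limiting_length = report@limitingLength,
       P = report@P,
       sink_threshold = report@sinkThreshold,
       sink_assumption_valid = report@sinkAssumptionValid)
}
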