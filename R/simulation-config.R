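#' Simulation configuration for EPIC-like methylation datasets
#'
#' Holds all parameters of the synthetic methylation-array generator:
#' array composition (probe count, design-type mix, annotation-flag
#' fractions), the four-group experimental design, the planted differential
#' and rescue effects, and the technical-noise model.
#'
#' Defaults describe the study conditions the pipeline is built for:
#' four groups (control and knockdown cells, each under vehicle or
#' demethylating drug: C0, C5, Z0, Z5) with 4 replicates per group, a
#' planted methylation gain of 0.3 beta units at 200 probes of which 100
#' are reverted by the drug, replicate noise of 0.03, and a type II
#' compression factor of 0.8. Annotation-flag and failure-rate defaults are
#' calibrated so that, at full array scale, the QC cascade removes probe
#' counts in proportion to those reported for EPIC arrays: SNP-associated
#' ~11\%, XY ~1.9\%, non-CpG ~0.34\%, multi-mapping ~1e-5, with sporadic
#' detection-p and bead-count failures at per-cell rates of 2.4e-4 and
#' 2e-3.
#'
#' @slot nProbes integer, number of probes.
#' @slot fracNonCpg,fracSnp,fracMultimap,fracXY numeric proportions of
#'   probes carrying each annotation flag.
#' @slot fracTypeII proportion of type II design probes.
#' @slot groups character vector of group labels.
#' @slot repsPerGroup integer replicates per group.
#' @slot nDifferential integer, probes planted with a C0->Z0 gain.
#' @slot nRescue integer, subset of those also reverted in Z5.
#' @slot deltaBeta numeric, mean planted effect on the beta scale.
#' @slot withinSd numeric, replicate noise SD.
#' @slot typeIICompression numeric in (0,1]: observed type II beta =
#'   0.5 + c * (true beta - 0.5).
#' @slot failRateDetP,failRateBeads numeric per-cell failure probabilities.
#' @slot seed integer; fully determines generator output.
#' @export
setClass("SimulationConfig",
  representation(
    nProbes = "integer", fracNonCpg = "numeric", fracSnp = "numeric",
    fracMultimap = "numeric", fracXY = "numeric", fracTypeII = "numeric",
    groups = "character", repsPerGroup = "integer",
    nDifferential = "integer", nRescue = "integer",
    deltaBeta = "numeric", withinSd = "numeric",
    typeIICompression = "numeric",
    failRateDetP = "numeric", failRateBeads = "numeric", seed = "integer"),
  prototype(
    nProbes = 20000L, fracNonCpg = 0.0034, fracSnp = 0.11,
    fracMultimap = 1.3e-05, fracXY = 0.019, fracTypeII = 0.84,
    groups = c("C0", "C5", "Z0", "Z5"), repsPerGroup = 4L,
    nDifferential = 200L, nRescue = 100L,
    deltaBeta = 0.3, withinSd = 0.03, typeIICompression = 0.8,
    failRateDetP = 2.4e-04, failRateBeads = 2e-03, seed = 1L))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- c(object@fracNonCpg, object@fracSnp, object@fracMultimap,
          object@fracXY, object@fracTypeII)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "flag fractions must lie in [0,1]")
  if (object@nProbes < 1L) msg <- c(msg, "nProbes must be positive")
  if (object@nRescue > object@nDifferential)
    msg <- c(msg, "nRescue must not exceed nDifferential")
  if (object@nDifferential > object@nProbes)
    msg <- c(msg, "nDifferential must not exceed nProbes")
  if (object@typeIICompression <= 0 || object@typeIICompression > 1)
    msg <- c(msg, "typeIICompression must lie in (0,1]")
  if (object@failRateDetP < 0 || object@failRateDetP > 1 ||
      object@failRateBeads < 0 || object@failRateBeads > 1)
    msg <- c(msg, "failure rates must lie in [0,1]")
  if (object@withinSd < 0) msg <- c(msg, "withinSd must be non-negative")
  if (object@repsPerGroup < 1L) msg <- c(msg, "repsPerGroup must be positive")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Create a SimulationConfig
#'
#' @param nProbes,fracNonCpg,fracSnp,fracMultimap,fracXY,fracTypeII,groups
#'   see \linkS4class{SimulationConfig}.
#' @param repsPerGroup,nDifferential,nRescue,deltaBeta,withinSd see
#'   \linkS4class{SimulationConfig}.
#' @param typeIICompression,failRateDetP,failRateBeads,seed see
#'   \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(nProbes = 1000, seed = 7)
#' @export
simulationConfig <- function(nProbes = 20000, fracNonCpg = 0.0034,
                             fracSnp = 0.11, fracMultimap = 1.3e-05,
                             fracXY = 0.019, fracTypeII = 0.84,
                             groups = c("C0", "C5", "Z0", "Z5"),
                             repsPerGroup = 4, nDifferential = 200,
                             nRescue = 100, deltaBeta = 0.3,
                             withinSd = 0.03, typeIICompression = 0.8,
                             failRateDetP = 2.4e-04, failRateBeads = 2e-03,
                             seed = 1) {
  obj <- new("SimulationConfig",
    nProbes = as.integer(nProbes), fracNonCpg = fracNonCpg,
    fracSnp = fracSnp, fracMultimap = fracMultimap, fracXY = fracXY,
    fracTypeII = fracTypeII, groups = as.character(groups),
    repsPerGroup = as.integer(repsPerGroup),
    nDifferential = as.integer(nDifferential),
    nRescue = as.integer(nRescue), deltaBeta = deltaBeta,
    withinSd = withinSd, typeIICompression = typeIICompression,
    failRateDetP = failRateDetP, failRateBeads = failRateBeads,
    seed = as.integer(seed))
  validObject(obj)
  obj
}
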