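#' Construct a MethylationExperiment
#'
#' Bundles the beta, detection p-value and bead-count matrices with a probe
#' manifest and sample sheet into a single validated container.
#'
#' @param beta numeric matrix, probes x samples, values in [0,1].
#' @param detP numeric matrix of detection p-values, same dimensions.
#' @param beadCount integer matrix of bead counts, same dimensions.
#' @param manifest data.frame with one row per probe; see
#'   \code{\link{simulateManifest}} for the required columns.
#' @param sampleInfo data.frame with columns \code{sample_id}, \code{group},
#'   \code{replicate}, one row per sample (column of \code{beta}).
#' @return a \linkS4class{MethylationExperiment}.
#' @examples
#' cfg <- simulationConfig(nProbes = 500, seed = 1)
#' man <- simulateManifest(cfg)
#' sim <- simulateMethylation(man, cfg)
#' sim$experiment
#' @export
MethylationExperiment <- function(beta, detP, beadCount, manifest, sampleInfo) {
  beta <- as.matrix(beta); detP <- as.matrix(detP); beadCount <- as.matrix(beadCount)
  if (!all(dim(beta) == dim(detP)) || !all(dim(beta) == dim(beadCount)))
    stop("beta, detP and beadCount must share dimensions", call. = FALSE)
  if (nrow(manifest) != nrow(beta))
    stop("manifest must have one row per probe", call. = FALSE)
  if (nrow(sampleInfo) != ncol(beta))
    stop("sampleInfo must have one row per sample", call. = FALSE)
  rownames(beta) <- rownames(detP) <- rownames(beadCount) <- manifest$probe_id
  colnames(beta) <- colnames(detP) <- colnames(beadCount) <- sampleInfo$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta, detP = detP, beadCount = beadCount),
    rowData = S4Vectors::DataFrame(manifest, row.names = manifest$probe_id),
    colData = S4Vectors::DataFrame(sampleInfo, row.names = sampleInfo$sample_id))
  new("MethylationExperiment", se)
}

#' Accessors for MethylationExperiment assays and annotation
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @return \code{betaValues}, \code{detectionP}, \code{beadCounts}: the
#'   corresponding probes x samples matrix; \code{probeManifest}: the probe
#'   manifest as a data.frame; \code{sampleGroups}: named character vector
#'   of group labels per sample.
#' @name methylation-accessors
NULL

#' @rdname methylation-accessors
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @rdname methylation-accessors
#' @export
detectionP <- function(x) SummarizedExperiment::assay(x, "detP")

#' @rdname methylation-accessors
#' @export
beadCounts <- function(x) SummarizedExperiment::assay(x, "beadCount")

#' @rdname methylation-accessors
#' @export
probeManifest <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname methylation-accessors
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$group), rownames(cd))
}

#' @describeIn QcReport-class per-stage removal counts (named integer vector)
#' @export
stageCounts <- function(object) {
  vapply(object@stages, length, integer(1))
}

#' @describeIn QcReport-class probe ids removed across all stages
#' @export
removedProbes <- function(object) unlist(object@stages, use.names = FALSE)
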