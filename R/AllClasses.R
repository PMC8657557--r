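#' MethylationExperiment: beta values, detection p-values and bead counts
#'
#' A thin extension of
#' \link[SummarizedExperiment]{SummarizedExperiment} holding the three
#' probe-by-sample matrices of an Infinium-style methylation experiment
#' (\code{beta}, \code{detP}, \code{beadCount}) together with the probe
#' manifest as \code{rowData} and the sample sheet as \code{colData}.
#'
#' Validity requires the three assays to be present with identical
#' dimensions, beta values and detection p-values inside \eqn{[0,1]}
#' (NA allowed), non-negative integer bead counts, a \code{group} and
#' \code{replicate} column in \code{colData}, and manifest columns
#' \code{probe_id}, \code{design_type}, \code{chrom}, \code{pos},
#' \code{gene}, \code{is_cpg}, \code{is_snp_associated},
#' \code{is_multimapping} in \code{rowData} with unique probe identifiers.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

.manifest_cols <- c("probe_id", "design_type", "chrom", "pos", "gene",
                    "is_cpg", "is_snp_associated", "is_multimapping")

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("beta", "detP", "beadCount")
  if (!all(need %in% an))
    return(paste("assays must include:", paste(setdiff(need, an), collapse = ", ")))
  b <- SummarizedExperiment::assay(object, "beta")
  p <- SummarizedExperiment::assay(object, "detP")
  n <- SummarizedExperiment::assay(object, "beadCount")
  if (any(b < 0 | b > 1, na.rm = TRUE)) msg <- c(msg, "beta values outside [0,1]")
  if (any(p < 0 | p > 1, na.rm = TRUE)) msg <- c(msg, "detection p-values outside [0,1]")
  if (any(n < 0, na.rm = TRUE)) msg <- c(msg, "negative bead counts")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'group' and 'replicate'")
  rd <- SummarizedExperiment::rowData(object)
  miss <- setdiff(.manifest_cols, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("rowData missing manifest columns:", paste(miss, collapse = ", ")))
  if ("probe_id" %in% colnames(rd) && anyDuplicated(rd$probe_id))
    msg <- c(msg, "probe identifiers must be unique")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Probe-level quality-control report
#'
#' Bookkeeping for a QC cascade: the preset that was run, the number of
#' input probes, and the probes removed at each stage in execution order.
#' A probe is attributed to the first stage at which it fails, so the
#' per-stage removal sets are disjoint and
#' \code{survivors + sum(removals) == input}.
#'
#' @slot preset character, one of \code{"raw"}, \code{"full"}, \code{"partial"}.
#' @slot nInput integer, probes entering the cascade.
#' @slot stages named list of character vectors of removed probe ids, in
#'   cascade order.
#' @slot survivors character vector of surviving probe ids.
#' @export
setClass("QcReport",
  representation(preset = "character", nInput = "integer",
                 stages = "list", survivors = "character"))

setValidity("QcReport", function(object) {
  removed <- unlist(object@stages, use.names = FALSE)
  if (anyDuplicated(removed))
    return("a probe may be removed at one stage only")
  if (length(removed) + length(object@survivors) != object@nInput)
    return("survivors + removals must equal input probe count")
  TRUE
})

#' Three-state beta-mixture fit
#'
#' Result of fitting a mixture of Beta densities to a vector of beta
#' values by expectation-maximisation, with states relabelled so that
#' component means are increasing: U (unmethylated), H (hemimethylated),
#' M (methylated).
#'
#' @slot weights numeric, mixture weights (sum to 1), named U/H/M.
#' @slot shapes 3 x 2 matrix of Beta shape parameters (a, b) per state.
#' @slot states factor of per-value maximum-posterior state assignments.
#' @slot logLik numeric, log-likelihood trace across EM iterations.
#' @slot converged logical, whether the tolerance was met before maxIter.
#' @export
setClass("BetaMixtureFit",
  representation(weights = "numeric", shapes = "matrix",
                 states = "factor", logLik = "numeric",
                 converged = "logical"))

setValidity("BetaMixtureFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  if (any(object@shapes <= 0)) return("Beta shapes must be positive")
  TRUE
})

#' Morphology classification cutoffs
#'
#' Control-derived thresholds on the roundness score: cells scoring at or
#' above \code{epithelialCut} are called epithelial, at or below
#' \code{mesenchymalCut} mesenchymal, and in between "mixed".
#'
#' @slot epithelialCut numeric, mean(epithelial controls) - SD.
#' @slot mesenchymalCut numeric, mean(mesenchymal controls) + SD.
#' @export
setClass("MorphologyCutoffs",
  representation(epithelialCut = "numeric", mesenchymalCut = "numeric"))

setValidity("MorphologyCutoffs", function(object) {
  if (object@mesenchymalCut <= 0 || object@epithelialCut > 1 ||
      object@mesenchymalCut >= object@epithelialCut)
    return("cutoffs must satisfy 0 < mesenchymalCut < epithelialCut <= 1")
  TRUE
})

#' Morphology population report
#'
#' Per-cell roundness scores and classes plus population percentages.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{score},
#'   \code{class}.
#' @slot percentages named numeric: percent epithelial / mixed /
#'   mesenchymal, summing to 100 up to rounding.
#' @slot cutoffs the \linkS4class{MorphologyCutoffs} used.
#' @export
setClass("MorphologyReport",
  representation(cells = "data.frame", percentages = "numeric",
                 cutoffs = "MorphologyCutoffs"))

#' @describeIn QcReport-class compact display of the cascade funnel
#' @param object a \code{QcReport}
#' @export
setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport (preset '%s'): %d probes in, %d surviving\n",
              object@preset, object@nInput, length(object@survivors)))
  for (s in names(object@stages))
    cat(sprintf("  %-12s removed %d\n", s, length(object@stages[[s]])))
})

#' @describeIn BetaMixtureFit-class display of weights and shapes
#' @param object a \code{BetaMixtureFit}
#' @export
setMethod("show", "BetaMixtureFit", function(object) {
  cat("BetaMixtureFit (", length(object@logLik), " EM iterations, ",
      if (object@converged) "converged" else "not converged", ")\n", sep = "")
  m <- object@shapes[, 1] / rowSums(object@shapes)
  for (k in seq_along(object@weights))
    cat(sprintf("  %s: weight %.3f, a=%.3f b=%.3f (mean %.3f)\n",
                names(object@weights)[k], object@weights[k],
                object@shapes[k, 1], object@shapes[k, 2], m[k]))
})

#' @describeIn MorphologyReport-class display of class percentages
#' @param object a \code{MorphologyReport}
#' @export
setMethod("show", "MorphologyReport", function(object) {
  cat(sprintf("MorphologyReport: %d cells\n", nrow(object@cells)))
  cat(sprintf("  epithelial %.1f%% | mixed %.1f%% | mesenchymal %.1f%%\n",
              object@percentages["epithelial"], object@percentages["mixed"],
              object@percentages["mesenchymal"]))
  cat(sprintf("  cutoffs: epithelial >= %.3f, mesenchymal <= %.3f\n",
              object@cutoffs@epithelialCut, object@cutoffs@mesenchymalCut))
})
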