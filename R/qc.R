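## Probe-level QC cascade.
##
## Three presets are provided: "raw" (no filtering), "full"
## (detection p-value -> bead count -> non-CpG -> SNP -> multi-mapping ->
## XY) and "partial" (detection p-value, bead count and non-CpG only).
## Removal counts are attributed to the first failing stage, so per-stage
## sets are disjoint and sum with survivors to the input probe count.

.subset_probes <- function(x, keep) {
  x[keep, ]
}

#' Filter probes by detection p-value
#'
#' A probe is removed when its fraction of samples with detection p-value
#' above \code{threshold} exceeds \code{maxFailFraction}. The default
#' \code{maxFailFraction = 0} is the any-sample rule: a single failing
#' sample removes the probe.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param threshold detection p-value threshold (default 0.01).
#' @param maxFailFraction maximum tolerated failing-sample fraction
#'   (strict inequality; default 0).
#' @return list with \code{experiment} (filtered) and \code{removed}
#'   (character vector of removed probe ids).
#' @export
filterDetectionP <- function(x, threshold = 0.01, maxFailFraction = 0) {
  if (nrow(x) == 0) stop("empty dataset", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0,1)", call. = FALSE)
  frac <- rowMeans(detectionP(x) > threshold)
  bad <- frac > maxFailFraction
  list(experiment = .subset_probes(x, !bad), removed = rownames(x)[bad])
}

#' Filter probes by bead count
#'
#' A probe is removed when bead count falls below \code{minBeads} in at
#' least \code{maxFailFraction} of samples (boundary inclusive: exactly
#' 5\% of samples failing removes the probe under the defaults).
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param minBeads minimum bead count (default 3).
#' @param maxFailFraction failing-sample fraction at or above which the
#'   probe is removed (default 0.05).
#' @return list with \code{experiment} and \code{removed}.
#' @export
filterBeadCount <- function(x, minBeads = 3, maxFailFraction = 0.05) {
  if (nrow(x) == 0) stop("empty dataset", call. = FALSE)
  if (minBeads < 1) stop("minBeads must be >= 1", call. = FALSE)
  frac <- rowMeans(beadCounts(x) < minBeads)
  bad <- frac >= maxFailFraction
  list(experiment = .subset_probes(x, !bad), removed = rownames(x)[bad])
}

#' Filter probes by manifest annotation flags
#'
#' Removes probes flagged in the manifest, counting each removed probe
#' under the first category that flags it, in the fixed cascade order
#' non-CpG -> SNP -> multi-mapping -> XY (restricted to \code{which}).
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param manifest probe manifest; defaults to \code{probeManifest(x)}.
#'   Must cover every probe of \code{x}.
#' @param which subset of \code{c("non_cpg", "snp", "multimap", "xy")}.
#' @return list with \code{experiment} and \code{removed} (named list of
#'   probe ids per category, in cascade order).
#' @export
filterAnnotation <- function(x, manifest = probeManifest(x),
                             which = c("non_cpg", "snp", "multimap", "xy")) {
  which <- match.arg(which, several.ok = TRUE)
  ids <- rownames(x)
  missing <- setdiff(ids, manifest$probe_id)
  if (length(missing))
    stop("probes missing from manifest: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  man <- manifest[match(ids, manifest$probe_id), ]
  flags <- list(
    non_cpg = !man$is_cpg,
    snp = man$is_snp_associated,
    multimap = man$is_multimapping,
    xy = man$chrom %in% c("chrX", "chrY", "X", "Y"))
  order_all <- c("non_cpg", "snp", "multimap", "xy")
  stages <- order_all[order_all %in% which]
  removed <- stats::setNames(vector("list", length(stages)), stages)
  taken <- rep(FALSE, length(ids))
  for (s in stages) {
    hit <- flags[[s]] & !taken
    removed[[s]] <- ids[hit]
    taken <- taken | hit
  }
  list(experiment = .subset_probes(x, !taken), removed = removed)
}

#' Run a QC preset
#'
#' Executes one of the three QC presets as a cascade and reports per-stage
#' removal counts. \code{"raw"} performs no filtering; \code{"full"} runs
#' detection p-value, bead count, non-CpG, SNP, multi-mapping and XY
#' filters; \code{"partial"} runs only detection p-value, bead count and
#' non-CpG.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param preset one of \code{"raw"}, \code{"full"}, \code{"partial"}.
#' @param detPThreshold,detPMaxFailFraction detection p-value settings.
#' @param minBeads,beadMaxFailFraction bead-count settings.
#' @return list with \code{experiment} (surviving probes) and
#'   \code{report} (\linkS4class{QcReport}).
#' @examples
#' cfg <- simulationConfig(nProbes = 2000, seed = 2)
#' sim <- simulateMethylation(simulateManifest(cfg), cfg)
#' runQC(sim$experiment, "full")$report
#' @export
runQC <- function(x, preset = c("full", "partial", "raw"),
                  detPThreshold = 0.01, detPMaxFailFraction = 0,
                  minBeads = 3, beadMaxFailFraction = 0.05) {
  preset <- match.arg(preset)
  n0 <- nrow(x)
  stages <- list()
  if (preset != "raw") {
    r1 <- filterDetectionP(x, detPThreshold, detPMaxFailFraction)
    stages$detection_p <- r1$removed
    x <- r1$experiment
    r2 <- filterBeadCount(x, minBeads, beadMaxFailFraction)
    stages$bead_count <- r2$removed
    x <- r2$experiment
    ann <- if (preset == "full") c("non_cpg", "snp", "multimap", "xy") else "non_cpg"
    r3 <- filterAnnotation(x, which = ann)
    stages <- c(stages, r3$removed)
    x <- r3$experiment
  }
  report <- new("QcReport", preset = preset, nInput = n0,
                stages = stages, survivors = rownames(x))
  validObject(report)
  list(experiment = x, report = report)
}
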