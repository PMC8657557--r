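#' Simulate an EPIC-like probe manifest
#'
#' Draws a manifest of \code{nProbes} probes: unique identifiers, design
#' type (I/II), chromosome and position, a gene symbol for roughly 60\% of
#' probes, and independent annotation flags (non-CpG, SNP-associated,
#' multi-mapping) at the configured fractions. XY membership follows from
#' the chromosome assignment. Non-CpG probes get "ch."-style identifiers,
#' CpG probes "cg"-style, mirroring array naming practice.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with columns \code{probe_id}, \code{design_type},
#'   \code{chrom}, \code{pos}, \code{gene}, \code{is_cpg},
#'   \code{is_snp_associated}, \code{is_multimapping}.
#' @examples
#' man <- simulateManifest(simulationConfig(nProbes = 1000, seed = 7))
#' table(man$design_type)
#' @export
simulateManifest <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nProbes
  with_seed(config@seed, {
    is_cpg <- runif(n) >= config@fracNonCpg
    is_snp <- runif(n) < config@fracSnp
    is_mm  <- runif(n) < config@fracMultimap
    xy     <- runif(n) < config@fracXY
    chrom <- ifelse(xy,
                    sample(c("chrX", "chrY"), n, replace = TRUE, prob = c(0.8, 0.2)),
                    paste0("chr", sample(1:22, n, replace = TRUE)))
    design <- ifelse(runif(n) < config@fracTypeII, "II", "I")
    pos <- sample.int(2.4e8, n, replace = TRUE)
    n_genes <- max(50L, ceiling(n / 15))
    pool <- sprintf("GENE%04d", seq_len(n_genes))
    gene <- ifelse(runif(n) < 0.6, sample(pool, n, replace = TRUE), "")
    id <- character(n)
    id[is_cpg]  <- sprintf("cg%08d", which(is_cpg))
    id[!is_cpg] <- sprintf("ch.%d.%07d", sample(1:22, sum(!is_cpg), replace = TRUE),
                           which(!is_cpg))
    data.frame(probe_id = id, design_type = design, chrom = chrom, pos = pos,
               gene = gene, is_cpg = is_cpg, is_snp_associated = is_snp,
               is_multimapping = is_mm, stringsAsFactors = FALSE)
  })
}

#' Simulate beta values, detection p-values and bead counts
#'
#' Generates a four-group methylation dataset with planted ground truth.
#' Per-probe baseline betas come from a bimodal mixture
#' 0.5 Beta(2,10) + 0.5 Beta(10,2) (unmethylated / methylated peaks).
#' Differential probes gain \code{deltaBeta} in Z0 (and in Z5 when not
#' rescued); rescue probes revert to the C0 baseline in Z5; C5 mirrors C0.
#' Group means are clipped to [0,1]. Type II probes are compressed toward
#' 0.5 by \code{typeIICompression} before replicate noise
#' (Gaussian, SD \code{withinSd}) is added and the result clipped to
#' [0,1]. Detection p-values are near zero for passing cells and
#' Uniform(0.01, 1) for failing cells; bead counts are Poisson(12) floored
#' at 3 for passing cells and 0-2 for failing cells, so expected failure
#' rates match the configuration.
#'
#' Planted probes are drawn from probes carrying no annotation flags and
#' whose baseline leaves headroom for the full effect
#' (\code{baseline + deltaBeta} inside [0,1]), so the planted effect size
#' is exact and recovery of the planted truth measures the statistics
#' rather than the annotation filters or boundary clipping. Clipping
#' still applies as a guard for configurations where the headroom
#' condition cannot hold.
#'
#' @param manifest manifest from \code{\link{simulateManifest}}.
#' @param config the matching \linkS4class{SimulationConfig}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{MethylationExperiment}), \code{truth} (list with
#'   \code{differential_ids}, \code{rescue_ids},
#'   \code{baseline}, \code{groupMeans}).
#' @examples
#' cfg <- simulationConfig(nProbes = 500, nDifferential = 10, nRescue = 5, seed = 3)
#' sim <- simulateMethylation(simulateManifest(cfg), cfg)
#' length(sim$truth$rescue_ids)
#' @export
simulateMethylation <- function(manifest, config) {
  stopifnot(is(config, "SimulationConfig"))
  if (nrow(manifest) != config@nProbes)
    stop("manifest does not match config@nProbes", call. = FALSE)
  n <- config@nProbes
  groups <- config@groups
  reps <- config@repsPerGroup
  with_seed(config@seed + 1L, {
    comp <- runif(n) < 0.5
    baseline <- ifelse(comp, rbeta(n, 10, 2), rbeta(n, 2, 10))

    headroom <- baseline + config@deltaBeta >= 0 &
      baseline + config@deltaBeta <= 1
    clean <- which(manifest$is_cpg & !manifest$is_snp_associated &
                   !manifest$is_multimapping &
                   !manifest$chrom %in% c("chrX", "chrY") & headroom)
    if (length(clean) < config@nDifferential)
      stop("too few unflagged probes with headroom to plant differential effects",
           call. = FALSE)
    diff_idx <- sort(sample(clean, config@nDifferential))
    rescue_idx <- sort(sample(diff_idx, config@nRescue))

    gm <- matrix(baseline, nrow = n, ncol = length(groups),
                 dimnames = list(manifest$probe_id, groups))
    if (length(diff_idx) && all(c("C0", "Z0", "Z5") %in% groups)) {
      gm[diff_idx, "Z0"] <- clip01(baseline[diff_idx] + config@deltaBeta)
      non_rescue <- setdiff(diff_idx, rescue_idx)
      gm[non_rescue, "Z5"] <- clip01(baseline[non_rescue] + config@deltaBeta)
      gm[rescue_idx, "Z5"] <- baseline[rescue_idx]
    }

    type2 <- manifest$design_type == "II"
    S <- length(groups) * reps
    sample_id <- paste0(rep(groups, each = reps), "_r", rep(seq_len(reps), length(groups)))
    grp_of <- rep(groups, each = reps)

    beta <- matrix(NA_real_, n, S)
    for (s in seq_len(S)) {
      m <- gm[, grp_of[s]]
      m[type2] <- 0.5 + config@typeIICompression * (m[type2] - 0.5)
      if (config@withinSd > 0) m <- m + rnorm(n, 0, config@withinSd)
      ## observed betas are intensity ratios with an offset and never
      ## reach the boundary exactly
      beta[, s] <- clip01(m, 1e-3, 1 - 1e-3)
    }

    fail_p <- matrix(runif(n * S) < config@failRateDetP, n, S)
    detp <- matrix(runif(n * S, 0, 1e-3), n, S)
    detp[fail_p] <- runif(sum(fail_p), 0.01, 1)

    fail_b <- matrix(runif(n * S) < config@failRateBeads, n, S)
    beads <- matrix(pmax(rpois(n * S, 12), 3L), n, S)
    beads[fail_b] <- sample(0:2, sum(fail_b), replace = TRUE)

    sample_info <- data.frame(sample_id = sample_id, group = grp_of,
                              replicate = rep(seq_len(reps), length(groups)),
                              stringsAsFactors = FALSE)
    mexp <- MethylationExperiment(beta, detp, beads, manifest, sample_info)
    truth <- list(differential_ids = manifest$probe_id[diff_idx],
                  rescue_ids = manifest$probe_id[rescue_idx],
                  baseline = stats::setNames(baseline, manifest$probe_id),
                  groupMeans = gm)
    list(experiment = mexp, truth = truth)
  })
}
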