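## Fixture builders shared across test files. Everything is generated in
## code; no stored data.

## minimal manifest for hand-built experiments
make_manifest <- function(n, design = "I", gene = "") {
  data.frame(probe_id = sprintf("cg%08d", seq_len(n)),
             design_type = rep(design, length.out = n),
             chrom = paste0("chr", rep_len(1:22, n)),
             pos = seq_len(n) * 1000L,
             gene = rep(gene, length.out = n),
             is_cpg = TRUE, is_snp_associated = FALSE,
             is_multimapping = FALSE, stringsAsFactors = FALSE)
}

## experiment from an explicit beta matrix; detP ~ 0 and beads = 10
## unless overridden
make_mexp <- function(beta, groups, detP = NULL, beads = NULL,
                      manifest = NULL) {
  beta <- as.matrix(beta)
  n <- nrow(beta); S <- ncol(beta)
  if (is.null(manifest)) manifest <- make_manifest(n)
  if (is.null(detP)) detP <- matrix(0, n, S)
  if (is.null(beads)) beads <- matrix(10L, n, S)
  reps <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  si <- data.frame(sample_id = paste0(groups, "_r", reps),
                   group = groups, replicate = reps,
                   stringsAsFactors = FALSE)
  MethylationExperiment(beta, detP, beads, manifest, si)
}

## small simulated experiment for cascade tests
sim_fixture <- function(nProbes = 1000, seed = 42,
                        nDifferential = min(20, nProbes %/% 10),
                        nRescue = min(10, nProbes %/% 20), ...) {
  cfg <- simulationConfig(nProbes = nProbes, seed = seed,
                          nDifferential = nDifferential,
                          nRescue = nRescue, ...)
  sim <- simulateMethylation(simulateManifest(cfg), cfg)
  sim$config <- cfg
  sim
}
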