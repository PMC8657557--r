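test_that("detection-p filter uses the any-sample rule by default", {
  beta <- matrix(0.5, 3, 16)
  detp <- matrix(0, 3, 16)
  detp[1, 5] <- 0.02           # one failing sample
  x <- make_mexp(beta, rep(c("C0", "C5", "Z0", "Z5"), each = 4), detP = detp)
  r <- filterDetectionP(x)
  expect_identical(r$removed, "cg00000001")
  expect_equal(nrow(r$experiment), 2)
  ## all-zero detection p: nothing removed
  r0 <- filterDetectionP(make_mexp(beta, rep(c("C0", "C5", "Z0", "Z5"), each = 4)))
  expect_length(r0$removed, 0)
  ## relaxed fraction keeps the probe (1/16 = 6.25% not > 10%)
  r2 <- filterDetectionP(x, maxFailFraction = 0.1)
  expect_length(r2$removed, 0)
})

test_that("detection-p removals match the binomial expectation on synthetic data", {
  cfg <- simulationConfig(nProbes = 20000, failRateDetP = 0.001,
                          failRateBeads = 0, seed = 31)
  sim <- simulateMethylation(simulateManifest(cfg), cfg)
  r <- filterDetectionP(sim$experiment)
  p_fail <- 1 - (1 - 0.001)^16
  expected <- 20000 * p_fail
  expect_lt(abs(length(r$removed) - expected),
            3 * sqrt(20000 * p_fail * (1 - p_fail)))
})

test_that("bead-count boundary is inclusive at the failing-sample fraction", {
  mk <- function(nS, nFail) {
    beads <- matrix(10L, 1, nS)
    if (nFail > 0) beads[1, seq_len(nFail)] <- 2L
    make_mexp(matrix(0.5, 1, nS), rep("C0", nS), beads = beads)
  }
  ## 1 of 16 failing: 6.25% >= 5% -> removed
  expect_length(filterBeadCount(mk(16, 1))$removed, 1)
  ## 1 of 20 failing: exactly 5% >= 5% -> removed (boundary inclusive)
  expect_length(filterBeadCount(mk(20, 1))$removed, 1)
  ## 1 of 24 failing: 4.17% < 5% -> retained
  expect_length(filterBeadCount(mk(24, 1))$removed, 0)
  ## all beads >= 3: nothing removed
  expect_length(filterBeadCount(mk(16, 0))$removed, 0)
})

test_that("annotation filter counts each probe at its first failing stage", {
  man <- make_manifest(100)
  man$is_cpg[1:10] <- FALSE
  man$is_snp_associated[5:20] <- TRUE     # 5:10 overlap non-CpG
  man$chrom[15:25] <- "chrX"              # 15:20 overlap SNP
  x <- make_mexp(matrix(0.5, 100, 4), rep(c("C0", "Z0"), each = 2),
                 manifest = man)
  r <- filterAnnotation(x)
  expect_equal(lengths(r$removed),
               c(non_cpg = 10, snp = 10, multimap = 0, xy = 5))
  ## removed sets are disjoint and conservation holds
  all_removed <- unlist(r$removed)
  expect_false(anyDuplicated(all_removed) > 0)
  expect_equal(length(all_removed) + nrow(r$experiment), 100)
  ## zero flags: identity
  x0 <- make_mexp(matrix(0.5, 50, 4), rep(c("C0", "Z0"), each = 2))
  r0 <- filterAnnotation(x0)
  expect_equal(nrow(r0$experiment), 50)
  expect_equal(sum(lengths(r0$removed)), 0)
})

test_that("annotation filter errors when a probe is missing from the manifest", {
  x <- make_mexp(matrix(0.5, 10, 4), rep(c("C0", "Z0"), each = 2))
  bad_man <- probeManifest(x)[-3, ]
  expect_error(filterAnnotation(x, manifest = bad_man), "cg00000003")
})

test_that("QC presets behave as specified and conserve probes", {
  sim <- sim_fixture(nProbes = 1000, seed = 19,
                     failRateDetP = 0.02, failRateBeads = 0.05)
  x <- sim$experiment
  raw <- runQC(x, "raw")
  expect_identical(betaValues(raw$experiment), betaValues(x))
  expect_length(raw$report@stages, 0)

  full <- runQC(x, "full")
  part <- runQC(x, "partial")
  for (res in list(full, part)) {
    rep <- res$report
    expect_equal(length(rep@survivors) + sum(stageCounts(rep)), 1000)
    expect_false(anyDuplicated(removedProbes(rep)) > 0)
  }
  ## partial retains SNP/multimap/XY-flagged probes
  man <- probeManifest(x)
  flagged <- man$probe_id[man$is_snp_associated & man$is_cpg]
  surv_part <- rownames(part$experiment)
  kept_flagged <- intersect(flagged, surv_part)
  expect_gt(length(kept_flagged), 0)
  expect_length(intersect(flagged, rownames(full$experiment)), 0)
  ## monotone nesting: full survivors within partial within raw
  expect_true(all(rownames(full$experiment) %in% surv_part))
  expect_true(all(surv_part %in% rownames(raw$experiment)))
})

test_that("QC survivors equal an exhaustive per-probe oracle", {
  sim <- sim_fixture(nProbes = 1000, seed = 23,
                     failRateDetP = 0.02, failRateBeads = 0.05)
  x <- sim$experiment
  man <- probeManifest(x)
  detp <- detectionP(x); beads <- beadCounts(x)
  ## independent per-probe rule evaluation
  ok_detp <- vapply(seq_len(1000), function(i) all(detp[i, ] <= 0.01), logical(1))
  ok_bead <- vapply(seq_len(1000), function(i)
    mean(beads[i, ] < 3) < 0.05, logical(1))
  ok_ann_full <- man$is_cpg & !man$is_snp_associated & !man$is_multimapping &
    !man$chrom %in% c("chrX", "chrY")
  oracle_full <- man$probe_id[ok_detp & ok_bead & ok_ann_full]
  oracle_part <- man$probe_id[ok_detp & ok_bead & man$is_cpg]
  expect_setequal(rownames(runQC(x, "full")$experiment), oracle_full)
  expect_setequal(rownames(runQC(x, "partial")$experiment), oracle_part)
})

test_that("QC presets are idempotent", {
  sim <- sim_fixture(nProbes = 500, seed = 29, failRateDetP = 0.02)
  once <- runQC(sim$experiment, "full")
  twice <- runQC(once$experiment, "full")
  expect_identical(rownames(twice$experiment), rownames(once$experiment))
  expect_equal(sum(stageCounts(twice$report)), 0)
})

test_that("empty datasets are rejected", {
  x <- make_mexp(matrix(0.5, 2, 4), rep(c("C0", "Z0"), each = 2))
  empty <- x[integer(0), ]
  expect_error(filterDetectionP(empty), "empty")
  expect_error(filterBeadCount(empty), "empty")
})
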