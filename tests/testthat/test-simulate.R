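test_that("manifest generation is deterministic and respects flag fractions", {
  cfg <- simulationConfig(nProbes = 1000, fracNonCpg = 0.1, seed = 7)
  m1 <- simulateManifest(cfg)
  m2 <- simulateManifest(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 1000)
  expect_false(anyDuplicated(m1$probe_id) > 0)
  expect_true(all(m1$design_type %in% c("I", "II")))

  ## zero-fraction config: every probe survives every annotation filter
  cfg0 <- simulationConfig(nProbes = 500, fracNonCpg = 0, fracSnp = 0,
                           fracMultimap = 0, fracXY = 0, seed = 1)
  m0 <- simulateManifest(cfg0)
  expect_true(all(m0$is_cpg))
  expect_false(any(m0$is_snp_associated))
  expect_false(any(m0$is_multimapping))
  expect_false(any(m0$chrom %in% c("chrX", "chrY")))

  ## flag counts within 3 * sqrt(np(1-p)) of expectation
  cfgb <- simulationConfig(nProbes = 20000, fracSnp = 0.2, seed = 11)
  mb <- simulateManifest(cfgb)
  checks <- list(
    c(sum(mb$is_snp_associated), 0.2),
    c(sum(!mb$is_cpg), cfgb@fracNonCpg),
    c(sum(mb$chrom %in% c("chrX", "chrY")), cfgb@fracXY))
  for (ch in checks) {
    n <- 20000; p <- ch[2]
    expect_lt(abs(ch[1] - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(nProbes = 100, fracSnp = 1.5), "fractions")
  expect_error(simulationConfig(nProbes = 100, nDifferential = 10, nRescue = 20),
               "nRescue")
  expect_error(simulationConfig(nProbes = 100, typeIICompression = 0),
               "typeIICompression")
})

test_that("noiseless planting is exact and rescue reversion symmetric", {
  cfg <- simulationConfig(nProbes = 400, fracNonCpg = 0, fracSnp = 0,
                          fracMultimap = 0, fracXY = 0,
                          nDifferential = 40, nRescue = 20, deltaBeta = 0.3,
                          withinSd = 0, typeIICompression = 1,
                          failRateDetP = 0, failRateBeads = 0, seed = 5)
  sim <- simulateMethylation(simulateManifest(cfg), cfg)
  b <- betaValues(sim$experiment)
  grp <- sampleGroups(sim$experiment)
  gm <- function(g) rowMeans(b[, grp == g, drop = FALSE])
  ## every replicate equals its group mean exactly in the noiseless limit
  for (g in unique(grp))
    expect_true(all(b[, grp == g] == gm(g)))
  truth <- sim$truth
  d <- truth$differential_ids
  r <- truth$rescue_ids
  nr <- setdiff(d, r)
  expect_true(all(r %in% d))
  ## planted gain is exactly deltaBeta (headroom guaranteed by design)
  expect_equal(unname(gm("Z0")[d] - gm("C0")[d]), rep(0.3, length(d)))
  ## non-rescued probes keep the gain in Z5; rescued revert to baseline
  expect_equal(unname(gm("Z5")[nr] - gm("C0")[nr]), rep(0.3, length(nr)))
  expect_equal(unname(gm("Z5")[r]), unname(gm("C0")[r]))
  ## exact reversion symmetry: Z5 - Z0 = -(Z0 - C0)
  expect_equal(unname(gm("Z5")[r] - gm("Z0")[r]),
               -unname(gm("Z0")[r] - gm("C0")[r]))
  ## C5 mirrors C0
  expect_equal(unname(gm("C5")), unname(gm("C0")))
})

test_that("generated values respect ranges and seeds determine output", {
  sim <- sim_fixture(nProbes = 800, seed = 3)
  b <- betaValues(sim$experiment); p <- detectionP(sim$experiment)
  n <- beadCounts(sim$experiment)
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(n >= 0 & n == floor(n)))
  sim2 <- sim_fixture(nProbes = 800, seed = 3)
  expect_identical(betaValues(sim$experiment), betaValues(sim2$experiment))
  expect_identical(sim$truth, sim2$truth)
  sim3 <- sim_fixture(nProbes = 800, seed = 4)
  expect_false(identical(betaValues(sim$experiment), betaValues(sim3$experiment)))
})

test_that("non-differential group differences stay within standard error", {
  cfg <- simulationConfig(nProbes = 2000, nDifferential = 0, nRescue = 0,
                          withinSd = 0.03, seed = 13)
  sim <- simulateMethylation(simulateManifest(cfg), cfg)
  b <- betaValues(sim$experiment)
  grp <- sampleGroups(sim$experiment)
  dz <- rowMeans(b[, grp == "Z0"]) - rowMeans(b[, grp == "C0"])
  ## mean absolute group difference ~ E|N(0, sd*sqrt(2/4))| < 3 se bound
  se <- 0.03 * sqrt(2 / 4)
  expect_lt(mean(abs(dz)), 3 * se)
})

test_that("detection-p and bead failure rates match configuration", {
  cfg <- simulationConfig(nProbes = 20000, failRateDetP = 0.01,
                          failRateBeads = 0.02, seed = 17)
  sim <- simulateMethylation(simulateManifest(cfg), cfg)
  fr_p <- mean(detectionP(sim$experiment) > 0.01)
  fr_b <- mean(beadCounts(sim$experiment) < 3)
  n_cells <- 20000 * 16
  expect_lt(abs(fr_p - 0.01), 3 * sqrt(0.01 * 0.99 / n_cells))
  expect_lt(abs(fr_b - 0.02), 3 * sqrt(0.02 * 0.98 / n_cells))
})

test_that("ellipse outlines have analytic roundness b/a and are valid polygons", {
  circ <- ellipseOutline(5, 5, 360)
  expect_equal(roundnessScore(circ), 1, tolerance = 1e-3)
  ell <- ellipseOutline(2, 1, 360)
  expect_equal(roundnessScore(ell), 0.5, tolerance = 1e-3)
  ## rotation changes the score by < 1e-6
  expect_equal(roundnessScore(ellipseOutline(2, 1, 360, rotation = 0)),
               roundnessScore(ellipseOutline(2, 1, 360, rotation = 1.1)),
               tolerance = 1e-6)
  expect_error(ellipseOutline(1, 2), "semiMajor")
  expect_error(ellipseOutline(2, 0), "semiMajor")
  expect_error(ellipseOutline(2, 1, nVertices = 8), "nVertices")
})

test_that("cell populations are reproducible and separable mixes recoverable", {
  pop1 <- simulateCellPopulation(250, c(0.5, 0.3, 0.2), seed = 9)
  pop2 <- simulateCellPopulation(250, c(0.5, 0.3, 0.2), seed = 9)
  expect_identical(pop1$outlines, pop2$outlines)
  expect_identical(pop1$labels, pop2$labels)

  params <- list(epithelial = c(0.93, 0.02), mixed = c(0.50, 0.05),
                 mesenchymal = c(0.10, 0.02))
  cut <- deriveCutoffs(c(0.88, 0.9, 0.92), c(0.12, 0.15, 0.18))
  ## pure epithelial population: >= 95% recovered
  pe <- simulateCellPopulation(200, c(1, 0, 0), params, seed = 2)
  repE <- classifyCells(roundnessScores(pe$outlines), cut)
  expect_gte(repE@percentages[["epithelial"]], 95)
  ## pure mesenchymal population with ratios below the cutoff: 100%
  pm <- simulateCellPopulation(100, c(0, 0, 1), params, seed = 3)
  repM <- classifyCells(roundnessScores(pm$outlines), cut)
  expect_equal(repM@percentages[["mesenchymal"]], 100)
})

test_that("assay mask generators report self-consistent ground truth", {
  w <- simulateAssayMasks("wound", list(dims = c(10L, 20L), widths = c(10L, 5L)))
  expect_true(all(unlist(w$masks) %in% 0:1))
  expect_equal(w$truth$wound_area_px, c(100, 50))
  expect_equal(w$truth$closure_pct, 50)
  ## identical halo at both timepoints: zero invasion
  s0 <- simulateAssayMasks("spheroid", list(radii = c(15, 15)))
  expect_equal(unname(s0$truth$invasion_area), 0)
  bd <- simulateAssayMasks("brdu", list(nTotal = 120, nPositive = 30), seed = 1)
  expect_equal(bd$truth$positive_pct, 25)
  expect_equal(sum(bd$masks$dapi) / 9, 120)  # 3x3 nuclei
  bd2 <- simulateAssayMasks("brdu", list(nTotal = 120, nPositive = 30), seed = 1)
  expect_identical(bd$masks, bd2$masks)
})
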